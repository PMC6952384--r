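#' Fit a nearest shrunken centroid classifier
#'
#' Standard NSC estimator: per gene i and class k the standardised centroid
#' contrast is `d_ik = (xbar_ik - xbar_i) / (m_k * (s_i + s0))` with `s_i` the
#' pooled within-class SD, `s0` the median of the `s_i` (a variance-offset
#' guard), and `m_k = sqrt(1/n_k + 1/n)`. Soft-thresholding by `delta` gives
#' `d'_ik = sign(d_ik) * max(|d_ik| - delta, 0)`; class centroids are
#' reconstructed from the shrunken contrasts, and classification minimises the
#' discriminant `delta_k(x) = sum_i (x_i - xbar'_ik)^2 / (s_i + s0)^2 -
#' 2 log pi_k` with empirical class priors.
#'
#' @param x a [leat_expr] or numeric matrix (genes x samples).
#' @param labels per-sample class labels (>= 2 classes, each with >= 2
#'   samples).
#' @param delta non-negative shrinkage threshold.
#' @return object of class `nsc_model`: `genes`, `classes`, `centroid_overall`,
#'   `centroids`, `shrunken_centroids`, `s` (pooled SD), `s0`, `m_k`, `d`,
#'   `d_shrunk`, `priors`, `delta`, `survivors` (genes with a non-zero shrunken
#'   contrast in some class).
#' @export
nsc_fit <- function(x, labels, delta = 0) {
  m <- as_expr_values(x)
  if (delta < 0) stop("delta must be non-negative")
  y <- factor(labels)
  if (length(y) != ncol(m)) stop("one label per sample required")
  nk <- table(y)
  if (nlevels(y) < 2) stop("need >= 2 classes")
  if (any(nk < 2))
    stop("class(es) with a single sample: ",
         paste(names(nk)[nk < 2], collapse = ", "))
  n <- ncol(m)
  K <- nlevels(y)

  centroids <- vapply(levels(y), function(k)
    rowMeans(m[, y == k, drop = FALSE]), numeric(nrow(m)))
  overall <- rowMeans(m)
  within_ss <- rowSums((m - centroids[, as.integer(y), drop = FALSE])^2)
  s <- sqrt(within_ss / (n - K))
  s0 <- stats::median(s)
  if (s0 == 0) {
    # variance-offset guard: a zero median (many flat genes) would leave
    # zero-SD genes with an undefined contrast
    if (all(s == 0)) stop("every gene has zero within-class variance")
    s0 <- min(s[s > 0])
  }
  m_k <- sqrt(1 / as.numeric(nk) + 1 / n)
  names(m_k) <- levels(y)

  d <- sweep(centroids - overall, 1L, s + s0, "/")
  d <- sweep(d, 2L, m_k, "/")
  d_shrunk <- sign(d) * pmax(abs(d) - delta, 0)
  shrunken <- overall + sweep(sweep(d_shrunk, 1L, s + s0, "*"), 2L, m_k, "*")

  structure(list(genes = rownames(m), classes = levels(y),
                 centroid_overall = overall, centroids = centroids,
                 shrunken_centroids = shrunken, s = s, s0 = s0, m_k = m_k,
                 d = d, d_shrunk = d_shrunk,
                 priors = as.numeric(nk) / n, delta = delta,
                 survivors = rownames(m)[rowSums(d_shrunk != 0) > 0]),
            class = "nsc_model")
}

#' @export
print.nsc_model <- function(x, ...) {
  cat(sprintf("<nsc_model> %d genes, %d classes (%s), delta = %.4g, %d surviving genes\n",
              length(x$genes), length(x$classes),
              paste(x$classes, collapse = ", "), x$delta, length(x$survivors)))
  invisible(x)
}

#' Predict from a nearest shrunken centroid model
#'
#' @param object an `nsc_model`.
#' @param newdata a [leat_expr] or matrix over the model's genes.
#' @param type `"class"` (argmin of the discriminant, ties to the first
#'   class), `"posterior"` (softmax over `-discriminant/2`, rows sum to 1), or
#'   `"discriminant"`.
#' @param ... ignored.
#' @export
predict.nsc_model <- function(object, newdata,
                              type = c("class", "posterior", "discriminant"),
                              ...) {
  type <- match.arg(type)
  m <- as_expr_values(newdata)
  if (!identical(rownames(m), object$genes)) {
    if (!all(object$genes %in% rownames(m)))
      stop("newdata is missing model genes")
    m <- m[object$genes, , drop = FALSE]
  }
  w <- 1 / (object$s + object$s0)^2
  disc <- vapply(seq_along(object$classes), function(k) {
    colSums((m - object$shrunken_centroids[, k])^2 * w) -
      2 * log(object$priors[k])
  }, numeric(ncol(m)))
  disc <- matrix(disc, ncol = length(object$classes),
                 dimnames = list(colnames(m), object$classes))
  switch(type,
         discriminant = disc,
         class = factor(object$classes[apply(disc, 1L, which.min)],
                        levels = object$classes),
         posterior = {
           e <- exp(-(disc - apply(disc, 1L, min)) / 2)
           e / rowSums(e)
         })
}

default_delta_grid <- function(x, labels, n_delta = 30) {
  fit0 <- nsc_fit(x, labels, delta = 0)
  seq(0, max(abs(fit0$d)), length.out = n_delta)
}

#' Cross-validated NSC gene ranking
#'
#' Stratified `n_folds`-fold cross-validation over a shrinkage grid: the
#' threshold minimising the pooled held-out misclassification count is chosen.
#' When several thresholds tie (common when classes are cleanly separable, so
#' the error is 0 over a whole range), the default keeps the smallest tying
#' threshold: the densest signature, which preserves the per-gene scores that
#' downstream enrichment ranks on. `delta_tie = "sparsest"` instead keeps the
#' largest tying threshold (the most parsimonious classifier).
#' Within each fold the surviving genes are ranked by their largest absolute
#' shrunken contrast across classes (rank 1 = strongest); a gene's average rank
#' is taken over the folds in which it survived, and genes never surviving get
#' the sentinel rank `n_genes + 1`. A full-data fit at the selected threshold
#' supplies the per-class shrunken scores consumed by [rank_from_classifier()].
#'
#' @param x a [leat_expr] or numeric matrix.
#' @param labels per-sample class labels.
#' @param n_folds folds; reduced with a warning if the smallest class is
#'   smaller.
#' @param delta_grid thresholds to scan; default 30 evenly spaced values from
#'   0 to the largest unshrunken |d|.
#' @param delta_tie tie-break among thresholds with equal CV error:
#'   `"densest"` (smallest delta, default) or `"sparsest"` (largest delta).
#' @param seed integer seed for the fold assignment.
#' @return object of class `gene_ranking`: `avg_rank` (named per gene),
#'   `survival_folds` (folds in which each gene survived), `d_shrunk`
#'   (full-data per-class shrunken scores at the selected threshold),
#'   `delta_grid`, `delta` (selected), `cv_error` (per grid point),
#'   `cv_accuracy` (at the selection), `n_folds`, `model` (full-data
#'   `nsc_model`).
#' @export
nsc_cv_rank <- function(x, labels, n_folds = 5, delta_grid = NULL,
                        delta_tie = c("densest", "sparsest"), seed = NULL) {
  delta_tie <- match.arg(delta_tie)
  m <- as_expr_values(x)
  y <- factor(labels)
  nk <- table(y)
  if (min(nk) < n_folds) {
    n_folds <- max(2L, min(nk))
    warning("smallest class is below the fold count; reducing to ",
            n_folds, " folds")
  }
  if (is.null(delta_grid)) delta_grid <- default_delta_grid(m, y)
  if (length(delta_grid) == 0) stop("empty delta grid")
  delta_grid <- sort(delta_grid)
  if (!is.null(seed)) set.seed(seed)

  fold <- integer(length(y))
  for (k in levels(y)) {                       # stratified assignment
    idx <- sample(which(y == k))
    fold[idx] <- rep_len(seq_len(n_folds), length(idx))
  }

  errors <- matrix(0L, n_folds, length(delta_grid))
  fold_fits <- vector("list", n_folds)
  for (f in seq_len(n_folds)) {
    tr <- fold != f
    fit0 <- nsc_fit(m[, tr, drop = FALSE], y[tr], delta = 0)
    fold_fits[[f]] <- fit0
    for (gi in seq_along(delta_grid)) {
      fit <- shrink_model(fit0, delta_grid[gi])
      pred <- predict(fit, m[, !tr, drop = FALSE], type = "class")
      errors[f, gi] <- sum(pred != y[!tr])
    }
  }
  total_err <- colSums(errors)
  ties <- which(total_err == min(total_err))
  best <- if (delta_tie == "densest") min(ties) else max(ties)
  delta <- delta_grid[best]

  ng <- nrow(m)
  rank_sum <- stats::setNames(numeric(ng), rownames(m))
  n_surv <- stats::setNames(integer(ng), rownames(m))
  for (f in seq_len(n_folds)) {
    fit <- shrink_model(fold_fits[[f]], delta)
    score <- apply(abs(fit$d_shrunk), 1L, max)
    surv <- score > 0
    if (any(surv)) {
      r <- rank(-score[surv], ties.method = "average")
      rank_sum[names(r)] <- rank_sum[names(r)] + r
      n_surv[surv] <- n_surv[surv] + 1L
    }
  }
  avg_rank <- ifelse(n_surv > 0, rank_sum / pmax(n_surv, 1L), ng + 1)
  names(avg_rank) <- rownames(m)

  full <- nsc_fit(m, y, delta = delta)
  structure(list(avg_rank = avg_rank, survival_folds = n_surv,
                 d_shrunk = full$d_shrunk, delta_grid = delta_grid,
                 delta = delta, cv_error = stats::setNames(total_err, delta_grid),
                 cv_accuracy = 1 - min(total_err) / length(y),
                 n_folds = n_folds, model = full),
            class = "gene_ranking")
}

# re-threshold an nsc_model without re-estimating centroids/variances
shrink_model <- function(fit, delta) {
  fit$d_shrunk <- sign(fit$d) * pmax(abs(fit$d) - delta, 0)
  fit$shrunken_centroids <- fit$centroid_overall +
    sweep(sweep(fit$d_shrunk, 1L, fit$s + fit$s0, "*"), 2L, fit$m_k, "*")
  fit$delta <- delta
  fit$survivors <- fit$genes[rowSums(fit$d_shrunk != 0) > 0]
  fit
}

#' Per-sample subgroup affiliation and per-gene subclass scores
#'
#' The affiliation likelihood of a sample for class k is the softmax of
#' `-discriminant_k/2` from the fitted NSC model (rows sum to 1; a sample
#' sitting on a class's shrunken centroid with uniform priors is maximally
#' affiliated with it). The per-gene table reports each gene's best class (by
#' absolute shrunken contrast), its signed shrunken score, and — when a
#' [pairwise_de()] result is supplied — the matched one-vs-rest FDR q-value
#' plus `-log10(q)`, the scatterplot-ready pairing of effect and significance.
#'
#' @param model an `nsc_model`.
#' @param x a [leat_expr] or matrix over the model's genes.
#' @param de optional data.frame from [pairwise_de()].
#' @return list with `affiliation` (samples x classes) and `gene_scores`
#'   (data.frame: gene, class, score, and q/neg_log10_q when `de` is given).
#' @export
subclass_scores <- function(model, x, de = NULL) {
  if (!inherits(model, "nsc_model")) stop("`model` must be an nsc_model")
  aff <- predict(model, x, type = "posterior")
  best <- apply(abs(model$d_shrunk), 1L, which.max)
  gene_scores <- data.frame(
    gene = model$genes,
    class = model$classes[best],
    score = model$d_shrunk[cbind(seq_along(best), best)],
    stringsAsFactors = FALSE)
  if (!is.null(de)) {
    key <- paste(de$gene, de$subgroup)
    qs <- stats::setNames(de$q, key)
    gene_scores$q <- unname(qs[paste(gene_scores$gene, gene_scores$class)])
    gene_scores$neg_log10_q <- -log10(gene_scores$q)
  }
  list(affiliation = aff, gene_scores = gene_scores)
}
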