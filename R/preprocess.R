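#' Merge datasets over their shared gene space
#'
#' Intersects the gene sets of several expression matrices (exact ID match),
#' reorders genes to sorted ID order and concatenates samples. Each input keeps
#' its own batch labels; inputs that carry the default single batch are
#' relabelled `dataset<i>` so that the merged object distinguishes its sources.
#'
#' @param matrices a list of [leat_expr] objects (>= 1).
#' @return a merged [leat_expr].
#' @export
intersect_and_merge <- function(matrices) {
  if (!is.list(matrices) || length(matrices) == 0)
    stop("need a non-empty list of expression matrices")
  matrices <- lapply(matrices, function(m)
    if (inherits(m, "leat_expr")) m else leat_expr(m))
  shared <- Reduce(intersect, lapply(matrices, function(m) rownames(m$values)))
  if (length(shared) == 0) {
    nm <- paste(sprintf("dataset%d (%d genes)", seq_along(matrices),
                        vapply(matrices, function(m) nrow(m$values), 1L)),
                collapse = ", ")
    stop("empty gene intersection across: ", nm)
  }
  shared <- sort(shared)
  all_samples <- unlist(lapply(matrices, function(m) colnames(m$values)))
  if (anyDuplicated(all_samples))
    stop("duplicate sample IDs across datasets: ",
         paste(unique(all_samples[duplicated(all_samples)]), collapse = ", "))
  vals <- do.call(cbind, lapply(matrices, function(m)
    m$values[shared, , drop = FALSE]))
  batch <- unlist(lapply(seq_along(matrices), function(i) {
    b <- as.character(matrices[[i]]$batch)
    if (all(b == "batch1")) rep(paste0("dataset", i), length(b)) else b
  }))
  leat_expr(vals, batch = batch)
}

#' Row-standardise genes
#'
#' Centres every gene to mean 0 and scales to sample SD 1 (n - 1 denominator).
#' Zero-variance genes cannot be scaled and are dropped with a warning.
#'
#' @param x a [leat_expr] or numeric matrix (genes x samples).
#' @return object of the same kind as the input, with scaled rows.
#' @export
scale_genes <- function(x) {
  m <- as_expr_values(x)
  if (ncol(m) < 2) stop("scaling needs at least 2 samples")
  mu <- rowMeans(m)
  sdv <- sqrt(rowSums((m - mu)^2) / (ncol(m) - 1))
  keep <- sdv > 0
  if (!all(keep))
    warning(sprintf("dropping %d constant gene row(s): %s", sum(!keep),
                    paste(utils::head(rownames(m)[!keep], 5), collapse = ", ")))
  out <- (m[keep, , drop = FALSE] - mu[keep]) / sdv[keep]
  if (inherits(x, "leat_expr")) leat_expr(out, batch = as.character(x$batch))
  else out
}

#' Empirical-Bayes batch correction (location/scale model)
#'
#' Removes additive and multiplicative batch effects with the parametric
#' empirical-Bayes location/scale adjustment: (1) gene-wise standardisation
#' against a least-squares grand mean and pooled variance, (2) method-of-moments
#' estimation of a normal prior on the additive effects and an inverse-gamma
#' prior on the squared multiplicative effects across genes, (3) iterative
#' shrinkage of the per-(batch, gene) estimates to the EB posterior
#' (absolute change < `conv`, at most `max_iter` sweeps), (4) back-transform
#' `((standardised - gamma*) / delta*) * pooled SD + grand mean`.
#'
#' @param x a [leat_expr] with at least two batches of >= 2 samples each.
#' @param parametric only the parametric-prior variant is implemented; `FALSE`
#'   is rejected.
#' @param allow_single_batch if `TRUE`, a single-batch input is passed through
#'   unchanged (nothing to correct) instead of raising an error.
#' @param conv absolute convergence tolerance of the EB iteration.
#' @param max_iter iteration cap.
#' @return list with `corrected` (a [leat_expr], same dimensions as input) and
#'   `model` (class `batch_model`: `gamma_hat`/`delta_hat` per-(batch, gene)
#'   raw estimates, `gamma_star`/`delta_star` shrunken estimates, per-gene
#'   `grand_mean` and `pooled_var`, and the estimated prior hyperparameters).
#' @export
combat_correct <- function(x, parametric = TRUE, allow_single_batch = FALSE,
                           conv = 1e-4, max_iter = 100) {
  if (!parametric) stop("only parametric priors are implemented")
  if (!inherits(x, "leat_expr")) stop("`x` must be a leat_expr (batch labels required)")
  dat <- x$values
  batch <- droplevels(x$batch)
  nb <- table(batch)
  if (nlevels(batch) < 2) {
    if (allow_single_batch)
      return(list(corrected = x, model = NULL))
    stop("need >= 2 batches; pass allow_single_batch = TRUE to skip correction")
  }
  if (any(nb < 2))
    stop("batch(es) with < 2 samples: ",
         paste(names(nb)[nb < 2], collapse = ", "),
         "; exclude them or merge them upstream")

  levs <- levels(batch)
  n <- ncol(dat)
  batch_means <- vapply(levs, function(b)
    rowMeans(dat[, batch == b, drop = FALSE]), numeric(nrow(dat)))
  grand_mean <- as.vector(batch_means %*% (as.numeric(nb) / n))
  resid <- dat - batch_means[, as.integer(batch), drop = FALSE]
  pooled_var <- rowSums(resid^2) / n
  if (any(pooled_var == 0))
    stop("gene(s) with zero pooled variance cannot be standardised: ",
         paste(utils::head(rownames(dat)[pooled_var == 0], 5), collapse = ", "))
  s_data <- (dat - grand_mean) / sqrt(pooled_var)

  gamma_hat <- vapply(levs, function(b)
    rowMeans(s_data[, batch == b, drop = FALSE]), numeric(nrow(dat)))
  delta_hat <- vapply(levs, function(b)
    apply(s_data[, batch == b, drop = FALSE], 1L, stats::var),
    numeric(nrow(dat)))

  # method-of-moments hyperparameters per batch
  gamma_bar <- colMeans(gamma_hat)
  tau2 <- apply(gamma_hat, 2L, stats::var)
  d_bar <- colMeans(delta_hat)
  d_s2 <- apply(delta_hat, 2L, stats::var)
  a_prior <- (2 * d_s2 + d_bar^2) / d_s2
  b_prior <- (d_bar * d_s2 + d_bar^3) / d_s2

  gamma_star <- gamma_hat
  delta_star <- delta_hat
  for (bi in seq_along(levs)) {
    jb <- batch == levs[bi]
    nbi <- sum(jb)
    g_old <- gamma_hat[, bi]
    d_old <- delta_hat[, bi]
    sb <- s_data[, jb, drop = FALSE]
    for (it in seq_len(max_iter)) {
      g_new <- (nbi * tau2[bi] * gamma_hat[, bi] + d_old * gamma_bar[bi]) /
        (nbi * tau2[bi] + d_old)
      sum2 <- rowSums((sb - g_new)^2)
      d_new <- (0.5 * sum2 + b_prior[bi]) / (nbi / 2 + a_prior[bi] - 1)
      if (max(abs(g_new - g_old), abs(d_new - d_old)) < conv) {
        g_old <- g_new; d_old <- d_new
        break
      }
      g_old <- g_new; d_old <- d_new
    }
    gamma_star[, bi] <- g_old
    delta_star[, bi] <- d_old
  }

  adj <- s_data
  for (bi in seq_along(levs)) {
    jb <- batch == levs[bi]
    adj[, jb] <- (s_data[, jb, drop = FALSE] - gamma_star[, bi]) /
      sqrt(delta_star[, bi])
  }
  adj <- adj * sqrt(pooled_var) + grand_mean

  model <- structure(
    list(batches = levs, gamma_hat = gamma_hat, delta_hat = delta_hat,
         gamma_star = gamma_star, delta_star = delta_star,
         grand_mean = grand_mean, pooled_var = pooled_var,
         priors = list(gamma_bar = gamma_bar, tau2 = tau2,
                       a = a_prior, b = b_prior)),
    class = "batch_model")
  list(corrected = leat_expr(adj, batch = as.character(x$batch)),
       model = model)
}
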