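#' Sample-by-sample dissimilarity
#'
#' Default metric is one minus the Pearson correlation of sample expression
#' profiles (scale-free after gene standardisation, the transcriptomics
#' convention); Euclidean distance between sample columns is available as an
#' option.
#'
#' @param x a [leat_expr] or numeric matrix (genes x samples).
#' @param metric `"pearson"` (1 - correlation) or `"euclidean"`.
#' @return symmetric distance matrix (samples x samples) with zero diagonal and
#'   a `"metric"` attribute.
#' @export
expr_distance <- function(x, metric = c("pearson", "euclidean")) {
  metric <- match.arg(metric)
  m <- as_expr_values(x)
  d <- switch(metric,
              pearson = 1 - stats::cor(m),
              euclidean = as.matrix(stats::dist(t(m))))
  d <- (d + t(d)) / 2
  diag(d) <- 0
  attr(d, "metric") <- metric
  d
}

check_distance <- function(d) {
  d <- as.matrix(d)
  if (nrow(d) != ncol(d) || max(abs(d - t(d))) > 1e-8)
    stop("distance input must be a symmetric matrix")
  if (any(d < -1e-12)) stop("distances must be non-negative")
  diag(d) <- 0
  d
}

# total cost of a candidate medoid set, vectorised over columns
pam_cost <- function(d, med) {
  sum(do.call(pmin, lapply(med, function(m) d[m, ])))
}

#' Partitioning around medoids (k-medoids)
#'
#' Deterministic BUILD + SWAP k-medoids: BUILD greedily adds the medoid that
#' most reduces total dissimilarity; SWAP repeatedly applies the single best
#' medoid/non-medoid exchange while the total cost strictly decreases. Ties are
#' broken to the lowest sample index throughout, so the result is fully
#' reproducible from the distance matrix alone. Samples are assigned to the
#' nearest medoid (ties to the lowest-index medoid) and clusters are numbered
#' by increasing medoid index.
#'
#' @param d symmetric distance matrix (or `dist`), e.g. from [expr_distance()].
#' @param k number of clusters, `1 <= k <= n`.
#' @param seed unused (the algorithm is deterministic); accepted for interface
#'   symmetry with the stochastic steps of the pipeline.
#' @return object of class `cluster_result`: `k`, `assignment` (named integer
#'   1..k), `medoids` (sample IDs), `cost`, per-sample `silhouette`,
#'   `mean_silhouette`, and `core_mask` (silhouette >= 0). Silhouette fields
#'   are `NULL` when `k` is 1 or n.
#' @export
pam_kmedoids <- function(d, k, seed = NULL) {
  d <- check_distance(d)
  n <- nrow(d)
  if (k < 1 || k > n) stop("k must lie in 1..n_samples")
  ids <- rownames(d)
  if (is.null(ids)) ids <- as.character(seq_len(n))

  # BUILD
  cost0 <- rowSums(d)
  med <- which.min(cost0)                       # which.min takes lowest index on ties
  dn <- d[med, ]
  while (length(med) < k) {
    cand_cost <- rowSums(pmin(d, rep(dn, each = n)))
    cand_cost[med] <- Inf
    med <- c(med, which.min(cand_cost))
    dn <- pmin(dn, d[med[length(med)], ])
  }

  # SWAP (best-improvement)
  cur_cost <- sum(dn)
  if (k < n && k > 1) {
    repeat {
      best <- list(cost = cur_cost, m = NA, h = NA)
      for (mi in seq_along(med)) {
        others <- med[-mi]
        dn_others <- if (length(others))
          do.call(pmin, lapply(others, function(m) d[m, ]))
        else rep(Inf, n)
        cand_cost <- rowSums(pmin(d, rep(dn_others, each = n)))
        cand_cost[med] <- Inf
        h <- which.min(cand_cost)
        if (cand_cost[h] < best$cost - 1e-12) best <- list(cost = cand_cost[h], m = mi, h = h)
      }
      if (is.na(best$m)) break
      med[best$m] <- best$h
      cur_cost <- best$cost
    }
  } else if (k == 1 && n > 1) {
    # single medoid: global optimum directly
    med <- which.min(cost0)
    cur_cost <- cost0[med]
  }

  med <- sort(med)
  dm <- d[med, , drop = FALSE]
  assignment <- apply(dm, 2L, which.min)        # ties -> lowest-index medoid
  assignment[med] <- seq_along(med)             # medoids belong to their own cluster
  names(assignment) <- ids
  cur_cost <- sum(dm[cbind(assignment, seq_len(n))])

  sil <- NULL
  if (k >= 2 && length(unique(assignment)) >= 2) {
    sil <- silhouette_widths(d, assignment)
    names(sil) <- ids
  }
  structure(list(k = k, assignment = assignment, medoids = ids[med],
                 cost = cur_cost, silhouette = sil,
                 mean_silhouette = if (is.null(sil)) NULL else mean(sil),
                 core_mask = if (is.null(sil)) NULL else sil >= 0),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("<cluster_result> k = %d, sizes: %s, cost = %.4g%s\n", x$k,
              paste(tabulate(x$assignment, x$k), collapse = "/"), x$cost,
              if (!is.null(x$mean_silhouette))
                sprintf(", mean silhouette = %.3f", x$mean_silhouette) else ""))
  invisible(x)
}

#' Per-sample silhouette widths
#'
#' `s(i) = (b(i) - a(i)) / max(a(i), b(i))` with `a(i)` the mean dissimilarity
#' to the sample's own cluster (excluding itself) and `b(i)` the smallest mean
#' dissimilarity to any other cluster. Members of singleton clusters get 0 by
#' convention.
#'
#' @param d symmetric distance matrix or `dist`.
#' @param assignment integer/factor cluster labels, one per sample.
#' @return numeric vector of widths in \[-1, 1\].
#' @export
silhouette_widths <- function(d, assignment) {
  d <- check_distance(d)
  n <- nrow(d)
  if (length(assignment) != n) stop("one cluster label per sample required")
  cl <- as.integer(factor(assignment))
  k <- max(cl)
  if (k < 2) stop("silhouette needs >= 2 clusters")
  sizes <- tabulate(cl, k)
  # mean distance from every sample to every cluster
  msum <- vapply(seq_len(k), function(c) rowSums(d[, cl == c, drop = FALSE]),
                 numeric(n))
  s <- numeric(n)
  for (i in seq_len(n)) {
    ci <- cl[i]
    if (sizes[ci] == 1) { s[i] <- 0; next }
    a <- msum[i, ci] / (sizes[ci] - 1)
    b <- min(msum[i, -ci] / sizes[-ci])
    s[i] <- if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }
  s
}
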