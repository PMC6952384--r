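#' Select the most variable genes
#'
#' Keeps the `n` genes with the largest variance across samples (sample
#' variance, n - 1); ties are broken by gene-ID sort order. Clustering operates
#' on this reduced matrix, which concentrates the between-subgroup signal.
#'
#' @param x a [leat_expr] or numeric matrix.
#' @param n number of genes to keep.
#' @return same kind of object as the input, rows ordered by decreasing
#'   variance.
#' @export
top_variable_genes <- function(x, n = 1000) {
  m <- as_expr_values(x)
  if (n <= 0) stop("n must be positive")
  if (n > nrow(m)) stop("n exceeds the gene count")
  v <- rowSums((m - rowMeans(m))^2) / (ncol(m) - 1)
  sel <- order(-v, rownames(m))[seq_len(n)]
  if (inherits(x, "leat_expr")) x[sel, ] else m[sel, , drop = FALSE]
}

#' Choose the cluster number by mean silhouette width
#'
#' Runs [pam_kmedoids()] for every k in `k_min..k_max` on the chosen
#' dissimilarity and returns the k with the highest mean silhouette width
#' (ties to the smaller k). When even the best mean silhouette is below
#' `structure_threshold` the result is flagged as showing no reliable cluster
#' structure.
#'
#' @param x a [leat_expr] or numeric matrix (genes x samples), typically
#'   already batch-corrected, scaled, and reduced with [top_variable_genes()].
#' @param k_min,k_max k range to scan (`k_max < n_samples`).
#' @param metric passed to [expr_distance()].
#' @param structure_threshold mean-silhouette level below which the cohort is
#'   flagged unstructured.
#' @param seed unused (deterministic); kept for pipeline interface symmetry.
#' @return list: `k` (selected), `mean_silhouette` (named per-k vector),
#'   `no_structure` flag, `best` (the selected `cluster_result`), `distance`.
#' @export
select_k_by_silhouette <- function(x, k_min = 2, k_max = 10,
                                   metric = "pearson",
                                   structure_threshold = 0.05, seed = NULL) {
  d <- expr_distance(x, metric)
  if (k_max >= nrow(d)) stop("k_max must be below the sample count")
  ks <- seq.int(k_min, k_max)
  fits <- lapply(ks, function(k) pam_kmedoids(d, k))
  msil <- vapply(fits, function(f) f$mean_silhouette, numeric(1))
  names(msil) <- ks
  best <- which.max(msil)                       # ties -> smaller k
  list(k = ks[best], mean_silhouette = msil,
       no_structure = max(msil) < structure_threshold,
       best = fits[[best]], distance = d)
}

#' Core-sample filtering by silhouette sign
#'
#' Samples with negative silhouette width sit closer (on average) to another
#' cluster than to their own; removing them sharpens the subgroup definition.
#'
#' @param r a `cluster_result` from [pam_kmedoids()] with silhouettes.
#' @return list with `retained` (sample IDs with s >= 0) and `excluded`
#'   (data.frame of dropped IDs, their cluster and silhouette width).
#' @export
filter_core_samples <- function(r) {
  if (!inherits(r, "cluster_result") || is.null(r$silhouette))
    stop("need a cluster_result with silhouette widths (k >= 2)")
  keep <- r$silhouette >= 0
  if (!any(keep)) stop("no core samples: every silhouette width is negative")
  excluded <- data.frame(sample_id = names(r$silhouette)[!keep],
                         cluster = unname(r$assignment[!keep]),
                         silhouette = unname(r$silhouette[!keep]),
                         stringsAsFactors = FALSE)
  if (nrow(excluded))
    message(sprintf("excluding %d non-core sample(s): %s", nrow(excluded),
                    paste(sprintf("%s (%.3f)", excluded$sample_id,
                                  excluded$silhouette), collapse = ", ")))
  list(retained = names(r$silhouette)[keep], excluded = excluded)
}

#' Consensus clustering over subsampled repetitions
#'
#' For each k, repeatedly subsamples `ceiling(subsample_frac * n)` samples
#' without replacement, clusters them with [pam_kmedoids()], and tallies how
#' often each sample pair lands in the same cluster relative to how often it
#' was co-sampled. Stability per k is summarised by the empirical CDF of the
#' consensus values (upper triangle, 101 grid points on \[0, 1\]) and its
#' trapezoid area. Both the raw area and the relative change in area between
#' consecutive k are reported: the raw area tends to grow with k simply
#' because more pairs are split, so the change in area is the more
#' conventional selector; `selected_k` follows the raw-area maximum and
#' `selected_k_delta` the last k with a substantial area increase.
#'
#' @param x a [leat_expr] or numeric matrix.
#' @param k_min,k_max k range.
#' @param reps subsampling repetitions (>= 2).
#' @param subsample_frac fraction of samples drawn per repetition.
#' @param metric passed to [expr_distance()].
#' @param seed integer seed for the subsampling.
#' @param delta_threshold relative area increase below which adding a cluster
#'   is considered uninformative (used by `selected_k_delta`): an extra
#'   cluster must improve the stability area by at least this fraction to
#'   count as real structure.
#' @return list of class `consensus_result`: `consensus` (per-k matrices),
#'   `cdf_grid`, `cdf` (per-k), `area` (named per-k), `delta_area`,
#'   `selected_k`, `selected_k_delta`, `never_cosampled` counts.
#' @export
consensus_cluster <- function(x, k_min = 2, k_max = 10, reps = 100,
                              subsample_frac = 0.8, metric = "pearson",
                              seed = NULL, delta_threshold = 0.1) {
  if (reps < 2) stop("reps must be >= 2")
  if (subsample_frac <= 0 || subsample_frac > 1)
    stop("subsample_frac must lie in (0, 1]")
  d <- expr_distance(x, metric)
  n <- nrow(d)
  m <- ceiling(subsample_frac * n)
  if (m < k_max) stop("subsample too small for k_max clusters")
  if (!is.null(seed)) set.seed(seed)
  ks <- seq.int(k_min, k_max)
  subsets <- lapply(seq_len(reps), function(r) sort(sample.int(n, m)))

  co_sampled <- matrix(0, n, n)
  for (idx in subsets) co_sampled[idx, idx] <- co_sampled[idx, idx] + 1

  grid <- seq(0, 1, length.out = 101)
  consensus <- cdfs <- list()
  area <- numeric(length(ks))
  for (ki in seq_along(ks)) {
    co_clustered <- matrix(0, n, n)
    for (idx in subsets) {
      cl <- pam_kmedoids(d[idx, idx], ks[ki])$assignment
      same <- outer(cl, cl, "==")
      co_clustered[idx, idx] <- co_clustered[idx, idx] + same
    }
    cons <- ifelse(co_sampled > 0, co_clustered / pmax(co_sampled, 1), 0)
    diag(cons) <- 1
    dimnames(cons) <- dimnames(d)
    vals <- cons[upper.tri(cons)]
    cdf <- stats::ecdf(vals)(grid)
    area[ki] <- sum(diff(grid) * (utils::head(cdf, -1) + utils::tail(cdf, -1)) / 2)
    consensus[[as.character(ks[ki])]] <- cons
    cdfs[[as.character(ks[ki])]] <- cdf
  }
  names(area) <- ks
  delta <- c(area[1], diff(area) / pmax(area[-length(area)], .Machine$double.eps))
  names(delta) <- ks
  sel_delta <- if (any(delta[-1] > delta_threshold))
    ks[max(which(delta > delta_threshold))] else ks[1]
  structure(list(consensus = consensus, cdf_grid = grid, cdf = cdfs,
                 area = area, delta_area = delta,
                 selected_k = ks[which.max(area)],
                 selected_k_delta = sel_delta,
                 never_cosampled = sum(co_sampled[upper.tri(co_sampled)] == 0)),
            class = "consensus_result")
}
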