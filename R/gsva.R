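#' Per-sample gene set variation scores
#'
#' Unsupervised single-sample enrichment: (1) each gene's expression is turned
#' into a kernel-smoothed cumulative density across samples (Gaussian kernel,
#' bandwidth = gene SD / 4); (2) within each sample, genes are ranked by that
#' density (largest first) and the ranks are symmetrised around the list
#' midpoint, `|N/2 - rank|`; (3) for each set and sample a weighted
#' Kolmogorov-Smirnov random walk over the density-ordered gene list is taken,
#' with hit increments proportional to the symmetrised rank raised to `tau`
#' and miss decrements of `1/(N - |S|)`. The default score is the difference
#' between the maximum positive and maximum negative walk deviations
#' (`stat = "diff"`); `stat = "maxdev"` returns the single largest signed
#' deviation.
#'
#' @param x a [leat_expr] or numeric matrix (genes x samples, >= 3 samples).
#' @param sets a `gene_set_collection` or named list of gene vectors.
#' @param tau rank-weight exponent.
#' @param kernel only `"gaussian"` is implemented.
#' @param stat score form, `"diff"` or `"maxdev"`.
#' @param min_size,max_size set-size bounds after universe filtering.
#' @return matrix of scores, gene sets x samples.
#' @export
gsva_scores <- function(x, sets, tau = 1, kernel = "gaussian",
                        stat = c("diff", "maxdev"),
                        min_size = 5, max_size = 500) {
  stat <- match.arg(stat)
  kernel <- match.arg(kernel, "gaussian")
  m <- as_expr_values(x)
  if (ncol(m) < 3) stop("GSVA needs at least 3 samples")
  sdv <- apply(m, 1L, stats::sd)
  if (any(sdv == 0)) {
    warning(sprintf("dropping %d constant gene row(s)", sum(sdv == 0)))
    m <- m[sdv > 0, , drop = FALSE]
    sdv <- sdv[sdv > 0]
  }
  n_genes <- nrow(m)
  n_samp <- ncol(m)
  sets <- filter_gene_sets(sets, rownames(m), min_size, max_size)

  # kernel CDF per gene across samples
  z <- m
  for (i in seq_len(n_genes)) {
    xi <- m[i, ]
    z[i, ] <- rowMeans(stats::pnorm(outer(xi, xi, "-") / (sdv[i] / 4)))
  }

  scores <- matrix(NA_real_, length(sets), n_samp,
                   dimnames = list(names(sets), colnames(m)))
  set_idx <- lapply(sets, match, rownames(m))
  for (j in seq_len(n_samp)) {
    ord <- order(z[, j], decreasing = TRUE)
    r_sym <- abs(n_genes / 2 - rank(-z[, j], ties.method = "first"))^tau
    hit_rank <- match(seq_len(n_genes), ord)       # position of gene i in the walk
    for (si in seq_along(sets)) {
      idx <- set_idx[[si]]
      s <- length(idx)
      hits <- logical(n_genes)
      hits[hit_rank[idx]] <- TRUE
      w <- r_sym[ord]
      inc <- ifelse(hits, w, 0)
      walk <- cumsum(inc) / sum(w[hits]) -
        cumsum(!hits) / (n_genes - s)
      scores[si, j] <- if (stat == "diff")
        max(c(0, walk)) + min(c(0, walk))
      else
        walk[which.max(abs(walk))]
    }
  }
  scores
}
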