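#' One-vs-rest differential expression (Welch t)
#'
#' For every gene and every subgroup, a two-sided Welch two-sample t-test of
#' the subgroup against all remaining samples, with Benjamini-Hochberg
#' adjustment applied within each subgroup's p-value vector. Genes that are
#' constant in both groups carry no information and get p = 1 by convention
#' (counted in a message).
#'
#' @param x a [leat_expr] or numeric matrix (genes x samples).
#' @param labels per-sample subgroup labels (each subgroup >= 2 samples).
#' @return data.frame with one row per (gene, subgroup): `mean_in`,
#'   `mean_rest`, `t`, `df`, `p`, `q`. The sign of `t` follows
#'   `mean_in - mean_rest`.
#' @export
pairwise_de <- function(x, labels) {
  m <- as_expr_values(x)
  y <- factor(labels)
  nk <- table(y)
  if (any(nk < 2) || nlevels(y) < 2)
    stop("every subgroup needs >= 2 samples (and >= 2 subgroups)")
  out <- vector("list", nlevels(y))
  n_degenerate <- 0L
  for (ki in seq_len(nlevels(y))) {
    sel <- y == levels(y)[ki]
    n1 <- sum(sel); n0 <- sum(!sel)
    m1 <- rowMeans(m[, sel, drop = FALSE])
    m0 <- rowMeans(m[, !sel, drop = FALSE])
    v1 <- rowSums((m[, sel, drop = FALSE] - m1)^2) / (n1 - 1)
    v0 <- rowSums((m[, !sel, drop = FALSE] - m0)^2) / (n0 - 1)
    se2 <- v1 / n1 + v0 / n0
    tstat <- ifelse(se2 > 0, (m1 - m0) / sqrt(se2), 0)
    df <- ifelse(se2 > 0,
                 se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v0 / n0)^2 / (n0 - 1)),
                 NA_real_)
    p <- ifelse(se2 > 0, 2 * stats::pt(-abs(tstat), df), 1)
    n_degenerate <- n_degenerate + sum(se2 == 0)
    out[[ki]] <- data.frame(gene = rownames(m), subgroup = levels(y)[ki],
                            mean_in = m1, mean_rest = m0, t = tstat, df = df,
                            p = p, q = stats::p.adjust(p, "BH"),
                            row.names = NULL, stringsAsFactors = FALSE)
  }
  if (n_degenerate > 0)
    message(n_degenerate,
            " (gene, subgroup) test(s) had zero variance in both groups; p set to 1")
  do.call(rbind, out)
}
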