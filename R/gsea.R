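#' Per-subgroup ranking from the classifier
#'
#' Extracts the signed shrunken centroid contrasts of one subgroup from a
#' cross-validated [nsc_cv_rank()] result; genes shrunk to zero (non-survivors)
#' score 0. This vector is the pre-ranked input for [gsea_preranked()].
#'
#' @param ranking a `gene_ranking` from [nsc_cv_rank()].
#' @param subgroup one of the fitted class labels.
#' @return named numeric vector of per-gene scores.
#' @export
rank_from_classifier <- function(ranking, subgroup) {
  if (!inherits(ranking, "gene_ranking"))
    stop("`ranking` must come from nsc_cv_rank()")
  if (!subgroup %in% colnames(ranking$d_shrunk))
    stop("unknown subgroup: ", subgroup, " (have: ",
         paste(colnames(ranking$d_shrunk), collapse = ", "), ")")
  stats::setNames(ranking$d_shrunk[, subgroup], rownames(ranking$d_shrunk))
}

# ES of one set given the score-sorted list. `w_abs` are |score|^weight in
# sorted order, `pos` the (sorted ascending) list positions of the set members.
# Sets whose members all carry zero weight fall back to unweighted hits.
gsea_es <- function(w_abs, pos, n) {
  s <- length(pos)
  w <- w_abs[pos]
  if (sum(w) == 0) w <- rep(1, s)
  ms <- 1 / (n - s)
  cw <- cumsum(w) / sum(w)
  before <- c(0, cw[-s]) - (pos - seq_len(s)) * ms   # just before each hit
  after <- cw - (pos - seq_len(s)) * ms              # just after each hit
  es_pos <- max(after)
  es_neg <- min(c(before, 0))
  if (es_pos >= -es_neg)
    list(es = es_pos, edge = seq_len(which.max(after)))
  else
    list(es = es_neg, edge = seq.int(which.min(before), s))
}

#' Permutation-based pre-ranked GSEA
#'
#' Genes are sorted by score (descending); the running-sum statistic increments
#' by `|score|^weight / sum_hits |score|^weight` at set members and decrements
#' by `1/(N - |S|)` elsewhere; the enrichment score (ES) is the signed extreme
#' deviation. The null is built by gene-label permutation (random placement of
#' the set on the ranked list); the nominal p-value is
#' `(1 + #direction-consistent permutation ES at least as extreme) /
#' (n_perm + 1)`. NES divides the ES by the mean same-sign permutation ES, and
#' the FDR q-value follows the sign-stratified pooled-NES convention
#' (`fdr = "BH"` switches to plain Benjamini-Hochberg on the nominal p).
#' Sets whose members all score exactly zero carry no rank information; their
#' hits are treated as unweighted (the `weight = 0` increment), observed and
#' permuted alike.
#'
#' @param scores named per-gene scores covering the universe (ties keep input
#'   order; an all-zero vector is rejected as a degenerate ranking).
#' @param sets a `gene_set_collection` or named list of gene vectors.
#' @param weight running-sum exponent (1 = classic weighted GSEA; 0 =
#'   Kolmogorov-Smirnov).
#' @param n_perm number of permutations.
#' @param seed integer seed.
#' @param min_size,max_size set-size bounds after restriction to the universe.
#' @param fdr `"gsea"` (sign-stratified) or `"BH"`.
#' @return data.frame, one row per analysed set: `set`, `size`, `es`, `nes`,
#'   `p`, `q`, `leading_edge` (list column of gene IDs).
#' @export
gsea_preranked <- function(scores, sets, weight = 1, n_perm = 1000,
                           seed = NULL, min_size = 5, max_size = 500,
                           fdr = c("gsea", "BH")) {
  fdr <- match.arg(fdr)
  if (length(scores) == 0) stop("empty ranking")
  if (is.null(names(scores))) stop("scores must be named by gene ID")
  if (all(scores == 0)) stop("degenerate ranking: all scores are zero")
  sets <- filter_gene_sets(sets, names(scores), min_size, max_size)
  n <- length(scores)
  if (any(lengths(sets) >= n))
    stop("gene set spans the whole universe; miss decrement undefined")
  ord <- order(scores, decreasing = TRUE)
  sorted_names <- names(scores)[ord]
  w_abs <- abs(scores[ord])^weight
  if (!is.null(seed)) set.seed(seed)

  res <- lapply(names(sets), function(nm) {
    pos <- sort(match(intersect(sets[[nm]], sorted_names), sorted_names))
    obs <- gsea_es(w_abs, pos, n)
    s <- length(pos)
    perm_es <- vapply(seq_len(n_perm), function(i)
      gsea_es(w_abs, sort(sample.int(n, s)), n)$es, numeric(1))
    p <- if (obs$es >= 0)
      (1 + sum(perm_es >= obs$es)) / (n_perm + 1)
    else
      (1 + sum(perm_es <= obs$es)) / (n_perm + 1)
    same_sign <- if (obs$es >= 0) perm_es[perm_es >= 0] else perm_es[perm_es < 0]
    nes <- if (length(same_sign)) obs$es / mean(abs(same_sign)) else NA_real_
    # permutation NES on both sides, for the pooled FDR
    pos_mean <- mean(perm_es[perm_es >= 0])
    neg_mean <- mean(abs(perm_es[perm_es < 0]))
    perm_nes <- ifelse(perm_es >= 0, perm_es / pos_mean, perm_es / neg_mean)
    list(set = nm, size = s, es = obs$es, nes = nes, p = p,
         leading_edge = sorted_names[pos[obs$edge]], perm_nes = perm_nes)
  })

  out <- data.frame(set = vapply(res, `[[`, "", "set"),
                    size = vapply(res, `[[`, 1L, "size"),
                    es = vapply(res, `[[`, 1, "es"),
                    nes = vapply(res, `[[`, 1, "nes"),
                    p = vapply(res, `[[`, 1, "p"),
                    stringsAsFactors = FALSE)
  out$q <- if (fdr == "BH") stats::p.adjust(out$p, "BH")
           else gsea_fdr(out$nes, unlist(lapply(res, `[[`, "perm_nes")))
  out$leading_edge <- I(lapply(res, `[[`, "leading_edge"))
  out
}

# sign-stratified FDR: for each observed NES, the fraction of pooled
# permutation NES at least as extreme on its side, divided by the fraction of
# observed NES at least as extreme, capped at 1.
gsea_fdr <- function(nes, perm_nes) {
  perm_nes <- perm_nes[is.finite(perm_nes)]
  vapply(nes, function(x) {
    if (is.na(x)) return(NA_real_)
    if (x >= 0) {
      num_d <- sum(perm_nes >= 0); den_d <- sum(nes >= 0, na.rm = TRUE)
      num <- if (num_d) sum(perm_nes >= x) / num_d else 0
      den <- sum(nes >= x, na.rm = TRUE) / den_d
    } else {
      num_d <- sum(perm_nes < 0); den_d <- sum(nes < 0, na.rm = TRUE)
      num <- if (num_d) sum(perm_nes <= x) / num_d else 0
      den <- sum(nes <= x, na.rm = TRUE) / den_d
    }
    min(1, num / max(den, .Machine$double.eps))
  }, numeric(1))
}
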