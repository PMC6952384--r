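#' Synthetic multi-batch LEAT cohort configuration
#'
#' Parameters of the synthetic-cohort generator. Defaults emulate the merged
#' study cohort: four transcriptional subgroups of sizes 11/18/13/11 spread
#' over three dataset batches, 100 marker genes per subgroup shifted by 1.5
#' (standardised units) against a residual SD of 1, additive and multiplicative
#' batch effects applied to all genes, and subgroup-coupled clinical
#' covariates — an elevated recurrence rate (42%) and BRAF-alteration
#' prevalence (71%) in subgroup 2, and a 4-fold progression hazard for
#' BRAF-mutant samples.
#'
#' @param n_genes number of genes.
#' @param subgroup_sizes integer vector of per-subgroup sample counts.
#' @param n_batches number of batches (datasets) samples are assigned to.
#' @param markers_per_subgroup marker genes planted per subgroup (pairwise
#'   disjoint blocks).
#' @param marker_effect additive shift of a subgroup's markers in its samples,
#'   in units of the residual SD.
#' @param batch_shift_sd SD of the additive per-(batch, gene) effect.
#' @param batch_scale_range bounds of the uniform multiplicative
#'   per-(batch, gene) noise-scale effect.
#' @param noise_sd residual (within-subgroup) SD.
#' @param recurrence_prob per-subgroup tumor-recurrence probabilities.
#' @param braf_prob per-subgroup BRAF-alteration probabilities.
#' @param braf_pfs_hazard_ratio hazard multiplier on progression-free survival
#'   for BRAF-altered samples.
#' @param n_outliers unstructured (marker-free, pure-noise) samples appended to
#'   emulate the pre-filter cohort; they carry batch effects but no subgroup
#'   signal and are labelled `"outlier"` in the ground truth.
#' @param seed integer seed; identical seed and configuration give
#'   bitwise-identical output.
#' @return a list of class `cohort_config`.
#' @export
cohort_config <- function(n_genes = 5000,
                          subgroup_sizes = c(11, 18, 13, 11),
                          n_batches = 3,
                          markers_per_subgroup = 100,
                          marker_effect = 1.5,
                          batch_shift_sd = 0.5,
                          batch_scale_range = c(0.8, 1.25),
                          noise_sd = 1,
                          recurrence_prob = c(0.09, 0.42, 0.075, 0),
                          braf_prob = c(0, 0.71, 0.08, 0),
                          braf_pfs_hazard_ratio = 4,
                          n_outliers = 0,
                          seed = 1) {
  cfg <- list(n_genes = n_genes, subgroup_sizes = as.integer(subgroup_sizes),
              n_batches = n_batches,
              markers_per_subgroup = markers_per_subgroup,
              marker_effect = marker_effect, batch_shift_sd = batch_shift_sd,
              batch_scale_range = batch_scale_range, noise_sd = noise_sd,
              recurrence_prob = recurrence_prob, braf_prob = braf_prob,
              braf_pfs_hazard_ratio = braf_pfs_hazard_ratio,
              n_outliers = as.integer(n_outliers), seed = as.integer(seed))
  class(cfg) <- "cohort_config"
  validate_cohort_config(cfg)
  cfg
}

validate_cohort_config <- function(cfg) {
  k <- length(cfg$subgroup_sizes)
  if (sum(cfg$subgroup_sizes) == 0)
    stop("subgroup_sizes must sum to a positive sample count")
  if (cfg$markers_per_subgroup * k > cfg$n_genes)
    stop("marker blocks do not fit: markers_per_subgroup * n_subgroups > n_genes")
  for (p in list(cfg$recurrence_prob, cfg$braf_prob)) {
    if (length(p) != k) stop("per-subgroup probability vectors must match subgroup count")
    if (any(p < 0 | p > 1)) stop("probabilities must lie in [0, 1]")
  }
  if (cfg$noise_sd < 0 || cfg$batch_shift_sd < 0)
    stop("SD parameters must be non-negative")
  invisible(cfg)
}

#' Generate a synthetic multi-batch cohort with planted subgroups
#'
#' Expression for gene g in sample j is
#' `baseline(g) + marker_effect * [g is a marker of subgroup(j)] +
#' gamma(batch(j), g) + delta(batch(j), g) * eps`, with `eps ~ N(0, noise_sd^2)`,
#' `gamma ~ N(0, batch_shift_sd^2)` additive and
#' `delta ~ U(batch_scale_range)` multiplicative batch effects drawn once per
#' (batch, gene). Batches are assigned to samples at random, independent of
#' subgroup. Clinical covariates are drawn per subgroup; progression-free
#' survival times are exponential with the configured hazard multiplier for
#' BRAF-altered samples and administratively censored at the 75th percentile
#' of the simulated event times.
#'
#' @param config a [cohort_config].
#' @return a list with elements
#'   * `expr`: [leat_expr], genes x samples with batch labels;
#'   * `clinical`: data.frame (sample_id, batch, histology, age, engel,
#'     recurrence, braf, pfs_time, pfs_event);
#'   * `truth`: list with per-sample `subgroup` (factor; `"outlier"` for
#'     unstructured samples), `batch`, and `markers` (list of per-subgroup
#'     marker gene IDs).
#' @export
simulate_cohort <- function(config = cohort_config()) {
  validate_cohort_config(config)
  set.seed(config$seed)
  k <- length(config$subgroup_sizes)
  n_struct <- sum(config$subgroup_sizes)
  n <- n_struct + config$n_outliers
  ng <- config$n_genes

  genes <- sprintf("g%05d", seq_len(ng))
  samples <- sprintf("s%03d", seq_len(n))
  subgroup <- factor(c(rep(paste0("C", seq_len(k)), config$subgroup_sizes),
                       rep("outlier", config$n_outliers)),
                     levels = c(paste0("C", seq_len(k)), "outlier"))

  marker_idx <- matrix(sample.int(ng, k * config$markers_per_subgroup),
                       nrow = config$markers_per_subgroup)
  markers <- lapply(seq_len(k), function(s) sort(genes[marker_idx[, s]]))
  names(markers) <- paste0("C", seq_len(k))

  batch <- factor(sample(rep_len(paste0("batch", seq_len(config$n_batches)), n)))

  baseline <- stats::rnorm(ng, mean = 7, sd = 1)
  x <- baseline + matrix(stats::rnorm(ng * n, sd = config$noise_sd), ng, n)
  gamma <- matrix(stats::rnorm(ng * config$n_batches,
                               sd = config$batch_shift_sd),
                  ng, config$n_batches)
  delta <- matrix(stats::runif(ng * config$n_batches,
                               config$batch_scale_range[1],
                               config$batch_scale_range[2]),
                  ng, config$n_batches)
  for (b in seq_len(config$n_batches)) {
    jb <- which(as.integer(batch) == b)
    x[, jb] <- baseline + delta[, b] * (x[, jb] - baseline) + gamma[, b]
  }
  for (s in seq_len(k)) {
    js <- which(subgroup == paste0("C", s))
    x[marker_idx[, s], js] <- x[marker_idx[, s], js] + config$marker_effect
  }
  dimnames(x) <- list(genes, samples)

  clinical <- simulate_clinical(subgroup, config)
  clinical <- data.frame(sample_id = samples, batch = as.character(batch),
                         clinical, stringsAsFactors = FALSE)

  list(expr = leat_expr(x, batch = as.character(batch)),
       clinical = clinical,
       truth = list(subgroup = stats::setNames(subgroup, samples),
                    batch = stats::setNames(batch, samples),
                    markers = markers))
}

# Covariate model: histology mixes, age distributions and Engel rates follow
# the cohort the generator emulates (subgroup 1 pure DNT, subgroup 2 GG/PXA,
# subgroup 3 young GG, subgroup 4 mixed); outliers draw subgroup-averaged
# probabilities. Baseline PFS median 60 months for BRAF wild-type.
simulate_clinical <- function(subgroup, config) {
  n <- length(subgroup)
  k <- length(config$subgroup_sizes)
  grp <- as.integer(subgroup)            # outliers get k + 1
  p_rec <- c(config$recurrence_prob, mean(config$recurrence_prob))[grp]
  p_braf <- c(config$braf_prob, mean(config$braf_prob))[grp]
  recurrence <- stats::rbinom(n, 1, p_rec) == 1
  braf <- ifelse(stats::rbinom(n, 1, p_braf) == 1, "V600E", "WT")

  hist_probs <- list(c(DNT = 1, GG = 0, PXA = 0),
                     c(DNT = 0, GG = 0.8, PXA = 0.2),
                     c(DNT = 0.1, GG = 0.9, PXA = 0),
                     c(DNT = 0.6, GG = 0.4, PXA = 0))
  histology <- vapply(grp, function(g) {
    p <- if (g <= k && g <= 4L) hist_probs[[g]] else c(DNT = .4, GG = .4, PXA = .2)
    sample(names(p), 1L, prob = p)
  }, character(1))
  age <- ifelse(grp == 3L,
                pmax(3, round(stats::rnorm(n, 14, 4))),
                pmax(3, round(stats::rnorm(n, 30, 14))))
  engel <- ifelse(stats::rbinom(n, 1, 0.88) == 1, "Ia",
                  sample(c("Ib", "II", "IIIa"), n, replace = TRUE))

  base_rate <- log(2) / 60               # months^-1, median 60 for wild-type
  rate <- base_rate * ifelse(braf == "V600E", config$braf_pfs_hazard_ratio, 1)
  t_event <- stats::rexp(n, rate)
  horizon <- stats::quantile(t_event, 0.75, names = FALSE)
  pfs_time <- pmin(t_event, horizon)
  pfs_event <- as.integer(t_event <= horizon)

  data.frame(histology = histology, age = age, engel = engel,
             recurrence = recurrence, braf = braf,
             pfs_time = pfs_time, pfs_event = pfs_event,
             stringsAsFactors = FALSE)
}

#' Build gene sets around the planted cohort structure
#'
#' One "planted" set per subgroup, sampled from that subgroup's marker block,
#' plus `n_random_sets` sets sampled uniformly from non-marker genes (so random
#' sets contain no markers by construction). The result is GMT-serialisable via
#' [write_gmt()].
#'
#' @param truth the `truth` element returned by [simulate_cohort()].
#' @param set_size members per set; must not exceed the marker-block size.
#' @param n_random_sets number of marker-free control sets.
#' @param universe gene universe to sample random sets from (gene IDs).
#' @param seed integer seed.
#' @return a `gene_set_collection` (named list of gene-ID vectors with a
#'   `description` attribute); planted sets are named `PLANTED_<subgroup>`.
#' @export
simulate_gene_sets <- function(truth, set_size = 50, n_random_sets = 20,
                               universe, seed = 1) {
  if (set_size <= 0) stop("set_size must be positive")
  if (set_size > length(truth$markers[[1]]))
    stop("set_size exceeds the marker-block size")
  set.seed(seed)
  all_markers <- unlist(truth$markers, use.names = FALSE)
  non_markers <- setdiff(universe, all_markers)
  sets <- lapply(truth$markers, function(m) sort(sample(m, set_size)))
  names(sets) <- paste0("PLANTED_", names(truth$markers))
  rnd <- lapply(seq_len(n_random_sets),
                function(i) sort(sample(non_markers, set_size)))
  names(rnd) <- sprintf("RANDOM_%02d", seq_len(n_random_sets))
  sets <- c(sets, rnd)
  gene_set_collection(sets,
                      description = ifelse(grepl("^PLANTED", names(sets)),
                                           "planted subgroup markers",
                                           "random non-marker genes"))
}

#' Packaged 18-patient clinical table
#'
#' Loads the packaged clinical/neuropathological fixture: 18 surgical patients
#' with long-term epilepsy-associated tumors profiled on the local array
#' dataset, transcribed from the published per-patient table (sex, age at
#' surgery, Engel outcome, diagnosis, WHO grade, CD34, IDH status, MIB
#' proliferation index, death, recurrence, and assigned transcriptional
#' cluster).
#'
#' @return data.frame with 18 rows.
#' @export
load_table1 <- function() {
  path <- system.file("extdata", "table1_clinical.tsv",
                      package = "leatsubtype", mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE,
                    na.strings = "NA", check.names = FALSE)
}
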