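# Shared fixtures, all generated in code.

# small random expression container
make_expr <- function(n_genes = 50, n_samples = 12, n_batches = 1, seed = 1,
                      prefix = "g") {
  set.seed(seed)
  m <- matrix(rnorm(n_genes * n_samples), n_genes, n_samples,
              dimnames = list(sprintf("%s%03d", prefix, seq_len(n_genes)),
                              sprintf("s%03d", seq_len(n_samples))))
  leat_expr(m, batch = rep_len(paste0("b", seq_len(n_batches)), n_samples))
}

# the 1-D four-point toy used in several hand computations
toy4_dist <- function() {
  x <- c(0, 1, 10, 11)
  d <- abs(outer(x, x, "-"))
  dimnames(d) <- list(paste0("p", 1:4), paste0("p", 1:4))
  d
}

# default synthetic cohort, cached across tests in one file run
cohort_cache <- new.env(parent = emptyenv())
default_cohort <- function(seed = 1) {
  key <- paste0("c", seed)
  if (is.null(cohort_cache[[key]]))
    cohort_cache[[key]] <- simulate_cohort(cohort_config(seed = seed))
  cohort_cache[[key]]
}

# corrected + scaled top-gene matrix for the default cohort
cohort_top <- function(seed = 1, n = 1000) {
  key <- paste0("t", seed, "_", n)
  if (is.null(cohort_cache[[key]])) {
    sim <- default_cohort(seed)
    cb <- combat_correct(sim$expr)$corrected
    cohort_cache[[key]] <- scale_genes(top_variable_genes(cb, n))
  }
  cohort_cache[[key]]
}

# brute-force k-medoids over all medoid subsets (oracle for small n)
exhaustive_kmedoids_cost <- function(d, k) {
  n <- nrow(d)
  min(apply(utils::combn(n, k), 2L, function(m)
    sum(apply(d[m, , drop = FALSE], 2L, min))))
}
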