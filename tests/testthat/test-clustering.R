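test_that("top_variable_genes selects by variance with deterministic ties", {
  m <- rbind(g1 = c(1, 1.1, 0.9, 1), g2 = c(0, 5, -3, 2), g3 = c(1, 3, 0, 2))
  colnames(m) <- paste0("s", 1:4)
  keep <- top_variable_genes(m, 2)
  expect_setequal(rownames(keep), c("g2", "g3"))
  expect_equal(rownames(top_variable_genes(m, 3)), c("g2", "g3", "g1"))
  expect_error(top_variable_genes(m, 0), "positive")
  expect_error(top_variable_genes(m, 4), "exceeds")

  e <- make_expr(40, 8)
  expect_equal(sort(rownames(top_variable_genes(e, 40)$values)),
               sort(rownames(e$values)))   # n = gene count keeps everything
})

test_that("variance ranking strongly enriches planted markers", {
  sim <- default_cohort(1)
  cb <- combat_correct(sim$expr)$corrected
  top <- top_variable_genes(cb, 1000)
  retention <- mean(unlist(sim$truth$markers) %in% rownames(top$values))
  # markers carry the between-subgroup variance: retention far above the
  # 1000/5000 = 20% a random pick would give
  expect_gt(retention, 0.5)
})

test_that("silhouette scan recovers the planted cluster number", {
  sel <- select_k_by_silhouette(cohort_top(1))
  expect_equal(sel$k, 4)
  expect_false(sel$no_structure)
  expect_named(sel$mean_silhouette, as.character(2:10))
  expect_equal(sel$best$k, 4)
})

test_that("two well-separated subgroups give k = 2", {
  sim <- simulate_cohort(cohort_config(
    seed = 8, n_genes = 1500, subgroup_sizes = c(12, 12),
    recurrence_prob = c(0.1, 0.4), braf_prob = c(0, 0.5)))
  cb <- combat_correct(sim$expr)$corrected
  top <- scale_genes(top_variable_genes(cb, 500))
  expect_equal(select_k_by_silhouette(top, 2, 6)$k, 2)
})

test_that("a cohort without planted structure is flagged", {
  sim <- simulate_cohort(cohort_config(seed = 9, n_genes = 1500,
                                       marker_effect = 0, batch_shift_sd = 0))
  top <- scale_genes(top_variable_genes(sim$expr, 500))
  sel <- select_k_by_silhouette(top, 2, 8)
  expect_true(all(sel$mean_silhouette < 0.2))
  expect_true(sel$no_structure)
})

test_that("core filtering drops exactly the negative-silhouette samples", {
  d <- toy4_dist()
  r <- pam_kmedoids(d, 2)
  core <- filter_core_samples(r)
  expect_equal(core$retained, rownames(d))
  expect_equal(nrow(core$excluded), 0L)

  r2 <- r
  r2$silhouette <- setNames(c(0.5, -0.1, 0.4, -0.3), rownames(d))
  expect_message(core2 <- filter_core_samples(r2), "excluding 2")
  expect_equal(core2$retained, c("p1", "p3"))
  expect_equal(core2$excluded$sample_id, c("p2", "p4"))
  expect_equal(length(core2$retained),
               length(r2$silhouette) - sum(r2$silhouette < 0))

  r3 <- r
  r3$silhouette <- setNames(rep(-0.2, 4), rownames(d))
  expect_error(filter_core_samples(r3), "no core samples")
})

test_that("unstructured outliers are mostly excluded, structured samples kept", {
  neg <- ret <- numeric(0)
  for (s in 1:3) {
    sim <- simulate_cohort(cohort_config(seed = s, n_outliers = 12))
    cb <- combat_correct(sim$expr)$corrected
    top <- scale_genes(top_variable_genes(cb, 1000))
    r <- pam_kmedoids(expr_distance(top), 4)
    is_out <- sim$truth$subgroup == "outlier"
    neg <- c(neg, mean(r$silhouette[is_out] < 0))
    ret <- c(ret, mean(r$silhouette[!is_out] >= 0))
  }
  expect_gt(mean(neg), 0.5)    # the majority of outliers turn non-core
  expect_gte(mean(ret), 0.9)   # structured samples stay
})

test_that("perfectly separated data give a binary consensus matrix", {
  x <- c(0, 0.1, 0.2, 10, 10.1, 10.2)
  m <- rbind(a = x, b = x + rnorm(6, sd = 0.01), c = -x)
  colnames(m) <- paste0("s", 1:6)
  cons <- consensus_cluster(m, k_min = 2, k_max = 2, reps = 25,
                            subsample_frac = 0.8, metric = "euclidean",
                            seed = 5)
  cm <- cons$consensus[["2"]]
  expect_true(all(cm %in% c(0, 1)))
  expect_true(isSymmetric(cm))
  expect_equal(diag(cm), setNames(rep(1, 6), colnames(m)))
  # co-clustering follows the two planted blobs wherever pairs were co-sampled
  blob <- rep(1:2, each = 3)
  same <- outer(blob, blob, "==")
  expect_true(all(cm[same & upper.tri(cm)] %in% c(0, 1)))
  expect_true(all(cm[!same] == 0))
  expect_true(all(cm[same & upper.tri(cm) & cm > 0] == 1))
})

test_that("consensus CDF and areas are well-formed and reproducible", {
  top <- cohort_top(1, n = 500)
  cons <- consensus_cluster(top, 2, 6, reps = 30, seed = 3)
  expect_true(all(unlist(cons$cdf) >= 0 & unlist(cons$cdf) <= 1))
  for (k in names(cons$cdf))
    expect_true(all(diff(cons$cdf[[k]]) >= 0))   # CDF non-decreasing
  expect_true(all(cons$area >= 0 & cons$area <= 1))
  cons2 <- consensus_cluster(top, 2, 6, reps = 30, seed = 3)
  expect_identical(cons$consensus, cons2$consensus)
  # adding clusters beyond the planted 4 yields only marginal stability gains
  expect_gt(cons$delta_area[["4"]], max(cons$delta_area[c("5", "6")]))
})

test_that("consensus input validation", {
  top <- cohort_top(1, n = 200)
  expect_error(consensus_cluster(top, reps = 1), "reps")
  expect_error(consensus_cluster(top, subsample_frac = 0), "subsample_frac")
  expect_error(consensus_cluster(top, k_min = 2, k_max = 50, reps = 5,
                                 subsample_frac = 0.8), "below the sample count|subsample too small")
})
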