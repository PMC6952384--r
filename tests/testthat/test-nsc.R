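# 2 genes x 6 samples, two classes; gene 2 is flat, so its centroid contrast
# is exactly zero in every training subset.
toy_nsc <- function() {
  m <- rbind(g1 = c(0, 1, 2, 3, 4, 5),
             g2 = rep(0, 6))
  colnames(m) <- paste0("s", 1:6)
  list(m = m, y = factor(rep(c("a", "b"), each = 3)))
}

test_that("unshrunken statistics match a spreadsheet-style recomputation", {
  t <- toy_nsc()
  fit <- nsc_fit(t$m, t$y, delta = 0)

  # oracle: scalar arithmetic straight from the estimator definition
  n <- 6; K <- 2; n_k <- c(a = 3, b = 3)
  xbar <- rowMeans(t$m)
  cent_a <- rowMeans(t$m[, 1:3]); cent_b <- rowMeans(t$m[, 4:6])
  ss <- rowSums((t$m[, 1:3] - cent_a)^2) + rowSums((t$m[, 4:6] - cent_b)^2)
  s_i <- sqrt(ss / (n - K))
  s0 <- median(s_i)
  m_k <- sqrt(1 / 3 + 1 / 6)
  d_a <- (cent_a - xbar) / (m_k * (s_i + s0))
  d_b <- (cent_b - xbar) / (m_k * (s_i + s0))

  expect_equal(fit$centroid_overall, xbar)
  expect_equal(fit$s, s_i)
  expect_equal(fit$s0, s0)
  expect_equal(unname(fit$m_k), rep(m_k, 2))
  expect_equal(fit$d[, "a"], d_a)
  expect_equal(fit$d[, "b"], d_b)
  expect_equal(fit$d_shrunk, fit$d)           # delta = 0: no shrinkage
  expect_equal(fit$d["g2", "a"], 0)           # no-signal gene: zero contrast
  expect_equal(sum(fit$priors), 1)
})

test_that("shrinkage semantics: survivors shrink monotonically, full shrinkage predicts the prior", {
  t <- toy_nsc()
  fit0 <- nsc_fit(t$m, t$y, delta = 0)
  expect_setequal(fit0$survivors, "g1")       # only the signal gene has d != 0

  deltas <- seq(0, max(abs(fit0$d)) * 1.1, length.out = 8)
  surv_counts <- sapply(deltas, function(dl)
    length(nsc_fit(t$m, t$y, delta = dl)$survivors))
  expect_true(all(diff(surv_counts) <= 0))    # non-increasing in delta
  for (dl in deltas) {
    f <- nsc_fit(t$m, t$y, delta = dl)
    expect_true(all(abs(f$d_shrunk) <= abs(f$d) + 1e-12))
  }

  full <- nsc_fit(t$m, t$y, delta = max(abs(fit0$d)) + 1)
  expect_length(full$survivors, 0)
  # with equal priors all discriminants tie; unbalance the classes instead
  m2 <- cbind(t$m, s7 = c(1.5, 0.5))
  y2 <- factor(c(as.character(t$y), "b"))
  full2 <- nsc_fit(m2, y2, delta = 99)
  pred <- predict(full2, m2, type = "class")
  expect_true(all(pred == "b"))               # argmax prior everywhere
})

test_that("delta = 0 with equal class sizes reproduces nearest-centroid classification", {
  set.seed(14)
  m <- matrix(rnorm(30 * 12), 30, 12,
              dimnames = list(sprintf("g%02d", 1:30), sprintf("s%02d", 1:12)))
  m[1:5, 1:6] <- m[1:5, 1:6] + 2
  y <- factor(rep(c("a", "b"), each = 6))
  fit <- nsc_fit(m, y, delta = 0)
  pred <- predict(fit, m, type = "class")
  # oracle: direct (s_i + s0)-standardised distances to the raw centroids
  w <- 1 / (fit$s + fit$s0)^2
  d_a <- colSums((m - rowMeans(m[, 1:6]))^2 * w)
  d_b <- colSums((m - rowMeans(m[, 7:12]))^2 * w)
  expect_equal(as.character(pred), unname(ifelse(d_a <= d_b, "a", "b")))
})

test_that("posteriors are proper and symmetric at the midpoint", {
  t <- toy_nsc()
  fit <- nsc_fit(t$m, t$y, delta = 0)
  post <- predict(fit, t$m, type = "posterior")
  expect_equal(unname(rowSums(post)), rep(1, 6))
  # sample exactly on the shrunken centroid of class a -> maximal affiliation
  cent <- matrix(fit$shrunken_centroids[, "a"], ncol = 1,
                 dimnames = list(fit$genes, "probe"))
  p1 <- predict(fit, cent, type = "posterior")
  expect_gt(p1[1, "a"], p1[1, "b"])
  # midpoint between the two centroids -> 50/50 (equal priors)
  mid <- matrix(rowMeans(fit$shrunken_centroids), ncol = 1,
                dimnames = list(fit$genes, "mid"))
  pm <- predict(fit, mid, type = "posterior")
  expect_equal(unname(pm[1, ]), c(0.5, 0.5), tolerance = 1e-12)
})

test_that("input validation matches the estimator's preconditions", {
  t <- toy_nsc()
  expect_error(nsc_fit(t$m, t$y, delta = -1), "non-negative")
  expect_error(nsc_fit(t$m, factor(rep("a", 6))), "2 classes")
  expect_error(nsc_fit(t$m, factor(c("a", "a", "a", "a", "a", "b"))),
               "single sample")
})

test_that("leave-one-out folds on the toy give identical surviving sets per fold", {
  t <- toy_nsc()
  r <- suppressWarnings(nsc_cv_rank(t$m, t$y, n_folds = 6, delta_grid = c(0, 0.1),
                                    seed = 1))
  # g1 must survive every fold, g2 none (its contrast is exactly zero)
  expect_equal(unname(r$survival_folds["g1"]), r$n_folds)
  expect_equal(unname(r$survival_folds["g2"]), 0L)
  expect_equal(unname(r$avg_rank["g2"]), nrow(t$m) + 1)  # sentinel
})

test_that("cross-validated ranking recovers planted markers and separates classes", {
  sim <- default_cohort(1)
  cb <- combat_correct(sim$expr)$corrected
  keep <- sim$truth$subgroup != "outlier"
  r <- nsc_cv_rank(cb[, keep], droplevels(sim$truth$subgroup[keep]),
                   n_folds = 5, seed = 2)
  expect_gte(r$cv_accuracy, 0.9)
  markers <- unlist(sim$truth$markers)
  top400 <- names(sort(r$avg_rank))[1:400]
  expect_gte(mean(markers %in% top400), 0.8)
  expect_true(all(r$avg_rank >= 1 & r$avg_rank <= nrow(cb$values) + 1))
})

test_that("label permutation drops CV accuracy to chance", {
  sim <- simulate_cohort(cohort_config(seed = 6, n_genes = 1500))
  cb <- combat_correct(sim$expr)$corrected
  y <- sim$truth$subgroup
  set.seed(77)
  y_perm <- sample(y)
  r <- nsc_cv_rank(cb, y_perm, n_folds = 5, seed = 3)
  maj <- max(table(y)) / length(y)
  expect_lt(r$cv_accuracy, maj + 3 * sqrt(maj * (1 - maj) / length(y)))
})

test_that("subclass scores attach effect and significance per gene", {
  sim <- simulate_cohort(cohort_config(seed = 4, n_genes = 1200))
  cb <- combat_correct(sim$expr)$corrected
  y <- sim$truth$subgroup
  r <- nsc_cv_rank(cb, y, n_folds = 4, seed = 5)
  de <- pairwise_de(cb, y)
  sc <- subclass_scores(r$model, cb, de = de)
  expect_equal(unname(rowSums(sc$affiliation)), rep(1, ncol(cb$values)))
  # mean affiliation of samples to their planted subgroup is high
  own <- sc$affiliation[cbind(seq_along(y), match(y, colnames(sc$affiliation)))]
  expect_gt(mean(own), 0.8)
  expect_true(all(c("gene", "class", "score", "q", "neg_log10_q") %in%
                    names(sc$gene_scores)))
  expect_error(subclass_scores(r$model, cb$values[1:50, ]), "missing model genes")
})
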