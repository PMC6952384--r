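test_that("product-limit estimate matches the hand computation", {
  km <- km_estimate(c(1, 2, 3), c(1, 0, 1))
  expect_equal(km$curve$surv[km$curve$time == 1], 2 / 3)
  expect_equal(km$curve$surv[km$curve$time == 3], 0)   # (2/3) * (1 - 1/1)
  expect_equal(km$median, 3)                           # smallest t with S <= .5
  expect_equal(km$n_events, 2)

  all_cens <- km_estimate(c(2, 4, 6), c(0, 0, 0))
  expect_true(all(all_cens$curve$surv == 1))
  expect_true(is.na(all_cens$median))

  # no censoring: S(t) is the empirical survival fraction
  t <- c(5, 1, 3, 2, 4)
  km2 <- km_estimate(t, rep(1, 5))
  expect_equal(km2$curve$surv, 1 - ecdf(t)(km2$curve$time))

  expect_error(km_estimate(c(-1, 2), c(1, 1)), "negative")
  expect_error(km_estimate(numeric(0), numeric(0)), "one observation")
})

test_that("log-rank statistic matches an O-E hand tally and its null behaviour", {
  # textbook two-group toy
  time <- c(1, 3, 4, 5, 2, 4, 6, 8)
  event <- c(1, 1, 1, 0, 1, 1, 1, 1)
  grp <- rep(c("a", "b"), each = 4)
  lr <- logrank_test(time, event, grp)
  # oracle: loop over distinct event times tallying O - E and the variance
  oe <- 0; v <- 0
  for (tt in sort(unique(time[event == 1]))) {
    at_risk <- time >= tt
    d <- sum(event == 1 & time == tt)
    n <- sum(at_risk); n1 <- sum(at_risk & grp == "a")
    o1 <- sum(event == 1 & time == tt & grp == "a")
    oe <- oe + o1 - d * n1 / n
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  expect_equal(lr$chisq, oe^2 / v, tolerance = 1e-9)
  expect_equal(lr$df, 1)

  # identical groups: statistic ~ 0, p ~ 1
  lr0 <- logrank_test(rep(time[1:4], 2), rep(event[1:4], 2), grp)
  expect_lt(lr0$chisq, 1e-10)
  expect_equal(lr0$p, 1, tolerance = 1e-6)
  expect_error(logrank_test(time, rep(0, 8), grp), "no events")
})

test_that("log-rank rejects reliably under a strong simulated hazard ratio", {
  set.seed(30)
  rej <- replicate(60, {
    t1 <- rexp(100, 1); t2 <- rexp(100, 4)
    cens <- quantile(c(t1, t2), 0.8)
    time <- pmin(c(t1, t2), cens)
    event <- as.integer(c(t1, t2) <= cens)
    logrank_test(time, event, rep(c("a", "b"), each = 100))$p < 0.05
  })
  expect_gt(mean(rej), 0.9)
})

test_that("Cox regression: null HR is 1, simulated HR 4 is recovered", {
  set.seed(31)
  t0 <- rexp(80, 1)
  same <- cox_hr(rep(t0, 2), rep(1, 160), rep(c("a", "b"), each = 80))
  expect_equal(same$hr, 1, tolerance = 1e-8)   # beta = 0 stationary point

  hrs <- replicate(60, {
    t1 <- rexp(100, 1); t2 <- rexp(100, 4)
    cens <- quantile(c(t1, t2), 0.8)
    cox_hr(pmin(c(t1, t2), cens), as.integer(c(t1, t2) <= cens),
           factor(rep(c("wt", "mut"), each = 100), levels = c("wt", "mut")))$hr
  })
  expect_gte(median(hrs), 3.0)
  expect_lte(median(hrs), 5.3)
})

test_that("a monotone partial likelihood is flagged as an infinite HR", {
  time <- c(1, 2, 3, 4, 10, 11, 12, 13)
  event <- c(1, 1, 1, 1, 1, 1, 1, 1)
  grp <- rep(c("b_fast", "a_slow"), each = 4)
  res <- suppressWarnings(cox_hr(time, event, grp))
  expect_true(res$infinite)
  expect_true(is.infinite(res$hr))
})

test_that("cluster-marker association reproduces exact hypergeometric tails", {
  # 2x2 toy (3,1 / 1,3): two-sided Fisher p = 34/70
  cl <- rep(c("x", "y"), each = 4)
  marker <- c(TRUE, TRUE, TRUE, FALSE, TRUE, FALSE, FALSE, FALSE)
  res <- cluster_marker_association(cl, marker)
  expect_equal(res$per_cluster$p, rep(34 / 70, 2), tolerance = 1e-12)

  # marker confined to one of four clusters: that cluster's p < 0.001
  cl4 <- rep(c("C1", "C2", "C3", "C4"), c(11, 18, 13, 11))
  m4 <- rep(FALSE, 53); m4[12:23] <- TRUE      # 12 of 18 in C2
  res4 <- cluster_marker_association(cl4, m4)
  expect_lt(res4$per_cluster$p[res4$per_cluster$cluster == "C2"], 0.001)
  expect_equal(res4$per_cluster$q, p.adjust(res4$per_cluster$p, "BH"))
  expect_error(cluster_marker_association(cl4, rep(NA, 53)), "missing")
})

test_that("group comparisons: exact rank-sum p and ANOVA calibration", {
  gc <- group_compare(c(1, 2, 3, 4, 5, 6), rep(c("A", "B"), each = 3),
                      test = "wilcoxon")
  expect_equal(gc$p, 0.1, tolerance = 1e-12)   # 2/choose(6,3)

  same <- suppressWarnings(            # identical values tie; normal approx
    group_compare(rep(c(5, 6, 7), 2), rep(c("A", "B"), each = 3),
                  test = "wilcoxon"))
  expect_gt(same$p, 0.9)

  set.seed(32)
  hits <- replicate(400, {
    v <- rnorm(18)
    group_compare(v, rep(c("a", "b", "c"), each = 6), test = "anova")$p < 0.05
  })
  expect_lt(abs(mean(hits) - 0.05), 3 * sqrt(0.05 * 0.95 / 400))

  # BH across a marker panel
  set.seed(33)
  panel <- matrix(rnorm(20 * 3), 20, dimnames = list(NULL, c("CD34", "pS6K", "pMAPK")))
  panel[1:10, 1] <- panel[1:10, 1] + 3
  gcp <- suppressWarnings(
    group_compare(panel, rep(c("g1", "g2"), each = 10), test = "wilcoxon"))
  expect_equal(gcp$q, p.adjust(gcp$p, "BH"))
  expect_error(group_compare(1:6, rep("a", 6)), "2 groups")
})

test_that("normality screen calibrates on normal data and flags exponential data", {
  set.seed(34)
  rej_norm <- replicate(300, normality_screen(rnorm(50))$p < 0.05)
  expect_lt(abs(mean(rej_norm) - 0.05), 3 * sqrt(0.05 * 0.95 / 300))
  rej_exp <- replicate(100, normality_screen(rexp(100))$p < 0.05)
  expect_gt(mean(rej_exp), 0.9)
  expect_error(normality_screen(c(1, 2)), "3 <= n")
  expect_error(normality_screen(rep(1, 10)), "constant")
})
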