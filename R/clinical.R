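#' Kaplan-Meier product-limit estimate
#'
#' Wraps [survival::survfit()] for a single group and returns the step function
#' plus the median survival time, defined as the smallest observed time at
#' which the survival probability drops to 0.5 or below (NA when never
#' reached).
#'
#' @param time event/censoring times (non-negative).
#' @param event event indicator (1 = event, 0 = censored).
#' @return object of class `survival_curve`: `curve` (data.frame: time,
#'   n_risk, n_event, n_censor, surv), `median`, `n`, `n_events`.
#' @export
km_estimate <- function(time, event) {
  if (length(time) == 0) stop("need at least one observation")
  if (any(time < 0)) stop("negative survival time")
  if (!all(event %in% c(0, 1))) stop("event indicator must be 0/1")
  sf <- survival::survfit(survival::Surv(time, event) ~ 1)
  curve <- data.frame(time = sf$time, n_risk = sf$n.risk,
                      n_event = sf$n.event, n_censor = sf$n.censor,
                      surv = sf$surv)
  med <- if (any(curve$surv <= 0.5)) min(curve$time[curve$surv <= 0.5]) else NA_real_
  structure(list(curve = curve, median = med, n = length(time),
                 n_events = sum(event)), class = "survival_curve")
}

#' @export
print.survival_curve <- function(x, ...) {
  cat(sprintf("<survival_curve> n = %d, events = %d, median = %s\n", x$n,
              x$n_events, ifelse(is.na(x$median), "not reached",
                                 format(x$median, digits = 4))))
  invisible(x)
}

#' Log-rank test between survival groups
#'
#' Standard observed-minus-expected log-rank chi-square with k - 1 degrees of
#' freedom, via [survival::survdiff()].
#'
#' @param time,event survival times and 0/1 event indicators.
#' @param group group labels (>= 2 groups).
#' @return list: `chisq`, `df`, `p`.
#' @export
logrank_test <- function(time, event, group) {
  group <- factor(group)
  if (nlevels(group) < 2) stop("need >= 2 groups")
  if (sum(event) == 0) stop("no events observed")
  sd <- survival::survdiff(survival::Surv(time, event) ~ group)
  df <- nlevels(group) - 1
  list(chisq = sd$chisq, df = df,
       p = stats::pchisq(sd$chisq, df, lower.tail = FALSE))
}

#' Cox proportional-hazards ratio for a binary group
#'
#' Single-covariate Cox partial likelihood (Breslow tie handling) via
#' [survival::coxph()], returning the hazard ratio with a Wald 95% CI. A
#' monotone likelihood (all events on one side, infinite HR) is detected and
#' flagged rather than reported as a finite estimate.
#'
#' @param time,event survival times and 0/1 event indicators.
#' @param group binary group indicator (factor/logical/0-1); the HR is for the
#'   second level versus the first.
#' @return list: `hr`, `ci_lower`, `ci_upper`, `p`, `beta`, `se`, `infinite`.
#' @export
cox_hr <- function(time, event, group) {
  g <- factor(group)
  if (nlevels(g) != 2) stop("`group` must be binary")
  if (any(tapply(event, g, sum) == 0))
    warning("a group has no events; the hazard ratio is weakly identified")
  fit <- withCallingHandlers(
    survival::coxph(survival::Surv(time, event) ~ g, ties = "breslow"),
    warning = function(w) {
      if (grepl("infinite|converge", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  beta <- unname(stats::coef(fit))
  se <- sqrt(unname(stats::vcov(fit)[1, 1]))
  infinite <- abs(beta) > 10 || se > 100
  z <- beta / se
  list(hr = if (infinite) sign(beta) * Inf else exp(beta),
       ci_lower = exp(beta - 1.96 * se), ci_upper = exp(beta + 1.96 * se),
       p = 2 * stats::pnorm(-abs(z)), beta = beta, se = se,
       infinite = infinite)
}

#' Cluster-marker association (one-vs-rest exact tests)
#'
#' Cross-tabulates a binary marker (e.g. BRAF alteration, recurrence) against
#' cluster membership and tests each cluster one-vs-rest with Fisher's exact
#' (hypergeometric) test, Benjamini-Hochberg adjusted across clusters.
#'
#' @param clusters per-sample cluster labels.
#' @param marker per-sample logical (or 0/1) marker status; missing values are
#'   dropped pairwise.
#' @return list: `table` (clusters x marker contingency table) and
#'   `per_cluster` data.frame (cluster, n, n_marker, odds_ratio, p, q).
#' @export
cluster_marker_association <- function(clusters, marker) {
  ok <- !is.na(marker) & !is.na(clusters)
  clusters <- factor(clusters[ok])
  marker <- as.logical(marker[ok])
  if (length(marker) == 0) stop("marker is entirely missing")
  if (nlevels(clusters) < 2) stop("need >= 2 clusters")
  tab <- table(cluster = clusters, marker = marker)
  rows <- lapply(levels(clusters), function(cl) {
    a <- sum(marker & clusters == cl)
    b <- sum(!marker & clusters == cl)
    c <- sum(marker & clusters != cl)
    d <- sum(!marker & clusters != cl)
    ft <- stats::fisher.test(matrix(c(a, b, c, d), 2, byrow = TRUE))
    data.frame(cluster = cl, n = a + b, n_marker = a,
               odds_ratio = unname(ft$estimate), p = ft$p.value,
               stringsAsFactors = FALSE)
  })
  per_cluster <- do.call(rbind, rows)
  per_cluster$q <- stats::p.adjust(per_cluster$p, "BH")
  list(table = tab, per_cluster = per_cluster)
}

#' Compare marker values between groups
#'
#' Runs the chosen test per marker — unpaired Wilcoxon rank-sum (exact for
#' small untied samples, normal approximation with tie correction otherwise)
#' or one-way ANOVA (equal-variance F) — and adjusts across the marker panel
#' with Benjamini-Hochberg.
#'
#' @param values numeric vector (single marker) or samples-x-markers
#'   matrix/data.frame.
#' @param groups per-sample group labels (>= 2 groups, >= 2 values each;
#'   Wilcoxon requires exactly 2 groups).
#' @param test `"wilcoxon"` or `"anova"`.
#' @return data.frame: marker, statistic, p, q.
#' @export
group_compare <- function(values, groups, test = c("wilcoxon", "anova")) {
  test <- match.arg(test)
  if (is.null(dim(values)))
    values <- matrix(values, ncol = 1, dimnames = list(NULL, "marker"))
  values <- as.matrix(values)
  g <- factor(groups)
  if (nlevels(g) < 2 || any(table(g) < 2))
    stop("need >= 2 groups with >= 2 values each")
  if (test == "wilcoxon" && nlevels(g) != 2)
    stop("the rank-sum test compares exactly 2 groups")
  if (all(apply(values, 2L, function(v) stats::var(v) == 0)))
    stop("all markers are constant")
  rows <- lapply(seq_len(ncol(values)), function(j) {
    v <- values[, j]
    if (test == "wilcoxon") {
      wt <- stats::wilcox.test(v[g == levels(g)[1]], v[g == levels(g)[2]])
      data.frame(marker = colnames(values)[j], statistic = unname(wt$statistic),
                 p = wt$p.value, stringsAsFactors = FALSE)
    } else {
      ot <- stats::oneway.test(v ~ g, var.equal = TRUE)
      data.frame(marker = colnames(values)[j], statistic = unname(ot$statistic),
                 p = ot$p.value, stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  out$q <- stats::p.adjust(out$p, "BH")
  out
}

#' Shapiro-Wilk normality screen
#'
#' Annotates whether a parametric group test is defensible for a sample;
#' 3 <= n <= 5000.
#'
#' @param values numeric vector.
#' @return list: `w`, `p`.
#' @export
normality_screen <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) < 3 || length(values) > 5000)
    stop("Shapiro-Wilk requires 3 <= n <= 5000")
  if (stats::var(values) == 0) stop("constant input")
  sw <- stats::shapiro.test(values)
  list(w = unname(sw$statistic), p = sw$p.value)
}
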