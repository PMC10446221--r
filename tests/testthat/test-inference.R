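test_that("ratio-of-means NI test reproduces the trial's primary analysis", {
  cmp <- ratio_of_means(0.69, 0.26, 39, 0.79, 0.16, 39)
  expect_equal(round(cmp$estimate, 2), 0.87)
  expect_equal(round(cmp$ci_low, 2), 0.77)
  expect_true(is.infinite(cmp$ci_high))
  expect_equal(cmp$decision, "not_established")  # 0.77 < margin 0.80
  expect_gt(cmp$p_value, 0.05)
  # the acceptable-zone secondary endpoint, two-sided
  cmp2 <- ratio_of_means(0.25, 0.23, 39, 0.19, 0.14, 39, sided = "two")
  expect_equal(round(cmp2$estimate, 2), 1.32)
  expect_true(cmp2$ci_low < 1 && cmp2$ci_high > 1)
})

test_that("identical samples give ratio 1 with lower bound below 1", {
  x <- c(0.6, 0.7, 0.8, 0.75, 0.9)
  cmp <- mean_ratio_ni(x, x)
  expect_equal(cmp$estimate, 1)
  expect_lt(cmp$ci_low, 1)
})

test_that("mean ratio inference is scale equivariant", {
  set.seed(5)
  x <- rnorm(30, 0.7, 0.2); y <- rnorm(30, 0.8, 0.15)
  a <- mean_ratio_ni(x, y)
  b <- mean_ratio_ni(x * 37.2, y * 37.2)
  expect_equal(a$estimate, b$estimate)
  expect_equal(a$ci_low, b$ci_low)
  expect_equal(a$p_value, b$p_value)
})

test_that("decision, CI bound and P value are mutually consistent", {
  set.seed(8)
  for (i in 1:40) {
    x <- rnorm(25, runif(1, 0.5, 0.9), 0.2)
    y <- rnorm(25, runif(1, 0.5, 0.9), 0.2)
    if (mean(y) <= 0) next
    cmp <- mean_ratio_ni(x, y)
    expect_identical(cmp$decision %in% c("non_inferior", "superior"),
                     cmp$ci_low > 0.80)
    expect_identical(cmp$p_value < 0.05, cmp$ci_low > 0.80)
  }
})

test_that("one-sided rejection rate is close to alpha at the margin", {
  # true ratio exactly at the margin: rejecting H0 should occur at ~alpha
  set.seed(99)
  reps <- 4000
  rej <- logical(reps)
  for (i in seq_len(reps)) {
    x <- rnorm(39, 0.8 * 69, 23)
    y <- rnorm(39, 69, 23)
    if (mean(y) <= 0) { rej[i] <- NA; next }
    rej[i] <- mean_ratio_ni(x, y)$decision != "not_established"
  }
  rate <- mean(rej, na.rm = TRUE)
  mc_se <- sqrt(0.05 * 0.95 / reps)
  expect_lt(abs(rate - 0.05), 4 * mc_se)
})

test_that("alternative CI methods behave sensibly", {
  lo_t <- ratio_of_means(0.69, 0.26, 39, 0.79, 0.16, 39)$ci_low
  lo_z <- ratio_of_means(0.69, 0.26, 39, 0.79, 0.16, 39,
                         config = ni_config(ci_method = "delta_z"))$ci_low
  lo_l <- ratio_of_means(0.69, 0.26, 39, 0.79, 0.16, 39,
                         config = ni_config(ci_method = "log_delta"))$ci_low
  expect_gt(lo_z, lo_t)            # z quantile is tighter than t
  expect_equal(round(lo_l, 2), 0.78)
  set.seed(14)
  x <- rnorm(39, 0.69, 0.26); y <- rnorm(39, 0.79, 0.16)
  cb <- mean_ratio_ni(x, y, ni_config(ci_method = "bootstrap",
                                      boot_reps = 4000))
  ct <- mean_ratio_ni(x, y)
  expect_equal(cb$estimate, ct$estimate)
  expect_equal(cb$ci_low, ct$ci_low, tolerance = 0.05)
})

test_that("degenerate ratio inputs raise informative errors", {
  expect_error(ratio_of_means(0.7, 0.2, 1, 0.8, 0.2, 39), "insufficient")
  expect_error(ratio_of_means(0.7, 0.2, 39, -0.8, 0.2, 39), "undefined")
})

test_that("mean difference matches Welch inference and shift invariance", {
  d <- mean_difference(c(0.70, 0.71, 0.69), c(0.79, 0.80, 0.78))
  expect_equal(d$estimate, -0.09, tolerance = 1e-12)
  x <- rnorm(20); y <- rnorm(20)
  a <- mean_difference(x, y)
  b <- mean_difference(x + 5, y + 5)
  expect_equal(b$estimate, a$estimate, tolerance = 1e-9)
  expect_equal(b$p_value, a$p_value, tolerance = 1e-9)
  # identical arms: difference 0, CI containing 0
  same <- mean_difference(x, x)
  expect_equal(same$estimate, 0)
  expect_true(same$ci_low < 0 && same$ci_high > 0)
  # constructed separation: large n, tiny SD
  big <- mean_difference(rnorm(200, 3, 0.01), rnorm(200, 1, 0.01))
  expect_equal(big$estimate, 2, tolerance = 0.01)
  expect_lt(big$ci_high - big$ci_low, 0.01)
})

test_that("odds ratios match hand arithmetic with zero-cell correction", {
  o <- odds_ratio_2x2(2, 37, 1, 38)
  expect_equal(round(o$estimate, 2), 2.05)
  expect_equal(odds_ratio_2x2(3, 27, 3, 27)$estimate, 1)
  expect_equal(odds_ratio_2x2(1, 9, 2, 8)$estimate, (1 * 8) / (9 * 2),
               tolerance = 1e-12)
  z <- odds_ratio_2x2(0, 39, 2, 37)
  expect_true(z$extra$corrected)
  expect_true(z$ci_low < z$estimate && z$estimate < z$ci_high)
  expect_error(odds_ratio_2x2(0, 0, 1, 9), "zero subjects")
})

test_that("log-rank agrees with a brute-force risk-table computation", {
  # textbook toy: all events
  time <- c(1, 2, 3, 4, 2, 4, 5, 6)
  arm <- rep(c("a", "b"), each = 4)
  event <- rep(TRUE, 8)
  # brute force O - E for arm a over distinct event times
  oe <- 0; v <- 0
  for (tt in sort(unique(time))) {
    at_risk <- time >= tt
    d <- sum(time == tt & event)
    n <- sum(at_risk)
    n1 <- sum(at_risk & arm == "a")
    o1 <- sum(time == tt & event & arm == "a")
    e1 <- d * n1 / n
    oe <- oe + o1 - e1
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  chisq_ref <- oe^2 / v
  res <- km_logrank(time, event, arm)
  expect_equal(res$extra$chisq, chisq_ref, tolerance = 1e-9)
  # identical arms: P near 1
  res2 <- km_logrank(c(1, 2, 3, 1, 2, 3), rep(TRUE, 6),
                     rep(c("a", "b"), each = 3))
  expect_gt(res2$p_value, 0.95)
  # no events anywhere: P undefined
  res3 <- km_logrank(c(1, 2, 3, 4), rep(FALSE, 4), rep(c("a", "b"), 2))
  expect_true(is.na(res3$p_value))
  # KM step function: single subject per arm
  res4 <- km_logrank(c(1, 2), c(TRUE, TRUE), c("a", "b"))
  expect_equal(res4$extra$fit$time, c(1, 2))
  expect_equal(res4$extra$fit$surv, c(0, 0))
})

test_that("subgroup interaction is null for symmetric strata", {
  set.seed(60)
  x <- rnorm(40, 0.7, 0.1); y <- rnorm(40, 0.8, 0.1)
  values <- c(x, y)
  arm <- rep(c("sidestream", "mainstream"), each = 40)
  # duplicate the data across both strata: identical strata, z = 0
  res <- subgroup_interaction(c(values, values), c(arm, arm),
                              rep(c(0, 1), each = 80))
  expect_equal(res$interaction_z, 0, tolerance = 1e-9)
  expect_equal(res$interaction_p, 1, tolerance = 1e-9)
  expect_length(res$strata, 2)
})

test_that("interaction P follows the normal tail for a constructed difference", {
  # build strata whose log-ratio difference is exactly 3 combined SEs
  mk <- function(m) ratio_of_means(m, 0.1, 50, 1, 0.1, 50, sided = "one")
  r1 <- mk(1.0)
  se1 <- r1$extra$se / r1$estimate
  # choose the second stratum ratio so that log difference = 3 * sqrt(2) * se1
  target <- exp(log(1.0) - 3 * sqrt(se1^2 + se1^2))
  z <- (log(1.0) - log(target)) / sqrt(2 * se1^2)
  expect_equal(z, 3, tolerance = 0.05)
  expect_equal(2 * pnorm(-3), 0.0027, tolerance = 1e-4)
})

test_that("missing per-subject endpoints are dropped pairwise with a note", {
  x <- c(0.7, 0.8, NA, 0.75); y <- c(0.8, 0.82, 0.78, 0.81)
  expect_message(cmp <- mean_ratio_ni(x, y), "missing")
  expect_equal(cmp$n_x, 3)
})
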