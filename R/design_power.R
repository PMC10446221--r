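#' Trial design parameters and derived sample size
#'
#' Design container for the non-inferiority trial: an expected control
#' mean of 69 % of breaths in the optimal zone with SD 23 %, a 20 %
#' relative non-inferiority margin (13.8 percentage points), one-sided
#' alpha 0.05 and target power 0.80.
#'
#' @param expected_mean expected control-arm mean, percent.
#' @param sd between-subject SD, percent.
#' @param relative_margin relative non-inferiority margin, fraction.
#' @param alpha one-sided significance level.
#' @param power_target target power.
#' @return List of class `"trial_design"` with the derived
#'   `absolute_margin` (percentage points), standardized effect size
#'   `d`, and `n_per_arm` / `n_total` from [sample_size_t()].
#' @export
trial_design <- function(expected_mean = 69, sd = 23, relative_margin = 0.20,
                         alpha = 0.05, power_target = 0.80) {
  stopifnot(expected_mean > 0, sd > 0, relative_margin > 0,
            alpha > 0, alpha < 0.5, power_target > 0, power_target < 1)
  abs_margin <- margin_points(expected_mean, relative_margin)$raw
  d <- abs_margin / sd
  n <- sample_size_t(d, alpha, power_target)
  structure(list(expected_mean = expected_mean, sd = sd,
                 relative_margin = relative_margin,
                 absolute_margin = abs_margin, d = d, alpha = alpha,
                 power_target = power_target, n_per_arm = n,
                 n_total = 2L * n),
            class = "trial_design")
}

#' Convert a relative margin into percentage points
#'
#' @param expected_mean expected mean, percent.
#' @param relative_margin relative margin, fraction of the mean.
#' @return List `raw` (exact product) and `rounded` (nearest integer):
#'   e.g. 20 % of 69 % is 13.8, which rounds to 14 percentage points.
#' @export
margin_points <- function(expected_mean, relative_margin) {
  stopifnot(expected_mean >= 0, relative_margin >= 0)
  raw <- expected_mean * relative_margin
  list(raw = raw, rounded = as.integer(round(raw)))
}

#' Exact power of the one-sided two-sample t-test
#'
#' Noncentral-t power for detecting a standardized mean shift `d` with
#' `n` subjects per arm at one-sided level `alpha` (2n - 2 df,
#' noncentrality `d * sqrt(n/2)`).
#'
#' @param n subjects per arm (>= 2); vectorised.
#' @param d standardized effect size (absolute margin / SD).
#' @param alpha one-sided significance level.
#' @return Power in (0, 1).
#' @export
power_t_onesided <- function(n, d, alpha = 0.05) {
  stopifnot(all(n >= 2), d > 0)
  df <- 2 * n - 2
  ncp <- d * sqrt(n / 2)
  stats::pt(stats::qt(1 - alpha, df), df, ncp = ncp, lower.tail = FALSE)
}

#' Sample size for the one-sided two-sample t-test
#'
#' Smallest per-arm n whose exact noncentral-t power reaches the target.
#'
#' @param d standardized effect size.
#' @param alpha one-sided significance level.
#' @param power_target target power.
#' @param n_max search ceiling.
#' @return Integer n per arm (so total sample size is `2 * n`). At the
#'   trial's design values (d = 13.8/23 = 0.6, alpha 0.05, power 0.80)
#'   this is 36 per arm, 72 in total.
#' @export
sample_size_t <- function(d, alpha = 0.05, power_target = 0.80,
                          n_max = 1e6) {
  stopifnot(d > 0, power_target > 0, power_target < 1)
  n <- 2L
  while (power_t_onesided(n, d, alpha) < power_target) {
    n <- n + 1L
    if (n > n_max) stop("target power unattainable within n_max",
                        call. = FALSE)
  }
  n
}

#' Simulation-based power of the non-inferiority test
#'
#' Draws both arms from Normal(expected_mean, sd^2) — a true ratio of 1
#' — and applies the one-sided pooled t-test of the mean difference
#' against the absolute margin at level alpha. The rejection fraction
#' estimates the design's power. Proportions are not truncated to
#' [0, 100]: the design works on the normal approximation.
#'
#' @param design a [trial_design()].
#' @param n_per_arm subjects per arm (default the design's n).
#' @param reps Monte-Carlo replicates (>= 1000).
#' @param seed RNG seed; same seed gives identical output.
#' @return List `power`, `mc_se` (binomial standard error), `reps`,
#'   `n_per_arm`.
#' @export
simulate_power <- function(design = trial_design(),
                           n_per_arm = design$n_per_arm,
                           reps = 10000, seed = 1) {
  stopifnot(reps >= 1000, n_per_arm >= 2)
  set.seed(seed)
  n <- n_per_arm
  x <- matrix(stats::rnorm(reps * n, design$expected_mean, design$sd),
              nrow = reps)
  y <- matrix(stats::rnorm(reps * n, design$expected_mean, design$sd),
              nrow = reps)
  mx <- rowMeans(x); my <- rowMeans(y)
  vx <- apply(x, 1, stats::var); vy <- apply(y, 1, stats::var)
  sp <- sqrt((vx + vy) / 2)                     # pooled SD, equal n
  tstat <- (mx - my + design$absolute_margin) / (sp * sqrt(2 / n))
  crit <- stats::qt(1 - design$alpha, 2 * n - 2)
  pow <- mean(tstat > crit)
  list(power = pow, mc_se = sqrt(pow * (1 - pow) / reps), reps = reps,
       n_per_arm = n)
}

#' @export
print.trial_design <- function(x, ...) {
  cat(sprintf(paste0("Non-inferiority design: mean %.1f%% (SD %.1f), ",
                     "relative margin %.0f%% (= %.1f points), one-sided ",
                     "alpha %.2f, power %.2f -> n = %d/arm (%d total)\n"),
              x$expected_mean, x$sd, 100 * x$relative_margin,
              x$absolute_margin, x$alpha, x$power_target, x$n_per_arm,
              x$n_total))
  invisible(x)
}
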