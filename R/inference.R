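#' Construct an arm-comparison result
#'
#' Container for one endpoint contrast between trial arms.
#'
#' @param endpoint endpoint name.
#' @param estimator one of `"mean_ratio"`, `"mean_diff"`, `"odds_ratio"`,
#'   `"logrank"`.
#' @param estimate point estimate.
#' @param ci_low,ci_high confidence limits (`ci_high = Inf` for a
#'   one-sided lower bound).
#' @param alpha significance level.
#' @param sidedness `"one"` or `"two"`.
#' @param p_value the test's P value.
#' @param n_x,n_y per-arm sample sizes.
#' @param decision `"non_inferior"`, `"not_established"`, `"superior"`
#'   or `"n/a"`.
#' @param extra optional list of method-specific details.
#' @return List of class `"arm_comparison"`.
#' @export
arm_comparison <- function(endpoint, estimator, estimate, ci_low, ci_high,
                           alpha, sidedness, p_value, n_x, n_y,
                           decision = "n/a", extra = list()) {
  stopifnot(is.na(estimate) || (ci_low <= estimate && estimate <= ci_high))
  structure(list(endpoint = endpoint, estimator = estimator,
                 estimate = estimate, ci_low = ci_low, ci_high = ci_high,
                 alpha = alpha, sidedness = sidedness, p_value = p_value,
                 n_x = n_x, n_y = n_y, decision = decision, extra = extra),
            class = "arm_comparison")
}

#' @export
print.arm_comparison <- function(x, ...) {
  ci <- sprintf("(%.3f to %s)", x$ci_low,
                if (is.infinite(x$ci_high)) "Inf" else sprintf("%.3f", x$ci_high))
  cat(sprintf("%s [%s]: %.3f %s, P = %.4g (%s-sided), n = %d/%d",
              x$endpoint, x$estimator, x$estimate, ci, x$p_value,
              x$sidedness, x$n_x, x$n_y))
  if (x$decision != "n/a") cat(", decision:", x$decision)
  cat("\n")
  invisible(x)
}

#' Non-inferiority configuration for the ratio-of-means test
#'
#' @param margin_ratio non-inferiority margin on the ratio scale
#'   (default 0.80, i.e. a 20 % relative reduction).
#' @param alpha one-sided significance level (default 0.05).
#' @param ci_method `"delta_t"` (linear-scale delta method with a Welch
#'   t quantile; default), `"delta_z"` (normal quantile), `"log_delta"`
#'   (delta method on the log ratio) or `"bootstrap"` (percentile, raw
#'   data only).
#' @param boot_reps bootstrap replicates when `ci_method = "bootstrap"`.
#' @return List of class `"vz_ni_config"`.
#' @export
ni_config <- function(margin_ratio = 0.80, alpha = 0.05,
                      ci_method = c("delta_t", "delta_z", "log_delta",
                                    "bootstrap"),
                      boot_reps = 10000) {
  stopifnot(margin_ratio > 0, margin_ratio < 1, alpha > 0, alpha < 0.5)
  structure(list(margin_ratio = margin_ratio, alpha = alpha,
                 ci_method = match.arg(ci_method), boot_reps = boot_reps),
            class = "vz_ni_config")
}

# Delta-method pieces shared by the summary-stat and raw-data interfaces.
# a, b are the squared coefficients of variation of the two sample means;
# the Welch df uses the same variance components.
.ratio_delta <- function(mx, sx, nx, my, sy, ny) {
  R <- mx / my
  a <- sx^2 / (nx * mx^2)
  b <- sy^2 / (ny * my^2)
  list(R = R, se = abs(R) * sqrt(a + b), se_log = sqrt(a + b),
       df = (a + b)^2 / (a^2 / (nx - 1) + b^2 / (ny - 1)))
}

#' Ratio-of-means test from summary statistics
#'
#' Mean ratio (experimental over control) with a delta-method confidence
#' interval, tested for non-inferiority against a ratio margin
#' (one-sided) or for equality of means (two-sided).
#'
#' @param mx,sx,nx mean, SD and n of the experimental arm.
#' @param my,sy,ny mean, SD and n of the control arm (mean must be > 0).
#' @param config an [ni_config()] (`"bootstrap"` is not available from
#'   summaries).
#' @param sided `"one"` (non-inferiority; default) or `"two"`
#'   (superiority at level `2 * alpha` two-sided, i.e. a conventional
#'   95 % CI at the default).
#' @param endpoint endpoint name for the report.
#' @return An [arm_comparison()]. One-sided: `ci = (lower, Inf)` with
#'   `lower = R - t[1-alpha, nu] * SE` (Welch `nu`), P for H0: ratio at
#'   or below the margin, decision `"non_inferior"` iff the lower bound
#'   exceeds the margin; if non-inferior, superiority is then tested at
#'   the two-sided level against 1 (hierarchical closed testing) and the
#'   decision upgraded to `"superior"` when the two-sided lower bound
#'   exceeds 1. Two-sided: symmetric CI and P for H0: ratio = 1.
#' @export
ratio_of_means <- function(mx, sx, nx, my, sy, ny,
                           config = ni_config(), sided = c("one", "two"),
                           endpoint = "endpoint") {
  sided <- match.arg(sided)
  if (nx < 2 || ny < 2) stop("insufficient data: need n >= 2 per arm",
                             call. = FALSE)
  if (my <= 0) stop("undefined ratio: control mean must be positive",
                    call. = FALSE)
  d <- .ratio_delta(mx, sx, nx, my, sy, ny)
  alpha <- config$alpha
  method <- config$ci_method
  if (method == "bootstrap") {
    stop("bootstrap CI requires raw data; use mean_ratio_ni()", call. = FALSE)
  }
  q <- function(p) if (method == "delta_z") stats::qnorm(p)
                   else stats::qt(p, d$df)
  pdist <- function(t) if (method == "delta_z")
    stats::pnorm(t, lower.tail = FALSE) else
    stats::pt(t, d$df, lower.tail = FALSE)

  if (sided == "one") {
    lo <- if (method == "log_delta") exp(log(d$R) - q(1 - alpha) * d$se_log)
          else d$R - q(1 - alpha) * d$se
    tstat <- if (method == "log_delta")
      (log(d$R) - log(config$margin_ratio)) / d$se_log
      else (d$R - config$margin_ratio) / d$se
    p <- pdist(tstat)
    decision <- if (lo > config$margin_ratio) "non_inferior" else
      "not_established"
    if (decision == "non_inferior") {
      lo2 <- if (method == "log_delta")
        exp(log(d$R) - q(1 - alpha / 2) * d$se_log)
        else d$R - q(1 - alpha / 2) * d$se
      if (lo2 > 1) decision <- "superior"
    }
    arm_comparison(endpoint, "mean_ratio", d$R, lo, Inf, alpha, "one", p,
                   nx, ny, decision,
                   extra = list(se = d$se, df = d$df, method = method,
                                margin = config$margin_ratio))
  } else {
    lo <- if (method == "log_delta")
      exp(log(d$R) - q(1 - alpha / 2) * d$se_log)
      else d$R - q(1 - alpha / 2) * d$se
    hi <- if (method == "log_delta")
      exp(log(d$R) + q(1 - alpha / 2) * d$se_log)
      else d$R + q(1 - alpha / 2) * d$se
    tstat <- if (method == "log_delta") log(d$R) / d$se_log
             else (d$R - 1) / d$se
    p <- 2 * pdist(abs(tstat))
    arm_comparison(endpoint, "mean_ratio", d$R, lo, hi, alpha, "two", p,
                   nx, ny, "n/a",
                   extra = list(se = d$se, df = d$df, method = method))
  }
}

#' Ratio-of-means non-inferiority test on per-subject values
#'
#' @param x per-subject endpoint values, experimental (sidestream) arm;
#'   `NA`s dropped with a message.
#' @param y per-subject endpoint values, control (mainstream) arm.
#' @param config an [ni_config()].
#' @param sided `"one"` or `"two"`; see [ratio_of_means()].
#' @param endpoint endpoint name.
#' @return An [arm_comparison()].
#' @export
mean_ratio_ni <- function(x, y, config = ni_config(),
                          sided = c("one", "two"), endpoint = "endpoint") {
  sided <- match.arg(sided)
  if (anyNA(x) || anyNA(y)) {
    message("dropping ", sum(is.na(x)) + sum(is.na(y)),
            " missing per-subject value(s) for '", endpoint, "'")
    x <- x[!is.na(x)]; y <- y[!is.na(y)]
  }
  if (config$ci_method == "bootstrap") {
    if (length(x) < 2 || length(y) < 2)
      stop("insufficient data: need n >= 2 per arm", call. = FALSE)
    if (mean(y) <= 0) stop("undefined ratio: control mean must be positive",
                           call. = FALSE)
    R <- mean(x) / mean(y)
    reps <- config$boot_reps
    bx <- matrix(sample(x, length(x) * reps, replace = TRUE), nrow = reps)
    by <- matrix(sample(y, length(y) * reps, replace = TRUE), nrow = reps)
    ratios <- rowMeans(bx) / rowMeans(by)
    alpha <- config$alpha
    if (sided == "one") {
      lo <- unname(stats::quantile(ratios, alpha))
      p <- mean(ratios <= config$margin_ratio)
      decision <- if (lo > config$margin_ratio) "non_inferior" else
        "not_established"
      return(arm_comparison(endpoint, "mean_ratio", R, lo, Inf, alpha,
                            "one", p, length(x), length(y), decision,
                            extra = list(method = "bootstrap")))
    }
    ci <- unname(stats::quantile(ratios, c(alpha / 2, 1 - alpha / 2)))
    p <- 2 * min(mean(ratios <= 1), mean(ratios >= 1))
    return(arm_comparison(endpoint, "mean_ratio", R, ci[1], ci[2], alpha,
                          "two", p, length(x), length(y),
                          extra = list(method = "bootstrap")))
  }
  ratio_of_means(mean(x), stats::sd(x), length(x),
                 mean(y), stats::sd(y), length(y),
                 config = config, sided = sided, endpoint = endpoint)
}

#' Absolute mean difference with Welch confidence interval
#'
#' Two-arm difference in means (equivalent to the slope of a univariate
#' linear regression on the arm indicator), Welch two-sided CI and P.
#'
#' @param x,y per-subject values (experimental, control); `NA`s dropped.
#' @param alpha two-sided significance level (default 0.05).
#' @param endpoint endpoint name.
#' @return An [arm_comparison()].
#' @export
mean_difference <- function(x, y, alpha = 0.05, endpoint = "endpoint") {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 2 || length(y) < 2)
    stop("insufficient data: need n >= 2 per arm", call. = FALSE)
  tt <- stats::t.test(x, y, conf.level = 1 - alpha)
  arm_comparison(endpoint, "mean_diff", mean(x) - mean(y),
                 tt$conf.int[1], tt$conf.int[2], alpha, "two", tt$p.value,
                 length(x), length(y))
}

#' Odds ratio for a 2x2 table with Wald interval
#'
#' @param a,b events and non-events in the experimental arm.
#' @param c,d events and non-events in the control arm.
#' @param alpha two-sided level (default 0.05).
#' @param endpoint endpoint name.
#' @return An [arm_comparison()] with the Wald log-scale CI and P. When
#'   any cell is zero the Haldane--Anscombe correction (0.5 added to all
#'   cells) is applied; this is flagged in `extra$corrected`.
#' @export
odds_ratio_2x2 <- function(a, b, c, d, alpha = 0.05, endpoint = "endpoint") {
  stopifnot(a >= 0, b >= 0, c >= 0, d >= 0)
  if ((a + b) == 0 || (c + d) == 0)
    stop("undefined odds ratio: an arm has zero subjects", call. = FALSE)
  corrected <- any(c(a, b, c, d) == 0)
  est <- if (corrected) NA_real_ else (a / b) / (c / d)
  aa <- a; bb <- b; cc <- c; dd <- d
  if (corrected) { aa <- a + 0.5; bb <- b + 0.5; cc <- c + 0.5; dd <- d + 0.5 }
  or <- (aa / bb) / (cc / dd)
  if (is.na(est)) est <- or
  se <- sqrt(1 / aa + 1 / bb + 1 / cc + 1 / dd)
  z <- stats::qnorm(1 - alpha / 2)
  p <- 2 * stats::pnorm(abs(log(or)) / se, lower.tail = FALSE)
  arm_comparison(endpoint, "odds_ratio", est,
                 exp(log(or) - z * se), exp(log(or) + z * se),
                 alpha, "two", p, a + b, c + d,
                 extra = list(corrected = corrected, a = a, b = b,
                              c = c, d = d))
}

#' Kaplan-Meier curves and log-rank test between arms
#'
#' Product-limit estimates per arm and the standard two-sample log-rank
#' chi-square (1 df). Subjects who die during follow-up should be coded
#' `event = FALSE` (censored), per the trial's time-to-event rule.
#'
#' @param time time to event or censoring (>= 0).
#' @param event logical/0-1 event indicator.
#' @param arm arm labels (two levels).
#' @param endpoint endpoint name.
#' @return An [arm_comparison()] (estimate is the log-rank chi-square,
#'   no CI) with `extra$fit` the [survival::survfit] object and
#'   `extra$chisq`. With no events anywhere the P value is `NA`.
#' @export
km_logrank <- function(time, event, arm, endpoint = "endpoint") {
  stopifnot(all(time >= 0), length(unique(arm)) == 2)
  event <- as.integer(event)
  fit <- survival::survfit(survival::Surv(time, event) ~ arm)
  if (sum(event) == 0) {
    return(arm_comparison(endpoint, "logrank", NA_real_, -Inf, Inf, 0.05,
                          "two", NA_real_, sum(arm == unique(arm)[1]),
                          sum(arm == unique(arm)[2]),
                          extra = list(fit = fit, chisq = NA_real_)))
  }
  sd <- survival::survdiff(survival::Surv(time, event) ~ arm)
  p <- stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE)
  tab <- table(arm)
  arm_comparison(endpoint, "logrank", unname(sd$chisq), 0, Inf, 0.05,
                 "two", p, unname(tab[1]), unname(tab[2]),
                 extra = list(fit = fit, chisq = unname(sd$chisq),
                              obs = sd$obs, exp = sd$exp))
}

#' Subgroup analysis with interaction test
#'
#' Splits subjects at the in-sample median of a continuous covariate,
#' runs the ratio-of-means non-inferiority analysis within each stratum,
#' and tests the arm-by-subgroup interaction as a z-test on the
#' difference of the two log mean ratios (delta-method standard errors).
#'
#' @param values per-subject endpoint values.
#' @param arm per-subject arm labels (`"sidestream"`/`"mainstream"`).
#' @param split_values per-subject covariate to split at its median
#'   (values at the median go to the lower stratum).
#' @param config an [ni_config()].
#' @param endpoint endpoint name.
#' @return List: `strata` (named list of [arm_comparison()], strata with
#'   fewer than 2 subjects in either arm skipped with a warning),
#'   `interaction_z`, `interaction_p`.
#' @export
subgroup_interaction <- function(values, arm, split_values,
                                 config = ni_config(),
                                 endpoint = "endpoint") {
  stopifnot(length(values) == length(arm),
            length(values) == length(split_values))
  med <- stats::median(split_values, na.rm = TRUE)
  stratum <- ifelse(split_values <= med, "low", "high")
  res <- list()
  logr <- se_log <- c()
  for (s in c("low", "high")) {
    sel <- stratum == s & !is.na(values)
    x <- values[sel & arm == "sidestream"]
    y <- values[sel & arm == "mainstream"]
    if (length(x) < 2 || length(y) < 2) {
      warning("stratum '", s, "' skipped: fewer than 2 subjects per arm",
              call. = FALSE)
      next
    }
    cmp <- ratio_of_means(mean(x), stats::sd(x), length(x),
                          mean(y), stats::sd(y), length(y),
                          config = config, sided = "one",
                          endpoint = paste0(endpoint, " [", s, "]"))
    res[[s]] <- cmp
    logr[s] <- log(cmp$estimate)
    se_log[s] <- cmp$extra$se / cmp$estimate
  }
  if (length(logr) == 2) {
    z <- (logr[["low"]] - logr[["high"]]) /
      sqrt(se_log[["low"]]^2 + se_log[["high"]]^2)
    p <- 2 * stats::pnorm(abs(z), lower.tail = FALSE)
  } else {
    z <- NA_real_; p <- NA_real_
  }
  list(strata = res, interaction_z = unname(z), interaction_p = unname(p))
}
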