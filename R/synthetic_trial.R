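#' Configuration of the synthetic two-arm trial generator
#'
#' Defaults emulate the study conditions of a two-arm postoperative
#' closed-loop ventilation trial: 39 subjects per arm, breath-by-breath
#' recording up to 6 h, extubation times lognormal with medians 4.5 h
#' (sidestream) and 4.2 h (mainstream), between-subject optimal-zone
#' proportions with means 0.69 / 0.79 and SDs 0.26 / 0.16, a mainstream
#' etCO2 sensor offset of +2 mmHg, transient first-hour sidestream
#' effects (higher RR and FiO2, lower VT), per-parameter missingness and
#' SpO2 quality-index dropouts, and arm-specific hypoxemia rates.
#'
#' Zone structure is produced by persistent excursion episodes (etCO2
#' drifting into the acceptable or critical band) rather than i.i.d.
#' noise, so proportions by breaths and by time differ realistically.
#'
#' @param n_per_arm subjects per arm.
#' @param seed RNG seed; fixes the whole trial.
#' @param horizon_s maximum recording duration, seconds.
#' @param extubation_median_h,extubation_log_sd lognormal extubation
#'   model per arm (sidestream, mainstream).
#' @param weaning_median_h,weaning_log_sd lognormal sedation-stop-to-
#'   extubation model per arm.
#' @param p_optimal_mean,p_optimal_sd between-subject distribution of
#'   the true optimal-zone proportion per arm (Beta, truncated to
#'   `[0.02, 0.995]`); a mean of 1 with SD 0 disables excursions.
#' @param setpoints named list of population setpoints: `vt_per_pbw`
#'   (mL/kg), `pmax` (cm H2O), `etco2` (mmHg), `spo2` (%), `fio2`
#'   (fraction), `rr` (breaths/min), `peep` (cm H2O).
#' @param between_sd named list of between-subject setpoint SDs.
#' @param noise_sd named list of within-subject (breath-level) marginal
#'   SDs of the AR(1) fluctuations.
#' @param ar1 AR(1) coefficient of breath-level fluctuations, in `[0, 1)`.
#' @param etco2_offset_mainstream additive mainstream sensor offset,
#'   mmHg (mainstream capnography reads higher).
#' @param early_effects list describing the transient sidestream
#'   first-hour effects: `duration_s`, `rr`, `vt_per_pbw`, `fio2`
#'   (additive shifts).
#' @param excursion_mean_len mean excursion episode length, breaths.
#' @param excursion_critical_frac fraction of excursion episodes that
#'   reach the critical band.
#' @param hypox_rate stationary fraction of breaths in a hypoxemic dip,
#'   per arm.
#' @param hypox_mean_len mean hypoxemic dip length, breaths.
#' @param missing_rate per-parameter missingness rate (VT, Pmax, etCO2,
#'   SpO2, RR).
#' @param missing_mode `"mcar"` (independent per breath) or `"burst"`
#'   (episodic runs with the same stationary rate).
#' @param qi_dropout_rate fraction of breaths whose SpO2 quality index
#'   falls below the 50 % gate.
#' @param calibration_offset per-arm additive offsets on the logit of
#'   `p_optimal_mean`, set by [calibrate_to_target()].
#' @return List of class `"vz_generator_config"`.
#' @export
generator_config <- function(n_per_arm = 39,
                             seed = 1,
                             horizon_s = 21600,
                             extubation_median_h = c(4.5, 4.2),
                             extubation_log_sd = c(0.63, 0.50),
                             weaning_median_h = c(1.2, 1.7),
                             weaning_log_sd = c(0.6, 0.6),
                             p_optimal_mean = c(0.69, 0.79),
                             p_optimal_sd = c(0.26, 0.16),
                             setpoints = list(vt_per_pbw = 6.8, pmax = 18,
                                              etco2 = 38, spo2 = 96.5,
                                              fio2 = 0.35, rr = 14,
                                              peep = 5),
                             between_sd = list(vt_per_pbw = 0.35, pmax = 2,
                                               etco2 = 1.5, spo2 = 0.8,
                                               fio2 = 0.04, rr = 1.2),
                             noise_sd = list(vt_per_pbw = 0.25, pmax = 1.2,
                                             etco2 = 1.2, spo2 = 0.5,
                                             rr = 0.8),
                             ar1 = 0.9,
                             etco2_offset_mainstream = 2,
                             early_effects = list(duration_s = 3600,
                                                  rr = 2,
                                                  vt_per_pbw = -0.5,
                                                  fio2 = 0.05),
                             excursion_mean_len = 60,
                             excursion_critical_frac = 0.25,
                             hypox_rate = c(0.0033, 0.0013),
                             hypox_mean_len = 20,
                             missing_rate = 0.01,
                             missing_mode = c("mcar", "burst"),
                             qi_dropout_rate = 0.05,
                             calibration_offset = c(0, 0)) {
  missing_mode <- match.arg(missing_mode)
  stopifnot(n_per_arm >= 1, horizon_s > 0,
            all(p_optimal_mean > 0), all(p_optimal_mean <= 1),
            all(p_optimal_sd >= 0), ar1 >= 0, ar1 < 1,
            all(hypox_rate >= 0), all(hypox_rate < 1),
            missing_rate >= 0, missing_rate < 1,
            qi_dropout_rate >= 0, qi_dropout_rate < 1)
  structure(list(n_per_arm = n_per_arm, seed = seed, horizon_s = horizon_s,
                 extubation_median_h = extubation_median_h,
                 extubation_log_sd = extubation_log_sd,
                 weaning_median_h = weaning_median_h,
                 weaning_log_sd = weaning_log_sd,
                 p_optimal_mean = p_optimal_mean,
                 p_optimal_sd = p_optimal_sd,
                 setpoints = setpoints, between_sd = between_sd,
                 noise_sd = noise_sd, ar1 = ar1,
                 etco2_offset_mainstream = etco2_offset_mainstream,
                 early_effects = early_effects,
                 excursion_mean_len = excursion_mean_len,
                 excursion_critical_frac = excursion_critical_frac,
                 hypox_rate = hypox_rate, hypox_mean_len = hypox_mean_len,
                 missing_rate = missing_rate, missing_mode = missing_mode,
                 qi_dropout_rate = qi_dropout_rate,
                 calibration_offset = calibration_offset),
            class = "vz_generator_config")
}

# Stationary AR(1) series of length n with marginal SD `sd`.
.ar1_series <- function(n, sd, phi) {
  if (sd == 0 || n == 0) return(numeric(n))
  innov <- stats::rnorm(n, 0, sd * sqrt(1 - phi^2))
  innov[1] <- stats::rnorm(1, 0, sd)
  as.numeric(stats::filter(innov, phi, method = "recursive"))
}

# Two-state alternating-renewal indicator with stationary on-fraction q
# and mean on-sojourn `len` breaths (geometric sojourns). Vectorised by
# drawing segments.
.episode_indicator <- function(n, q, len) {
  if (n == 0) return(logical(0))
  if (q <= 0) return(rep(FALSE, n))
  if (q >= 1) return(rep(TRUE, n))
  mu <- 1 / len                      # leave prob from the on state
  nu <- min(1, mu * q / (1 - q))     # enter prob from the off state
  state <- stats::runif(1) < q
  out <- logical(n)
  i <- 1L
  while (i <= n) {
    p_leave <- if (state) mu else nu
    run <- stats::rgeom(1, p_leave) + 1L
    j <- min(n, i + run - 1L)
    out[i:j] <- state
    i <- j + 1L
    state <- !state
  }
  out
}

# Beta draw parameterised by mean and SD, truncated to [0.02, 0.995].
.rbeta_ms <- function(n, m, s) {
  if (s == 0) return(rep(min(m, 0.995), n))
  v <- s^2
  if (v >= m * (1 - m)) {
    stop("p_optimal_sd too large for mean ", m, call. = FALSE)
  }
  k <- m * (1 - m) / v - 1
  pmin(pmax(stats::rbeta(n, m * k, (1 - m) * k), 0.02), 0.995)
}

.missing_mask <- function(n, rate, mode) {
  if (rate <= 0 || n == 0) return(rep(FALSE, n))
  if (mode == "mcar") stats::runif(n) < rate
  else .episode_indicator(n, rate, 30)
}

# One subject's breath stream; `arm_i` is 1 (sidestream) or 2 (mainstream).
.gen_subject <- function(cfg, sid, arm_i, pbw, duration_s, p_opt) {
  sp <- cfg$setpoints; bs <- cfg$between_sd; ns <- cfg$noise_sd
  rr_set <- max(8, sp$rr + stats::rnorm(1, 0, bs$rr))
  n_max <- ceiling(duration_s / (60 / (rr_set + 4))) + 10L

  sidestream <- arm_i == 1
  rr <- rr_set + .ar1_series(n_max, ns$rr, cfg$ar1)
  # transient first-hour effects in the sidestream arm
  t_approx <- cumsum(60 / pmax(rr, 6))
  early <- sidestream & t_approx <= cfg$early_effects$duration_s
  rr <- pmax(rr + ifelse(early, cfg$early_effects$rr, 0), 6)
  t_s <- cumsum(60 / rr)
  keep <- t_s < duration_s
  n <- sum(keep)
  if (n == 0) return(NULL)
  rr <- rr[seq_len(n)]; t_s <- t_s[seq_len(n)]; early <- early[seq_len(n)]

  vt_set <- min(max(sp$vt_per_pbw + stats::rnorm(1, 0, bs$vt_per_pbw), 5.5),
                7.6)
  vt <- vt_set + .ar1_series(n, ns$vt_per_pbw, cfg$ar1) +
    ifelse(early, cfg$early_effects$vt_per_pbw, 0)
  pmax_v <- sp$pmax + stats::rnorm(1, 0, bs$pmax) +
    .ar1_series(n, ns$pmax, cfg$ar1)
  fio2_set <- min(max(sp$fio2 + stats::rnorm(1, 0, bs$fio2), 0.25), 0.40)
  fio2 <- pmin(fio2_set + ifelse(early, cfg$early_effects$fio2, 0), 1)

  etco2_set <- sp$etco2 + stats::rnorm(1, 0, bs$etco2) +
    if (sidestream) 0 else cfg$etco2_offset_mainstream
  etco2 <- etco2_set + .ar1_series(n, ns$etco2, cfg$ar1)

  # excursion episodes drive the non-optimal fraction
  exc <- .episode_indicator(n, 1 - p_opt, cfg$excursion_mean_len)
  if (any(exc)) {
    seg <- cumsum(c(TRUE, diff(exc) != 0))      # segment index per breath
    on_segs <- unique(seg[exc])
    crit <- stats::runif(length(on_segs)) < cfg$excursion_critical_frac
    high <- stats::runif(length(on_segs)) < 0.5
    target <- ifelse(crit, ifelse(high, 53, 22), ifelse(high, 48.5, 27.5))
    target <- target + stats::rnorm(length(on_segs), 0, 0.5)
    etco2[exc] <- target[match(seg[exc], on_segs)] +
      stats::rnorm(sum(exc), 0, 0.6)
  }

  spo2_set <- min(sp$spo2 + stats::rnorm(1, 0, bs$spo2), 99)
  spo2 <- pmin(spo2_set + .ar1_series(n, ns$spo2, cfg$ar1), 100)
  dip <- .episode_indicator(n, cfg$hypox_rate[arm_i], cfg$hypox_mean_len)
  if (any(dip)) {
    spo2[dip] <- pmin(82 + stats::rnorm(sum(dip), 0, 1.2), 84.8)
  }

  qi <- pmin(95 + stats::rnorm(n, 0, 3), 100)
  qi_drop <- stats::runif(n) < cfg$qi_dropout_rate
  qi[qi_drop] <- stats::runif(sum(qi_drop), 0, 50)

  mm <- cfg$missing_mode; mr <- cfg$missing_rate
  vt[.missing_mask(n, mr, mm)] <- NA
  pmax_v[.missing_mask(n, mr, mm)] <- NA
  etco2[.missing_mask(n, mr, mm)] <- NA
  spo2[.missing_mask(n, mr, mm)] <- NA
  rr_rec <- rr; rr_rec[.missing_mask(n, mr, mm)] <- NA

  data.frame(subject_id = sid, t_s = round(t_s, 3),
             vt_ml = round(vt * pbw, 1),
             pmax_cmh2o = round(pmax_v, 1),
             etco2_mmhg = round(etco2, 1),
             spo2_pct = round(spo2, 1),
             spo2_qi_pct = round(qi, 1),
             fio2 = round(fio2, 3),
             rr_bpm = round(rr_rec, 1),
             peep_cmh2o = cfg$setpoints$peep,
             stringsAsFactors = FALSE)
}

#' Generate a complete synthetic two-arm trial
#'
#' Produces a subject table, a breath-by-breath table and a truth record
#' with every latent quantity (per-subject true optimal proportions and
#' the arm-level target means), for parameter-recovery testing of the
#' full pipeline. Output is bit-for-bit reproducible from
#' `config$seed`.
#'
#' @param config a [generator_config()].
#' @return List `subjects` (data.frame in the [read_subjects()] schema),
#'   `breaths` (data.frame in the [read_breaths()] schema) and `truth`
#'   (list with `p_optimal_subject`, `arm_target_mean`, `seed`).
#' @export
generate_trial <- function(config = generator_config()) {
  cfg <- config
  set.seed(cfg$seed)
  n <- cfg$n_per_arm
  arms <- c("sidestream", "mainstream")
  arm_i <- rep(1:2, each = n)
  ids <- sprintf("S%03d", seq_len(2 * n))

  sex <- ifelse(stats::runif(2 * n) < 0.72, "male", "female")
  height <- round(ifelse(sex == "male", stats::rnorm(2 * n, 178, 7),
                         stats::rnorm(2 * n, 166, 6)), 1)
  pbw <- round(predicted_body_weight(height, sex), 1)

  ext_h <- stats::rlnorm(2 * n, log(cfg$extubation_median_h[arm_i]),
                         cfg$extubation_log_sd[arm_i])
  ext_s <- round(pmax(ext_h * 3600, 1200))
  wean_h <- stats::rlnorm(2 * n, log(cfg$weaning_median_h[arm_i]),
                          cfg$weaning_log_sd[arm_i])
  sed_s <- round(pmax(ext_s - wean_h * 3600, 0))

  m_adj <- stats::plogis(stats::qlogis(pmin(cfg$p_optimal_mean, 0.999)) +
                           cfg$calibration_offset)
  p_opt <- numeric(2 * n)
  for (a in 1:2) {
    p_opt[arm_i == a] <- .rbeta_ms(n, m_adj[a], cfg$p_optimal_sd[a])
  }

  subjects <- data.frame(
    subject_id = ids, arm = arms[arm_i], received_arm = arms[arm_i],
    height_cm = height, sex = sex, pbw_kg = pbw,
    sedation_stop_s = sed_s, extubation_s = ext_s,
    reintubated_48h = stats::runif(2 * n) < 0.04,
    pneumonia = stats::runif(2 * n) < 0.04,
    pneumothorax = stats::runif(2 * n) < 0.10,
    atelectasis = stats::runif(2 * n) < 0.03,
    icu_los_d = round(1 + stats::rexp(2 * n, 2), 1),
    hosp_los_d = round(5 + stats::rlnorm(2 * n, log(2.5), 0.5), 1),
    died_day30 = stats::runif(2 * n) < 0.04,
    stringsAsFactors = FALSE)

  streams <- vector("list", 2 * n)
  for (i in seq_len(2 * n)) {
    dur <- min(ext_s[i], cfg$horizon_s)
    streams[[i]] <- .gen_subject(cfg, ids[i], arm_i[i], pbw[i], dur,
                                 p_opt[i])
  }
  breaths <- do.call(rbind, streams)
  rownames(breaths) <- NULL

  truth <- list(p_optimal_subject = stats::setNames(p_opt, ids),
                arm_target_mean = stats::setNames(as.numeric(m_adj), arms),
                seed = cfg$seed)
  list(subjects = subjects, breaths = breaths, truth = truth)
}

# Arm-level mean optimal proportions of one generated trial.
.trial_arm_means <- function(trial, window = analysis_window()) {
  ss <- subject_summaries(trial$breaths, trial$subjects, window)
  c(sidestream = mean(ss$p_breaths_optimal[ss$arm == "sidestream"],
                      na.rm = TRUE),
    mainstream = mean(ss$p_breaths_optimal[ss$arm == "mainstream"],
                      na.rm = TRUE))
}

#' Calibrate the generator to target arm-level optimal proportions
#'
#' Adjusts the generator's logit-scale offsets until the arm-level mean
#' optimal-zone proportions, measured through the actual
#' classify-and-summarise pipeline and averaged over replicate trials,
#' fall within a tolerance of the targets.
#'
#' @param config a [generator_config()].
#' @param targets per-arm target mean optimal proportions, each in
#'   (0, 1); default the study conditions `c(0.69, 0.79)`.
#' @param tol calibration tolerance (default 0.03).
#' @param reps replicate trials per evaluation (default 20).
#' @param max_iter maximum adjustment rounds.
#' @return The adjusted config, with attribute `"calibration"` recording
#'   the measured arm means per iteration.
#' @export
calibrate_to_target <- function(config = generator_config(),
                                targets = c(0.69, 0.79), tol = 0.03,
                                reps = 20, max_iter = 8) {
  stopifnot(all(targets > 0), all(targets < 1))
  cfg <- config
  cfg$p_optimal_mean <- targets
  history <- list()
  best <- NULL; best_err <- Inf
  for (iter in seq_len(max_iter)) {
    means <- matrix(0, reps, 2)
    for (r in seq_len(reps)) {
      cr <- cfg
      cr$seed <- cfg$seed + 7919L * iter + r
      means[r, ] <- .trial_arm_means(generate_trial(cr))
    }
    m <- colMeans(means)
    history[[iter]] <- m
    err <- max(abs(m - targets))
    if (err < best_err) { best <- cfg; best_err <- err }
    if (err <= tol) {
      attr(cfg, "calibration") <- history
      return(cfg)
    }
    cfg$calibration_offset <- cfg$calibration_offset +
      (stats::qlogis(targets) - stats::qlogis(pmin(pmax(m, 0.01), 0.99)))
  }
  stop("calibration did not converge within ", max_iter,
       " iterations; best offsets: ",
       paste(signif(best$calibration_offset, 4), collapse = ", "),
       " (max error ", signif(best_err, 3), ")", call. = FALSE)
}
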