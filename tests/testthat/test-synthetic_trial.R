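# Reduced problem sizes (fewer subjects, shorter horizons) keep these
# structural checks fast; the full study conditions are exercised in the
# acceptance suite.

test_that("generated trials are deterministic given the seed", {
  cfg <- generator_config(n_per_arm = 4, seed = 17, horizon_s = 3600)
  a <- generate_trial(cfg)
  b <- generate_trial(cfg)
  expect_identical(a$subjects, b$subjects)
  expect_identical(a$breaths, b$breaths)
  # byte-identical CSV output
  fa <- withr::local_tempfile(fileext = ".csv")
  fb <- withr::local_tempfile(fileext = ".csv")
  write_breaths(a$breaths, fa)
  write_breaths(b$breaths, fb)
  expect_identical(readLines(fa), readLines(fb))
  # and a different seed changes the stream
  c2 <- generate_trial(generator_config(n_per_arm = 4, seed = 18,
                                        horizon_s = 3600))
  expect_false(identical(a$breaths, c2$breaths))
})

test_that("trial structure matches the configured design", {
  cfg <- generator_config(n_per_arm = 8, seed = 2)
  tr <- generate_trial(cfg)
  expect_equal(nrow(tr$subjects), 16)
  expect_equal(sum(tr$subjects$arm == "sidestream"), 8)
  expect_true(all(tr$breaths$subject_id %in% tr$subjects$subject_id))
  # breath times strictly increasing within subject
  by_subj <- split(tr$breaths$t_s, tr$breaths$subject_id)
  expect_true(all(vapply(by_subj, function(t) all(diff(t) > 0), logical(1))))
  # subjects ventilated >= 90 min have over 1000 breaths at ~14/min
  long <- tr$subjects$subject_id[
    pmin(tr$subjects$extubation_s, cfg$horizon_s) >= 5400]
  expect_true(all(vapply(by_subj[long], length, integer(1)) > 1000))
  # generated values satisfy the read-side plausibility bounds
  f <- withr::local_tempfile(fileext = ".csv")
  write_breaths(tr$breaths, f)
  expect_no_warning(read_breaths(f))
})

test_that("noise-free optimal setpoints give all-optimal classification", {
  cfg <- generator_config(
    n_per_arm = 2, seed = 5, horizon_s = 1800,
    p_optimal_mean = c(1, 1), p_optimal_sd = c(0, 0),
    between_sd = list(vt_per_pbw = 0, pmax = 0, etco2 = 0, spo2 = 0,
                      fio2 = 0, rr = 0),
    noise_sd = list(vt_per_pbw = 0, pmax = 0, etco2 = 0, spo2 = 0, rr = 0),
    hypox_rate = c(0, 0), missing_rate = 0, qi_dropout_rate = 0)
  tr <- generate_trial(cfg)
  cl <- classify_breaths(tr$breaths,
                         setNames(tr$subjects$pbw_kg,
                                  tr$subjects$subject_id))
  expect_true(all(cl$zone == "optimal"))
  ss <- subject_summaries(tr$breaths, tr$subjects)
  expect_true(all(ss$p_breaths_optimal == 1))
})

test_that("an out-of-range etCO2 setpoint makes every breath critical", {
  cfg <- generator_config(
    n_per_arm = 2, seed = 5, horizon_s = 1800,
    p_optimal_mean = c(1, 1), p_optimal_sd = c(0, 0),
    setpoints = list(vt_per_pbw = 6.8, pmax = 18, etco2 = 55, spo2 = 96.5,
                     fio2 = 0.35, rr = 14, peep = 5),
    between_sd = list(vt_per_pbw = 0, pmax = 0, etco2 = 0, spo2 = 0,
                      fio2 = 0, rr = 0),
    noise_sd = list(vt_per_pbw = 0, pmax = 0, etco2 = 0, spo2 = 0, rr = 0),
    etco2_offset_mainstream = 0,
    hypox_rate = c(0, 0), missing_rate = 0, qi_dropout_rate = 0)
  tr <- generate_trial(cfg)
  cl <- classify_breaths(tr$breaths,
                         setNames(tr$subjects$pbw_kg,
                                  tr$subjects$subject_id))
  expect_true(all(cl$zone == "critical"))
})

test_that("arm effects appear in the generated streams", {
  cfg <- generator_config(n_per_arm = 10, seed = 9, horizon_s = 10800)
  tr <- generate_trial(cfg)
  b <- merge(tr$breaths, tr$subjects[c("subject_id", "arm")])
  # mainstream etCO2 sensor reads higher on average
  m_et <- tapply(b$etco2_mmhg, b$arm, mean, na.rm = TRUE)
  expect_gt(m_et[["mainstream"]] - m_et[["sidestream"]], 0.5)
  # transient first-hour sidestream effects: higher RR and FiO2, lower VT
  early <- b$t_s <= 3600
  late <- b$t_s > 3600
  rr_gap_early <- mean(b$rr_bpm[early & b$arm == "sidestream"], na.rm = TRUE) -
    mean(b$rr_bpm[early & b$arm == "mainstream"], na.rm = TRUE)
  rr_gap_late <- mean(b$rr_bpm[late & b$arm == "sidestream"], na.rm = TRUE) -
    mean(b$rr_bpm[late & b$arm == "mainstream"], na.rm = TRUE)
  expect_gt(rr_gap_early, rr_gap_late + 0.5)
  fio2_gap <- mean(b$fio2[early & b$arm == "sidestream"]) -
    mean(b$fio2[late & b$arm == "sidestream"])
  expect_gt(fio2_gap, 0.02)
})

test_that("missingness and quality dropouts are injected at the set rates", {
  cfg <- generator_config(n_per_arm = 6, seed = 13, horizon_s = 7200,
                          missing_rate = 0.05, qi_dropout_rate = 0.10)
  tr <- generate_trial(cfg)
  for (col in c("vt_ml", "pmax_cmh2o", "etco2_mmhg", "spo2_pct")) {
    rate <- mean(is.na(tr$breaths[[col]]))
    expect_gt(rate, 0.02)
    expect_lt(rate, 0.10)
  }
  qi_fail <- mean(tr$breaths$spo2_qi_pct <= 50, na.rm = TRUE)
  expect_gt(qi_fail, 0.05)
  expect_lt(qi_fail, 0.15)
  # burst mode produces runs but the same stationary rate
  cfgb <- generator_config(n_per_arm = 6, seed = 13, horizon_s = 7200,
                           missing_rate = 0.05, missing_mode = "burst")
  trb <- generate_trial(cfgb)
  rate_b <- mean(is.na(trb$breaths$etco2_mmhg))
  expect_gt(rate_b, 0.01)
  expect_lt(rate_b, 0.15)
  runs <- rle(is.na(trb$breaths$etco2_mmhg))
  expect_gt(max(runs$lengths[runs$values]), 5)
})

test_that("extubation times follow the configured lognormal medians", {
  cfg <- generator_config(n_per_arm = 150, seed = 31, horizon_s = 900)
  tr <- generate_trial(cfg)
  med <- tapply(tr$subjects$extubation_s / 3600, tr$subjects$arm, median)
  expect_equal(unname(med[["sidestream"]]), 4.5, tolerance = 0.15)
  expect_equal(unname(med[["mainstream"]]), 4.2, tolerance = 0.15)
})

test_that("calibration rejects boundary targets and symmetric targets give ratio ~1", {
  expect_error(calibrate_to_target(generator_config(), targets = c(1, 0.8)),
               "targets")
  # identical arm targets: generated mean ratio close to 1 (small trial)
  cfg <- generator_config(n_per_arm = 25, seed = 44,
                          p_optimal_mean = c(0.75, 0.75),
                          p_optimal_sd = c(0.05, 0.05),
                          hypox_rate = c(0.002, 0.002))
  means <- rowMeans(sapply(1:4, function(r) {
    cfg$seed <- 44 + r
    ventzones:::.trial_arm_means(generate_trial(cfg))
  }))
  expect_equal(unname(means[1] / means[2]), 1, tolerance = 0.05)
})
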