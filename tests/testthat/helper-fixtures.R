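# Small in-code fixtures shared across test files.

# A minimal canonical breath row; override fields as needed.
breath_row <- function(subject_id = "A", t_s = 0, vt_ml = 420,
                       pmax_cmh2o = 18, etco2_mmhg = 38, spo2_pct = 96,
                       spo2_qi_pct = 95, fio2 = 0.35, rr_bpm = 14,
                       peep_cmh2o = 5) {
  data.frame(subject_id = subject_id, t_s = t_s, vt_ml = vt_ml,
             pmax_cmh2o = pmax_cmh2o, etco2_mmhg = etco2_mmhg,
             spo2_pct = spo2_pct, spo2_qi_pct = spo2_qi_pct, fio2 = fio2,
             rr_bpm = rr_bpm, peep_cmh2o = peep_cmh2o,
             stringsAsFactors = FALSE)
}

breath_table <- function(n, subject_id = "A", dt = 4, ...) {
  do.call(rbind, lapply(seq_len(n), function(i) {
    breath_row(subject_id = subject_id, t_s = (i - 1) * dt, ...)
  }))
}

subject_row <- function(subject_id = "A", arm = "sidestream",
                        received_arm = arm, height_cm = 175, sex = "male",
                        pbw_kg = 70, sedation_stop_s = 9000,
                        extubation_s = 16200, reintubated_48h = FALSE,
                        pneumonia = FALSE, pneumothorax = FALSE,
                        atelectasis = FALSE, icu_los_d = 1,
                        hosp_los_d = 7, died_day30 = FALSE) {
  data.frame(subject_id = subject_id, arm = arm, received_arm = received_arm,
             height_cm = height_cm, sex = sex, pbw_kg = pbw_kg,
             sedation_stop_s = sedation_stop_s, extubation_s = extubation_s,
             reintubated_48h = reintubated_48h, pneumonia = pneumonia,
             pneumothorax = pneumothorax, atelectasis = atelectasis,
             icu_los_d = icu_los_d, hosp_los_d = hosp_los_d,
             died_day30 = died_day30, stringsAsFactors = FALSE)
}

# Brute-force reference classifier written directly from the combination
# definition; deliberately scalar and independent of classify_breaths().
reference_zone <- function(vt_per_pbw, pmax, etco2, spo2, fio2) {
  band1 <- function(value, crit, opt) {
    if (is.na(value)) return(NA_character_)
    if (crit(value)) "critical" else if (opt(value)) "optimal" else "acceptable"
  }
  bands <- c(
    band1(vt_per_pbw, function(x) x > 12, function(x) x <= 8),
    band1(pmax, function(x) x >= 36, function(x) x <= 30),
    band1(etco2, function(x) x < 25 || x >= 51,
          function(x) x >= 30 && x <= 46),
    band1(spo2, function(x) x < 85,
          function(x) (!is.na(fio2) && fio2 <= 0.40 && x >= 93) ||
            (x >= 93 && x <= 98)))
  n_avail <- sum(!is.na(bands))
  if (any(bands == "critical", na.rm = TRUE)) return("critical")
  if (n_avail < 4) return("missing")
  if (all(bands == "optimal")) "optimal" else "acceptable"
}
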