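#' Zone boundary resolution options
#'
#' The printed zone table uses overlapping or gapped integer boundaries
#' for continuous quantities. The resolution used here closes the
#' optimal band on boundaries it shares with the acceptable band (VT 8
#' mL/kg; etCO2 30 and 46 mmHg; SpO2 93 and 98 %) and closes the
#' critical band on boundaries it shares with the acceptable band (Pmax
#' 36 cm H2O; etCO2 51 mmHg). Each choice can be flipped.
#'
#' @param vt8_optimal is VT exactly 8 mL/kg PBW optimal (default) or
#'   acceptable?
#' @param pmax36_critical is Pmax exactly 36 cm H2O critical (default)
#'   or acceptable?
#' @param etco2_30_optimal,etco2_46_optimal are etCO2 exactly 30 / 46
#'   mmHg optimal (default) or acceptable?
#' @param etco2_51_critical is etCO2 exactly 51 mmHg critical (default)
#'   or acceptable?
#' @param spo2_93_optimal,spo2_98_optimal are SpO2 exactly 93 / 98 %
#'   optimal (default) or acceptable?
#' @return Named list of logical flags, class `"vz_boundaries"`.
#' @export
zone_boundaries <- function(vt8_optimal = TRUE,
                            pmax36_critical = TRUE,
                            etco2_30_optimal = TRUE,
                            etco2_46_optimal = TRUE,
                            etco2_51_critical = TRUE,
                            spo2_93_optimal = TRUE,
                            spo2_98_optimal = TRUE) {
  structure(list(vt8_optimal = vt8_optimal,
                 pmax36_critical = pmax36_critical,
                 etco2_30_optimal = etco2_30_optimal,
                 etco2_46_optimal = etco2_46_optimal,
                 etco2_51_critical = etco2_51_critical,
                 spo2_93_optimal = spo2_93_optimal,
                 spo2_98_optimal = spo2_98_optimal),
            class = "vz_boundaries")
}

.band_levels <- c("critical", "acceptable", "optimal")

#' Band tidal volume per kg predicted body weight
#'
#' Optimal at or below 8 mL/kg PBW, acceptable above 8 up to 12,
#' critical above 12.
#'
#' @param vt_per_pbw tidal volume in mL per kg PBW; vectorised, `NA`
#'   yields `NA`.
#' @param boundaries a [zone_boundaries()] list.
#' @return Character vector in `c("optimal", "acceptable", "critical")`.
#' @export
band_vt <- function(vt_per_pbw, boundaries = zone_boundaries()) {
  opt <- if (boundaries$vt8_optimal) vt_per_pbw <= 8 else vt_per_pbw < 8
  ifelse(is.na(vt_per_pbw), NA_character_,
         ifelse(vt_per_pbw > 12, "critical",
                ifelse(opt, "optimal", "acceptable")))
}

#' Band maximum airway pressure
#'
#' Optimal at or below 30 cm H2O, critical at or above 36, acceptable
#' in between (the printed integer gap 30--31 is closed into the
#' acceptable interval).
#'
#' @param pmax_cmh2o maximum airway pressure, cm H2O; vectorised.
#' @inheritParams band_vt
#' @return Character band vector.
#' @export
band_pmax <- function(pmax_cmh2o, boundaries = zone_boundaries()) {
  crit <- if (boundaries$pmax36_critical) pmax_cmh2o >= 36 else pmax_cmh2o > 36
  ifelse(is.na(pmax_cmh2o), NA_character_,
         ifelse(crit, "critical",
                ifelse(pmax_cmh2o <= 30, "optimal", "acceptable")))
}

#' Band end-tidal CO2
#'
#' Optimal between 30 and 46 mmHg, acceptable 25--30 and 46--51,
#' critical below 25 or at/above 51.
#'
#' @param etco2_mmhg end-tidal CO2, mmHg; vectorised.
#' @inheritParams band_vt
#' @return Character band vector.
#' @export
band_etco2 <- function(etco2_mmhg, boundaries = zone_boundaries()) {
  x <- etco2_mmhg
  lo_opt <- if (boundaries$etco2_30_optimal) x >= 30 else x > 30
  hi_opt <- if (boundaries$etco2_46_optimal) x <= 46 else x < 46
  hi_crit <- if (boundaries$etco2_51_critical) x >= 51 else x > 51
  ifelse(is.na(x), NA_character_,
         ifelse(x < 25 | hi_crit, "critical",
                ifelse(lo_opt & hi_opt, "optimal", "acceptable")))
}

#' Band pulse-oximetry saturation
#'
#' Critical below 85 %. With FiO2 at or below 0.40, any SpO2 at or
#' above 93 % is optimal; otherwise 93--98 % is optimal and values above
#' 98 % (hyperoxemia under high FiO2) or 85--93 % are acceptable.
#' Missing FiO2 is treated as FiO2 above 0.40 (the relaxation requires
#' positive evidence).
#'
#' @param spo2_pct SpO2 in percent; vectorised.
#' @param fio2 inspired oxygen fraction (0.21--1.0); vectorised,
#'   recycled; may be `NA`.
#' @inheritParams band_vt
#' @return Character band vector.
#' @export
band_spo2 <- function(spo2_pct, fio2 = NA_real_,
                      boundaries = zone_boundaries()) {
  n <- max(length(spo2_pct), length(fio2))
  s <- rep_len(spo2_pct, n)
  f <- rep_len(fio2, n)
  ge93 <- if (boundaries$spo2_93_optimal) s >= 93 else s > 93
  le98 <- if (boundaries$spo2_98_optimal) s <= 98 else s < 98
  low_fio2 <- !is.na(f) & f <= 0.40
  ifelse(is.na(s), NA_character_,
         ifelse(s < 85, "critical",
                ifelse((low_fio2 & ge93) | (ge93 & le98), "optimal",
                       "acceptable")))
}

#' Classify breaths into ventilation zones
#'
#' Applies the four parameter bands (tidal volume per kg PBW, maximum
#' airway pressure, end-tidal CO2, SpO2) and combines them: any
#' available critical band makes the breath critical; all four bands
#' available and optimal makes it optimal; all four available with none
#' critical makes it acceptable; otherwise (at least one parameter
#' missing and no available critical band) the zone is missing.
#'
#' @param breaths breath data.frame in the canonical schema (see
#'   [read_breaths()]); one subject or many.
#' @param pbw_kg predicted body weight in kg: a single value, or a
#'   vector named by `subject_id`.
#' @param boundaries a [zone_boundaries()] list.
#' @return `breaths` augmented with columns `vt_per_pbw`, `band_vt`,
#'   `band_pmax`, `band_etco2`, `band_spo2`, `n_params_available`,
#'   `zone` and `hypoxemic`.
#' @export
classify_breaths <- function(breaths, pbw_kg,
                             boundaries = zone_boundaries()) {
  stopifnot(all(pbw_kg > 0, na.rm = TRUE))
  if (!is.null(names(pbw_kg))) {
    pbw <- unname(pbw_kg[breaths$subject_id])
  } else {
    pbw <- rep_len(pbw_kg, nrow(breaths))
  }
  out <- breaths
  out$vt_per_pbw <- out$vt_ml / pbw
  out$band_vt    <- band_vt(out$vt_per_pbw, boundaries)
  out$band_pmax  <- band_pmax(out$pmax_cmh2o, boundaries)
  out$band_etco2 <- band_etco2(out$etco2_mmhg, boundaries)
  out$band_spo2  <- band_spo2(out$spo2_pct, out$fio2, boundaries)

  bands <- cbind(out$band_vt, out$band_pmax, out$band_etco2, out$band_spo2)
  avail <- !is.na(bands)
  out$n_params_available <- rowSums(avail)
  any_crit <- rowSums(bands == "critical", na.rm = TRUE) > 0
  all_opt  <- rowSums(bands == "optimal", na.rm = TRUE) == 4
  complete <- out$n_params_available == 4
  out$zone <- ifelse(any_crit, "critical",
                     ifelse(complete & all_opt, "optimal",
                            ifelse(complete, "acceptable", "missing")))
  out$hypoxemic <- flag_hypoxemia(out)
  out
}

#' Classify a single breath
#'
#' Scalar convenience wrapper around [classify_breaths()].
#'
#' @param vt_ml,pmax_cmh2o,etco2_mmhg,spo2_pct,fio2 breath measurements
#'   (may be `NA`).
#' @param pbw_kg predicted body weight, kg.
#' @param boundaries a [zone_boundaries()] list.
#' @return One of `"optimal"`, `"acceptable"`, `"critical"`, `"missing"`.
#' @export
classify_breath <- function(vt_ml = NA, pmax_cmh2o = NA, etco2_mmhg = NA,
                            spo2_pct = NA, fio2 = NA, pbw_kg,
                            boundaries = zone_boundaries()) {
  b <- data.frame(subject_id = "s", t_s = 0, vt_ml = vt_ml,
                  pmax_cmh2o = pmax_cmh2o, etco2_mmhg = etco2_mmhg,
                  spo2_pct = spo2_pct, spo2_qi_pct = NA_real_, fio2 = fio2,
                  rr_bpm = NA_real_, peep_cmh2o = NA_real_)
  classify_breaths(b, pbw_kg, boundaries)$zone
}

#' Flag hypoxemic breaths under the SpO2 quality gate
#'
#' A breath counts as hypoxemic when SpO2 is below 85 % and the SpO2
#' quality index exceeds 50 %. Breaths failing the quality gate (quality
#' index at or below 50 %, or missing) or without an SpO2 reading are
#' `NA` and excluded from the hypoxemia denominator.
#'
#' @param breaths breath data.frame with columns `spo2_pct` and
#'   `spo2_qi_pct`.
#' @return Logical vector, `NA` where the gate fails.
#' @export
flag_hypoxemia <- function(breaths) {
  gate <- !is.na(breaths$spo2_qi_pct) & breaths$spo2_qi_pct > 50 &
    !is.na(breaths$spo2_pct)
  ifelse(gate, breaths$spo2_pct < 85, NA)
}
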