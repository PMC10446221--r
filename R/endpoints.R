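.zones3 <- c("optimal", "acceptable", "critical")

#' Per-subject zone proportions by breath count
#'
#' Proportion of breaths in each zone: number of breaths in the zone
#' divided by the total number of classified breaths. Missing-zone
#' breaths are excluded from the denominator by default and reported
#' separately, so the three proportions sum to 1.
#'
#' @param zones character vector of per-breath zones
#'   (`optimal`/`acceptable`/`critical`/`missing`).
#' @param include_missing if `TRUE`, missing-zone breaths stay in the
#'   denominator (the three proportions then sum to less than 1).
#' @return List: `p_breaths` (named numeric over the three zones, `NA`
#'   when no breath is classified), `n_total`, `n_classified`,
#'   `n_missing`.
#' @export
zone_proportions <- function(zones, include_missing = FALSE) {
  n_total <- length(zones)
  n_missing <- sum(zones == "missing")
  n_classified <- n_total - n_missing
  counts <- vapply(.zones3, function(z) sum(zones == z), integer(1))
  denom <- if (include_missing) n_total else n_classified
  p <- if (denom > 0) counts / denom else
    stats::setNames(rep(NA_real_, 3), .zones3)
  list(p_breaths = p, n_total = n_total, n_classified = n_classified,
       n_missing = n_missing)
}

#' Per-subject zone proportions by time
#'
#' Each breath is weighted by its duration, taken as the time to the
#' next breath; the final breath is weighted by 60/RR seconds (fallback:
#' the median of the subject's observed inter-breath intervals, then a
#' 4 s nominal breath). The denominator is the total weighted duration
#' of breaths with a non-missing zone.
#'
#' @param zones per-breath zone vector.
#' @param t_s breath timestamps, seconds, strictly increasing.
#' @param rr_bpm per-breath respiratory rate (used for the final
#'   breath's weight); may be `NA`.
#' @return List `p_time` (named numeric over the three zones) and
#'   `total_s` (weighted duration of classified breaths).
#' @export
time_proportions <- function(zones, t_s, rr_bpm = NULL) {
  n <- length(zones)
  stopifnot(length(t_s) == n)
  if (n == 0) {
    return(list(p_time = stats::setNames(rep(NA_real_, 3), .zones3),
                total_s = 0))
  }
  d <- diff(t_s)
  if (any(d <= 0)) stop("timestamps must be strictly increasing", call. = FALSE)
  last_rr <- if (!is.null(rr_bpm)) rr_bpm[n] else NA_real_
  last_w <- if (!is.na(last_rr) && last_rr > 0) 60 / last_rr
            else if (length(d)) stats::median(d)
            else 4
  w <- c(d, last_w)
  keep <- zones != "missing"
  denom <- sum(w[keep])
  p <- if (denom > 0) {
    vapply(.zones3, function(z) sum(w[keep & zones == z]) / denom, numeric(1))
  } else stats::setNames(rep(NA_real_, 3), .zones3)
  list(p_time = p, total_s = denom)
}

#' Hypoxemia incidence from gated per-breath flags
#'
#' @param flags logical vector from [flag_hypoxemia()]; `NA` entries
#'   failed the quality gate and are excluded from the denominator.
#' @return List `n_hypoxemic`, `n_qi_valid`, `proportion` (`NA` when no
#'   breath passes the gate). Pass the concatenated flags of several
#'   subjects for a pooled arm-level incidence.
#' @export
hypoxemia_incidence <- function(flags) {
  n_valid <- sum(!is.na(flags))
  n_hyp <- sum(flags, na.rm = TRUE)
  list(n_hypoxemic = n_hyp, n_qi_valid = n_valid,
       proportion = if (n_valid > 0) n_hyp / n_valid else NA_real_)
}

#' Duration endpoints for one or more subjects
#'
#' Total duration of postoperative ventilation (start of ICU ventilation
#' to extubation) and duration of weaning (cessation of sedatives to
#' extubation), in hours.
#'
#' @param subjects subject data.frame with `extubation_s` and
#'   `sedation_stop_s` (seconds since ventilation start).
#' @return data.frame `subject_id`, `vent_duration_h`,
#'   `weaning_duration_h` (`NA` where the inputs are missing).
#' @export
durations <- function(subjects) {
  wean <- (subjects$extubation_s - subjects$sedation_stop_s) / 3600
  if (any(!is.na(wean) & wean < 0)) {
    stop("negative weaning duration (extubation before sedation stop)",
         call. = FALSE)
  }
  data.frame(subject_id = subjects$subject_id,
             vent_duration_h = subjects$extubation_s / 3600,
             weaning_duration_h = wean,
             stringsAsFactors = FALSE)
}

#' Five-minute binned means of ventilation parameters
#'
#' Summarises each parameter as its arithmetic mean within half-open
#' 5-minute bins `[start, start + 5)` until extubation or the analysis
#' horizon. Minute ventilation is derived as VT x RR / 1000 L/min where
#' both are present. Empty bins are absent from the output.
#'
#' @param breaths windowed, classified breaths of one subject (must
#'   contain `vt_per_pbw`; see [classify_breaths()]), or raw breaths
#'   plus `pbw_kg`.
#' @param pbw_kg predicted body weight, used only if `vt_per_pbw` is
#'   absent.
#' @param bin_min bin width in minutes (default 5).
#' @return Long-format data.frame `subject_id`, `bin_start_min`,
#'   `parameter`, `mean`.
#' @export
bin_parameters <- function(breaths, pbw_kg = NULL, bin_min = 5) {
  b <- breaths
  if (is.null(b$vt_per_pbw)) {
    stopifnot(!is.null(pbw_kg))
    pbw <- if (!is.null(names(pbw_kg))) unname(pbw_kg[b$subject_id])
           else rep_len(pbw_kg, nrow(b))
    b$vt_per_pbw <- b$vt_ml / pbw
  }
  b$minute_vent_l <- b$vt_ml * b$rr_bpm / 1000
  pars <- c("vt_per_pbw", "rr_bpm", "etco2_mmhg", "spo2_pct", "fio2",
            "pmax_cmh2o", "peep_cmh2o", "minute_vent_l")
  bin <- floor(b$t_s / (60 * bin_min)) * bin_min
  out <- list()
  for (p in pars) {
    keep <- !is.na(b[[p]])
    if (!any(keep)) next
    agg <- stats::aggregate(b[[p]][keep],
                            by = list(subject_id = b$subject_id[keep],
                                      bin_start_min = bin[keep]),
                            FUN = mean)
    out[[p]] <- data.frame(subject_id = agg$subject_id,
                           bin_start_min = agg$bin_start_min,
                           parameter = p, mean = agg$x,
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  if (is.null(res)) {
    return(data.frame(subject_id = character(0), bin_start_min = numeric(0),
                      parameter = character(0), mean = numeric(0)))
  }
  res <- res[order(res$subject_id, res$bin_start_min, res$parameter), ]
  rownames(res) <- NULL
  res
}

#' Build per-subject endpoint summaries
#'
#' Windows, classifies and aggregates each subject's breath stream into
#' the endpoint vector used by the arm-level analysis.
#'
#' @param breaths breath table (all subjects).
#' @param subjects subject table (the analysis population).
#' @param window an [analysis_window()].
#' @param boundaries a [zone_boundaries()] list.
#' @param include_missing passed to [zone_proportions()].
#' @return data.frame with one row per subject: arm, zone proportions by
#'   breaths (`p_breaths_*`) and by time (`p_time_*`), breath counts,
#'   hypoxemia counts and proportion, and duration endpoints.
#' @export
subject_summaries <- function(breaths, subjects,
                              window = analysis_window(),
                              boundaries = zone_boundaries(),
                              include_missing = FALSE) {
  dur <- durations(subjects)
  rows <- lapply(seq_len(nrow(subjects)), function(i) {
    s <- subjects[i, ]
    b <- breaths[breaths$subject_id == s$subject_id, , drop = FALSE]
    b <- window_breaths(b, s, window)
    cl <- classify_breaths(b, s$pbw_kg, boundaries)
    zp <- zone_proportions(cl$zone, include_missing)
    tp <- if (nrow(cl)) time_proportions(cl$zone, cl$t_s, cl$rr_bpm)
          else list(p_time = stats::setNames(rep(NA_real_, 3), .zones3))
    hy <- hypoxemia_incidence(cl$hypoxemic)
    data.frame(subject_id = s$subject_id, arm = s$received_arm,
               p_breaths_optimal = zp$p_breaths[["optimal"]],
               p_breaths_acceptable = zp$p_breaths[["acceptable"]],
               p_breaths_critical = zp$p_breaths[["critical"]],
               p_time_optimal = tp$p_time[["optimal"]],
               p_time_acceptable = tp$p_time[["acceptable"]],
               p_time_critical = tp$p_time[["critical"]],
               n_breaths_total = zp$n_total,
               n_breaths_classified = zp$n_classified,
               n_breaths_missing_zone = zp$n_missing,
               n_hypoxemic = hy$n_hypoxemic,
               n_qi_valid = hy$n_qi_valid,
               p_hypoxemia = hy$proportion,
               vent_duration_h = dur$vent_duration_h[i],
               weaning_duration_h = dur$weaning_duration_h[i],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
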