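#' Plausibility bounds for breath-level measurements
#'
#' Values outside these bounds are physically implausible for adult
#' postoperative ventilation and are treated as missing on import.
#'
#' @return Named list of `c(lower, upper)` bounds per column:
#'   `vt_ml` 0--3000 mL, `pmax_cmh2o` 0--80 cm H2O, `etco2_mmhg`
#'   0--150 mmHg, `spo2_pct` 0--100, `spo2_qi_pct` 0--100, `fio2`
#'   0.21--1.0, `rr_bpm` 0--80 breaths/min, `peep_cmh2o` 0--50 cm H2O.
#' @export
plausibility_bounds <- function() {
  list(
    vt_ml       = c(0, 3000),
    pmax_cmh2o  = c(0, 80),
    etco2_mmhg  = c(0, 150),
    spo2_pct    = c(0, 100),
    spo2_qi_pct = c(0, 100),
    fio2        = c(0.21, 1.0),
    rr_bpm      = c(0, 80),
    peep_cmh2o  = c(0, 50)
  )
}

#' I/O configuration for delimited breath and subject tables
#'
#' @param columns named character vector mapping canonical column names
#'   (names) to the column headers present in the file (values). Defaults
#'   to the identity mapping for the canonical schema.
#' @param missing character vector of markers interpreted as missing
#'   (default the empty string and `"NA"`).
#' @param decimal decimal separator (default `"."`).
#' @param bounds plausibility bounds, as from [plausibility_bounds()].
#' @return A list of class `"vz_io_config"`.
#' @seealso [read_io_config()] to load the same settings from YAML.
#' @export
io_config <- function(columns = NULL,
                      missing = c("", "NA"),
                      decimal = ".",
                      bounds = plausibility_bounds()) {
  canonical <- c("subject_id", "t_s", "vt_ml", "pmax_cmh2o", "etco2_mmhg",
                 "spo2_pct", "spo2_qi_pct", "fio2", "rr_bpm", "peep_cmh2o")
  map <- stats::setNames(canonical, canonical)
  if (!is.null(columns)) {
    stopifnot(!is.null(names(columns)))
    map[names(columns)] <- unlist(columns)
  }
  structure(list(columns = map, missing = missing, decimal = decimal,
                 bounds = bounds),
            class = "vz_io_config")
}

#' Read an I/O configuration from a YAML file
#'
#' The YAML file may contain any of the keys `columns` (a mapping from
#' canonical to file column names), `missing`, `decimal` and `bounds`.
#'
#' @param path path to a YAML file.
#' @return A `"vz_io_config"` list, see [io_config()].
#' @export
read_io_config <- function(path) {
  y <- yaml::read_yaml(path)
  bounds <- plausibility_bounds()
  if (!is.null(y$bounds)) {
    for (nm in names(y$bounds)) bounds[[nm]] <- as.numeric(y$bounds[[nm]])
  }
  io_config(columns = y$columns,
            missing = if (is.null(y$missing)) c("", "NA") else as.character(y$missing),
            decimal = if (is.null(y$decimal)) "." else y$decimal,
            bounds  = bounds)
}

#' Read breath-by-breath ventilator records
#'
#' Reads a delimited text file with one row per breath, validates it
#' against the plausibility bounds, nulls out-of-bounds values (counting
#' them), and returns records sorted by subject and time.
#'
#' @param path path to a delimited text file.
#' @param config an [io_config()]; controls column mapping, missing-value
#'   markers, decimal separator and plausibility bounds.
#' @return A data.frame with canonical columns `subject_id`, `t_s`,
#'   `vt_ml`, `pmax_cmh2o`, `etco2_mmhg`, `spo2_pct`, `spo2_qi_pct`,
#'   `fio2`, `rr_bpm`, `peep_cmh2o`, sorted by `(subject_id, t_s)`, with
#'   attribute `n_nulled` giving the per-column count of
#'   plausibility-violating values replaced by `NA`.
#' @details Mandatory columns are `subject_id` and `t_s`; a missing
#'   mandatory column is a schema error naming the column. Duplicate
#'   `(subject_id, t_s)` rows and negative times are rejected.
#' @export
read_breaths <- function(path, config = io_config()) {
  stopifnot(file.exists(path))
  raw <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                         na.strings = config$missing, dec = config$decimal,
                         colClasses = "character")
  map <- config$columns
  mandatory <- c("subject_id", "t_s")
  for (m in mandatory) {
    if (!map[[m]] %in% names(raw)) {
      stop("schema error: mandatory column '", map[[m]], "' (", m,
           ") not found in ", path, call. = FALSE)
    }
  }
  out <- data.frame(subject_id = as.character(raw[[map[["subject_id"]]]]),
                    stringsAsFactors = FALSE)
  num_cols <- setdiff(names(map), "subject_id")
  for (nm in num_cols) {
    col <- map[[nm]]
    if (col %in% names(raw)) {
      v <- raw[[col]]
      v[v %in% config$missing] <- NA
      suppressWarnings(x <- as.numeric(v))
      bad <- which(!is.na(v) & is.na(x))
      if (length(bad)) {
        stop("unparseable value '", v[bad[1]], "' in column '", col,
             "' at data row ", bad[1], call. = FALSE)
      }
      out[[nm]] <- x
    } else {
      out[[nm]] <- rep(NA_real_, nrow(out))
    }
  }
  if (anyNA(out$t_s)) stop("missing breath timestamps in ", path, call. = FALSE)
  if (any(out$t_s < 0)) stop("negative breath timestamps in ", path, call. = FALSE)

  n_nulled <- integer(0)
  for (nm in names(config$bounds)) {
    b <- config$bounds[[nm]]
    viol <- !is.na(out[[nm]]) & (out[[nm]] < b[1] | out[[nm]] > b[2])
    if (any(viol)) {
      out[[nm]][viol] <- NA_real_
      warning(sum(viol), " value(s) in '", nm,
              "' outside plausibility bounds set to NA", call. = FALSE)
    }
    n_nulled[nm] <- sum(viol)
  }
  if (anyDuplicated(out[c("subject_id", "t_s")])) {
    stop("duplicate (subject_id, t_s) rows in ", path, call. = FALSE)
  }
  out <- out[order(out$subject_id, out$t_s), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_nulled") <- n_nulled
  out
}

#' Write breath records to CSV in the canonical schema
#'
#' @param breaths data.frame as returned by [read_breaths()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_breaths <- function(breaths, path) {
  utils::write.csv(breaths, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read the subject-level table
#'
#' @param path path to a CSV with columns `subject_id`, `arm`
#'   (`sidestream`/`mainstream`), `height_cm`, `sex` (`male`/`female`),
#'   `pbw_kg`, `sedation_stop_s`, `extubation_s`, `reintubated_48h`,
#'   `pneumonia`, `pneumothorax`, `atelectasis`, `icu_los_d`,
#'   `hosp_los_d`, `died_day30` and optionally `received_arm` (defaults
#'   to `arm`; a mismatch marks a crossover).
#' @param config an [io_config()] (missing markers and decimal only).
#' @return A validated data.frame; `pbw_kg` is derived with
#'   [predicted_body_weight()] where absent but height and sex are given.
#' @export
read_subjects <- function(path, config = io_config()) {
  stopifnot(file.exists(path))
  s <- utils::read.csv(path, stringsAsFactors = FALSE,
                       na.strings = config$missing, dec = config$decimal)
  if (!"subject_id" %in% names(s)) {
    stop("schema error: mandatory column 'subject_id' not found", call. = FALSE)
  }
  if (!"arm" %in% names(s)) {
    stop("schema error: mandatory column 'arm' not found", call. = FALSE)
  }
  s$subject_id <- as.character(s$subject_id)
  bad_arm <- !s$arm %in% c("sidestream", "mainstream")
  if (any(bad_arm)) {
    stop("arm must be 'sidestream' or 'mainstream'; offending subject: ",
         s$subject_id[which(bad_arm)[1]], call. = FALSE)
  }
  if (!"received_arm" %in% names(s)) s$received_arm <- s$arm
  s$received_arm[is.na(s$received_arm)] <- s$arm[is.na(s$received_arm)]
  if (!"pbw_kg" %in% names(s)) s$pbw_kg <- NA_real_
  need <- is.na(s$pbw_kg)
  if (any(need)) {
    if (!all(c("height_cm", "sex") %in% names(s))) {
      stop("pbw_kg missing and no height_cm/sex columns to derive it",
           call. = FALSE)
    }
    s$pbw_kg[need] <- predicted_body_weight(s$height_cm[need], s$sex[need])
  }
  if (any(!is.na(s$pbw_kg) & s$pbw_kg <= 0)) {
    stop("pbw_kg must be positive", call. = FALSE)
  }
  both <- !is.na(s$extubation_s) & !is.na(s$sedation_stop_s)
  if (any(both & s$extubation_s < s$sedation_stop_s)) {
    stop("extubation_s earlier than sedation_stop_s for subject ",
         s$subject_id[which(both & s$extubation_s < s$sedation_stop_s)[1]],
         call. = FALSE)
  }
  s
}

#' Write the subject table to CSV
#'
#' @param subjects subject data.frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_subjects <- function(subjects, path) {
  utils::write.csv(subjects, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Predicted body weight (ARDSnet formula)
#'
#' Sex-specific linear formula used to normalise tidal volume to mL/kg
#' PBW: males 50 + 0.91 (height - 152.4), females 45.5 + 0.91
#' (height - 152.4), floored at 20 kg.
#'
#' @param height_cm body height in cm (> 0); vectorised.
#' @param sex `"male"` or `"female"`; vectorised, recycled against height.
#' @return Predicted body weight in kg.
#' @examples
#' predicted_body_weight(175, "male")    # 70.57
#' predicted_body_weight(152.4, "female") # 45.5
#' @export
predicted_body_weight <- function(height_cm, sex) {
  n <- max(length(height_cm), length(sex))
  height_cm <- rep_len(height_cm, n)
  sex <- rep_len(sex, n)
  if (any(!is.na(height_cm) & height_cm <= 0)) {
    stop("height_cm must be positive", call. = FALSE)
  }
  ok <- sex %in% c("male", "female")
  if (any(!ok & !(is.na(sex) & is.na(height_cm)))) {
    stop("unknown sex '", sex[which(!ok)[1]],
         "': provide pbw_kg explicitly", call. = FALSE)
  }
  base <- ifelse(sex == "male", 50, 45.5)
  pmax(base + 0.91 * (height_cm - 152.4), 20)
}

#' Analysis window for the quality-of-breathing endpoints
#'
#' @param horizon_s analysis horizon in seconds since start of
#'   postoperative ventilation (default 10800 s = 3 h).
#' @param min_duration_s minimum ventilation duration for per-protocol
#'   eligibility (default 5400 s = 90 min).
#' @return List of class `"vz_window"`.
#' @export
analysis_window <- function(horizon_s = 10800, min_duration_s = 5400) {
  stopifnot(min_duration_s > 0, min_duration_s <= horizon_s)
  structure(list(horizon_s = horizon_s, min_duration_s = min_duration_s),
            class = "vz_window")
}

#' Restrict one subject's breaths to the analysis window
#'
#' Keeps breaths recorded before extubation or before the horizon,
#' whichever comes first.
#'
#' @param breaths breath data.frame (one subject).
#' @param subject one row of the subject table (list or 1-row
#'   data.frame); only `extubation_s` is used, `NA` means not extubated
#'   within the recording.
#' @param window an [analysis_window()].
#' @return The breaths with `t_s < min(horizon, extubation)`, order
#'   preserved. May be empty.
#' @export
window_breaths <- function(breaths, subject, window = analysis_window()) {
  cut <- window$horizon_s
  ext <- subject$extubation_s
  if (length(ext) && !is.na(ext)) cut <- min(cut, ext)
  breaths[breaths$t_s < cut, , drop = FALSE]
}

#' Partition subjects into analysis populations
#'
#' Applies the trial's eligibility rules: the intention-to-treat (ITT)
#' set contains every randomized subject with recorded breaths, analysed
#' by the capnography sensor actually received; the per-protocol (PP)
#' set additionally excludes subjects ventilated for less than the
#' minimum duration (drop-outs) and subjects ventilated with the sensor
#' they were not assigned to (crossovers).
#'
#' @param subjects subject table, see [read_subjects()].
#' @param breaths breath table covering (at least) those subjects.
#' @param window an [analysis_window()]; `min_duration_s` defines
#'   drop-outs. Ventilation duration is `extubation_s`, or the last
#'   recorded breath time when extubation is missing. Duration exactly
#'   equal to the minimum is eligible.
#' @return List with elements `itt` and `pp` (subject data.frames) and
#'   `excluded` (data.frame `subject_id`, `population`, `reason`).
#' @export
eligibility_filter <- function(subjects, breaths, window = analysis_window()) {
  orphan <- setdiff(unique(breaths$subject_id), subjects$subject_id)
  if (length(orphan)) {
    stop("breath records without a subject record: ",
         paste(orphan, collapse = ", "), call. = FALSE)
  }
  last_t <- tapply(breaths$t_s, breaths$subject_id, max)
  dur <- subjects$extubation_s
  no_breaths <- !subjects$subject_id %in% names(last_t)
  fallback <- is.na(dur) & !no_breaths
  dur[fallback] <- last_t[subjects$subject_id[fallback]]

  excluded <- data.frame(subject_id = character(0), population = character(0),
                         reason = character(0), stringsAsFactors = FALSE)
  add_excl <- function(ids, population, reason) {
    if (!length(ids)) return()
    excluded <<- rbind(excluded, data.frame(subject_id = ids,
                                            population = population,
                                            reason = reason,
                                            stringsAsFactors = FALSE))
  }
  add_excl(subjects$subject_id[no_breaths], "itt", "no-breaths")
  itt <- subjects[!no_breaths, , drop = FALSE]

  dur_itt <- dur[!no_breaths]
  dropout <- !is.na(dur_itt) & dur_itt < window$min_duration_s
  crossover <- itt$received_arm != itt$arm
  add_excl(itt$subject_id[dropout], "pp", "min-duration")
  add_excl(itt$subject_id[crossover & !dropout], "pp", "crossover")
  pp <- itt[!dropout & !crossover, , drop = FALSE]
  rownames(itt) <- rownames(pp) <- NULL
  list(itt = itt, pp = pp, excluded = excluded)
}
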