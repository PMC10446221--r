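#' Run the full quality-of-breathing analysis pipeline
#'
#' Reads the breath and subject tables, applies the eligibility rules,
#' classifies every breath, builds per-subject endpoint summaries and
#' the arm-level comparisons, and (optionally) writes
#' `subject_summary.csv`, `binned.csv`, `analysis.json` and `report.md`
#' plus a config snapshot to an output directory.
#'
#' The endpoint set mirrors the trial's analysis: ratio-of-means
#' non-inferiority for the proportion of breaths in the optimal zone
#' (primary), two-sided mean ratios for the acceptable/critical
#' proportions and the hypoxemia proportion, mean differences for the
#' time-in-zone proportions and durations, and an odds ratio for
#' reintubation.
#'
#' @param breaths breath data.frame or path to a breaths CSV.
#' @param subjects subject data.frame or path to a subjects CSV.
#' @param window an [analysis_window()].
#' @param population `"itt"` or `"pp"`.
#' @param config an [ni_config()] for the primary analysis.
#' @param boundaries a [zone_boundaries()] list.
#' @param io an [io_config()] used when paths are given.
#' @param out_dir optional output directory (created if needed).
#' @return List: `summaries` (per-subject endpoint data.frame),
#'   `comparisons` (named list of [arm_comparison()]), `binned` (5-min
#'   binned parameter means), `population`, `eligibility`, `counts`.
#' @export
run_pipeline <- function(breaths, subjects, window = analysis_window(),
                         population = c("itt", "pp"),
                         config = ni_config(),
                         boundaries = zone_boundaries(),
                         io = io_config(), out_dir = NULL) {
  population <- match.arg(population)
  if (is.character(breaths)) breaths <- read_breaths(breaths, io)
  if (is.character(subjects)) subjects <- read_subjects(subjects, io)
  if (nrow(breaths) == 0) {
    stop("pipeline stage 'read': no breath records", call. = FALSE)
  }
  elig <- eligibility_filter(subjects, breaths, window)
  pop <- elig[[population]]
  if (nrow(pop) == 0) {
    stop("pipeline stage 'eligibility': empty ", population, " population",
         call. = FALSE)
  }
  message(nrow(breaths), " breaths read; ", nrow(subjects),
          " subjects; ", nrow(pop), " in ", toupper(population),
          " population")

  ss <- subject_summaries(breaths, pop, window, boundaries)
  message(sum(ss$n_breaths_total), " breaths windowed, ",
          sum(ss$n_breaths_classified), " classified, ",
          sum(ss$n_breaths_missing_zone), " missing-zone")

  pbw <- stats::setNames(pop$pbw_kg, pop$subject_id)
  win_list <- lapply(seq_len(nrow(pop)), function(i) {
    window_breaths(breaths[breaths$subject_id == pop$subject_id[i], ,
                           drop = FALSE], pop[i, ], window)
  })
  binned <- bin_parameters(do.call(rbind, win_list), pbw)

  sx <- ss[ss$arm == "sidestream", ]
  mx <- ss[ss$arm == "mainstream", ]
  # endpoints with no usable data (all-NA columns) are dropped, not fatal
  safe <- function(expr) tryCatch(suppressMessages(expr),
                                  error = function(e) NULL)
  two <- function(x, y, ep) safe(mean_ratio_ni(x, y, config, "two", ep))
  mdiff <- function(x, y, ep) safe(mean_difference(x, y, config$alpha, ep))
  cmp <- list(
    p_breaths_optimal = safe(mean_ratio_ni(
      sx$p_breaths_optimal, mx$p_breaths_optimal, config, "one",
      "Proportion of breaths in optimal zone")),
    p_breaths_acceptable = two(sx$p_breaths_acceptable,
                               mx$p_breaths_acceptable,
                               "Proportion of breaths in acceptable zone"),
    p_breaths_critical = two(sx$p_breaths_critical, mx$p_breaths_critical,
                             "Proportion of breaths in critical zone"),
    p_time_optimal = mdiff(sx$p_time_optimal, mx$p_time_optimal,
                           "Proportion of time in optimal zone"),
    p_time_acceptable = mdiff(sx$p_time_acceptable, mx$p_time_acceptable,
                              "Proportion of time in acceptable zone"),
    p_time_critical = mdiff(sx$p_time_critical, mx$p_time_critical,
                            "Proportion of time in critical zone"),
    p_hypoxemia = two(sx$p_hypoxemia, mx$p_hypoxemia,
                      "Proportion of breaths with SpO2 < 85%"),
    vent_duration = mdiff(sx$vent_duration_h, mx$vent_duration_h,
                          "Duration of postoperative ventilation, hours"),
    weaning_duration = mdiff(sx$weaning_duration_h, mx$weaning_duration_h,
                             "Duration of weaning, hours"),
    reintubation = safe({
      a <- sum(pop$reintubated_48h[pop$arm == "sidestream"], na.rm = TRUE)
      c <- sum(pop$reintubated_48h[pop$arm == "mainstream"], na.rm = TRUE)
      odds_ratio_2x2(a, sum(pop$arm == "sidestream") - a,
                     c, sum(pop$arm == "mainstream") - c,
                     endpoint = "Reintubations")
    }))
  cmp <- Filter(Negate(is.null), cmp)

  res <- list(summaries = ss, comparisons = cmp, binned = binned,
              population = population, eligibility = elig,
              counts = list(n_breaths_read = nrow(breaths),
                            n_subjects = nrow(subjects),
                            n_population = nrow(pop),
                            n_windowed = sum(ss$n_breaths_total),
                            n_classified = sum(ss$n_breaths_classified),
                            n_missing_zone = sum(ss$n_breaths_missing_zone)))

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(ss, file.path(out_dir, "subject_summary.csv"),
                     row.names = FALSE, na = "")
    utils::write.csv(binned, file.path(out_dir, "binned.csv"),
                     row.names = FALSE, na = "")
    strip <- lapply(cmp, function(x) {
      x$extra <- x$extra[setdiff(names(x$extra), "fit")]
      unclass(x)
    })
    jsonlite::write_json(list(population = population, counts = res$counts,
                              comparisons = strip),
                         file.path(out_dir, "analysis.json"),
                         auto_unbox = TRUE, digits = NA, na = "null")
    writeLines(render_table3(res), file.path(out_dir, "report.md"))
    snapshot <- list(window = unclass(window), population = population,
                     ni = unclass(config), boundaries = unclass(boundaries))
    yaml::write_yaml(snapshot, file.path(out_dir, "config_snapshot.yaml"))
  }
  res
}

.fmt_med_iqr <- function(x) {
  x <- x[!is.na(x)]
  if (!length(x)) return("-")
  q <- stats::quantile(x, c(0.5, 0.25, 0.75), names = FALSE)
  sprintf("%.2f [%.2f-%.2f]", q[1], q[2], q[3])
}

.fmt_mean_sd <- function(x) {
  x <- x[!is.na(x)]
  if (!length(x)) return("-")
  sprintf("%.2f +/- %.2f", mean(x), stats::sd(x))
}

.fmt_ci <- function(cmp) {
  if (is.null(cmp) || is.na(cmp$estimate)) return("-")
  hi <- if (is.infinite(cmp$ci_high)) "Inf" else sprintf("%.2f", cmp$ci_high)
  sprintf("%.2f (%.2f to %s)", cmp$estimate, cmp$ci_low, hi)
}

#' Render the arm-level analysis as a trial-style report table
#'
#' Formats the pipeline output as a markdown table with one row block
#' per endpoint: median [IQR] and mean +/- SD per arm, the effect
#' estimate with its confidence interval, and the P value; the primary
#' non-inferiority row carries its one-sided P and decision.
#'
#' @param results the list returned by [run_pipeline()].
#' @return Character vector of markdown lines.
#' @export
render_table3 <- function(results) {
  ss <- results$summaries
  sx <- ss[ss$arm == "sidestream", ]
  mx <- ss[ss$arm == "mainstream", ]
  rows <- c(
    sprintf("# Endpoint report (%s population)", toupper(results$population)),
    "",
    sprintf("| Endpoint | Sidestream (N = %d) | Mainstream (N = %d) | Effect (95%% CI) | P |",
            nrow(sx), nrow(mx)),
    "|---|---|---|---|---|")
  vars <- list(
    p_breaths_optimal = "p_breaths_optimal",
    p_breaths_acceptable = "p_breaths_acceptable",
    p_breaths_critical = "p_breaths_critical",
    p_time_optimal = "p_time_optimal",
    p_time_acceptable = "p_time_acceptable",
    p_time_critical = "p_time_critical",
    p_hypoxemia = "p_hypoxemia",
    vent_duration = "vent_duration_h",
    weaning_duration = "weaning_duration_h")
  for (key in names(vars)) {
    cmp <- results$comparisons[[key]]
    if (is.null(cmp)) next
    v <- vars[[key]]
    pstr <- if (is.na(cmp$p_value)) "-" else sprintf("%.3f", cmp$p_value)
    if (identical(cmp$sidedness, "one")) {
      pstr <- paste0(pstr, "*")
    }
    rows <- c(rows, sprintf(
      "| %s | %s; %s | %s; %s | %s | %s |",
      cmp$endpoint,
      .fmt_med_iqr(sx[[v]]), .fmt_mean_sd(sx[[v]]),
      .fmt_med_iqr(mx[[v]]), .fmt_mean_sd(mx[[v]]),
      .fmt_ci(cmp), pstr))
  }
  ri <- results$comparisons$reintubation
  if (!is.null(ri)) {
    rows <- c(rows, sprintf(
      "| %s | %d / %d | %d / %d | OR %s | %.3f |", ri$endpoint,
      ri$extra$a %||% sum(sx$arm == "sidestream"), ri$n_x,
      ri$extra$c %||% 0, ri$n_y, .fmt_ci(ri), ri$p_value))
  }
  prim <- results$comparisons$p_breaths_optimal
  if (!is.null(prim)) {
    rows <- c(rows, "",
              sprintf("*One-sided P for non-inferiority (margin %.2f); decision: %s.*",
                      prim$extra$margin, prim$decision))
  }
  rows
}

`%||%` <- function(a, b) if (is.null(a)) b else a
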