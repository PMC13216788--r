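#' Timing rule for a single radiology event
#'
#' A chest radiology procedure can only be relevant if performed strictly
#' more than `min_hours_after_admission` hours after admission — or at any
#' time during the stay for patients readmitted within the configured gap
#' (their pneumonia may have been incubating across stays).
#'
#' @param rad One radiology event (one-row tibble or named list with `ts`).
#' @param stay The stay the event belongs to (`admission_ts`,
#'   `discharge_ts`, `prior_stay_id`).
#' @param config An [algorithm_config()].
#' @return Logical flag.
#' @export
radiology_timing_ok <- function(rad, stay, config = algorithm_config()) {
  ts <- rad$ts[[1]]
  if (ts < stay$admission_ts[[1]] || ts > stay$discharge_ts[[1]]) {
    abort_validation("radiology event timestamped outside its stay")
  }
  linked <- !is.null(stay$prior_stay_id) && !is.na(stay$prior_stay_id[[1]])
  hours <- hours_between(ts, stay$admission_ts[[1]])
  isTRUE(hours > config$min_hours_after_admission) || linked
}

#' Leukocyte signal around a radiology timestamp
#'
#' TRUE if any leukocyte result within `lab_window_hours` (inclusive) of `t`
#' is below the leukopenia threshold or at/above the leukocytosis threshold.
#'
#' @param labs Lab tibble for the stay (`ts`, `leukocytes`).
#' @param t Radiology timestamp.
#' @param config An [algorithm_config()].
#' @return Logical flag; `FALSE` when no result falls in the window.
#' @export
leukocyte_signal <- function(labs, t, config = algorithm_config()) {
  if (is.null(labs) || nrow(labs) == 0) return(FALSE)
  in_win <- abs(hours_between(labs$ts, t)) <= config$lab_window_hours
  abnormal <- labs$leukocytes < config$leukopenia_threshold |
    labs$leukocytes >= config$leukocytosis_threshold
  any(in_win & abnormal)
}

#' Fever signal around a radiology timestamp
#'
#' TRUE if any body-temperature measurement within `temp_window_hours`
#' (inclusive) of `t` is strictly above the fever threshold.
#'
#' @param vitals Vital-sign tibble for the stay (`ts`, `temperature`).
#' @inheritParams leukocyte_signal
#' @return Logical flag.
#' @export
temperature_signal <- function(vitals, t, config = algorithm_config()) {
  if (is.null(vitals) || nrow(vitals) == 0) return(FALSE)
  in_win <- abs(hours_between(vitals$ts, t)) <= config$temp_window_hours
  any(in_win & vitals$temperature > config$fever_threshold)
}

# Merge abutting/overlapping episodes of one stay into maximal intubated
# intervals; missing extubation is carried to `stay_end` (or +Inf).
merge_episodes <- function(devices, stay_end = NULL) {
  if (is.null(devices) || nrow(devices) == 0) {
    return(tibble(start = numeric(0), end = numeric(0)))
  }
  start <- as.numeric(devices$intubation_ts)
  end <- as.numeric(devices$extubation_ts)
  end[is.na(end)] <- if (is.null(stay_end)) Inf else as.numeric(stay_end)
  o <- order(start)
  start <- start[o]; end <- end[o]
  run_end <- cummax(end)
  new_grp <- c(TRUE, start[-1] > run_end[-length(run_end)])
  grp <- cumsum(new_grp)
  tibble(
    start = tapply(start, grp, min)[],
    end = tapply(end, grp, max)[]
  )
}

#' Ventilator filter for a single radiology event
#'
#' FALSE (vetoing relevance) only when the patient was continuously
#' intubated throughout the full `[t - vap_exclusion_hours, t]` window —
#' such an event belongs to a VAP candidate and is outside nvHAP
#' surveillance. Partial intubation in the window keeps the event relevant,
#' so indeterminate HAP (iHAP) is not lost.
#'
#' @param devices Device-episode tibble for the stay (`intubation_ts`,
#'   `extubation_ts`, `NA` = ongoing).
#' @inheritParams leukocyte_signal
#' @return Logical flag.
#' @export
device_ok <- function(devices, t, config = algorithm_config()) {
  eps <- merge_episodes(devices)
  if (nrow(eps) == 0) return(TRUE)
  t <- as.numeric(t)
  w0 <- t - config$vap_exclusion_hours * 3600
  !any(eps$start <= w0 & eps$end >= t)
}

#' Evaluate one radiology event against the enabled indicators
#'
#' Relevance is the conjunction of all enabled indicator flags; disabled
#' indicators are `NA` and never veto — absence of data must not suppress
#' preselection. Events with modality `OTHER` are never relevant.
#'
#' @param rad One radiology event (with `ts`, `modality`, `report_text`).
#' @param stay The stay it belongs to.
#' @param dataset The [surveillance_dataset()] providing labs, vitals,
#'   devices for the stay.
#' @param config An [algorithm_config()].
#' @return One-row tibble: `radiology_timing_ok`, `report_not_excluding`,
#'   `leukocyte_signal`, `temperature_signal`, `device_ok` (logical; `NA`
#'   for disabled indicators) and `relevant`.
#' @export
evaluate_radiology_event <- function(rad, stay, dataset,
                                     config = algorithm_config()) {
  check_streams(dataset, config)
  en <- config$enabled_indicators
  sid <- stay$stay_id[[1]]
  t <- rad$ts[[1]]
  timing <- radiology_timing_ok(rad, stay, config)
  rep_flag <- if ("RADIOLOGY_REPORT" %in% en) {
    classify_report(rad$report_text[[1]], config$termset)$verdict !=
      "EXCLUDES_PNEUMONIA"
  } else NA
  leu_flag <- if ("LEUKOCYTES" %in% en) {
    leukocyte_signal(dataset$labs[dataset$labs$stay_id == sid, ], t, config)
  } else NA
  tmp_flag <- if ("TEMPERATURE" %in% en) {
    temperature_signal(dataset$vitals[dataset$vitals$stay_id == sid, ], t, config)
  } else NA
  dev_flag <- if ("DEVICE" %in% en) {
    device_ok(dataset$devices[dataset$devices$stay_id == sid, ], t, config)
  } else NA
  flags <- c(timing, rep_flag, leu_flag, tmp_flag, dev_flag)
  relevant <- rad$modality[[1]] != "OTHER" && all(flags[!is.na(flags)])
  tibble(
    radiology_timing_ok = timing,
    report_not_excluding = rep_flag,
    leukocyte_signal = leu_flag,
    temperature_signal = tmp_flag,
    device_ok = dev_flag,
    relevant = relevant
  )
}

check_streams <- function(dataset, config) {
  missing <- setdiff(config$enabled_indicators, dataset$available_streams)
  if (length(missing) > 0) {
    abort_validation(sprintf(
      "config enables stream(s) the dataset does not declare: %s",
      paste(missing, collapse = ", ")
    ))
  }
  invisible(TRUE)
}

#' Preselect stays for manual nvHAP review
#'
#' A stay is preselected if it has at least one relevant chest radiology
#' procedure under the enabled indicator subset. Because every indicator can
#' only veto, enabling more indicators always yields a subset of the stays
#' preselected with fewer indicators — the adaptability property: reduced
#' algorithms have equal or higher (never lower) sensitivity, at the price
#' of a longer review list.
#'
#' Readmission linkage is (re)computed here with the configured gap.
#'
#' @param dataset A [surveillance_dataset()].
#' @param config An [algorithm_config()].
#' @return Object of class `preselection`: list with `stays` (one row per
#'   stay: `stay_id`, `preselected`, `n_triggering_events`,
#'   `first_trigger_ts`) and `events` (per-radiology-event audit trail with
#'   the indicator flags).
#' @export
preselect <- function(dataset, config = algorithm_config()) {
  stopifnot(inherits(dataset, "surveillance_dataset"))
  check_streams(dataset, config)
  en <- config$enabled_indicators

  stays <- link_readmissions(dataset$stays, config$readmission_gap_days)
  rad <- dplyr::inner_join(
    dataset$radiology,
    dplyr::select(
      stays, stay_id, admission_ts, discharge_ts, prior_stay_id
    ),
    by = "stay_id"
  )
  if (nrow(rad) > 0 &&
      any(rad$ts < rad$admission_ts | rad$ts > rad$discharge_ts)) {
    abort_validation(
      "radiology event timestamped outside its stay; clean the extract first"
    )
  }

  n_ev <- nrow(rad)
  timing <- if (n_ev == 0) logical(0) else {
    hours_between(rad$ts, rad$admission_ts) > config$min_hours_after_admission |
      !is.na(rad$prior_stay_id)
  }

  rep_flag <- rep(NA, n_ev)
  if ("RADIOLOGY_REPORT" %in% en && n_ev > 0) {
    rep_flag <- !reports_exclude(rad$report_text, config$termset)
  }

  window_signal <- function(events, obs, window_hours, abnormal) {
    # events: tibble(row, stay_id, ts); returns logical per event row
    hit <- rep(FALSE, nrow(events))
    if (nrow(obs) == 0 || nrow(events) == 0) return(hit)
    obs <- obs[abnormal, c("stay_id", "ts")]
    if (nrow(obs) == 0) return(hit)
    j <- dplyr::inner_join(events, obs, by = "stay_id",
                           suffix = c("", ".obs"),
                           relationship = "many-to-many")
    if (nrow(j) == 0) return(hit)
    ok <- abs(hours_between(j$ts.obs, j$ts)) <= window_hours
    hit[unique(j$row[ok])] <- TRUE
    hit
  }
  ev_key <- tibble(row = seq_len(n_ev), stay_id = rad$stay_id, ts = rad$ts)

  leu_flag <- rep(NA, n_ev)
  if ("LEUKOCYTES" %in% en && n_ev > 0) {
    leu_flag <- window_signal(
      ev_key, dataset$labs, config$lab_window_hours,
      dataset$labs$leukocytes < config$leukopenia_threshold |
        dataset$labs$leukocytes >= config$leukocytosis_threshold
    )
  }
  tmp_flag <- rep(NA, n_ev)
  if ("TEMPERATURE" %in% en && n_ev > 0) {
    tmp_flag <- window_signal(
      ev_key, dataset$vitals, config$temp_window_hours,
      dataset$vitals$temperature > config$fever_threshold
    )
  }

  dev_flag <- rep(NA, n_ev)
  if ("DEVICE" %in% en && n_ev > 0) {
    dev_flag <- rep(TRUE, n_ev)
    if (nrow(dataset$devices) > 0) {
      eps <- dataset$devices |>
        dplyr::group_by(stay_id) |>
        dplyr::group_modify(~ merge_episodes(.x)) |>
        dplyr::ungroup()
      j <- dplyr::inner_join(ev_key, eps, by = "stay_id",
                             relationship = "many-to-many")
      if (nrow(j) > 0) {
        covered <- j$start <= as.numeric(j$ts) - config$vap_exclusion_hours * 3600 &
          j$end >= as.numeric(j$ts)
        dev_flag[unique(j$row[covered])] <- FALSE
      }
    }
  }

  conj <- function(flag, acc) acc & (is.na(flag) | flag)
  relevant <- rad$modality != "OTHER"
  relevant <- conj(timing, relevant)
  relevant <- conj(rep_flag, relevant)
  relevant <- conj(leu_flag, relevant)
  relevant <- conj(tmp_flag, relevant)
  relevant <- conj(dev_flag, relevant)
  # timing applies to every modality-eligible event regardless of NA rules
  relevant <- relevant & timing

  events <- tibble(
    stay_id = rad$stay_id,
    event_id = rad$event_id,
    ts = rad$ts,
    modality = rad$modality,
    radiology_timing_ok = timing,
    report_not_excluding = rep_flag,
    leukocyte_signal = leu_flag,
    temperature_signal = tmp_flag,
    device_ok = dev_flag,
    relevant = relevant
  )
  trig <- events[events$relevant, ]
  per_stay <- if (nrow(trig) == 0) {
    tibble(
      stay_id = character(), n_triggering_events = integer(),
      first_trigger_ts = parse_ts(character())
    )
  } else {
    trig |>
      dplyr::group_by(stay_id) |>
      dplyr::summarise(
        n_triggering_events = dplyr::n(),
        first_trigger_ts = min(ts),
        .groups = "drop"
      )
  }
  res <- dplyr::left_join(
    tibble(stay_id = stays$stay_id), per_stay, by = "stay_id"
  )
  res$n_triggering_events <- dplyr::coalesce(res$n_triggering_events, 0L)
  res$preselected <- res$n_triggering_events > 0
  res <- res[, c("stay_id", "preselected", "n_triggering_events", "first_trigger_ts")]

  structure(
    list(
      stays = res,
      events = events,
      config_fingerprint = config_fingerprint(config),
      enabled_indicators = en
    ),
    class = "preselection"
  )
}

#' @export
print.preselection <- function(x, ...) {
  cat("<preselection>\n")
  cat(sprintf(
    "  %d of %d stays preselected (%.1f%%) with indicators: %s\n",
    sum(x$stays$preselected), nrow(x$stays),
    100 * mean(x$stays$preselected),
    paste(x$enabled_indicators, collapse = ", ")
  ))
  invisible(x)
}

#' Write preselection results as CSV
#'
#' One row per stay with the verdict, trigger count, first trigger time and
#' a compact per-event indicator-flag audit string.
#'
#' @param result A [preselect()] result.
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_preselection <- function(result, path) {
  stopifnot(inherits(result, "preselection"))
  flag_chr <- function(x) ifelse(is.na(x), "-", ifelse(x, "1", "0"))
  ev <- result$events
  ev_str <- paste0(
    ev$event_id, ":",
    flag_chr(ev$radiology_timing_ok), flag_chr(ev$report_not_excluding),
    flag_chr(ev$leukocyte_signal), flag_chr(ev$temperature_signal),
    flag_chr(ev$device_ok)
  )
  audit <- tibble(stay_id = ev$stay_id, s = ev_str, relevant = ev$relevant) |>
    dplyr::filter(relevant) |>
    dplyr::group_by(stay_id) |>
    dplyr::summarise(indicator_flags = paste(s, collapse = ";"), .groups = "drop")
  out <- dplyr::left_join(result$stays, audit, by = "stay_id")
  out$indicator_flags <- dplyr::coalesce(out$indicator_flags, "")
  out$first_trigger_ts <- format_ts(out$first_trigger_ts)
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}
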