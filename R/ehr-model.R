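#' Construct a surveillance dataset from in-memory tables
#'
#' Bundles the five event streams the preselection algorithm can draw on.
#' All tables are tibbles; timestamps are `POSIXct` at minute resolution in
#' one implicit hospital timezone. `available_streams` is a declaration (set
#' by the caller or by [load_dataset()] from the files provided), never
#' inferred from table contents: an empty lab table with `LEUKOCYTES`
#' declared means "stream exists but no results", not "stream unavailable".
#'
#' @param stays Tibble: `stay_id`, `patient_id`, `admission_ts`,
#'   `discharge_ts`, `department`, `icd_codes` (list-column of ICD-10
#'   strings), optionally `prior_stay_id`.
#' @param radiology Tibble: `event_id`, `stay_id`, `ts`, `modality`
#'   (`CHEST_XRAY`, `CHEST_CT`, `OTHER`), `report_text`.
#' @param labs Tibble: `stay_id`, `ts`, `leukocytes` (x10^9/L; no unit
#'   auto-detection — silent unit guessing is a classic surveillance bug).
#' @param vitals Tibble: `stay_id`, `ts`, `temperature` (degrees Celsius).
#' @param devices Tibble: `stay_id`, `intubation_ts`, `extubation_ts`
#'   (`NA` = still intubated at discharge).
#' @param available_streams Subset of [INDICATOR_STREAMS].
#' @param load_log Tibble of row-level load issues (see [load_dataset()]).
#' @return Object of class `surveillance_dataset`.
#' @export
surveillance_dataset <- function(stays,
                                 radiology = NULL,
                                 labs = NULL,
                                 vitals = NULL,
                                 devices = NULL,
                                 available_streams = "RADIOLOGY_PROCEDURE",
                                 load_log = NULL) {
  stays <- as_tibble(stays)
  if (nrow(stays) == 0) {
    abort_validation("no population under surveillance: stays table is empty")
  }
  if (!"prior_stay_id" %in% names(stays)) {
    stays$prior_stay_id <- NA_character_
  }
  if (!is.list(stays$icd_codes)) {
    stays$icd_codes <- pipe_split(stays$icd_codes)
  }
  if (anyDuplicated(stays$stay_id)) {
    abort_validation("stay_id values must be unique within a dataset")
  }
  available_streams <- unique(as.character(available_streams))
  bad <- setdiff(available_streams, INDICATOR_STREAMS)
  if (length(bad) > 0) {
    abort_validation(sprintf(
      "unknown stream(s): %s", paste(bad, collapse = ", ")
    ))
  }
  available_streams <- union("RADIOLOGY_PROCEDURE", available_streams)

  empty <- list(
    radiology = tibble(
      event_id = character(), stay_id = character(),
      ts = parse_ts(character()), modality = character(),
      report_text = character()
    ),
    labs = tibble(
      stay_id = character(), ts = parse_ts(character()),
      leukocytes = numeric()
    ),
    vitals = tibble(
      stay_id = character(), ts = parse_ts(character()),
      temperature = numeric()
    ),
    devices = tibble(
      stay_id = character(), intubation_ts = parse_ts(character()),
      extubation_ts = parse_ts(character())
    )
  )
  radiology <- if (is.null(radiology)) empty$radiology else as_tibble(radiology)
  labs <- if (is.null(labs)) empty$labs else as_tibble(labs)
  vitals <- if (is.null(vitals)) empty$vitals else as_tibble(vitals)
  devices <- if (is.null(devices)) empty$devices else as_tibble(devices)

  if (nrow(radiology) > 0) {
    bad_mod <- setdiff(unique(radiology$modality), RADIOLOGY_MODALITIES)
    if (length(bad_mod) > 0) {
      abort_validation(sprintf(
        "unknown radiology modality: %s", paste(bad_mod, collapse = ", ")
      ))
    }
  }
  if (nrow(devices) > 0) {
    both <- !is.na(devices$extubation_ts)
    if (any(devices$intubation_ts[both] >= devices$extubation_ts[both])) {
      abort_validation("device episode with extubation not after intubation")
    }
  }

  structure(
    list(
      stays = stays, radiology = radiology, labs = labs,
      vitals = vitals, devices = devices,
      available_streams = available_streams,
      load_log = load_log %||% tibble(
        table = character(), issue = character(), n = integer()
      )
    ),
    class = "surveillance_dataset"
  )
}

#' @export
print.surveillance_dataset <- function(x, ...) {
  cat("<surveillance_dataset>\n")
  cat(sprintf(
    "  %d stays, %d radiology events, %d labs, %d vitals, %d device episodes\n",
    nrow(x$stays), nrow(x$radiology), nrow(x$labs), nrow(x$vitals),
    nrow(x$devices)
  ))
  cat("  declared streams:", paste(x$available_streams, collapse = ", "), "\n")
  if (nrow(x$load_log) > 0) {
    cat("  load issues:", sum(x$load_log$n), "row(s) dropped/flagged\n")
  }
  invisible(x)
}

read_stream_csv <- function(path) {
  readr::read_csv(
    path,
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
}

#' Load a surveillance dataset from delimited files
#'
#' Reads the per-stream CSV tables (UTF-8, header row, comma-delimited).
#' The stays and radiology tables are mandatory — the chest radiology
#' procedure is the minimum indicator. Rows with malformed timestamps or a
#' `stay_id` that does not resolve to a stay are dropped and counted in the
#' load log rather than failing the load.
#'
#' @param data_dir Directory containing `stays.csv`, `radiology.csv` and
#'   optionally `labs.csv`, `vitals.csv`, `devices.csv`.
#' @param paths Alternative to `data_dir`: named character vector/list with
#'   entries `stays`, `radiology` and optionally `labs`, `vitals`, `devices`.
#' @param streams Declaration of available indicator streams. Default: the
#'   streams whose files were provided (`RADIOLOGY_REPORT` must be declared
#'   explicitly — having a radiology table does not promise usable report
#'   text).
#' @return A [surveillance_dataset()]; inspect `$load_log` for dropped rows.
#' @export
load_dataset <- function(data_dir = NULL, paths = NULL, streams = NULL) {
  if (is.null(paths)) {
    if (is.null(data_dir)) {
      abort_validation("provide either data_dir or paths")
    }
    if (!dir.exists(data_dir)) {
      abort_io(sprintf("data directory not found: %s", data_dir))
    }
    candidates <- c(
      stays = "stays.csv", radiology = "radiology.csv",
      labs = "labs.csv", vitals = "vitals.csv", devices = "devices.csv"
    )
    paths <- file.path(data_dir, candidates)
    names(paths) <- names(candidates)
    paths <- paths[file.exists(paths) | names(paths) %in% c("stays", "radiology")]
  }
  paths <- as.list(paths)
  for (tab in c("stays", "radiology")) {
    if (is.null(paths[[tab]]) || !file.exists(paths[[tab]])) {
      abort_io(sprintf(
        "mandatory table '%s' missing (%s)", tab,
        paths[[tab]] %||% "no path given"
      ))
    }
  }

  log <- list()
  note <- function(table, issue, n) {
    if (n > 0) log[[length(log) + 1]] <<- tibble(table = table, issue = issue, n = as.integer(n))
    invisible(NULL)
  }

  raw_stays <- read_stream_csv(paths$stays)
  need <- c("stay_id", "patient_id", "admission_ts", "discharge_ts", "department", "icd_codes")
  if (!all(need %in% names(raw_stays))) {
    abort_validation(sprintf(
      "stays table missing column(s): %s",
      paste(setdiff(need, names(raw_stays)), collapse = ", ")
    ))
  }
  stays <- tibble(
    stay_id = raw_stays$stay_id,
    patient_id = raw_stays$patient_id,
    admission_ts = parse_ts(raw_stays$admission_ts),
    discharge_ts = parse_ts(raw_stays$discharge_ts),
    department = raw_stays$department,
    icd_codes = pipe_split(raw_stays$icd_codes)
  )
  bad_ts <- is.na(stays$admission_ts) | is.na(stays$discharge_ts)
  note("stays", "malformed timestamp", sum(bad_ts))
  stays <- stays[!bad_ts, ]
  if (nrow(stays) == 0) {
    abort_validation("no population under surveillance: stays table is empty")
  }
  known <- stays$stay_id

  raw_rad <- read_stream_csv(paths$radiology)
  radiology <- tibble(
    event_id = raw_rad$event_id,
    stay_id = raw_rad$stay_id,
    ts = parse_ts(raw_rad$ts),
    modality = raw_rad$modality,
    report_text = dplyr::coalesce(raw_rad$report_text, "")
  )
  bad_ts <- is.na(radiology$ts)
  note("radiology", "malformed timestamp", sum(bad_ts))
  radiology <- radiology[!bad_ts, ]
  orphan <- !(radiology$stay_id %in% known)
  note("radiology", "unresolvable stay_id", sum(orphan))
  radiology <- radiology[!orphan, ]

  labs <- vitals <- devices <- NULL
  if (!is.null(paths$labs) && file.exists(paths$labs)) {
    raw <- read_stream_csv(paths$labs)
    labs <- tibble(
      stay_id = raw$stay_id, ts = parse_ts(raw$ts),
      leukocytes = suppressWarnings(as.numeric(raw$leukocytes))
    )
    bad <- is.na(labs$ts) | is.na(labs$leukocytes) | labs$leukocytes < 0
    note("labs", "malformed row", sum(bad))
    labs <- labs[!bad, ]
    orphan <- !(labs$stay_id %in% known)
    note("labs", "unresolvable stay_id", sum(orphan))
    labs <- labs[!orphan, ]
  }
  if (!is.null(paths$vitals) && file.exists(paths$vitals)) {
    raw <- read_stream_csv(paths$vitals)
    vitals <- tibble(
      stay_id = raw$stay_id, ts = parse_ts(raw$ts),
      temperature = suppressWarnings(as.numeric(raw$temperature))
    )
    bad <- is.na(vitals$ts) | is.na(vitals$temperature) |
      vitals$temperature < 25 | vitals$temperature > 45
    note("vitals", "malformed row", sum(bad))
    vitals <- vitals[!bad, ]
    orphan <- !(vitals$stay_id %in% known)
    note("vitals", "unresolvable stay_id", sum(orphan))
    vitals <- vitals[!orphan, ]
  }
  if (!is.null(paths$devices) && file.exists(paths$devices)) {
    raw <- read_stream_csv(paths$devices)
    devices <- tibble(
      stay_id = raw$stay_id,
      intubation_ts = parse_ts(raw$intubation_ts),
      extubation_ts = parse_ts(raw$extubation_ts)
    )
    bad <- is.na(devices$intubation_ts)
    note("devices", "malformed timestamp", sum(bad))
    devices <- devices[!bad, ]
    orphan <- !(devices$stay_id %in% known)
    note("devices", "unresolvable stay_id", sum(orphan))
    devices <- devices[!orphan, ]
  }

  if (is.null(streams)) {
    streams <- c(
      "RADIOLOGY_PROCEDURE",
      if (!is.null(labs)) "LEUKOCYTES",
      if (!is.null(vitals)) "TEMPERATURE",
      if (!is.null(devices)) "DEVICE"
    )
  }
  surveillance_dataset(
    stays = stays, radiology = radiology, labs = labs, vitals = vitals,
    devices = devices, available_streams = streams,
    load_log = if (length(log) > 0) dplyr::bind_rows(log) else NULL
  )
}

#' Write a surveillance dataset as delimited files
#'
#' Emits the five stream tables as CSV into `dir`. [load_dataset()] on the
#' result round-trips the tables.
#'
#' @param dataset A [surveillance_dataset()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "surveillance_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) abort_io(sprintf("cannot create directory: %s", dir))

  stays_out <- tibble(
    stay_id = dataset$stays$stay_id,
    patient_id = dataset$stays$patient_id,
    admission_ts = format_ts(dataset$stays$admission_ts),
    discharge_ts = format_ts(dataset$stays$discharge_ts),
    department = dataset$stays$department,
    icd_codes = pipe_collapse(dataset$stays$icd_codes)
  )
  rad_out <- dplyr::mutate(dataset$radiology, ts = format_ts(ts))
  labs_out <- dplyr::mutate(dataset$labs, ts = format_ts(ts))
  vitals_out <- dplyr::mutate(dataset$vitals, ts = format_ts(ts))
  dev_out <- tibble(
    stay_id = dataset$devices$stay_id,
    intubation_ts = format_ts(dataset$devices$intubation_ts),
    extubation_ts = format_ts(dataset$devices$extubation_ts)
  )
  paths <- file.path(dir, c(
    "stays.csv", "radiology.csv", "labs.csv", "vitals.csv", "devices.csv"
  ))
  readr::write_csv(stays_out, paths[1], progress = FALSE)
  readr::write_csv(rad_out, paths[2], progress = FALSE)
  readr::write_csv(labs_out, paths[3], progress = FALSE)
  readr::write_csv(vitals_out, paths[4], progress = FALSE)
  readr::write_csv(dev_out, paths[5], progress = FALSE)
  invisible(paths)
}

#' Link readmissions within a maximum gap
#'
#' Sets `prior_stay_id` on every stay whose same-patient predecessor was
#' discharged between 0 (exclusive) and `max_gap_days` (inclusive) days
#' before this admission. Readmitted patients qualify for preselection at
#' any time after admission, not only after 48 h. Recomputed from scratch on
#' every call, so the operation is idempotent and independent of row order.
#'
#' @param stays Stays tibble (see [surveillance_dataset()]).
#' @param max_gap_days Maximum discharge-to-readmission gap in days
#'   (inclusive boundary).
#' @return The stays tibble with `prior_stay_id` filled in, original row
#'   order preserved.
#' @export
link_readmissions <- function(stays, max_gap_days = 10) {
  stays <- as_tibble(stays)
  ord <- order(stays$patient_id, stays$admission_ts, stays$stay_id)
  s <- stays[ord, ]
  same_patient <- c(FALSE, s$patient_id[-1] == s$patient_id[-nrow(s)])
  prev_discharge <- dplyr::lag(s$discharge_ts)
  prev_id <- dplyr::lag(s$stay_id)
  # running latest discharge per patient to detect overlapping timelines
  grp <- cumsum(!same_patient)
  run_max <- stats::ave(as.numeric(s$discharge_ts), grp, FUN = cummax)
  overlap <- same_patient & as.numeric(s$admission_ts) < dplyr::lag(run_max)
  if (any(overlap, na.rm = TRUE)) {
    bad <- s$stay_id[which(overlap)]
    abort_validation(sprintf(
      "overlapping stays for one patient (ambiguous timeline): %s",
      paste(utils::head(bad, 5), collapse = ", ")
    ))
  }
  gap <- days_between(s$admission_ts, prev_discharge)
  linked <- same_patient & !is.na(gap) & gap > 0 & gap <= max_gap_days
  s$prior_stay_id <- ifelse(linked, prev_id, NA_character_)
  s[order(ord), ]
}

#' Diagnostic validation of a dataset against a configuration
#'
#' Purely diagnostic — never errors. Reports streams the configuration
#' requires but the dataset does not declare, stays with discharge before
#' admission, events timestamped outside their stay, and the fraction of
#' empty radiology reports when the report rule is enabled. Checking back
#' input data after seeing these warnings is a core part of validating a
#' surveillance implementation.
#'
#' @param dataset A [surveillance_dataset()].
#' @param config An [algorithm_config()], or `NULL` for data-only checks.
#' @return Tibble with columns `level`, `check`, `message`, `value`.
#' @export
validate_dataset <- function(dataset, config = NULL) {
  stopifnot(inherits(dataset, "surveillance_dataset"))
  out <- list()
  add <- function(level, check, message, value = NA_real_) {
    out[[length(out) + 1]] <<- tibble(
      level = level, check = check, message = message, value = value
    )
  }

  if (!is.null(config)) {
    missing <- setdiff(config$enabled_indicators, dataset$available_streams)
    for (m in missing) {
      add("warning", "missing_stream", sprintf(
        "config enables %s but the dataset does not declare this stream", m
      ))
    }
  }

  rev_stay <- dataset$stays$discharge_ts <= dataset$stays$admission_ts
  if (any(rev_stay)) {
    add("warning", "reversed_stay", sprintf(
      "%d stay(s) with discharge not after admission", sum(rev_stay)
    ), sum(rev_stay))
  }

  span <- dplyr::select(
    dataset$stays, stay_id, admission_ts, discharge_ts
  )
  check_window <- function(tab, ts_col, name) {
    if (nrow(tab) == 0) return(invisible(NULL))
    j <- dplyr::inner_join(tab, span, by = "stay_id")
    outside <- j[[ts_col]] < j$admission_ts | j[[ts_col]] > j$discharge_ts
    if (any(outside)) {
      add("warning", "event_outside_stay", sprintf(
        "%d %s event(s) timestamped outside their stay", sum(outside), name
      ), sum(outside))
    }
  }
  check_window(dataset$radiology, "ts", "radiology")
  check_window(dataset$labs, "ts", "lab")
  check_window(dataset$vitals, "ts", "vital-sign")

  report_enabled <- is.null(config) ||
    "RADIOLOGY_REPORT" %in% config$enabled_indicators
  if (report_enabled && "RADIOLOGY_REPORT" %in% dataset$available_streams &&
      nrow(dataset$radiology) > 0) {
    frac <- mean(!nzchar(trimws(dataset$radiology$report_text)))
    if (frac > 0) {
      add("warning", "empty_reports", sprintf(
        "%.0f%% of radiology reports are empty while the report rule is in use",
        100 * frac
      ), frac)
    }
  }

  if (length(out) == 0) {
    return(tibble(
      level = character(), check = character(), message = character(),
      value = numeric()
    ))
  }
  dplyr::bind_rows(out)
}
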