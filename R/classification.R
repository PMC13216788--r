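#' Confirm pneumonia from structured case features
#'
#' ECDC-style confirmation: radiological signs, at least one systemic sign
#' (fever, leukopenia or leukocytosis), at least one clinical sign (cough,
#' dyspnea, worsening gas exchange, purulent sputum), and hospital
#' acquisition (onset more than 48 h after admission or a qualifying
#' readmission). Microbiological strata are out of scope; this is the
#' summary criterion used for emulated manual review on structured features.
#'
#' @param features Tibble with columns `radiological_signs`, `fever`,
#'   `leukopenia`, `leukocytosis`, `clinical_signs` (pipe-separated subset
#'   of `COUGH|DYSPNEA|WORSENING_GAS_EXCHANGE|PURULENT_SPUTUM`) and
#'   `hospital_acquired`; or a single-row list.
#' @return Logical vector, one element per row.
#' @export
confirm_pneumonia <- function(features) {
  f <- as_tibble(features)
  signs <- pipe_split(f$clinical_signs)
  n_signs <- vapply(
    signs, function(s) sum(s %in% CLINICAL_SIGNS), integer(1)
  )
  as.logical(
    f$radiological_signs &
      (f$fever | f$leukopenia | f$leukocytosis) &
      n_signs >= 1 &
      f$hospital_acquired
  )
}

#' Split confirmed pneumonia by ventilation status at onset
#'
#' Uses the half-open window `(onset - window_hours, onset]`:
#' * `VAP` — continuously intubated throughout the full window;
#' * `NVHAP` — not intubated for a single minute inside the window
#'   (extubation exactly at `onset - window_hours` therefore counts as
#'   never intubated);
#' * `IHAP` — anything in between, i.e. both intubated and extubated inside
#'   the window.
#'
#' A patient intubated during part of the window and still intubated at
#' onset sits between the NVHAP and VAP definitions; by default this is
#' classified `IHAP` (VAP requires the full window) and flagged via the
#' `ongoing_at_onset` attribute, with `partial_ongoing` switching the
#' convention.
#'
#' @param onset_ts Symptom-onset timestamp.
#' @param devices Device-episode tibble for the stay.
#' @param window_hours Window length before onset (default 48).
#' @param partial_ongoing Category for the partially-intubated-and-ongoing
#'   cell: `"IHAP"` (default) or `"VAP"`.
#' @return `"NVHAP"`, `"IHAP"` or `"VAP"`, with attribute
#'   `ongoing_at_onset`.
#' @export
classify_ventilation <- function(onset_ts, devices, window_hours = 48,
                                 partial_ongoing = c("IHAP", "VAP")) {
  partial_ongoing <- match.arg(partial_ongoing)
  eps <- merge_episodes(devices)
  t1 <- as.numeric(onset_ts)
  t0 <- t1 - window_hours * 3600
  overlap <- eps$start < t1 & eps$end > t0
  if (!any(overlap)) {
    return(structure("NVHAP", ongoing_at_onset = FALSE))
  }
  covered <- any(eps$start <= t0 & eps$end >= t1)
  if (covered) {
    return(structure("VAP", ongoing_at_onset = TRUE))
  }
  ongoing <- any(eps$start[overlap] < t1 & eps$end[overlap] >= t1)
  structure(
    if (ongoing) partial_ongoing else "IHAP",
    ongoing_at_onset = ongoing
  )
}

#' Emulated full manual surveillance (reference standard)
#'
#' Deterministically labels every stay from structured case features: no
#' confirmed pneumonia yields `NO_HAP`; confirmed cases are split into
#' `NVHAP`, `IHAP` and `VAP` by [classify_ventilation()]. Downstream
#' performance statistics treat nvHAP as an umbrella term that includes
#' iHAP but never VAP.
#'
#' @param features Tibble with one row per stay: `stay_id`, `onset_ts`, and
#'   the [confirm_pneumonia()] feature columns.
#' @param devices Device-episode tibble for the whole dataset (may be
#'   `NULL`: no intubation anywhere).
#' @param window_hours Ventilation window before onset (hours).
#' @param partial_ongoing See [classify_ventilation()].
#' @return Tibble: `stay_id`, `onset_ts`, `category`, `ongoing_at_onset`.
#' @export
reference_surveillance <- function(features, devices = NULL,
                                   window_hours = 48,
                                   partial_ongoing = "IHAP") {
  f <- as_tibble(features)
  need <- c(
    "stay_id", "onset_ts", "radiological_signs", "fever", "leukopenia",
    "leukocytosis", "clinical_signs", "hospital_acquired"
  )
  missing <- setdiff(need, names(f))
  if (length(missing) > 0) {
    abort_validation(sprintf(
      "features missing column(s): %s", paste(missing, collapse = ", ")
    ))
  }
  if (anyNA(f$stay_id) || anyDuplicated(f$stay_id)) {
    abort_validation("features must carry exactly one row per stay")
  }
  confirmed <- confirm_pneumonia(f)
  confirmed[is.na(confirmed)] <- FALSE
  category <- rep("NO_HAP", nrow(f))
  ongoing <- rep(FALSE, nrow(f))
  for (i in which(confirmed)) {
    dev_i <- if (is.null(devices)) NULL else {
      devices[devices$stay_id == f$stay_id[i], ]
    }
    lab <- classify_ventilation(
      f$onset_ts[i], dev_i, window_hours, partial_ongoing
    )
    category[i] <- as.character(lab)
    ongoing[i] <- attr(lab, "ongoing_at_onset")
  }
  tibble(
    stay_id = f$stay_id,
    onset_ts = f$onset_ts,
    category = category,
    ongoing_at_onset = ongoing
  )
}

#' Emulate the two-tier manual review
#'
#' First-reviewer labels come from [reference_surveillance()]; a
#' deterministic escalation rule stands in for "in cases of uncertainty a
#' second reviewer assesses": a case is escalated when worsening gas
#' exchange is its only clinical sign (the least specific presentation).
#' Escalation never changes the label — it only exercises the two-tier
#' review plumbing.
#'
#' @param features Feature tibble (see [reference_surveillance()]).
#' @param labels Output of [reference_surveillance()] for the same stays.
#' @return Tibble: `stay_id`, `first_reviewer_label`, `escalated`,
#'   `final_label`.
#' @export
emulate_review <- function(features, labels) {
  f <- as_tibble(features)
  j <- dplyr::left_join(
    labels, f[, c("stay_id", "clinical_signs")], by = "stay_id"
  )
  escalated <- j$category != "NO_HAP" &
    vapply(
      pipe_split(j$clinical_signs),
      function(s) identical(sort(s[nzchar(s)]), "WORSENING_GAS_EXCHANGE"),
      logical(1)
    )
  tibble(
    stay_id = j$stay_id,
    first_reviewer_label = j$category,
    escalated = escalated,
    final_label = j$category
  )
}

#' Read / write case feature and label tables
#'
#' `features.csv` mirrors the case-feature schema with one row per stay;
#' `labels.csv` carries `stay_id`, `onset_ts`, `category`.
#'
#' @param path CSV path.
#' @return A tibble.
#' @export
read_features <- function(path) {
  if (!file.exists(path)) abort_io(sprintf("features file not found: %s", path))
  raw <- read_stream_csv(path)
  tibble(
    stay_id = raw$stay_id,
    onset_ts = parse_ts(raw$onset_ts),
    radiological_signs = as.logical(raw$radiological_signs),
    fever = as.logical(raw$fever),
    leukopenia = as.logical(raw$leukopenia),
    leukocytosis = as.logical(raw$leukocytosis),
    clinical_signs = dplyr::coalesce(raw$clinical_signs, ""),
    hospital_acquired = as.logical(raw$hospital_acquired)
  )
}

#' @rdname read_features
#' @param labels Label tibble.
#' @export
write_labels <- function(labels, path) {
  out <- dplyr::mutate(labels, onset_ts = format_ts(onset_ts))
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' @rdname read_features
#' @export
read_labels <- function(path) {
  if (!file.exists(path)) abort_io(sprintf("labels file not found: %s", path))
  raw <- read_stream_csv(path)
  tibble(
    stay_id = raw$stay_id,
    onset_ts = parse_ts(raw$onset_ts),
    category = raw$category
  )
}
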