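# Shared fixtures and independent naive oracles. The oracles deliberately
# re-implement the surveillance rules with plain loops and base R string
# handling so they share no code path with the package implementation.

en_termset <- function() {
  termset(
    negation_terms = c("no", "not", "without"),
    infiltrate_terms = c("infiltrate", "infiltrates", "consolidation"),
    restricting_terms = c("but", "left", "right", "however"),
    language_tag = "en"
  )
}

ts_at <- function(x) parse_ts(x)

# Minimal hand-built dataset: helpers below index stays by letter.
tiny_stays <- function() {
  tibble::tibble(
    stay_id = c("A", "B", "C"),
    patient_id = c("p1", "p1", "p2"),
    admission_ts = ts_at(c(
      "2023-01-01 08:00", "2023-01-10 09:00", "2023-02-01 12:00"
    )),
    discharge_ts = ts_at(c(
      "2023-01-05 10:00", "2023-01-20 17:00", "2023-02-10 08:00"
    )),
    department = c("MED", "MED", "SURG"),
    icd_codes = list("I10", c("U69.00", "J18.9"), "E11.9")
  )
}

# ---- naive text-rule oracle (base R only, no stringi) -----------------
naive_fold <- function(x) {
  tolower(iconv(x, from = "UTF-8", to = "ASCII//TRANSLIT"))
}

naive_excludes <- function(text, terms) {
  if (is.na(text) || !nzchar(trimws(text))) return(FALSE)
  sentences <- unlist(strsplit(text, "[.!?;\n]"))
  for (s in sentences) {
    words <- unlist(strsplit(naive_fold(s), "[^a-z0-9']+"))
    words <- words[nzchar(words)]
    has <- function(lst) any(words %in% naive_fold(lst))
    if (has(terms$negation_terms) && has(terms$infiltrate_terms) &&
        !has(terms$restricting_terms)) {
      return(TRUE)
    }
  }
  FALSE
}

# ---- naive preselection oracle ----------------------------------------
naive_linked <- function(stays, i, gap_days) {
  same <- which(stays$patient_id == stays$patient_id[i] &
                  stays$stay_id != stays$stay_id[i])
  for (j in same) {
    gap <- as.numeric(difftime(
      stays$admission_ts[i], stays$discharge_ts[j], units = "days"
    ))
    if (!is.na(gap) && gap > 0 && gap <= gap_days) return(TRUE)
  }
  FALSE
}

naive_intubated_at <- function(devs, t, stay_end = Inf) {
  if (is.null(devs) || nrow(devs) == 0) return(FALSE)
  t <- as.numeric(t)
  for (j in seq_len(nrow(devs))) {
    a <- as.numeric(devs$intubation_ts[j])
    b <- devs$extubation_ts[j]
    b <- if (is.na(b)) stay_end else as.numeric(b)
    if (a <= t && t <= b) return(TRUE)
  }
  FALSE
}

naive_preselect <- function(dataset, config) {
  stays <- dataset$stays
  en <- config$enabled_indicators
  preselected <- logical(nrow(stays))
  for (i in seq_len(nrow(stays))) {
    sid <- stays$stay_id[i]
    evs <- dataset$radiology[dataset$radiology$stay_id == sid, ]
    labs <- dataset$labs[dataset$labs$stay_id == sid, ]
    vit <- dataset$vitals[dataset$vitals$stay_id == sid, ]
    devs <- dataset$devices[dataset$devices$stay_id == sid, ]
    linked <- naive_linked(stays, i, config$readmission_gap_days)
    for (k in seq_len(nrow(evs))) {
      if (evs$modality[k] == "OTHER") next
      t <- evs$ts[k]
      hrs <- as.numeric(difftime(t, stays$admission_ts[i], units = "hours"))
      if (!(hrs > config$min_hours_after_admission || linked)) next
      if ("RADIOLOGY_REPORT" %in% en &&
          naive_excludes(evs$report_text[k], config$termset)) {
        next
      }
      if ("LEUKOCYTES" %in% en) {
        hit <- FALSE
        for (j in seq_len(nrow(labs))) {
          dh <- abs(as.numeric(difftime(labs$ts[j], t, units = "hours")))
          v <- labs$leukocytes[j]
          if (dh <= config$lab_window_hours &&
              (v < config$leukopenia_threshold ||
                 v >= config$leukocytosis_threshold)) {
            hit <- TRUE
          }
        }
        if (!hit) next
      }
      if ("TEMPERATURE" %in% en) {
        hit <- FALSE
        for (j in seq_len(nrow(vit))) {
          dh <- abs(as.numeric(difftime(vit$ts[j], t, units = "hours")))
          if (dh <= config$temp_window_hours &&
              vit$temperature[j] > config$fever_threshold) {
            hit <- TRUE
          }
        }
        if (!hit) next
      }
      if ("DEVICE" %in% en && nrow(devs) > 0) {
        # continuously intubated over the full window: check a minute grid
        grid <- as.numeric(t) - seq(0, config$vap_exclusion_hours * 3600, by = 60)
        if (all(vapply(grid, function(g) naive_intubated_at(devs, g),
                       logical(1)))) {
          next
        }
      }
      preselected[i] <- TRUE
      break
    }
  }
  stays$stay_id[preselected]
}

# ---- naive reference-surveillance oracle ------------------------------
naive_reference <- function(features, devices, window_hours = 48) {
  out <- character(nrow(features))
  for (i in seq_len(nrow(features))) {
    f <- features[i, ]
    signs <- unlist(strsplit(f$clinical_signs, "|", fixed = TRUE))
    confirmed <- isTRUE(f$radiological_signs) &&
      (isTRUE(f$fever) || isTRUE(f$leukopenia) || isTRUE(f$leukocytosis)) &&
      sum(nzchar(signs)) >= 1 &&
      isTRUE(f$hospital_acquired)
    if (!confirmed) {
      out[i] <- "NO_HAP"
      next
    }
    devs <- devices[devices$stay_id == f$stay_id, ]
    t1 <- as.numeric(f$onset_ts)
    # minute grid over the half-open window (onset-48h, onset]; the extra
    # point just after the open endpoint distinguishes full-window coverage
    # from coverage starting one minute in
    grid <- c(t1 - seq(0, window_hours * 3600 - 60, by = 60),
              t1 - window_hours * 3600 + 1)
    intub <- vapply(grid, function(g) naive_intubated_at(devs, g), logical(1))
    out[i] <- if (all(intub)) "VAP" else if (!any(intub)) "NVHAP" else "IHAP"
  }
  out
}

all_indicator_subsets <- function() {
  extra <- setdiff(INDICATOR_STREAMS, "RADIOLOGY_PROCEDURE")
  subsets <- list()
  for (k in 0:length(extra)) {
    for (cmb in utils::combn(extra, k, simplify = FALSE)) {
      subsets[[length(subsets) + 1]] <- c("RADIOLOGY_PROCEDURE", cmb)
    }
  }
  subsets
}
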