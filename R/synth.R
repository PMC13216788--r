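#' Scenario parameters for the synthetic hospital generator
#'
#' Defines the simulated hospital: population size, length-of-stay
#' distribution, nvHAP incidence and the split into NVHAP/IHAP/VAP, the
#' background imaging rate, how often background reports explicitly exclude
#' pneumonia, how often a true case's lab or temperature signal is missing
#' from the record (`signal_noise`), and the short-gap readmission rate.
#' Defaults describe a mid-size acute care hospital surveyed over a
#' six-month period: 5000 stays, log-normal length of stay with median
#' 4 days, 10 nvHAP episodes per 1000 stays.
#'
#' @param n_stays Number of hospital stays.
#' @param los_meanlog,los_sdlog Log-normal length-of-stay parameters (days).
#' @param nvhap_incidence Pneumonia episodes per 1000 stays (umbrella
#'   incidence across NVHAP, IHAP and VAP).
#' @param ihap_fraction,vap_fraction Fractions of pneumonia episodes that
#'   are iHAP / VAP; the remainder are nvHAP proper.
#' @param background_radiology_rate Chest procedures per stay-week in
#'   non-cases.
#' @param report_negation_rate Fraction of background reports that
#'   explicitly exclude pneumonia.
#' @param signal_noise Probability that a true case's lab (and,
#'   independently, temperature) signal is missing from the record.
#' @param readmission_rate Fraction of stays that are <=10-day readmissions.
#' @param period_start First possible admission date.
#' @param period_days Length of the admission window in days.
#' @param termset [termset()] used to render report text.
#' @param seed Integer master seed; one RNG stream per output table is
#'   derived from it, so extending the generator with a new table never
#'   perturbs existing ones.
#' @return Object of class `scenario_params`.
#' @export
scenario_params <- function(n_stays = 5000,
                            los_meanlog = log(4),
                            los_sdlog = 0.8,
                            nvhap_incidence = 10,
                            ihap_fraction = 0.05,
                            vap_fraction = 0.25,
                            background_radiology_rate = 0.35,
                            report_negation_rate = 0.3,
                            signal_noise = 0,
                            readmission_rate = 0.04,
                            period_start = "2023-01-01",
                            period_days = 181,
                            termset = default_termset("de"),
                            seed = 1L) {
  if (n_stays < 1) abort_validation("n_stays must be positive")
  props <- c(ihap_fraction, vap_fraction, report_negation_rate,
             signal_noise, readmission_rate)
  if (any(props < 0 | props > 1)) {
    abort_validation("all proportion parameters must lie in [0, 1]")
  }
  if (ihap_fraction + vap_fraction > 1) {
    abort_validation("ihap_fraction + vap_fraction must not exceed 1")
  }
  if (nvhap_incidence < 0 || nvhap_incidence > 1000) {
    abort_validation(
      "nvhap_incidence is per 1000 stays and must lie in [0, 1000]"
    )
  }
  stopifnot(inherits(termset, "nvhap_termset"))
  structure(
    list(
      n_stays = as.integer(n_stays),
      los_meanlog = los_meanlog, los_sdlog = los_sdlog,
      nvhap_incidence = nvhap_incidence,
      ihap_fraction = ihap_fraction, vap_fraction = vap_fraction,
      background_radiology_rate = background_radiology_rate,
      report_negation_rate = report_negation_rate,
      signal_noise = signal_noise,
      readmission_rate = readmission_rate,
      period_start = period_start, period_days = period_days,
      termset = termset,
      seed = as.integer(seed)
    ),
    class = "scenario_params"
  )
}

#' @export
print.scenario_params <- function(x, ...) {
  cat("<scenario_params>\n")
  cat(sprintf(
    "  %d stays, nvHAP incidence %g/1000 (iHAP %g, VAP %g), noise %g, seed %d\n",
    x$n_stays, x$nvhap_incidence, x$ihap_fraction, x$vap_fraction,
    x$signal_noise, x$seed
  ))
  invisible(x)
}

sanitize_words <- function(words, terms) {
  all_terms <- c(
    terms$negation_terms, terms$infiltrate_terms, terms$restricting_terms
  )
  ifelse(fold_text(words) %in% all_terms, "befund", words)
}

cap_first <- function(s) {
  substr(s, 1, 1) <- toupper(substr(s, 1, 1))
  s
}

#' Render a synthetic radiology report
#'
#' Closed-loop report templating: an excluding report always contains one
#' sentence satisfying the exclusion rule for `terms`; a non-excluding
#' report never does, drawing from benign, adversarial (negation +
#' infiltrate + restricting term in one sentence), split-sentence and
#' positive-finding templates. The construction is verified against
#' [classify_report()] before the text is returned. Uses the ambient RNG
#' stream.
#'
#' @param is_excluding Should the report explicitly rule out pneumonia?
#' @param terms A [termset()].
#' @return Report text (character scalar).
#' @export
render_report <- function(is_excluding, terms) {
  neg <- sample(terms$negation_terms, 1)
  inf <- sample(terms$infiltrate_terms, 1)
  res <- sample(terms$restricting_terms, 1)
  san <- function(...) {
    paste(sanitize_words(c(...), terms), collapse = " ")
  }
  benign <- san("herz", "und", "mediastinum", "unauffaellig")
  text <- if (is_excluding) {
    paste0(cap_first(paste(neg, inf)), ". ", cap_first(benign), ".")
  } else {
    switch(sample(4, 1),
      paste0(cap_first(benign), "."),
      paste0(cap_first(paste(neg, inf)), ", ", res, " ", san("erguss"), "."),
      paste0(
        cap_first(paste(neg, san("erguss"))), ". ",
        cap_first(paste(inf, san("basal"))), "."
      ),
      paste0(cap_first(paste(san("neues"), inf, san("basal"))), ".")
    )
  }
  got <- classify_report(text, terms)$verdict == "EXCLUDES_PNEUMONIA"
  if (!identical(got, is_excluding)) {
    abort_validation(
      "report template collides with the term set; use distinct filler terms"
    )
  }
  text
}

render_reports <- function(excluding, terms) {
  vapply(excluding, render_report, character(1), terms = terms)
}

#' Generate a synthetic hospital with ground-truth pneumonia episodes
#'
#' Produces the five EHR streams plus per-stay ground truth. Injected case
#' episodes emit a qualifying chest radiology event strictly more than 48 h
#' after admission with a non-excluding report, an abnormal leukocyte value
#' and a fever measurement within 12 h of onset (each independently dropped
#' with probability `signal_noise`), and device episodes consistent with
#' the episode's NVHAP/IHAP/VAP label over the 48 h pre-onset window.
#' Non-case stays emit background imaging (reports excluding pneumonia at
#' the configured rate), routine labs and vitals with occasional incidental
#' abnormalities, and rare unrelated intubation episodes.
#'
#' Reproducible: a fixed seed yields an identical dataset; each table draws
#' from its own derived RNG stream.
#'
#' @param params A [scenario_params()].
#' @return List with `dataset` (a [surveillance_dataset()]), `ground_truth`
#'   (one row per stay: case features, category — `NO_HAP` for non-cases —
#'   the emitting radiology `event_id` and signal bookkeeping) and
#'   `params`.
#' @export
generate_hospital <- function(params = scenario_params()) {
  stopifnot(inherits(params, "scenario_params"))
  p <- params
  n <- p$n_stays
  origin <- parse_ts(p$period_start)
  icd_pool <- c(
    "I10", "E11.9", "J44.1", "I50.0", "N39.0", "K52.9", "A41.9",
    "M17.1", "J18.9", "I21.4", "F05", "C34.9"
  )

  ## -- stays stream ---------------------------------------------------
  st <- with_seed(derive_seed(p$seed, "stays"), {
    admission <- as.numeric(origin) + runif(n, 0, p$period_days * 86400)
    los_days <- pmin(pmax(rlnorm(n, p$los_meanlog, p$los_sdlog), 0.25), 90)
    department <- sample(
      c("MED", "SURG", "GERI", "ONCO", "ICU"), n, TRUE,
      prob = c(0.35, 0.3, 0.15, 0.12, 0.08)
    )
    patient_id <- sprintf("P%05d", seq_len(n))
    n_codes <- sample(1:3, n, TRUE)
    codes <- split(
      sample(icd_pool, sum(n_codes), TRUE),
      factor(rep(seq_len(n), n_codes), levels = seq_len(n))
    )
    donors <- readm <- integer(0)
    gap_h <- numeric(0)
    k <- round(p$readmission_rate * n)
    if (k > 0 && 2 * k <= n) {
      idx <- sample(n, 2 * k)
      donors <- idx[seq_len(k)]
      readm <- idx[k + seq_len(k)]
      patient_id[readm] <- patient_id[donors]
      gap_h <- runif(k, 6, 236)
    }
    list(
      admission = admission, los_days = los_days, department = department,
      patient_id = patient_id, codes = unname(codes),
      donors = donors, readm = readm, gap_h = gap_h
    )
  })

  ## -- cases stream ---------------------------------------------------
  cs <- with_seed(derive_seed(p$seed, "cases"), {
    n_cases <- rbinom(1, n, p$nvhap_incidence / 1000)
    case_idx <- if (n_cases > 0) sample(n, n_cases) else integer(0)
    u <- runif(n_cases)
    category <- ifelse(
      u < p$vap_fraction, "VAP",
      ifelse(u < p$vap_fraction + p$ihap_fraction, "IHAP", "NVHAP")
    )
    los_case <- pmax(st$los_days[case_idx], 6.5)
    onset_off_h <- runif(
      n_cases, 60, pmin(los_case * 24 - 12, 400)
    )
    signs <- lapply(seq_len(n_cases), function(i) {
      sort(sample(CLINICAL_SIGNS, sample(1:3, 1)))
    })
    list(
      n_cases = n_cases, case_idx = case_idx, category = category,
      los_case = los_case, onset_off_h = onset_off_h, signs = signs,
      u69 = runif(n_cases) < 0.6,
      miscode = runif(n) < 0.002,
      lab_recorded = runif(n_cases) >= p$signal_noise,
      temp_recorded = runif(n_cases) >= p$signal_noise
    )
  })
  los_days <- st$los_days
  los_days[cs$case_idx] <- cs$los_case
  # the readmission shift is applied to the final lengths of stay, so a
  # donor stay later lengthened as a case can never overlap its readmission
  adm_num <- st$admission
  adm_num[st$readm] <- adm_num[st$donors] +
    los_days[st$donors] * 86400 + st$gap_h * 3600
  admission <- trunc_minute(
    as.POSIXct(adm_num, origin = "1970-01-01", tz = TZ)
  )
  discharge <- trunc_minute(admission + los_days * 86400)
  onset <- trunc_minute(
    admission[cs$case_idx] + cs$onset_off_h * 3600
  )
  stay_id <- sprintf("S%05d", seq_len(n))

  codes <- st$codes
  for (j in seq_len(cs$n_cases)) {
    if (cs$u69[j] && cs$category[j] != "VAP") {
      codes[[cs$case_idx[j]]] <- c(codes[[cs$case_idx[j]]], "U69.00")
    }
  }
  mis <- setdiff(which(cs$miscode), cs$case_idx)
  for (j in mis) codes[[j]] <- c(codes[[j]], "U69.00")

  stays <- tibble(
    stay_id = stay_id,
    patient_id = st$patient_id,
    admission_ts = admission,
    discharge_ts = discharge,
    department = st$department,
    icd_codes = codes
  )
  is_case <- seq_len(n) %in% cs$case_idx

  ## -- radiology stream -----------------------------------------------
  rad <- with_seed(derive_seed(p$seed, "radiology"), {
    case_mod <- sample(
      c("CHEST_XRAY", "CHEST_CT"), cs$n_cases, TRUE, prob = c(0.8, 0.2)
    )
    case_rep <- render_reports(rep(FALSE, cs$n_cases), p$termset)
    k_bg <- rpois(n, p$background_radiology_rate * los_days / 7)
    rows <- rep(seq_len(n), k_bg)
    m <- length(rows)
    bg_ts <- trunc_minute(
      admission[rows] + runif(m) * (los_days[rows] * 86400 - 120) + 60
    )
    bg_mod <- sample(
      c("CHEST_XRAY", "CHEST_CT", "OTHER"), m, TRUE,
      prob = c(0.7, 0.15, 0.15)
    )
    bg_rep <- render_reports(runif(m) < p$report_negation_rate, p$termset)
    tab <- tibble(
      stay_id = c(stay_id[cs$case_idx], stay_id[rows]),
      ts = c(onset, bg_ts),
      modality = c(case_mod, bg_mod),
      report_text = c(case_rep, bg_rep)
    )
    tab$event_id <- sprintf("R%06d", seq_len(nrow(tab)))
    tab[, c("event_id", "stay_id", "ts", "modality", "report_text")]
  })
  case_event_id <- rad$event_id[seq_len(cs$n_cases)]

  ## -- labs stream ----------------------------------------------------
  labs <- with_seed(derive_seed(p$seed, "labs"), {
    m_i <- rpois(n, pmax(los_days / 2, 0.5))
    rows <- rep(seq_len(n), m_i)
    m <- length(rows)
    ts <- trunc_minute(
      admission[rows] + runif(m) * (los_days[rows] * 86400 - 120) + 60
    )
    u <- runif(m)
    value <- ifelse(
      u < 0.05, runif(m, 12, 16),
      ifelse(u < 0.08, runif(m, 2.5, 3.9),
             pmin(pmax(rnorm(m, 7.5, 1.5), 4.3), 11.9))
    )
    sel <- cs$lab_recorded
    case_ts <- trunc_minute(onset[sel] + runif(sum(sel), -12, 12) * 3600)
    case_val <- runif(sum(sel), 12.5, 21)
    tibble(
      stay_id = c(stay_id[rows], stay_id[cs$case_idx[sel]]),
      ts = c(ts, case_ts),
      leukocytes = round(c(value, case_val), 1)
    )
  })

  ## -- vitals stream --------------------------------------------------
  vitals <- with_seed(derive_seed(p$seed, "vitals"), {
    m_i <- rpois(n, pmax(los_days * 1.5, 1)) + 1L
    rows <- rep(seq_len(n), m_i)
    m <- length(rows)
    ts <- trunc_minute(
      admission[rows] + runif(m) * (los_days[rows] * 86400 - 120) + 60
    )
    u <- runif(m)
    temp <- ifelse(
      u < 0.07, runif(m, 38.1, 39.2),
      pmin(pmax(rnorm(m, 36.9, 0.35), 35.9), 37.9)
    )
    sel <- cs$temp_recorded
    case_ts <- trunc_minute(onset[sel] + runif(sum(sel), -12, 12) * 3600)
    case_val <- runif(sum(sel), 38.4, 39.6)
    tibble(
      stay_id = c(stay_id[rows], stay_id[cs$case_idx[sel]]),
      ts = c(ts, case_ts),
      temperature = round(c(temp, case_val), 1)
    )
  })

  ## -- devices stream -------------------------------------------------
  devices <- with_seed(derive_seed(p$seed, "devices"), {
    out <- list()
    for (j in seq_len(cs$n_cases)) {
      i <- cs$case_idx[j]
      t1 <- onset[j]
      if (cs$category[j] == "IHAP") {
        in_off <- runif(1, 20, 46)
        ex_off <- runif(1, 0.5, in_off - 10)
        out[[length(out) + 1]] <- tibble(
          stay_id = stay_id[i],
          intubation_ts = trunc_minute(t1 - in_off * 3600),
          extubation_ts = trunc_minute(t1 - ex_off * 3600)
        )
      } else if (cs$category[j] == "VAP") {
        in_ts <- trunc_minute(t1 - runif(1, 50, 58) * 3600)
        ex_ts <- if (runif(1) < 0.5) {
          parse_ts(NA_character_)
        } else {
          trunc_minute(pmin(t1 + runif(1, 2, 24) * 3600, discharge[i]))
        }
        out[[length(out) + 1]] <- tibble(
          stay_id = stay_id[i], intubation_ts = in_ts, extubation_ts = ex_ts
        )
      } else if (runif(1) < 0.12 &&
                 hours_between(t1, admission[i]) > 62) {
        # an old, resolved intubation well before the 48 h window
        out[[length(out) + 1]] <- tibble(
          stay_id = stay_id[i],
          intubation_ts = trunc_minute(admission[i] + runif(1, 0, 2) * 3600),
          extubation_ts = trunc_minute(t1 - runif(1, 49, 53) * 3600)
        )
      }
    }
    bg <- which(!is_case & runif(n) < 0.015 & los_days >= 1.5)
    if (length(bg) > 0) {
      in_ts <- trunc_minute(
        admission[bg] + runif(length(bg), 0, los_days[bg] / 3) * 86400
      )
      ex_ts <- trunc_minute(pmin(
        as.numeric(in_ts) + runif(length(bg), 4, 48) * 3600,
        as.numeric(discharge[bg]) - 300
      ))
      keep <- as.numeric(ex_ts) > as.numeric(in_ts)
      out[[length(out) + 1]] <- tibble(
        stay_id = stay_id[bg][keep],
        intubation_ts = in_ts[keep],
        extubation_ts = ex_ts[keep]
      )
    }
    if (length(out) == 0) NULL else dplyr::bind_rows(out)
  })

  ## -- ground truth ----------------------------------------------------
  truth <- tibble(
    stay_id = stay_id,
    category = "NO_HAP",
    onset_ts = as.POSIXct(NA_real_, origin = "1970-01-01", tz = TZ),
    radiological_signs = FALSE,
    fever = FALSE,
    leukopenia = FALSE,
    leukocytosis = FALSE,
    clinical_signs = "",
    hospital_acquired = FALSE,
    event_id = NA_character_,
    lab_recorded = NA,
    temp_recorded = NA
  )
  if (cs$n_cases > 0) {
    ci <- cs$case_idx
    truth$category[ci] <- cs$category
    truth$onset_ts[ci] <- onset
    truth$radiological_signs[ci] <- TRUE
    truth$fever[ci] <- TRUE
    truth$leukocytosis[ci] <- TRUE
    truth$clinical_signs[ci] <- vapply(
      cs$signs, paste, character(1), collapse = "|"
    )
    truth$hospital_acquired[ci] <- TRUE
    truth$event_id[ci] <- case_event_id
    truth$lab_recorded[ci] <- cs$lab_recorded
    truth$temp_recorded[ci] <- cs$temp_recorded
  }

  dataset <- surveillance_dataset(
    stays = stays, radiology = rad, labs = labs, vitals = vitals,
    devices = devices, available_streams = INDICATOR_STREAMS
  )
  list(dataset = dataset, ground_truth = truth, params = p)
}

#' Write a generated scenario to disk
#'
#' Emits the five stream CSVs (see [write_dataset()]) plus
#' `ground_truth.csv` and `params.yaml`. [load_dataset()] on the directory
#' round-trips the dataset.
#'
#' @param sim Result of [generate_hospital()].
#' @param dir Output directory.
#' @return Invisibly, the paths written.
#' @export
write_scenario <- function(sim, dir) {
  paths <- write_dataset(sim$dataset, dir)
  gt <- dplyr::mutate(sim$ground_truth, onset_ts = format_ts(onset_ts))
  gt_path <- file.path(dir, "ground_truth.csv")
  readr::write_csv(gt, gt_path, progress = FALSE)
  par_path <- file.path(dir, "params.yaml")
  plain <- unclass(sim$params)
  plain$termset <- plain$termset$language_tag
  yaml::write_yaml(plain, par_path)
  invisible(c(paths, gt_path, par_path))
}

#' Read a ground-truth table written by [write_scenario()]
#'
#' @param path `ground_truth.csv` path.
#' @return Tibble in the [generate_hospital()] ground-truth schema.
#' @export
read_ground_truth <- function(path) {
  if (!file.exists(path)) abort_io(sprintf("ground truth not found: %s", path))
  raw <- read_stream_csv(path)
  tibble(
    stay_id = raw$stay_id,
    category = raw$category,
    onset_ts = parse_ts(raw$onset_ts),
    radiological_signs = as.logical(raw$radiological_signs),
    fever = as.logical(raw$fever),
    leukopenia = as.logical(raw$leukopenia),
    leukocytosis = as.logical(raw$leukocytosis),
    clinical_signs = dplyr::coalesce(raw$clinical_signs, ""),
    hospital_acquired = as.logical(raw$hospital_acquired),
    event_id = raw$event_id,
    lab_recorded = as.logical(raw$lab_recorded),
    temp_recorded = as.logical(raw$temp_recorded)
  )
}
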