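# Single-stay fixture builder: one radiology event at a chosen offset with
# controllable lab/temperature/device context.
single_event_ds <- function(rad_hours = 72,
                            report = "routine film",
                            leuko = NULL, leuko_offset_h = 0,
                            temp = NULL, temp_offset_h = 0,
                            intub_h = NULL, extub_h = NULL,
                            readmitted = FALSE,
                            modality = "CHEST_XRAY") {
  adm <- ts_at("2023-03-01 00:00")
  dis <- adm + 14 * 86400
  stays <- tibble::tibble(
    stay_id = "S1", patient_id = "p9",
    admission_ts = adm, discharge_ts = dis, department = "MED",
    icd_codes = list(character(0)),
    prior_stay_id = if (readmitted) "S0" else NA_character_
  )
  t <- adm + rad_hours * 3600
  rad <- tibble::tibble(
    event_id = "r1", stay_id = "S1", ts = t,
    modality = modality, report_text = report
  )
  labs <- if (is.null(leuko)) NULL else tibble::tibble(
    stay_id = "S1", ts = t + leuko_offset_h * 3600, leukocytes = leuko
  )
  vitals <- if (is.null(temp)) NULL else tibble::tibble(
    stay_id = "S1", ts = t + temp_offset_h * 3600, temperature = temp
  )
  devices <- if (is.null(intub_h)) NULL else tibble::tibble(
    stay_id = "S1",
    intubation_ts = t + intub_h * 3600,
    extubation_ts = if (is.null(extub_h)) parse_ts(NA_character_) else
      t + extub_h * 3600
  )
  surveillance_dataset(
    stays, rad, labs, vitals, devices,
    available_streams = INDICATOR_STREAMS
  )
}

full_cfg <- function() algorithm_config(termset = en_termset())

test_that("timing rule is strict at 48 h with readmission override", {
  cfg <- full_cfg()
  run1 <- function(...) {
    ds <- single_event_ds(...)
    radiology_timing_ok(ds$radiology[1, ], ds$stays[1, ], cfg)
  }
  expect_false(run1(rad_hours = 36, readmitted = FALSE))
  expect_true(run1(rad_hours = 49, readmitted = FALSE))
  expect_false(run1(rad_hours = 48, readmitted = FALSE))  # strictly >
  expect_true(run1(rad_hours = 24, readmitted = TRUE))
  # event outside the stay interval is a hard error
  ds <- single_event_ds(rad_hours = 72)
  bad <- ds$radiology[1, ]
  bad$ts <- ds$stays$admission_ts[1] - 3600
  expect_error(radiology_timing_ok(bad, ds$stays[1, ], cfg),
               class = "nvhap_validation_error")
})

test_that("leukocyte and temperature signals respect thresholds and windows", {
  cfg <- full_cfg()
  t <- ts_at("2023-03-04 00:00")
  lab <- function(v, off) tibble::tibble(
    stay_id = "S1", ts = t + off * 3600, leukocytes = v
  )
  expect_true(leukocyte_signal(lab(13.5, -6), t, cfg))   # elevated
  expect_true(leukocyte_signal(lab(3.2, 12), t, cfg))    # reduced
  expect_false(leukocyte_signal(lab(8.0, 0), t, cfg))    # in range
  expect_false(leukocyte_signal(lab(13.5, -49), t, cfg)) # outside window
  expect_true(leukocyte_signal(lab(13.5, -48), t, cfg))  # inclusive boundary
  expect_true(leukocyte_signal(lab(12.0, 0), t, cfg))    # >= threshold
  expect_false(leukocyte_signal(lab(4.0, 0), t, cfg))    # 4.0 is not < 4.0

  vit <- function(v, off) tibble::tibble(
    stay_id = "S1", ts = t + off * 3600, temperature = v
  )
  expect_true(temperature_signal(vit(38.6, -2), t, cfg))
  expect_false(temperature_signal(vit(38.0, 0), t, cfg))  # strictly >
  expect_false(temperature_signal(vit(38.6, 50), t, cfg))
  expect_false(temperature_signal(vit(numeric(0), numeric(0))[0, ], t, cfg))
})

test_that("device filter removes only full-window continuous intubation", {
  cfg <- full_cfg()
  t <- ts_at("2023-03-04 00:00")
  dev <- function(in_h, ex_h) tibble::tibble(
    stay_id = "S1",
    intubation_ts = t + in_h * 3600,
    extubation_ts = if (is.na(ex_h)) parse_ts(NA_character_) else t + ex_h * 3600
  )
  expect_true(device_ok(dev(-72, -50), t, cfg))   # resolved before window
  expect_false(device_ok(dev(-72, NA), t, cfg))   # still intubated: VAP
  expect_false(device_ok(dev(-72, 2), t, cfg))    # covers the full window
  expect_true(device_ok(dev(-30, -10), t, cfg))   # partial: iHAP stays in
  expect_true(device_ok(NULL, t, cfg))
  # two abutting episodes jointly covering the window still veto
  two <- dplyr::bind_rows(dev(-72, -20), dev(-20, 5))
  expect_false(device_ok(two, t, cfg))
})

test_that("event relevance equals the conjunction over enabled indicators", {
  cfg <- full_cfg()
  # all 2^5 indicator-flag combinations on constructed single-event fixtures
  for (timing in c(TRUE, FALSE)) {
    for (rep_ok in c(TRUE, FALSE)) {
      for (leu in c(TRUE, FALSE)) {
        for (tmp in c(TRUE, FALSE)) {
          for (dev in c(TRUE, FALSE)) {
            ds <- single_event_ds(
              rad_hours = if (timing) 72 else 36,
              report = if (rep_ok) "stable film" else "No infiltrate.",
              leuko = if (leu) 14 else 8, leuko_offset_h = -4,
              temp = if (tmp) 38.7 else 37.0, temp_offset_h = 2,
              intub_h = if (dev) -20 else -72,
              extub_h = if (dev) -10 else NULL
            )
            verdict <- evaluate_radiology_event(
              ds$radiology[1, ], ds$stays[1, ], ds, cfg
            )
            expect_equal(
              verdict$relevant, all(timing, rep_ok, leu, tmp, dev),
              label = paste(timing, rep_ok, leu, tmp, dev)
            )
            expect_equal(verdict$radiology_timing_ok, timing)
            expect_equal(verdict$report_not_excluding, rep_ok)
            expect_equal(verdict$leukocyte_signal, leu)
            expect_equal(verdict$temperature_signal, tmp)
            expect_equal(verdict$device_ok, dev)
          }
        }
      }
    }
  }
})

test_that("disabled indicators are N/A and never veto", {
  # hostile context on every optional indicator; only the procedure enabled
  ds <- single_event_ds(
    rad_hours = 72, report = "No infiltrate.",
    leuko = 8, temp = 37, intub_h = -72, extub_h = NULL
  )
  cfg1 <- algorithm_config("RADIOLOGY_PROCEDURE", termset = en_termset())
  verdict <- evaluate_radiology_event(ds$radiology[1, ], ds$stays[1, ], ds, cfg1)
  expect_true(verdict$relevant)
  expect_true(is.na(verdict$report_not_excluding))
  expect_true(is.na(verdict$leukocyte_signal))
  expect_true(is.na(verdict$temperature_signal))
  expect_true(is.na(verdict$device_ok))
  # modality OTHER is never a trigger, whatever the flags
  ds2 <- single_event_ds(rad_hours = 72, modality = "OTHER")
  expect_false(
    evaluate_radiology_event(ds2$radiology[1, ], ds2$stays[1, ], ds2, cfg1)$relevant
  )
})

test_that("enabling a stream the dataset lacks fails at pipeline start", {
  ds <- single_event_ds(rad_hours = 72)
  ds$available_streams <- c("RADIOLOGY_PROCEDURE", "RADIOLOGY_REPORT")
  expect_error(preselect(ds, full_cfg()), "does not declare",
               class = "nvhap_validation_error")
})

test_that("preselect matches the naive per-stay oracle on random hospitals", {
  for (seed in c(3, 17, 29)) {
    sim <- generate_hospital(scenario_params(
      n_stays = 150, seed = seed, signal_noise = 0.3,
      report_negation_rate = 0.4
    ))
    for (ind in list(INDICATOR_STREAMS,
                     c("RADIOLOGY_PROCEDURE", "LEUKOCYTES"),
                     "RADIOLOGY_PROCEDURE")) {
      cfg <- algorithm_config(ind)
      got <- preselect(sim$dataset, cfg)
      want <- naive_preselect(sim$dataset, cfg)
      expect_setequal(
        got$stays$stay_id[got$stays$preselected], want
      )
    }
  }
})

test_that("preselection is invariant under row permutation of inputs", {
  sim <- generate_hospital(scenario_params(n_stays = 120, seed = 5,
                                           signal_noise = 0.2))
  ds <- sim$dataset
  cfg <- algorithm_config()
  base <- preselect(ds, cfg)$stays
  withr::with_seed(1, {
    shuf <- ds
    shuf$stays <- shuf$stays[sample(nrow(shuf$stays)), ]
    shuf$radiology <- shuf$radiology[sample(nrow(shuf$radiology)), ]
    shuf$labs <- shuf$labs[sample(nrow(shuf$labs)), ]
    shuf$vitals <- shuf$vitals[sample(nrow(shuf$vitals)), ]
    if (nrow(shuf$devices) > 1) {
      shuf$devices <- shuf$devices[sample(nrow(shuf$devices)), ]
    }
  })
  perm <- preselect(shuf, cfg)$stays
  expect_equal(
    perm[order(perm$stay_id), ],
    base[order(base$stay_id), ],
    ignore_attr = TRUE
  )
})

test_that("more indicators can only shrink the preselected set", {
  sim <- generate_hospital(scenario_params(n_stays = 400, seed = 8,
                                           signal_noise = 0.1))
  sets <- list(
    "RADIOLOGY_PROCEDURE",
    c("RADIOLOGY_PROCEDURE", "RADIOLOGY_REPORT"),
    c("RADIOLOGY_PROCEDURE", "RADIOLOGY_REPORT", "LEUKOCYTES"),
    c("RADIOLOGY_PROCEDURE", "RADIOLOGY_REPORT", "LEUKOCYTES", "TEMPERATURE"),
    INDICATOR_STREAMS
  )
  picked <- lapply(sets, function(s) {
    r <- preselect(sim$dataset, algorithm_config(s))
    r$stays$stay_id[r$stays$preselected]
  })
  for (i in seq_len(length(sets) - 1)) {
    expect_true(all(picked[[i + 1]] %in% picked[[i]]))
  }
  # empty radiology table -> nobody preselected
  empty <- sim$dataset
  empty$radiology <- empty$radiology[0, ]
  r0 <- preselect(empty, algorithm_config())
  expect_equal(sum(r0$stays$preselected), 0)
})
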