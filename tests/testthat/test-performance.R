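test_that("Clopper-Pearson interval matches binomial tail inversion", {
  # independent oracle: invert the binomial tails numerically
  invert_cp <- function(x, n, conf = 0.95) {
    a <- (1 - conf) / 2
    lower <- if (x == 0) 0 else {
      stats::uniroot(function(p) 1 - stats::pbinom(x - 1, n, p) - a,
                     c(1e-12, 1 - 1e-12), tol = 1e-12)$root
    }
    upper <- if (x == n) 1 else {
      stats::uniroot(function(p) stats::pbinom(x, n, p) - a,
                     c(1e-12, 1 - 1e-12), tol = 1e-12)$root
    }
    c(lower, upper)
  }
  for (case in list(c(48, 48), c(0, 20), c(5, 10), c(33, 40), c(1, 73))) {
    got <- ci_clopper_pearson(case[1], case[2])
    want <- invert_cp(case[1], case[2])
    expect_equal(unname(got), want, tolerance = 1e-8,
                 label = paste(case, collapse = "/"))
    # cross-check against the stock exact binomial test
    bt <- stats::binom.test(case[1], case[2])$conf.int
    expect_equal(unname(got), as.numeric(bt), tolerance = 1e-8)
  }
  # detecting 0 of n: upper bound is 1 - (alpha/2)^(1/n) by symmetry
  n <- 30
  expect_equal(unname(ci_clopper_pearson(0, n)["upper"]),
               1 - 0.025^(1 / n), tolerance = 1e-10)
})

test_that("exact CI brackets the estimate and narrows with n", {
  for (n in c(10, 20, 50)) {
    for (x in c(0, floor(n / 2), n)) {
      ci <- ci_clopper_pearson(x, n)
      expect_lte(ci["lower"], x / n)
      expect_gte(ci["upper"], x / n)
    }
  }
  widths <- vapply(c(10, 40, 160, 640), function(n) {
    ci <- ci_clopper_pearson(round(0.8 * n), n)
    unname(ci["upper"] - ci["lower"])
  }, numeric(1))
  expect_true(all(diff(widths) < 0))
})

test_that("Wilson interval matches the score test and covers adequately", {
  for (case in list(c(130, 1000), c(3, 10), c(0, 50), c(48, 48))) {
    got <- ci_wilson(case[1], case[2])
    want <- suppressWarnings(
      stats::prop.test(case[1], case[2], correct = FALSE)$conf.int
    )
    expect_equal(unname(got), as.numeric(want), tolerance = 1e-8)
  }
  # seeded coverage experiment over random (p, n) fixtures
  withr::with_seed(4242, {
    reps <- 10000
    p <- runif(reps, 0.02, 0.5)
    n <- sample(50:500, reps, replace = TRUE)
    x <- rbinom(reps, n, p)
    z <- qnorm(0.975)
    denom <- 1 + z^2 / n
    ph <- x / n
    center <- (ph + z^2 / (2 * n)) / denom
    half <- z * sqrt(ph * (1 - ph) / n + z^2 / (4 * n^2)) / denom
    covered <- (center - half) <= p & p <= (center + half)
    expect_gte(mean(covered), 0.94)
  })
})

test_that("sensitivity uses the umbrella reference and errors when empty", {
  labels <- tibble::tibble(
    stay_id = c("a", "b", "c", "d"),
    onset_ts = ts_at(rep("2023-02-02 10:00", 4)),
    category = c("NVHAP", "IHAP", "VAP", "NO_HAP")
  )
  s <- sensitivity(c("a", "c", "d"), labels)
  expect_equal(s$n_reference, 2)  # VAP and NO_HAP are not reference cases
  expect_equal(s$estimate, 0.5)
  s2 <- sensitivity(c("a", "b"), labels)
  expect_equal(s2$estimate, 1)
  expect_equal(s2$lower, 0.025^(1 / 2), tolerance = 1e-10)
  none <- labels[labels$category == "VAP", ]
  expect_error(sensitivity("a", none), "undefined",
               class = "nvhap_validation_error")
})

test_that("workload and number needed to screen follow their definitions", {
  w <- workload_fraction(130, 1000)
  expect_equal(w$estimate, 0.13)
  expect_equal(workload_fraction(0, 1000)$lower, 0)
  expect_error(workload_fraction(5, 0), class = "nvhap_validation_error")
  expect_error(workload_fraction(11, 10), class = "nvhap_validation_error")

  expect_equal(nns(33, 5), 6.6)
  expect_equal(nns(100, 100), 1)
  expect_true(is.na(nns(50, 0)))
  expect_error(nns(5, 6), class = "nvhap_validation_error")
})

test_that("sample-size planning reproduces the closed form", {
  expect_identical(sample_size_sensitivity(0.95, 0.05, 0.95), 73L)
  expect_identical(sample_size_sensitivity(0.50, 0.50, 0.95), 4L)
  expect_identical(sample_size_sensitivity(0.50, 0.10, 0.95), 97L)
  # symmetric in p <-> 1-p, non-increasing in margin
  expect_identical(
    sample_size_sensitivity(0.3, 0.05), sample_size_sensitivity(0.7, 0.05)
  )
  margins <- c(0.02, 0.05, 0.1, 0.2)
  sizes <- vapply(margins, function(m) sample_size_sensitivity(0.9, m),
                  integer(1))
  expect_true(all(diff(sizes) <= 0))
  expect_error(sample_size_sensitivity(1, 0.05),
               class = "nvhap_validation_error")
  # exact-binomial mode plans at least as many cases as the approximation
  expect_gte(sample_size_sensitivity(0.95, 0.05, method = "exact"), 73L)
})

test_that("validation cohort combines coded stays with a seeded sample", {
  n <- 400
  stays <- tibble::tibble(
    stay_id = sprintf("S%03d", 1:n),
    patient_id = sprintf("P%03d", 1:n),
    admission_ts = ts_at("2023-01-01 00:00") + (1:n) * 3600,
    discharge_ts = ts_at("2023-01-01 00:00") + (1:n) * 3600 +
      rep(c(2, 20), n / 2) * 86400,
    department = "MED",
    icd_codes = c(
      rep(list("U69.00"), 5), rep(list(c("I10", "u69.01")), 2),
      rep(list("I10"), n - 7)
    )
  )
  rad <- tibble::tibble(
    event_id = "r", stay_id = "S001",
    ts = ts_at("2023-01-02 00:00"), modality = "CHEST_XRAY", report_text = ""
  )
  ds <- surveillance_dataset(stays, rad)
  cohort <- build_validation_cohort(ds, n_random = 50, seed = 9)
  # dot-insensitive, case-insensitive prefix match on the code family
  expect_true(all(sprintf("S%03d", 1:7) %in% cohort))
  expect_equal(length(cohort), 57)
  # deterministic given the seed; capped by eligibility
  expect_identical(cohort, build_validation_cohort(ds, n_random = 50, seed = 9))
  expect_false(identical(
    cohort, build_validation_cohort(ds, n_random = 50, seed = 10)
  ))
  long_cap <- build_validation_cohort(ds, n_random = 10000, seed = 1)
  los_days <- as.numeric(difftime(
    stays$discharge_ts, stays$admission_ts, units = "days"
  ))
  expect_equal(length(long_cap), 7 + sum(los_days[-(1:7)] >= 14))
})

test_that("the assembled report equals an independent recount", {
  sim <- generate_hospital(scenario_params(n_stays = 300, seed = 21,
                                           signal_noise = 0.2))
  cfg <- algorithm_config(c("RADIOLOGY_PROCEDURE", "LEUKOCYTES",
                            "TEMPERATURE"))
  labels <- reference_surveillance(sim$ground_truth, sim$dataset$devices)
  report <- evaluate_performance(sim$dataset, cfg, labels)

  pres <- preselect(sim$dataset, cfg)
  pres_ids <- pres$stays$stay_id[pres$stays$preselected]
  ref_ids <- labels$stay_id[labels$category %in% c("NVHAP", "IHAP")]
  detected <- sum(ref_ids %in% pres_ids)
  expect_equal(report$n_population, 300)
  expect_equal(report$n_preselected, length(pres_ids))
  expect_equal(report$n_reference_cases, length(ref_ids))
  expect_equal(report$n_detected_cases, detected)
  expect_equal(report$sensitivity, detected / length(ref_ids))
  expect_equal(report$workload_fraction, length(pres_ids) / 300)
  expect_equal(report$nns, length(pres_ids) / detected)
  expect_lte(report$n_detected_cases,
             min(report$n_preselected, report$n_reference_cases))

  # restricting to a validation cohort restricts every denominator
  cohort <- union(ref_ids, pres_ids)[1:5]
  sub <- evaluate_performance(sim$dataset, cfg, labels, population = cohort)
  expect_lte(sub$n_population, 5)
})

test_that("serialised reports carry aggregates only, never identifiers", {
  sim <- generate_hospital(scenario_params(n_stays = 150, seed = 2))
  labels <- reference_surveillance(sim$ground_truth, sim$dataset$devices)
  report <- evaluate_performance(sim$dataset, algorithm_config(), labels)
  f <- withr::local_tempfile(fileext = ".json")
  write_performance_report(report, f)
  parsed <- jsonlite::read_json(f)
  expect_false(any(grepl("stay_id|patient_id", names(unlist(parsed)))))
  expect_false(any(grepl("S\\d{5}|P\\d{5}", unlist(parsed))))
  expect_equal(parsed$n_population, 150)
})
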