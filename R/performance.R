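#' Exact (Clopper-Pearson) and Wilson binomial confidence intervals
#'
#' `ci_clopper_pearson()` inverts the binomial tails via the beta quantile;
#' `ci_wilson()` is the score interval. Sensitivity defaults to the exact
#' interval (for 48 detected of 48 reference cases the lower bound is
#' 0.025^(1/48) = 0.926), workload to Wilson; both are selectable in
#' [algorithm_config()].
#'
#' @param x Number of successes.
#' @param n Number of trials.
#' @param conf_level Two-sided confidence level.
#' @return Named numeric vector `c(lower, upper)`.
#' @export
ci_clopper_pearson <- function(x, n, conf_level = 0.95) {
  stopifnot(n >= 1, x >= 0, x <= n)
  a <- 1 - conf_level
  lower <- if (x == 0) 0 else qbeta(a / 2, x, n - x + 1)
  upper <- if (x == n) 1 else qbeta(1 - a / 2, x + 1, n - x)
  c(lower = lower, upper = upper)
}

#' @rdname ci_clopper_pearson
#' @export
ci_wilson <- function(x, n, conf_level = 0.95) {
  stopifnot(n >= 1, x >= 0, x <= n)
  z <- qnorm(1 - (1 - conf_level) / 2)
  p <- x / n
  denom <- 1 + z^2 / n
  center <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  c(lower = max(0, center - half), upper = min(1, center + half))
}

proportion_ci <- function(x, n, method, conf_level = 0.95) {
  switch(method,
    "clopper-pearson" = ci_clopper_pearson(x, n, conf_level),
    "wilson" = ci_wilson(x, n, conf_level),
    abort_validation(sprintf("unknown CI method: %s", method))
  )
}

#' Algorithm sensitivity against the reference standard
#'
#' Fraction of reference nvHAP cases (umbrella: NVHAP + IHAP, never VAP)
#' that appear on the preselected list, with a two-sided exact 95%
#' confidence interval by default.
#'
#' @param preselected A [preselect()] result, or a character vector of
#'   preselected stay ids.
#' @param reference A [reference_surveillance()] label tibble, or a
#'   character vector of reference-case stay ids.
#' @param conf_level Confidence level.
#' @param ci_method `"clopper-pearson"` (default) or `"wilson"`.
#' @return List: `estimate`, `lower`, `upper`, `n_detected`, `n_reference`.
#' @export
sensitivity <- function(preselected, reference, conf_level = 0.95,
                        ci_method = "clopper-pearson") {
  pres_ids <- preselected_ids(preselected)
  ref_ids <- reference_case_ids(reference)
  n <- length(ref_ids)
  if (n == 0) {
    abort_validation("sensitivity undefined: zero reference nvHAP cases")
  }
  x <- sum(ref_ids %in% pres_ids)
  ci <- proportion_ci(x, n, ci_method, conf_level)
  list(
    estimate = x / n, lower = unname(ci["lower"]), upper = unname(ci["upper"]),
    n_detected = x, n_reference = n
  )
}

preselected_ids <- function(preselected) {
  if (inherits(preselected, "preselection")) {
    preselected$stays$stay_id[preselected$stays$preselected]
  } else {
    unique(as.character(preselected))
  }
}

reference_case_ids <- function(reference) {
  if (is.data.frame(reference)) {
    unique(reference$stay_id[reference$category %in% c("NVHAP", "IHAP")])
  } else {
    unique(as.character(reference))
  }
}

#' Fraction of records to review manually
#'
#' Preselected stays over the population under surveillance, with a Wilson
#' 95% confidence interval by default. This is the workload the
#' semi-automated design trades against sensitivity.
#'
#' @param n_preselected Number of preselected stays.
#' @param n_population Number of stays under surveillance.
#' @inheritParams sensitivity
#' @param ci_method `"wilson"` (default) or `"clopper-pearson"`.
#' @return List: `estimate`, `lower`, `upper`, `n_preselected`,
#'   `n_population`.
#' @export
workload_fraction <- function(n_preselected, n_population,
                              conf_level = 0.95, ci_method = "wilson") {
  if (n_population <= 0) {
    abort_validation("workload undefined: zero population")
  }
  if (n_preselected > n_population || n_preselected < 0) {
    abort_validation("n_preselected must be between 0 and n_population")
  }
  ci <- proportion_ci(n_preselected, n_population, ci_method, conf_level)
  list(
    estimate = n_preselected / n_population,
    lower = unname(ci["lower"]), upper = unname(ci["upper"]),
    n_preselected = n_preselected, n_population = n_population
  )
}

#' Number needed to screen
#'
#' Preselected stays reviewed per nvHAP case detected. Undefined (`NA`)
#' when no case was detected.
#'
#' @param n_preselected Number of preselected stays.
#' @param n_detected Number of reference cases among them.
#' @return A real number `>= 1`, or `NA_real_` when `n_detected` is zero.
#' @export
nns <- function(n_preselected, n_detected) {
  if (n_detected < 0 || n_preselected < 0) {
    abort_validation("counts must be non-negative")
  }
  if (n_detected > n_preselected) {
    abort_validation("n_detected cannot exceed n_preselected")
  }
  if (n_detected == 0) return(NA_real_)
  n_preselected / n_detected
}

#' Sample size to demonstrate a target sensitivity
#'
#' Normal-approximation planning: `ceiling(z^2 p (1 - p) / margin^2)` cases,
#' `z` the two-sided normal quantile at `confidence`. Demonstrating 95%
#' sensitivity with a +/-5% margin at 95% confidence requires 73 nvHAP
#' cases. An exact-binomial mode searches for the smallest `n` whose
#' Clopper-Pearson interval at the expected count stays within the margin.
#'
#' @param expected_sensitivity Anticipated sensitivity, in (0, 1).
#' @param margin Acceptable half-width, in (0, 1).
#' @param confidence Confidence level.
#' @param method `"normal"` (default) or `"exact"`.
#' @return Integer number of reference cases.
#' @examples
#' sample_size_sensitivity(0.95, 0.05, 0.95)  # 73
#' @export
sample_size_sensitivity <- function(expected_sensitivity, margin,
                                    confidence = 0.95,
                                    method = c("normal", "exact")) {
  method <- match.arg(method)
  p <- expected_sensitivity
  if (!is.finite(p) || p <= 0 || p >= 1) {
    abort_validation("expected_sensitivity must be strictly inside (0, 1)")
  }
  if (!is.finite(margin) || margin <= 0 || margin >= 1) {
    abort_validation("margin must be strictly inside (0, 1)")
  }
  if (method == "normal") {
    z <- qnorm(1 - (1 - confidence) / 2)
    return(as.integer(ceiling(z^2 * p * (1 - p) / margin^2)))
  }
  for (n in 1:100000) {
    x <- round(n * p)
    ci <- ci_clopper_pearson(x, n, confidence)
    if (max(abs(ci - x / n)) <= margin) return(as.integer(n))
  }
  abort_validation("no feasible sample size below 100000")
}

#' Build an enriched validation cohort
#'
#' nvHAP is rare, so validation cohorts are enriched: all stays carrying a
#' discharge ICD code in the given family (prefix match on normalised codes,
#' dots stripped) plus a seeded uniform sample, without replacement, of up
#' to `n_random` further stays of at least `min_los_days` days.
#'
#' @param dataset A [surveillance_dataset()].
#' @param icd_prefix ICD-10 code family, e.g. `"U69.0"` for coded HAP.
#' @param n_random Size of the random long-stay complement.
#' @param min_los_days Minimum length of stay (days) for the complement.
#' @param seed Integer seed for the sample.
#' @return Character vector of stay ids (coded stays first, then sampled).
#' @export
build_validation_cohort <- function(dataset, icd_prefix = "U69.0",
                                    n_random = 200, min_los_days = 14,
                                    seed = 1L) {
  stopifnot(inherits(dataset, "surveillance_dataset"))
  norm <- function(x) gsub(".", "", toupper(x), fixed = TRUE)
  prefix <- norm(icd_prefix)
  coded <- vapply(
    dataset$stays$icd_codes,
    function(codes) any(startsWith(norm(codes), prefix)),
    logical(1)
  )
  coded_ids <- dataset$stays$stay_id[coded]
  los <- days_between(dataset$stays$discharge_ts, dataset$stays$admission_ts)
  eligible <- dataset$stays$stay_id[!coded & los >= min_los_days]
  k <- min(n_random, length(eligible))
  sampled <- if (k > 0) {
    with_seed(seed, sort(sample(eligible, k)))
  } else {
    character(0)
  }
  c(coded_ids, sampled)
}

#' Assemble the aggregate performance report
#'
#' Runs [preselect()] with the given configuration, compares against the
#' reference labels and assembles the aggregate report: sensitivity with
#' exact CI, workload fraction with Wilson CI, number needed to screen, the
#' cohort counts and the configuration fingerprint. The report carries only
#' aggregate values — no stay or patient identifiers ever leave the
#' hospital.
#'
#' @param dataset A [surveillance_dataset()].
#' @param config An [algorithm_config()].
#' @param reference_labels A [reference_surveillance()] tibble (restricted
#'   to the stays under evaluation, e.g. a validation cohort).
#' @param population Optional character vector of stay ids restricting the
#'   population under surveillance (default: all stays).
#' @return Object of class `performance_report`.
#' @export
evaluate_performance <- function(dataset, config, reference_labels,
                                 population = NULL) {
  pres <- preselect(dataset, config)
  stays <- pres$stays
  if (!is.null(population)) {
    stays <- stays[stays$stay_id %in% population, ]
    reference_labels <-
      reference_labels[reference_labels$stay_id %in% population, ]
  }
  pres_ids <- stays$stay_id[stays$preselected]
  ref_ids <- reference_case_ids(reference_labels)
  n_detected <- sum(ref_ids %in% pres_ids)
  sens <- sensitivity(
    pres_ids, ref_ids, ci_method = config$sensitivity_ci
  )
  work <- workload_fraction(
    length(pres_ids), nrow(stays), ci_method = config$workload_ci
  )
  structure(
    list(
      n_population = nrow(stays),
      n_preselected = length(pres_ids),
      n_reference_cases = length(ref_ids),
      n_detected_cases = n_detected,
      sensitivity = sens$estimate,
      sensitivity_lower = sens$lower,
      sensitivity_upper = sens$upper,
      workload_fraction = work$estimate,
      workload_lower = work$lower,
      workload_upper = work$upper,
      nns = nns(length(pres_ids), n_detected),
      enabled_indicators = config$enabled_indicators,
      config_fingerprint = config_fingerprint(config)
    ),
    class = "performance_report"
  )
}

#' @export
print.performance_report <- function(x, ...) {
  pct <- function(p, lo, hi) {
    sprintf("%.1f%% (95%% CI: %.1f-%.1f)", 100 * p, 100 * lo, 100 * hi)
  }
  cat("<performance_report>\n")
  cat(sprintf(
    "  population %d, preselected %d, reference nvHAP cases %d, detected %d\n",
    x$n_population, x$n_preselected, x$n_reference_cases, x$n_detected_cases
  ))
  cat("  sensitivity:", pct(x$sensitivity, x$sensitivity_lower, x$sensitivity_upper), "\n")
  cat("  records to review:", pct(x$workload_fraction, x$workload_lower, x$workload_upper), "\n")
  cat(sprintf(
    "  number needed to screen: %s\n",
    if (is.na(x$nns)) "undefined (no case detected)" else sprintf("%.1f", x$nns)
  ))
  cat("  algorithm:", paste(x$enabled_indicators, collapse = ", "), "\n")
  invisible(x)
}

#' Serialise a performance report to JSON
#'
#' Flat aggregate schema; contains no identifiers by construction.
#'
#' @param report A [evaluate_performance()] result.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_performance_report <- function(report, path) {
  stopifnot(inherits(report, "performance_report"))
  jsonlite::write_json(
    unclass(report), path, auto_unbox = TRUE, digits = NA, null = "null",
    na = "null", pretty = TRUE
  )
  invisible(path)
}
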