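#' Configuration of the adaptable preselection algorithm
#'
#' The algorithm is adaptable: hospitals enable between one and five
#' indicator streams depending on what their EHR can export. The chest
#' radiology procedure is the minimum indicator and is always enabled.
#' Numeric windows and thresholds are configuration, with defaults following
#' the ECDC hospital-acquired pneumonia definition (fever > 38.0 degrees C,
#' leukocytes < 4.0 or >= 12.0 x10^9/L) and a symmetric 48 h window around
#' the radiology timestamp for the lab/temperature temporal relationship.
#'
#' @param enabled_indicators Subset of [INDICATOR_STREAMS];
#'   `RADIOLOGY_PROCEDURE` is always included.
#' @param min_hours_after_admission Radiology counts only if performed
#'   strictly more than this many hours after admission (default 48), unless
#'   the stay is a qualifying readmission.
#' @param readmission_gap_days Maximum discharge-to-readmission gap (days,
#'   inclusive) for the "anytime after readmission" rule.
#' @param lab_window_hours,temp_window_hours Half-width (hours, inclusive)
#'   of the window around the radiology timestamp in which a leukocyte /
#'   temperature signal must fall.
#' @param leukopenia_threshold,leukocytosis_threshold Leukocyte bounds in
#'   x10^9/L: a value `< leukopenia_threshold` or `>= leukocytosis_threshold`
#'   is a signal.
#' @param fever_threshold Body temperature must be strictly above this value
#'   (degrees Celsius) to count as fever.
#' @param vap_exclusion_hours Patients continuously intubated throughout
#'   this many hours up to the radiology timestamp are VAP candidates and
#'   filtered from nvHAP preselection.
#' @param termset [termset()] used by the report rule.
#' @param sensitivity_ci,workload_ci Confidence-interval procedure used by
#'   [evaluate_performance()]: `"clopper-pearson"` or `"wilson"`.
#' @return Object of class `nvhap_config`.
#' @export
algorithm_config <- function(enabled_indicators = INDICATOR_STREAMS,
                             min_hours_after_admission = 48,
                             readmission_gap_days = 10,
                             lab_window_hours = 48,
                             temp_window_hours = 48,
                             leukopenia_threshold = 4.0,
                             leukocytosis_threshold = 12.0,
                             fever_threshold = 38.0,
                             vap_exclusion_hours = 48,
                             termset = default_termset("de"),
                             sensitivity_ci = c("clopper-pearson", "wilson"),
                             workload_ci = c("wilson", "clopper-pearson")) {
  enabled_indicators <- unique(as.character(enabled_indicators))
  bad <- setdiff(enabled_indicators, INDICATOR_STREAMS)
  if (length(bad) > 0) {
    abort_validation(sprintf(
      "unknown indicator(s): %s", paste(bad, collapse = ", ")
    ))
  }
  enabled_indicators <- intersect(
    INDICATOR_STREAMS, union("RADIOLOGY_PROCEDURE", enabled_indicators)
  )
  num_pos <- c(
    min_hours_after_admission = min_hours_after_admission,
    readmission_gap_days = readmission_gap_days,
    lab_window_hours = lab_window_hours,
    temp_window_hours = temp_window_hours,
    leukopenia_threshold = leukopenia_threshold,
    leukocytosis_threshold = leukocytosis_threshold,
    fever_threshold = fever_threshold,
    vap_exclusion_hours = vap_exclusion_hours
  )
  if (any(!is.finite(num_pos)) || any(num_pos <= 0)) {
    abort_validation("all window and threshold parameters must be positive")
  }
  if (leukopenia_threshold >= leukocytosis_threshold) {
    abort_validation(
      "leukopenia_threshold must be below leukocytosis_threshold"
    )
  }
  stopifnot(inherits(termset, "nvhap_termset"))
  structure(
    list(
      enabled_indicators = enabled_indicators,
      min_hours_after_admission = min_hours_after_admission,
      readmission_gap_days = readmission_gap_days,
      lab_window_hours = lab_window_hours,
      temp_window_hours = temp_window_hours,
      leukopenia_threshold = leukopenia_threshold,
      leukocytosis_threshold = leukocytosis_threshold,
      fever_threshold = fever_threshold,
      vap_exclusion_hours = vap_exclusion_hours,
      termset = termset,
      sensitivity_ci = match.arg(sensitivity_ci),
      workload_ci = match.arg(workload_ci)
    ),
    class = "nvhap_config"
  )
}

#' @export
print.nvhap_config <- function(x, ...) {
  cat("<nvhap_config>\n")
  cat("  indicators:", paste(x$enabled_indicators, collapse = ", "), "\n")
  cat(sprintf(
    "  radiology > %g h after admission (readmission gap <= %g d)\n",
    x$min_hours_after_admission, x$readmission_gap_days
  ))
  cat(sprintf(
    "  leukocytes < %g or >= %g x10^9/L within +/- %g h\n",
    x$leukopenia_threshold, x$leukocytosis_threshold, x$lab_window_hours
  ))
  cat(sprintf(
    "  temperature > %g C within +/- %g h; VAP filter window %g h\n",
    x$fever_threshold, x$temp_window_hours, x$vap_exclusion_hours
  ))
  cat("  termset:", x$termset$language_tag, "\n")
  invisible(x)
}

#' Stable fingerprint of a configuration
#'
#' MD5 digest of the canonicalised configuration, reported in performance
#' reports and run manifests so results can be traced to the exact algorithm
#' that produced them.
#'
#' @param config An [algorithm_config()].
#' @return Character scalar (32 hex digits).
#' @export
config_fingerprint <- function(config) {
  stopifnot(inherits(config, "nvhap_config"))
  plain <- config
  plain$termset <- unclass(plain$termset)
  fingerprint(unclass(plain))
}

#' Read an algorithm configuration from a YAML file
#'
#' The file may carry any subset of the [algorithm_config()] arguments;
#' unspecified values keep their defaults. A `termset` block is passed to
#' [load_termset()]; a `termset: "de"` / `"fr"` string selects a bundled set.
#'
#' @param path YAML file.
#' @return An [algorithm_config()].
#' @export
read_algorithm_config <- function(path) {
  if (!file.exists(path)) abort_io(sprintf("config file not found: %s", path))
  raw <- yaml::read_yaml(path) %||% list()
  args <- raw[intersect(names(raw), names(formals(algorithm_config)))]
  if (!is.null(raw$termset)) {
    args$termset <- if (is.character(raw$termset) && length(raw$termset) == 1 &&
                        raw$termset %in% c("de", "fr")) {
      default_termset(raw$termset)
    } else {
      load_termset(raw$termset)
    }
  }
  do.call(algorithm_config, args)
}
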