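#' Term set for the radiology-report exclusion rule
#'
#' A report sentence explicitly rules out pneumonia when it contains at least
#' one negation term and one infiltrate term and no restricting term. The
#' three lists are configuration, not code: inflected forms are handled by
#' enumerating them, and hospitals in other language regions supply their own
#' lists (see [default_termset()]).
#'
#' Terms are normalised to lowercase with diacritics folded; matching in
#' [classify_report()] is whole-word on the same normalisation.
#'
#' @param negation_terms Character vector, e.g. the language's "no".
#' @param infiltrate_terms Character vector, e.g. "infiltrate" and inflections.
#' @param restricting_terms Character vector of terms that void an otherwise
#'   exclusion-triggering sentence, e.g. "but", "left".
#' @param language_tag Short label for the language the lists cover.
#' @return An object of class `nvhap_termset`.
#' @examples
#' ts <- termset(
#'   negation_terms = "no",
#'   infiltrate_terms = c("infiltrate", "infiltrates"),
#'   restricting_terms = c("but", "left")
#' )
#' classify_report("No infiltrate.", ts)
#' @export
termset <- function(negation_terms, infiltrate_terms, restricting_terms,
                    language_tag = "custom") {
  norm <- function(x, what) {
    x <- unique(fold_text(trimws(as.character(x))))
    x <- x[nzchar(x)]
    if (length(x) == 0) {
      abort_validation(sprintf("termset: '%s' list must be non-empty", what))
    }
    x
  }
  neg <- norm(negation_terms, "negation_terms")
  inf <- norm(infiltrate_terms, "infiltrate_terms")
  res <- norm(restricting_terms, "restricting_terms")
  dup <- c(intersect(neg, inf), intersect(neg, res), intersect(inf, res))
  if (length(dup) > 0) {
    abort_validation(sprintf(
      "termset: term(s) present in more than one list: %s",
      paste(unique(dup), collapse = ", ")
    ))
  }
  structure(
    list(
      language_tag = as.character(language_tag)[1],
      negation_terms = neg,
      infiltrate_terms = inf,
      restricting_terms = res
    ),
    class = "nvhap_termset"
  )
}

#' @export
print.nvhap_termset <- function(x, ...) {
  cat("<nvhap_termset> language:", x$language_tag, "\n")
  cat("  negation:   ", paste(x$negation_terms, collapse = ", "), "\n")
  cat("  infiltrate: ", paste(x$infiltrate_terms, collapse = ", "), "\n")
  cat("  restricting:", paste(x$restricting_terms, collapse = ", "), "\n")
  invisible(x)
}

#' Load a term set from a file or configuration block
#'
#' @param source Path to a YAML file, or a named list, providing
#'   `negation_terms`, `infiltrate_terms`, `restricting_terms` and optionally
#'   `language_tag`.
#' @param language_tag Overrides the tag found in `source`.
#' @return An `nvhap_termset`.
#' @export
load_termset <- function(source, language_tag = NULL) {
  if (is.character(source) && length(source) == 1) {
    if (!file.exists(source)) {
      abort_io(sprintf("termset file not found: %s", source))
    }
    source <- yaml::read_yaml(source)
  }
  if (!is.list(source)) {
    abort_validation("termset source must be a file path or a named list")
  }
  need <- c("negation_terms", "infiltrate_terms", "restricting_terms")
  missing <- setdiff(need, names(source))
  if (length(missing) > 0) {
    abort_validation(sprintf(
      "termset source missing list(s): %s", paste(missing, collapse = ", ")
    ))
  }
  termset(
    negation_terms = source$negation_terms,
    infiltrate_terms = source$infiltrate_terms,
    restricting_terms = source$restricting_terms,
    language_tag = language_tag %||% source$language_tag %||% "custom"
  )
}

#' Bundled default term sets
#'
#' Ships reconstructed German-style (`"de"`) and French-style (`"fr"`) lists.
#' They cover common radiology phrasing but are explicitly placeholders:
#' any production deployment should review and extend them against local
#' report language before relying on the exclusion rule.
#'
#' @param language `"de"` or `"fr"`.
#' @return An `nvhap_termset`.
#' @export
default_termset <- function(language = c("de", "fr")) {
  language <- match.arg(language)
  path <- system.file(
    "extdata", "termsets", paste0(language, ".yaml"),
    package = "nvhap"
  )
  if (!nzchar(path)) {
    abort_io(sprintf("bundled termset '%s' not found", language))
  }
  load_termset(path)
}
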