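# Normalisation used everywhere text is compared: lowercase + diacritics
# folded to ASCII. No stemming — inflections are enumerated in the TermSet.
fold_text <- function(x) {
  stringi::stri_trans_tolower(stringi::stri_trans_general(x, "Latin-ASCII"))
}

tokenize_words <- function(x) {
  stringi::stri_extract_all_regex(x, "[\\p{L}\\p{N}']+", omit_no_match = TRUE)
}

#' Split a radiology report into sentences
#'
#' Boundaries are `.`, `!`, `?`, `;` and newline. Abbreviations are not
#' special-cased: reports are short, and a spurious split can only make the
#' exclusion rule more conservative (a case stays in the manual-review list),
#' which is the safe direction for surveillance.
#'
#' @param report_text A single report (character scalar; `NA` allowed).
#' @return Character vector of sentences, delimiters retained; empty input
#'   yields `character(0)`.
#' @examples
#' segment_sentences("No infiltrate. Heart normal.")
#' @export
segment_sentences <- function(report_text) {
  if (length(report_text) == 0 || is.na(report_text) || !nzchar(trimws(report_text))) {
    return(character(0))
  }
  pieces <- stringi::stri_split_regex(report_text, "(?<=[.!?;\\n])")[[1]]
  pieces <- trimws(pieces)
  # keep only pieces that still contain word content
  pieces[stringi::stri_detect_regex(pieces, "[\\p{L}\\p{N}]")]
}

#' Classify a radiology report with the pneumonia-exclusion text rule
#'
#' A report explicitly rules out pneumonia when at least one sentence
#' contains a negation term and an infiltrate term with no restricting term
#' in the same sentence. Matching is whole-word, case-insensitive and
#' diacritics-folded. Any ambiguity (empty report, terms split across
#' sentences, restricting term present) yields `NOT_EXCLUDING`: a false
#' "excluded" loses a case, a false "not excluded" only costs review time.
#'
#' @param report_text A single report text.
#' @param terms An [termset()] object.
#' @return A `report_verdict`: list with `verdict`
#'   (`"EXCLUDES_PNEUMONIA"` or `"NOT_EXCLUDING"`), `matched_sentence`
#'   (`NULL` unless excluding) and `matched_terms`.
#' @examples
#' ts <- termset("no", c("infiltrate", "infiltrates"), c("but", "left"))
#' classify_report("No infiltrate.", ts)$verdict
#' classify_report("No infiltrate, but retrocardiac opacity.", ts)$verdict
#' @export
classify_report <- function(report_text, terms) {
  stopifnot(inherits(terms, "nvhap_termset"))
  sentences <- segment_sentences(report_text)
  for (s in sentences) {
    toks <- tokenize_words(fold_text(s))[[1]]
    neg_hit <- intersect(terms$negation_terms, toks)
    if (length(neg_hit) == 0) next
    inf_hit <- intersect(terms$infiltrate_terms, toks)
    if (length(inf_hit) == 0) next
    if (length(intersect(terms$restricting_terms, toks)) > 0) next
    return(structure(
      list(
        verdict = "EXCLUDES_PNEUMONIA",
        matched_sentence = s,
        matched_terms = c(neg_hit, inf_hit)
      ),
      class = "report_verdict"
    ))
  }
  structure(
    list(
      verdict = "NOT_EXCLUDING",
      matched_sentence = NULL,
      matched_terms = character(0)
    ),
    class = "report_verdict"
  )
}

#' @export
print.report_verdict <- function(x, ...) {
  cat("<report_verdict>", x$verdict, "\n")
  if (!is.null(x$matched_sentence)) {
    cat("  sentence:", x$matched_sentence, "\n")
    cat("  terms:   ", paste(x$matched_terms, collapse = ", "), "\n")
  }
  invisible(x)
}

# Vectorised helper for the pipeline: TRUE where the report excludes
# pneumonia.
reports_exclude <- function(texts, terms) {
  vapply(
    texts,
    function(t) classify_report(t, terms)$verdict == "EXCLUDES_PNEUMONIA",
    logical(1),
    USE.NAMES = FALSE
  )
}
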