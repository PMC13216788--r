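`%||%` <- function(a, b) if (is.null(a)) b else a

abort_validation <- function(msg) {
  stop(structure(
    class = c("nvhap_validation_error", "nvhap_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

abort_io <- function(msg) {
  stop(structure(
    class = c("nvhap_io_error", "nvhap_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

# All timestamps live in one implicit timezone (intra-hospital surveillance);
# UTC is used as the internal representation.
TZ <- "UTC"

#' Parse timestamps at minute resolution
#'
#' Accepts ISO-8601 style timestamps (`"2023-01-05 14:30"`,
#' `"2023-01-05T14:30"`, with or without seconds) and bare dates
#' (midnight assumed). Unparseable entries become `NA`.
#'
#' @param x Character vector.
#' @return `POSIXct` vector (UTC, one implicit hospital timezone).
#' @export
parse_ts <- function(x) {
  x <- trimws(as.character(x))
  x[x == ""] <- NA_character_
  out <- as.POSIXct(rep(NA_real_, length(x)), origin = "1970-01-01", tz = TZ)
  fmts <- c(
    "%Y-%m-%d %H:%M:%S", "%Y-%m-%dT%H:%M:%S",
    "%Y-%m-%d %H:%M", "%Y-%m-%dT%H:%M", "%Y-%m-%d"
  )
  todo <- !is.na(x)
  for (f in fmts) {
    if (!any(todo)) break
    parsed <- as.POSIXct(x[todo], format = f, tz = TZ)
    ok <- !is.na(parsed)
    idx <- which(todo)[ok]
    out[idx] <- parsed[ok]
    todo[idx] <- FALSE
  }
  trunc_minute(out)
}

#' @rdname parse_ts
#' @param ts `POSIXct` vector.
#' @export
format_ts <- function(ts) {
  ifelse(is.na(ts), "", format(ts, "%Y-%m-%d %H:%M", tz = TZ))
}

trunc_minute <- function(ts) {
  as.POSIXct(floor(as.numeric(ts) / 60) * 60, origin = "1970-01-01", tz = TZ)
}

hours_between <- function(later, earlier) {
  as.numeric(difftime(later, earlier, units = "hours"))
}

days_between <- function(later, earlier) {
  as.numeric(difftime(later, earlier, units = "days"))
}

# Evaluate `code` under a temporary RNG state so callers' streams are
# untouched (generator and cohort sampling are seeded explicitly).
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# One deterministic sub-seed per named stream so that adding a table to the
# generator never perturbs the draws of the others. Kept below 2^31 - 1.
derive_seed <- function(seed, stream) {
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((as.double(seed) %% 2147483647 * 48271 + h * 7919) %% 2147483629)
}

# MD5 fingerprint of any plain R object via its canonical YAML rendering.
fingerprint <- function(x) {
  canon <- function(v) {
    if (is.list(v)) {
      v <- lapply(v, canon)
      if (!is.null(names(v))) v <- v[order(names(v))]
    }
    v
  }
  txt <- yaml::as.yaml(canon(x))
  tf <- tempfile(fileext = ".yaml")
  on.exit(unlink(tf))
  writeLines(txt, tf)
  unname(tools::md5sum(tf))
}

pipe_collapse <- function(x) {
  vapply(x, function(v) paste(v, collapse = "|"), character(1))
}

pipe_split <- function(x) {
  x <- as.character(x)
  x[is.na(x)] <- ""
  strsplit(x, "|", fixed = TRUE)
}
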