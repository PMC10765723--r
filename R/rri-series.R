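#' Build an RR-interval series
#'
#' An `rri_series` is a tibble with one row per heartbeat, carrying the
#' RR interval in milliseconds, the cumulative occurrence time in seconds
#' (`time_s[i]` is the sum of the first `i` intervals), a retention flag
#' used by the artifact filters, and a `removed_by` label recording which
#' filter (if any) discarded the beat.
#'
#' @param rr_ms Numeric vector of RR intervals in milliseconds. All values
#'   must be finite and strictly positive.
#'
#' @return A tibble of class `rri_series` with columns `beat`, `time_s`,
#'   `rr_ms`, `retained`, `removed_by`.
#' @export
#' @examples
#' rri_series(c(600, 610, 605))
rri_series <- function(rr_ms) {
  rr_ms <- as.numeric(rr_ms)
  if (length(rr_ms) == 0) {
    stop("RR-interval series is empty: no data to analyse", call. = FALSE)
  }
  if (any(!is.finite(rr_ms)) || any(rr_ms <= 0)) {
    stop("RR intervals must be finite and strictly positive (ms)", call. = FALSE)
  }
  out <- tibble::tibble(
    beat = seq_along(rr_ms),
    time_s = cumsum(rr_ms) / 1000,
    rr_ms = rr_ms,
    retained = TRUE,
    removed_by = NA_character_
  )
  class(out) <- c("rri_series", class(out))
  out
}

new_rri_series <- function(df) {
  class(df) <- unique(c("rri_series", class(df)))
  df
}

#' Retained beats of a series
#'
#' Returns the gap-closed subsequence of retained beats. Downstream scaling
#' analysis operates on this beat-index sequence, while each beat keeps its
#' original cumulative time.
#'
#' @param series An [rri_series()].
#' @return A tibble with the retained rows only.
#' @export
retained_beats <- function(series) {
  dplyr::filter(series, .data$retained)
}

#' @export
print.rri_series <- function(x, ...) {
  n <- nrow(x)
  kept <- sum(x$retained)
  cat(sprintf(
    "<rri_series> %d beats (%d retained, %.1f%% filtered), %.1f s\n",
    n, kept, 100 * (n - kept) / n, max(x$time_s)
  ))
  NextMethod()
}

#' Read an RR-interval series from disk
#'
#' Two plain-text dialects are supported: `"txt-ms"` (one interval in ms per
#' line) and `"csv-time-rr"` (a CSV with columns `time_s`, `rr_ms`; only
#' `rr_ms` is used and cumulative times are recomputed).
#'
#' @param path Path to the file.
#' @param dialect `"txt-ms"` or `"csv-time-rr"`.
#' @return An [rri_series()].
#' @export
read_rri <- function(path, dialect = c("txt-ms", "csv-time-rr")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (dialect == "txt-ms") {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    vals <- suppressWarnings(as.numeric(lines))
    if (anyNA(vals)) {
      bad <- which(is.na(vals))[1]
      stop(sprintf("cannot parse RR interval on line %d: '%s'", bad, lines[bad]),
        call. = FALSE
      )
    }
    rri_series(vals)
  } else {
    df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
    if (!"rr_ms" %in% names(df)) {
      stop("CSV dialect requires an 'rr_ms' column", call. = FALSE)
    }
    rri_series(df$rr_ms)
  }
}

#' Write the retained beats of a series as CSV
#'
#' @param series An [rri_series()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_rri_csv <- function(series, path) {
  out <- dplyr::select(retained_beats(series), "time_s", "rr_ms")
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}
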