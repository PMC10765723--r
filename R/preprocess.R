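#' Range filter for RR intervals
#'
#' Flags beats whose interval falls outside the physiological range
#' (default 200--2000 ms, i.e. 30--300 BPM) as not retained. Already-removed
#' beats are left untouched; flags only ever flip from retained to removed.
#'
#' @param series An [rri_series()].
#' @param lo,hi Inclusive physiological bounds in ms.
#' @return The series with out-of-range beats flagged `removed_by = "range"`.
#' @export
filter_rri_range <- function(series, lo = 200, hi = 2000) {
  stopifnot(nrow(series) > 0, lo > 0, hi > lo)
  hit <- series$retained & (series$rr_ms < lo | series$rr_ms > hi)
  series$retained[hit] <- FALSE
  series$removed_by[hit] <- "range"
  new_rri_series(series)
}

#' Windowed-median deviation filter
#'
#' Flags beats deviating by more than `frac` (default 10%) from the median
#' of a `kernel`-beat window (default 7) centred on the beat. Only retained
#' beats participate in the windows, in a single pass over the series: the
#' medians are computed from the retained set as it stands on entry, so a
#' removed spike cannot corrupt its neighbours' windows but beats removed by
#' this same pass still contribute to other beats' medians. Near the ends of
#' the series the window shrinks symmetrically (minimum 3 beats).
#'
#' @param series An [rri_series()].
#' @param kernel Odd window size in beats, >= 3.
#' @param frac Maximum allowed relative deviation from the window median.
#' @return The series with deviant beats flagged `removed_by = "median"`.
#' @export
filter_rri_median <- function(series, kernel = 7, frac = 0.10) {
  stopifnot(kernel >= 3, kernel %% 2 == 1, frac > 0)
  idx <- which(series$retained)
  n <- length(idx)
  if (n < kernel) {
    stop(sprintf(
      "median filter kernel (%d) exceeds retained beat count (%d)", kernel, n
    ), call. = FALSE)
  }
  x <- series$rr_ms[idx]
  half <- (kernel - 1L) %/% 2L
  med <- vapply(seq_len(n), function(i) {
    # shrink symmetrically at the edges, never below a 3-beat window
    h <- max(1L, min(half, i - 1L, n - i))
    w <- (i - h):(i + h)
    w <- w[w >= 1L & w <= n]
    if (length(w) < 3L) w <- if (i <= 2L) 1:3 else (n - 2L):n
    stats::median(x[w])
  }, numeric(1))
  dev <- abs(x - med) / med
  hit <- idx[dev > frac]
  series$retained[hit] <- FALSE
  series$removed_by[hit] <- "median"
  new_rri_series(series)
}

#' Clean an RR-interval series
#'
#' Applies, in order: the physiological range filter, the windowed-median
#' deviation filter, and an optional list of manually excluded beat indices
#' (standing in for removals by visual inspection). The filter report is
#' attached as an attribute and available through [filter_report()] or
#' `glance()`.
#'
#' @param series An [rri_series()].
#' @param lo,hi Range-filter bounds (ms).
#' @param kernel,frac Median-filter window (beats) and relative tolerance.
#' @param exclude Integer beat indices (into the raw series) to remove
#'   manually after the automatic filters.
#' @return The filtered `rri_series` with a `filter_report` attribute.
#' @export
#' @examples
#' s <- rri_series(c(rep(700, 10), 2500, rep(700, 10)))
#' s <- preprocess_rri(s)
#' filter_report(s)
preprocess_rri <- function(series, lo = 200, hi = 2000, kernel = 7,
                           frac = 0.10, exclude = integer()) {
  n_raw <- nrow(series)
  series <- filter_rri_range(series, lo = lo, hi = hi)
  series <- filter_rri_median(series, kernel = kernel, frac = frac)
  if (length(exclude)) {
    exclude <- intersect(as.integer(exclude), which(series$retained))
    series$retained[exclude] <- FALSE
    series$removed_by[exclude] <- "manual"
  }
  n_kept <- sum(series$retained)
  report <- tibble::tibble(
    n_raw = n_raw,
    n_retained = n_kept,
    n_removed_range = sum(series$removed_by == "range", na.rm = TRUE),
    n_removed_median = sum(series$removed_by == "median", na.rm = TRUE),
    n_removed_manual = sum(series$removed_by == "manual", na.rm = TRUE),
    removed_fraction = (n_raw - n_kept) / n_raw
  )
  attr(series, "filter_report") <- report
  new_rri_series(series)
}

#' Filter report of a preprocessed series
#'
#' @param series An `rri_series` returned by [preprocess_rri()].
#' @return A one-row tibble with per-filter removal counts and the removed
#'   fraction.
#' @export
filter_report <- function(series) {
  rep <- attr(series, "filter_report")
  if (is.null(rep)) {
    stop("series has no filter report; run preprocess_rri() first", call. = FALSE)
  }
  rep
}

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname filter_report
#' @param x An `rri_series`.
#' @param ... Unused.
#' @method glance rri_series
#' @export
glance.rri_series <- function(x, ...) filter_report(x)
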