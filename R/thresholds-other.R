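# Comparison estimators: fixed HRmax percentages, the regression on the
# short-term DFA exponent's decline, and the two-slope blood-lactate method.

#' Thresholds as fixed percentages of maximal heart rate
#'
#' @param hr_max Measured maximal HR in BPM, inside (30, 300).
#' @param p1,p2 Fractions of `hr_max` for the first and second threshold
#'   (defaults 0.70 and 0.85, the values commonly built into wearables).
#' @return A `threshold_result` (`method = "hrmax"`), thresholds rounded to
#'   integer BPM.
#' @export
#' @examples
#' hrmax_thresholds(200)
hrmax_thresholds <- function(hr_max, p1 = 0.70, p2 = 0.85) {
  if (!is.finite(hr_max) || hr_max <= 30 || hr_max >= 300) {
    stop("hr_max must lie in (30, 300) BPM", call. = FALSE)
  }
  if (p1 > p2) stop("p1 must not exceed p2 (threshold ordering)", call. = FALSE)
  new_threshold_result(
    "hrmax", p1 * hr_max, p2 * hr_max,
    diagnostics = list(hr_max = hr_max, p1 = p1, p2 = p2)
  )
}

#' Thresholds from the decline of the short-term DFA exponent
#'
#' Locates the near-linear decline of alpha1 with HR and reads the
#' thresholds where the regression line crosses 0.75 and 0.5:
#' points are sorted by HR; those inside the band are selected; disjoint
#' selections separated by at most `gap_n` out-of-band points are connected;
#' the largest region is kept and greedily expanded one point at a time from
#' either end while the regression's coefficient of determination improves.
#'
#' @param track A `dfa_alpha1_track` from [alpha1_track()].
#' @param band Alpha1 interval of the decline (default `c(0.5, 0.75)`).
#' @param gap_n Maximum number of intervening out-of-band points bridged
#'   when connecting regions (default 4).
#' @param levels Alpha1 levels defining T1 and T2 (default 0.75 and 0.5).
#' @return A `threshold_result` (`method = "alpha1"`). Thresholds are
#'   undefined when no usable band points exist or the fitted slope is not
#'   negative; diagnostics carry the region extent, fit coefficients and
#'   R squared.
#' @export
dfa_alpha1_thresholds <- function(track, band = c(0.5, 0.75), gap_n = 4,
                                  levels = c(0.75, 0.5)) {
  pts <- track |>
    dplyr::filter(is.finite(.data$alpha1), is.finite(.data$seg_hr)) |>
    dplyr::arrange(.data$seg_hr)
  in_band <- pts$alpha1 >= band[1] & pts$alpha1 <= band[2]
  if (sum(in_band) < 3) {
    return(new_threshold_result(
      "alpha1", NA, NA,
      diagnostics = list(reason = "fewer than 3 points inside the alpha1 band")
    ))
  }
  sel <- in_band
  # bridge gaps of at most gap_n out-of-band points between band regions
  idx <- which(in_band)
  for (k in seq_len(length(idx) - 1)) {
    if (idx[k + 1] - idx[k] - 1 <= gap_n) sel[idx[k]:idx[k + 1]] <- TRUE
  }
  # largest connected region
  runs <- rle(sel)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  cand <- which(runs$values)
  best <- cand[which.max(runs$lengths[cand])]
  lo <- starts[best]
  hi <- ends[best]
  r2_of <- function(lo, hi) {
    stats::cor(pts$seg_hr[lo:hi], pts$alpha1[lo:hi])^2
  }
  r2 <- r2_of(lo, hi)
  # greedy single-point expansion from either end
  repeat {
    cand_r2 <- c(
      if (lo > 1) r2_of(lo - 1, hi) else -Inf,
      if (hi < nrow(pts)) r2_of(lo, hi + 1) else -Inf
    )
    if (max(cand_r2) <= r2) break
    if (which.max(cand_r2) == 1) lo <- lo - 1 else hi <- hi + 1
    r2 <- max(cand_r2)
  }
  fit <- stats::lm(alpha1 ~ seg_hr, data = pts[lo:hi, ])
  slope <- stats::coef(fit)[[2]]
  intercept <- stats::coef(fit)[[1]]
  diag <- list(
    hr_range = range(pts$seg_hr[lo:hi]), n_points = hi - lo + 1,
    slope = slope, intercept = intercept, r_squared = r2
  )
  if (!is.finite(slope) || slope >= 0) {
    diag$reason <- "alpha1 does not decline with HR over the fitted region"
    return(new_threshold_result("alpha1", NA, NA, diagnostics = diag))
  }
  new_threshold_result(
    "alpha1",
    (levels[1] - intercept) / slope,
    (levels[2] - intercept) / slope,
    diagnostics = diag
  )
}

#' Interpolated heart rate at a time point
#'
#' Linear interpolation of a (30-s-averaged) HR trace.
#'
#' @param t Time in seconds, inside the trace's span.
#' @param hr_trace A data frame with columns `time_s` and `hr_bpm`.
#' @return HR in BPM at `t`.
#' @export
hr_at_time <- function(t, hr_trace) {
  if (any(t < min(hr_trace$time_s) | t > max(hr_trace$time_s))) {
    stop("time outside the span of the HR trace", call. = FALSE)
  }
  stats::approx(hr_trace$time_s, hr_trace$hr_bpm, xout = t, ties = "ordered")$y
}

#' Lactate thresholds by the two-slope method
#'
#' The aerobic threshold (LT1) is where the lactate curve first rises 0.3
#' mmol/L above its minimum, interpolating linearly between measurements.
#' Two lines are then fitted: line A through the interpolated LT1 point and
#' the following measurement, and line B by least squares through the
#' points of every exercise step whose lactate increment exceeds
#' `step_rise` (default 0.8 mmol/L; each qualifying step contributes both
#' endpoints, shared points counted once). The anaerobic threshold (LT2) is
#' the crossing time of the two lines. Both times are converted to BPM
#' against the HR trace.
#'
#' @param curve A data frame with columns `step_t` (end time of each
#'   exercise step, s), `lactate` (mmol/L) and `hr` (30-s-averaged HR at
#'   step end, BPM); at least 4 measurements.
#' @param delta Rise above the minimum defining LT1 (default 0.3 mmol/L).
#' @param step_rise Step increment qualifying points for line B (default
#'   0.8 mmol/L).
#' @return A `threshold_result` (`method = "lactate"`); diagnostics carry
#'   the threshold times and fit coefficients. LT1 is undefined when the
#'   curve never rises `delta` above its minimum; LT2 when line B has fewer
#'   than 2 points or the lines are parallel.
#' @export
lactate_thresholds <- function(curve, delta = 0.3, step_rise = 0.8) {
  stopifnot(all(c("step_t", "lactate", "hr") %in% names(curve)))
  if (nrow(curve) < 4) {
    stop("need at least 4 lactate measurements", call. = FALSE)
  }
  if (any(diff(curve$step_t) <= 0)) {
    stop("step times must be strictly increasing", call. = FALSE)
  }
  tt <- curve$step_t
  la <- curve$lactate
  hr_trace <- data.frame(time_s = tt, hr_bpm = curve$hr)
  imin <- which.min(la)
  target <- la[imin] + delta
  diag <- list(lactate_min = la[imin], target = target)

  # first crossing of min + delta on the rising side
  j <- NULL
  for (k in seq(imin, length(la))) {
    if (la[k] >= target) {
      j <- k
      break
    }
  }
  if (is.null(j)) {
    diag$reason <- sprintf("lactate never rises %.2f above its minimum", delta)
    return(new_threshold_result("lactate", NA, NA, diagnostics = diag))
  }
  t_lt1 <- if (j == imin) {
    tt[j]
  } else {
    tt[j - 1] + (tt[j] - tt[j - 1]) * (target - la[j - 1]) / (la[j] - la[j - 1])
  }
  diag$lt1_time_s <- t_lt1

  t2 <- NA_real_
  if (j <= length(la)) {
    # line A: exact line through the LT1 point and the following measurement
    nxt <- if (tt[j] > t_lt1) j else j + 1
    if (nxt <= length(la)) {
      a_slope <- (la[nxt] - target) / (tt[nxt] - t_lt1)
      a_int <- target - a_slope * t_lt1
      # line B: least squares through the points of steps rising > step_rise
      qual <- which(diff(la) > step_rise)
      b_pts <- sort(unique(c(qual, qual + 1)))
      diag$line_a <- c(intercept = a_int, slope = a_slope)
      diag$n_points_b <- length(b_pts)
      if (length(b_pts) >= 2) {
        b_fit <- stats::lm(la[b_pts] ~ tt[b_pts])
        b_int <- stats::coef(b_fit)[[1]]
        b_slope <- stats::coef(b_fit)[[2]]
        diag$line_b <- c(intercept = b_int, slope = b_slope)
        if (isTRUE(abs(b_slope - a_slope) > .Machine$double.eps^0.5)) {
          t2 <- (a_int - b_int) / (b_slope - a_slope)
          diag$lt2_time_s <- t2
        } else {
          diag$reason <- "the two lactate fits are parallel"
        }
      } else {
        diag$reason <- "fewer than 2 points qualify for the second lactate fit"
      }
    }
  }
  clamp <- function(t) min(max(t, min(tt)), max(tt))
  t1_bpm <- hr_at_time(clamp(t_lt1), hr_trace)
  t2_bpm <- if (is.finite(t2)) hr_at_time(clamp(t2), hr_trace) else NA
  new_threshold_result("lactate", t1_bpm, t2_bpm, diagnostics = diag)
}
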