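# Time- and scale-resolved second-order DFA (dynamical DFA).
#
# All sliding quantities are computed by convolution against an orthonormal
# polynomial basis: for a fixed window length w, the OLS residual sum of
# squares in every window is sum(y^2) minus the squared projections onto the
# basis, and each projection is a moving dot product. Per-segment profile
# mean subtraction only adds constant + linear terms inside any window, which
# the polynomial detrending annihilates, so per-window residuals computed on
# the single global profile are identical to those computed segment by
# segment. Segment-level fluctuation functions then reduce to moving
# averages of the per-window mean squared residuals.

moving_sum <- function(v, k) {
  out <- stats::filter(v, rep(1, k), method = "convolution", sides = 1)
  as.numeric(out[k:length(v)])
}

moving_mean <- function(v, k) moving_sum(v, k) / k

the_rss_expectation_cache <- new.env(parent = emptyenv())

# Expected residual sum of squares, in a w-point window of the profile of
# unit-variance white-noise increments, of an order-`order` polynomial OLS
# fit: tr(L' (I - P) L) with L the cumulative-sum operator and P the
# polynomial hat matrix. Used to calibrate away the finite-size detrending
# loss so that uncorrelated increments scale exactly as s^(1/2).
rss_quadratic_form <- function(w, order = 2) {
  key <- paste("K", w, order)
  val <- the_rss_expectation_cache[[key]]
  if (is.null(val)) {
    L <- 1 * lower.tri(matrix(1, w, w), diag = TRUE)
    Q <- qr.Q(qr(outer(seq_len(w) - 1, 0:order, `^`)))
    A <- L - Q %*% crossprod(Q, L) # (I - P) L
    val <- crossprod(A) # K = L' (I - P) L, so RSS = e' K e
    the_rss_expectation_cache[[key]] <- val
  }
  val
}

white_noise_rss <- function(w, order = 2) {
  sum(diag(rss_quadratic_form(w, order)))
}

# Mean squared residual of an order-`order` polynomial OLS fit, for every
# window of `w` consecutive points of `profile` (window starts 1..n-w+1).
# With `calibrate` the residuals are normalised by the white-noise
# expectation (times w, so levels match the raw convention asymptotically).
poly_window_mse <- function(profile, w, order = 2, calibrate = TRUE) {
  n <- length(profile)
  if (w > n || w < order + 2) return(numeric(0))
  # residuals in any window are invariant to adding a global polynomial of
  # the detrending degree; subtracting the profile's own fit conditions the
  # sum-minus-projections cancellation below
  profile <- stats::.lm.fit(
    qr.Q(qr(outer(seq_len(n) / n, 0:order, `^`))), profile
  )$residuals
  x <- seq_len(w) - 1
  Q <- qr.Q(qr(outer(x, 0:order, `^`)))
  rss <- moving_sum(profile^2, w)
  for (k in seq_len(ncol(Q))) {
    proj <- stats::filter(profile, rev(Q[, k]), method = "convolution", sides = 1)
    rss <- rss - as.numeric(proj[w:n])^2
  }
  denom <- if (calibrate) white_noise_rss(w, order) / w else w
  pmax(rss, 0) / denom
}

#' Second-order DFA fluctuation function of one segment
#'
#' Builds the profile (cumulative sum of the mean-subtracted intervals) and
#' fits a second-order polynomial in every window of `scale` consecutive
#' profile points, at every possible offset (stride 1, maximally
#' overlapping). The fluctuation is the root mean, over windows, of the mean
#' squared fit residuals.
#'
#' @param segment Numeric vector of RR intervals (or any increments).
#' @param scale Window size in points (beats), >= 4.
#' @param order Polynomial detrending order (default 2).
#' @param calibrate Normalise window residuals by their exact white-noise
#'   expectation (default `TRUE`), removing the finite-size detrending loss
#'   so uncorrelated increments scale exactly as `scale^0.5`; `FALSE` gives
#'   the raw mean-squared-residual convention.
#' @return `F(scale) >= 0`, or `NA` when the segment is too short for a
#'   single window (time edges degrade gracefully rather than erroring).
#' @export
dfa2_fluctuation <- function(segment, scale, order = 2, calibrate = TRUE) {
  scale <- as.integer(scale)
  if (scale < order + 2) return(NA_real_)
  if (length(segment) < scale) return(NA_real_)
  profile <- cumsum(segment - mean(segment))
  mse <- poly_window_mse(profile, scale, order = order, calibrate = calibrate)
  if (!length(mse)) return(NA_real_)
  sqrt(mean(mse))
}

#' Finite-difference scaling exponent on the log-log grid
#'
#' The local scaling exponent at integer scale `s` is the first derivative
#' of log-fluctuation with respect to log-scale, approximated on the
#' non-uniform three-point stencil `s - 1, s, s + 1`:
#' `alpha = (h-^2 L+ + (h+^2 - h-^2) L0 - h+^2 L-) / (h- h+ (h+ + h-))`
#' with `h- = log s - log(s-1)`, `h+ = log(s+1) - log s`, and `L*` the
#' natural-log fluctuations. On a uniform grid this reduces to the central
#' difference; it is exact for any log-quadratic fluctuation function.
#'
#' @param logF_minus,logF_0,logF_plus Natural logs of the fluctuation
#'   function at scales `s - 1`, `s`, `s + 1` (vectors recycle).
#' @param s Integer scale(s), >= 2 so that all three stencil points exist.
#' @return The exponent; `NA` wherever any input is non-finite (e.g. a zero
#'   fluctuation whose log is undefined).
#' @export
local_alpha <- function(logF_minus, logF_0, logF_plus, s) {
  stopifnot(all(s >= 2))
  hm <- log(s) - log(s - 1)
  hp <- log(s + 1) - log(s)
  a <- (hm^2 * logF_plus + (hp^2 - hm^2) * logF_0 - hp^2 * logF_minus) /
    (hm * hp * (hp + hm))
  a[!is.finite(logF_minus) | !is.finite(logF_0) | !is.finite(logF_plus)] <- NA_real_
  a
}

#' Logarithmically spaced integer scale grid
#'
#' Rounds `n_scales` log-spaced reals on `[s_min, s_max]` to integers and
#' de-duplicates, which can yield slightly fewer distinct scales.
#'
#' @param n_scales Number of grid points before de-duplication (default 20).
#' @param s_min,s_max Scale range in beats (default 5--64, spanning the
#'   joint range of the short- and intermediate-term DFA exponents).
#' @return Sorted unique integer scales.
#' @export
ddfa_scales <- function(n_scales = 20, s_min = 5, s_max = 64) {
  stopifnot(s_min >= 5, s_max > s_min)
  unique(round(exp(seq(log(s_min), log(s_max), length.out = n_scales))))
}

#' Dynamical DFA field alpha(t, s)
#'
#' For every scale `s` on the grid, slides a segment of `seg_factor * s`
#' beats along the retained-beat sequence (hop in beats, default 1, i.e.
#' maximally overlapping), computes the second-order DFA fluctuation at
#' scales `s - 1`, `s`, `s + 1` inside each segment, and differentiates on
#' the log-log grid with [local_alpha()]. Each segment also carries its mean
#' heart rate, `60000 / mean(rr)`.
#'
#' @param series A preprocessed [rri_series()] (scaling analysis runs on the
#'   gap-closed retained-beat sequence; reported times are the retained
#'   beats' original cumulative times).
#' @param scales Integer scale grid, see [ddfa_scales()].
#' @param seg_factor Segment length as a multiple of the scale (default 5).
#' @param hop Segment hop in beats (default 1).
#' @param anchor `"centre"` (default) reports each segment at its central
#'   beat; `"trailing"` at its last beat.
#' @param hr_mean `"arithmetic"` (default) computes segment HR from the
#'   arithmetic mean RR; `"harmonic"` averages the per-beat instantaneous HR.
#' @param calibrate Passed to the fluctuation computation, see
#'   [dfa2_fluctuation()].
#' @return A tibble of class `ddfa_field` with columns `t_index` (position
#'   in the retained sequence), `time_s`, `scale`, `alpha`, `seg_hr`.
#'   Segments that do not fit are absent (masked), never zero-filled.
#' @export
ddfa <- function(series, scales = ddfa_scales(), seg_factor = 5, hop = 1,
                 anchor = c("centre", "trailing"),
                 hr_mean = c("arithmetic", "harmonic"), calibrate = TRUE) {
  anchor <- match.arg(anchor)
  hr_mean <- match.arg(hr_mean)
  beats <- retained_beats(series)
  x <- beats$rr_ms
  n <- length(x)
  if (n < seg_factor * min(scales)) {
    stop(sprintf(
      "insufficient data: %d retained beats < one segment of %d beats",
      n, seg_factor * min(scales)
    ), call. = FALSE)
  }
  profile <- cumsum(x)
  mse_cache <- new.env(parent = emptyenv())
  window_mse <- function(w) {
    key <- as.character(w)
    if (is.null(mse_cache[[key]])) {
      mse_cache[[key]] <- poly_window_mse(profile, w, calibrate = calibrate)
    }
    mse_cache[[key]]
  }

  per_scale <- purrr::map(scales, function(s) {
    l <- seg_factor * s
    if (n < l) return(NULL)
    starts <- seq.int(1L, n - l + 1L, by = hop)
    logF <- purrr::map(c(s - 1L, s, s + 1L), function(sp) {
      mse <- window_mse(sp)
      segF2 <- moving_mean(mse, l - sp + 1L) # indexed by segment start
      log(segF2[starts]) / 2
    })
    alpha <- local_alpha(logF[[1]], logF[[2]], logF[[3]], s)
    hr <- if (hr_mean == "arithmetic") {
      60000 / moving_mean(x, l)[starts]
    } else {
      moving_mean(60000 / x, l)[starts]
    }
    t_idx <- starts + if (anchor == "centre") l %/% 2L else l - 1L
    tibble::tibble(
      t_index = t_idx, time_s = beats$time_s[t_idx],
      scale = s, alpha = alpha, seg_hr = hr
    )
  })
  out <- dplyr::bind_rows(per_scale)
  attr(out, "scales") <- scales
  attr(out, "seg_factor") <- seg_factor
  class(out) <- c("ddfa_field", class(out))
  out
}

#' Windowed short-term DFA alpha1 track
#'
#' Evaluates the conventional short-term scaling exponent alpha1 on a
#' sliding time window (default 120 s, every 5 s): the window's intervals
#' are detrended with smoothness priors ([smoothness_priors_detrend()],
#' `lambda = 500`), the DFA fluctuation function is computed over scales
#' 4--16 beats with maximally overlapping windows, and alpha1 is the
#' least-squares slope of log F versus log s. Each evaluation carries the
#' window's mean HR.
#'
#' @param series A preprocessed [rri_series()] spanning at least one window.
#' @param window_s,step_s Window length and evaluation step in seconds.
#' @param lambda Smoothness-priors parameter (default 500).
#' @param scales Integer DFA scales for the regression (default 4:16).
#' @param order Polynomial detrending order inside DFA windows; default 2
#'   for consistency with the dynamical-DFA engine, set 1 for the classic
#'   first-order alpha1.
#' @param calibrate See [dfa2_fluctuation()].
#' @return A tibble of class `dfa_alpha1_track` with columns `time_s`,
#'   `alpha1`, `seg_hr`, `n_beats`; windows with fewer than 18 beats are
#'   masked (`NA` alpha1).
#' @export
alpha1_track <- function(series, window_s = 120, step_s = 5, lambda = 500,
                         scales = 4:16, order = 2, calibrate = TRUE) {
  beats <- retained_beats(series)
  t <- beats$time_s
  span <- max(t) - min(t)
  if (span < window_s) {
    stop(sprintf(
      "series spans %.1f s: no complete %g-s window", span, window_s
    ), call. = FALSE)
  }
  t0 <- min(t) - beats$rr_ms[1] / 1000 # window start measured from series onset
  evals <- seq(t0 + window_s, max(t), by = step_s)
  logs <- log(scales)
  rows <- purrr::map(evals, function(te) {
    sel <- which(t > te - window_s & t <= te)
    nb <- length(sel)
    if (nb < max(scales) + 2) {
      return(tibble::tibble(
        time_s = te, alpha1 = NA_real_,
        seg_hr = if (nb) 60000 / mean(beats$rr_ms[sel]) else NA_real_,
        n_beats = nb
      ))
    }
    z <- smoothness_priors_detrend(beats$rr_ms[sel], lambda)
    profile <- cumsum(z - mean(z))
    logF <- vapply(scales, function(s) {
      mse <- poly_window_mse(profile, s, order = order, calibrate = calibrate)
      log(sqrt(mean(mse)))
    }, numeric(1))
    ok <- is.finite(logF)
    a1 <- if (sum(ok) >= 3) {
      stats::cov(logs[ok], logF[ok]) / stats::var(logs[ok])
    } else {
      NA_real_
    }
    tibble::tibble(
      time_s = te, alpha1 = a1,
      seg_hr = 60000 / mean(beats$rr_ms[sel]), n_beats = nb
    )
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("dfa_alpha1_track", class(out))
  out
}
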