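# Independent oracles used across the suite. They deliberately avoid the
# package's convolution machinery: window fits go through lm(), the
# exponent derivative through the Lagrange polynomial.

# Brute-force DFA fluctuation: per-window lm() fits on the segment profile.
bf_fluctuation <- function(seg, w, order = 2, calibrate = TRUE) {
  p <- cumsum(seg - mean(seg))
  n <- length(p)
  xx <- seq_len(w) - 1
  rss <- vapply(seq_len(n - w + 1), function(i) {
    y <- p[i:(i + w - 1)]
    fit <- stats::lm(y ~ stats::poly(xx, order, raw = TRUE))
    sum(stats::residuals(fit)^2)
  }, numeric(1))
  denom <- if (calibrate) ddfathresh:::white_noise_rss(w, order) / w else w
  sqrt(mean(rss) / denom)
}

# Derivative at x0 of the quadratic through (xm, fm), (x0, f0), (xp, fp).
lagrange_derivative <- function(xm, x0, xp, fm, f0, fp) {
  fm * (x0 - xp) / ((xm - x0) * (xm - xp)) +
    f0 * (2 * x0 - xm - xp) / ((x0 - xm) * (x0 - xp)) +
    fp * (x0 - xm) / ((xp - xm) * (xp - x0))
}

# Least-squares slope of log F against log s.
loglog_slope <- function(scales, f_values) {
  ok <- is.finite(log(f_values))
  stats::coef(stats::lm(log(f_values[ok]) ~ log(scales[ok])))[[2]]
}

# A stationary RR-like series around 700 ms with prescribed exponent.
fgn_series <- function(n, hurst, seed, sd_ms = 20) {
  rri_series(700 + sd_ms * gen_fgn(n, hurst, seed = seed))
}
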