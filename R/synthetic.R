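# Synthetic fixtures for validation: stationary series with a prescribed
# scaling exponent, incremental-exercise RR-interval series with a planted
# exponent-versus-HR schedule and beat artifacts, and lactate curves with
# planted thresholds. All generators are pure functions of their arguments
# and seed.

the_beta_cache <- new.env(parent = emptyenv())

# Expected mean local DDFA exponent, over the standard 5-64 scale grid, of
# spectrally synthesised noise with power spectrum f^-beta. Exact for the
# circular Gaussian process the generator produces: the autocovariance
# follows from the spectrum, and the expected window residual sum of
# squares is the trace form E[RSS] = tr(K Sigma) with K = L'(I-P)L.
expected_dfa_alpha <- function(beta, scales = ddfa_scales(), n_ref = 4096) {
  nf <- n_ref / 2
  k <- seq_len(nf - 1)
  pow <- c(k^(-beta), nf^(-beta) / 2) # conjugate pairs + Nyquist
  d <- 0:max(scales + 1)
  gam <- vapply(d, function(dd) {
    sum(pow * cos(2 * pi * c(k, nf) * dd / n_ref))
  }, numeric(1))
  gam <- gam / gam[1]
  logF <- vapply(sort(unique(c(scales - 1L, scales, scales + 1L))), function(w) {
    K <- rss_quadratic_form(w)
    Sigma <- stats::toeplitz(gam[seq_len(w)])
    0.5 * log(sum(K * Sigma) * w / white_noise_rss(w))
  }, numeric(1))
  names(logF) <- sort(unique(c(scales - 1L, scales, scales + 1L)))
  al <- local_alpha(
    logF[as.character(scales - 1L)], logF[as.character(scales)],
    logF[as.character(scales + 1L)], scales
  )
  mean(al)
}

# Spectral slope whose expected in-band DDFA exponent equals `hurst`,
# by monotone root finding (cached). The finite scale range 5-64 cannot
# resolve arbitrarily strong anticorrelation, so the attainable exponent
# floor (about 0.03) bounds requests from below.
dfa_matched_beta <- function(hurst) {
  key <- sprintf("%.6f", hurst)
  val <- the_beta_cache[[key]]
  if (is.null(val)) {
    f <- function(b) expected_dfa_alpha(b) - hurst
    lo <- -3
    if (f(lo) > 0) {
      stop(sprintf(
        "target exponent %.3f below the floor resolvable on scales 5-64",
        hurst
      ), call. = FALSE)
    }
    val <- stats::uniroot(f, c(lo, 2), tol = 1e-4)$root
    the_beta_cache[[key]] <- val
  }
  val
}

#' Gaussian noise with a prescribed scaling exponent
#'
#' Fourier (spectral) synthesis of a zero-mean, unit-variance Gaussian
#' sequence with a power-law spectrum `f^-beta`, whose second-order DFA
#' exponent over scales 5--64 beats equals `H` within sampling error. The
#' spectral slope is calibrated so that the *expected in-band* exponent --
#' not the asymptotic one -- matches `H`: on a finite scale range DFA sits
#' in a crossover regime (pronounced for anticorrelated noise), and the
#' calibration inverts the exactly computable expectation of the
#' fluctuation function. A single code path covers the whole range `H` in
#' (0, 1.2]: `H = 0.5` is white noise (`beta = 0` exactly), `H = 1` close
#' to 1/f noise, `H > 1` nonstationary fractal noise.
#'
#' @param n Length, >= 64.
#' @param hurst Target exponent in (0, 1.2].
#' @param seed Optional seed; a fixed seed gives a bit-identical sequence.
#' @return Numeric vector of length `n`.
#' @export
gen_fgn <- function(n, hurst, seed = NULL) {
  stopifnot(n >= 64)
  if (!is.finite(hurst) || hurst <= 0 || hurst > 1.2) {
    stop("hurst must lie in (0, 1.2]", call. = FALSE)
  }
  beta <- dfa_matched_beta(hurst)
  nf <- floor(n / 2)
  with_seed(seed, {
    amp <- (seq_len(nf))^(-beta / 2)
    phase <- stats::runif(nf, 0, 2 * pi)
    fs <- complex(length.out = n)
    fs[2:(nf + 1)] <- complex(modulus = amp, argument = phase)
    if (nf >= 2) fs[n:(n - nf + 2)] <- Conj(fs[2:nf])
    if (n %% 2 == 0) fs[nf + 1] <- complex(modulus = amp[nf], argument = 0)
    y <- Re(stats::fft(fs, inverse = TRUE)) / n
    as.numeric((y - mean(y)) / stats::sd(y))
  })
}

#' Piecewise-linear exponent-versus-HR schedule
#'
#' @param h1 HR (BPM) up to which the target exponent stays at `alpha_rest`.
#' @param h2 HR (BPM) at which the exponent reaches `alpha_high`; between
#'   `h1` and `h2` it declines linearly, beyond `h2` it stays at
#'   `alpha_high`.
#' @param alpha_rest,alpha_high Exponent levels (defaults 1.0 and 0).
#' @return A function mapping HR to the target exponent (clamped to the
#'   generator's valid range).
#' @export
alpha_schedule <- function(h1 = 145, h2 = 195, alpha_rest = 1.0,
                           alpha_high = 0) {
  stopifnot(h1 < h2, alpha_high <= alpha_rest)
  function(hr) {
    a <- alpha_rest + (alpha_high - alpha_rest) *
      pmin(pmax((hr - h1) / (h2 - h1), 0), 1)
    pmin(pmax(a, 0.05), 1.2)
  }
}

#' Synthetic incremental-exercise RR-interval series
#'
#' Emulates the beat-to-beat statistics of an incremental cyclo-ergometer
#' test: the mean RR interval follows `60000 / HR(t)` along a monotone HR
#' ramp; beat-to-beat fluctuations are spectrally synthesised Gaussian
#' blocks whose local target scaling exponent follows `schedule(HR)`,
#' overlap-added with variance-preserving cross-fade weights; missed-beat
#' artifacts merge two adjacent intervals and extra-beat artifacts split an
#' interval at a uniform random point. Artifact-free intervals stay inside
#' the physiological 200--2000 ms range, so every preprocessing removal is
#' attributable to a planted artifact.
#'
#' @param duration_s Exercise duration in seconds (default 1500, a ~25-min
#'   ramp).
#' @param hr_start,hr_end Ramp endpoints in BPM (defaults 110 and 200),
#'   inside (30, 300).
#' @param schedule Exponent schedule from [alpha_schedule()].
#' @param fluct_sd Beat-to-beat fluctuation magnitude in ms at the ramp
#'   start (default 15). The amplitude scales with the mean interval along
#'   the ramp (a constant coefficient of variation), mirroring the
#'   contraction of beat-to-beat variability as exercise intensifies.
#' @param miss_rate,extra_rate Artifact probabilities per beat, each in
#'   [0, 0.05].
#' @param crossfade_beats Cross-fade window of the exponent schedule in
#'   beats (default 60; synthesis windows span twice this at half-window
#'   hop).
#' @param seed Optional seed.
#' @return An [rri_series()]; attributes `artifact_beats` (indices of beats
#'   touched by injected artifacts, in the output series) and `target_alpha`
#'   (per-beat scheduled exponent before artifact injection).
#' @export
gen_exercise_rri <- function(duration_s = 1500, hr_start = 110, hr_end = 200,
                             schedule = alpha_schedule(), fluct_sd = 15,
                             miss_rate = 0, extra_rate = 0,
                             crossfade_beats = 60, seed = NULL) {
  stopifnot(
    hr_start < hr_end, hr_start > 30, hr_end < 300,
    miss_rate >= 0, miss_rate <= 0.05, extra_rate >= 0, extra_rate <= 0.05,
    fluct_sd >= 0, duration_s > 0
  )
  with_seed(seed, {
    # beat times from the deterministic ramp: beat count grows as the
    # integral of HR(t)/60, quadratic in t for a linear ramp
    mean_hr_fun <- function(t) hr_start + (hr_end - hr_start) * t / duration_s
    n_max <- ceiling(duration_s * hr_end / 60) + 2L * max(crossfade_beats, 8L)
    # per-beat target exponent via the beat-index -> time mapping
    t_of_beat <- numeric(n_max)
    t <- 0
    for (i in seq_len(n_max)) {
      t_of_beat[i] <- t
      t <- t + 60 / mean_hr_fun(min(t, duration_s))
    }
    target <- schedule(mean_hr_fun(pmin(t_of_beat, duration_s)))

    # overlap-add noise synthesis: windows of twice the cross-fade length
    # at half-window hop, triangular power weights (adjacent windows sum to
    # one, so the local variance is preserved through every cross-fade)
    cf <- max(crossfade_beats, 8L)
    win <- 2L * cf
    tri <- c(seq_len(cf) - 0.5, cf - seq_len(cf) + 0.5) / cf
    fl <- numeric(n_max)
    wsum <- numeric(n_max)
    for (b in seq.int(1L - cf, n_max, by = cf)) {
      span <- max(b, 1L):min(b + win - 1L, n_max)
      a_blk <- mean(target[span])
      blk <- gen_fgn(max(win, 64), a_blk)
      w <- tri[span - b + 1L]
      fl[span] <- fl[span] + sqrt(w) * blk[seq_along(span)]
      wsum[span] <- wsum[span] + w
    }
    fl <- fl / sqrt(wsum)

    # assemble intervals along the ramp until the duration is reached
    rr <- numeric(0)
    t <- 0
    i <- 1L
    while (t < duration_s && i <= n_max) {
      base <- 60000 / mean_hr_fun(t)
      amp <- fluct_sd * base * hr_start / 60000
      val <- min(max(base + amp * fl[i], 200), 2000)
      rr <- c(rr, val)
      t <- t + val / 1000
      i <- i + 1L
    }
    target <- target[seq_along(rr)]

    # artifact injection (missed beat: merge; extra beat: split)
    artifact <- logical(length(rr))
    if (miss_rate > 0 || extra_rate > 0) {
      u <- stats::runif(length(rr))
      merge_at <- which(u < miss_rate & seq_along(rr) < length(rr))
      split_at <- which(u >= miss_rate & u < miss_rate + extra_rate)
      out <- vector("list", length(rr))
      keep <- rep(TRUE, length(rr))
      for (k in seq_along(rr)) out[[k]] <- rr[k]
      for (k in merge_at) {
        if (!keep[k] || !keep[k + 1]) next
        out[[k]] <- sum(rr[k:(k + 1)])
        keep[k + 1] <- FALSE
        artifact[k] <- TRUE
      }
      for (k in split_at) {
        if (!keep[k] || artifact[k]) next
        u_split <- stats::runif(1)
        out[[k]] <- c(rr[k] * u_split, rr[k] * (1 - u_split))
        artifact[k] <- TRUE
      }
      flag <- unlist(purrr::map2(out, artifact, function(v, a) rep(a, length(v))))
      flag <- flag[unlist(purrr::map2(out, keep, function(v, kp) rep(kp, length(v))))]
      tgt <- unlist(purrr::map2(out, target, function(v, a) rep(a, length(v))))
      tgt <- tgt[unlist(purrr::map2(out, keep, function(v, kp) rep(kp, length(v))))]
      rr <- unlist(out[keep])
      artifact <- flag[seq_along(rr)]
      target <- tgt[seq_along(rr)]
    }
    series <- rri_series(rr)
    attr(series, "artifact_beats") <- which(artifact)
    attr(series, "target_alpha") <- target
    series
  })
}

#' Synthetic lactate curve with planted thresholds
#'
#' Builds a piecewise-linear lactate-versus-time curve: flat at `baseline`,
#' then a shallow rise crossing `baseline + 0.3` exactly at `lt1_time`,
#' then a steep rise of `rise_rate` per step starting at `lt2_time` (the
#' crossing point of the two lines). Sampled at the end of each `step_s`
#' exercise step, with optional iid Gaussian noise. With `noise_sd = 0` and
#' `lt2_time` on a step boundary, [lactate_thresholds()] recovers both
#' planted times exactly.
#'
#' @param n_steps Number of 3-min exercise steps (default 9).
#' @param step_s Step length in seconds (default 180).
#' @param baseline Resting lactate in mmol/L (default 1.2).
#' @param lt1_time,lt2_time Planted threshold times in seconds
#'   (`lt1_time < lt2_time < n_steps * step_s`).
#' @param pre_rate Shallow rise between the thresholds, mmol/L per second
#'   (default 0.45 per step, i.e. below the 0.8 step increment that
#'   qualifies points for the steep fit).
#' @param rise_rate Steep rise beyond `lt2_time`, mmol/L per step
#'   (default 1.2, above the 0.8 qualifying increment).
#' @param noise_sd Measurement noise in mmol/L (default 0).
#' @param hr_start,hr_end Linear HR ramp endpoints used for the 30-s-average
#'   HR column (defaults 110 and 185 BPM).
#' @param seed Optional seed for the noise.
#' @return A tibble with columns `step_t`, `lactate`, `hr`; attributes
#'   `lt1_time` and `lt2_time`.
#' @export
gen_lactate_curve <- function(n_steps = 9, step_s = 180, baseline = 1.2,
                              lt1_time = 570, lt2_time = 1260,
                              pre_rate = 0.45 / 180, rise_rate = 1.2,
                              noise_sd = 0, hr_start = 110, hr_end = 185,
                              seed = NULL) {
  stopifnot(lt1_time < lt2_time, lt2_time < n_steps * step_s, baseline > 0)
  t0 <- lt1_time - 0.3 / pre_rate # onset of the shallow rise
  if (t0 <= 0) stop("lt1_time too early for the shallow-rise onset", call. = FALSE)
  step_t <- seq_len(n_steps) * step_s
  line_a <- function(t) baseline + pre_rate * pmax(t - t0, 0)
  m2 <- rise_rate / step_s
  line_b <- function(t) line_a(lt2_time) + m2 * (t - lt2_time)
  lact <- pmax(line_a(step_t), line_b(step_t))
  lact <- with_seed(seed, lact + stats::rnorm(n_steps, sd = noise_sd))
  out <- tibble::tibble(
    step_t = step_t,
    lactate = lact,
    hr = hr_start + (hr_end - hr_start) * step_t / (n_steps * step_s)
  )
  attr(out, "lt1_time") <- lt1_time
  attr(out, "lt2_time") <- lt2_time
  out
}
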