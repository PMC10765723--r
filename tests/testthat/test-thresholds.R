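make_field <- function(df) {
  class(df) <- c("ddfa_field", class(df))
  df
}

make_curve <- function(bin, alpha_tilde) {
  out <- tibble::tibble(bin = bin, alpha_tilde = alpha_tilde)
  class(out) <- c("alpha_curve", class(out))
  out
}

test_that("heart-rate binning rounds to the nearest integer and averages", {
  fld <- make_field(tibble::tibble(
    t_index = 1:2, time_s = 1:2, scale = 8,
    alpha = c(0.8, 1.0), seg_hr = c(120.4, 119.6)
  ))
  p <- bin_by_hr(fld)
  expect_equal(p$bin, 120L)
  expect_equal(p$alpha_bin, 0.9)
  expect_equal(p$n, 2L)

  single <- bin_by_hr(make_field(tibble::tibble(
    t_index = 1, time_s = 1, scale = 8, alpha = 0.77, seg_hr = 131.2
  )))
  expect_equal(single$alpha_bin, 0.77)

  # ties round half to even (R convention)
  tie <- bin_by_hr(make_field(tibble::tibble(
    t_index = 1:2, time_s = 1:2, scale = 8,
    alpha = c(1, 1), seg_hr = c(120.5, 121.5)
  )))
  expect_equal(tie$bin, c(120L, 122L))

  expect_error(bin_by_hr(make_field(tibble::tibble(
    t_index = 1, time_s = 1, scale = 8, alpha = NA_real_, seg_hr = 120
  ))), "no defined")
})

test_that("the baseline is the mean of the lowest-HR occupied bins per scale", {
  prof <- bin_by_hr(make_field(tidyr::expand_grid(
    t_index = 1, time_s = 1, scale = c(5, 10), seg_hr = seq(100, 160, 1)
  ) |> dplyr::mutate(alpha = 1.0)))
  b <- compute_baseline(prof)
  expect_equal(b$b, c(1.0, 1.0))
  expect_equal(b$n_bins_used, c(25L, 25L))

  # construction isolates the baseline region from later decline
  prof2 <- bin_by_hr(make_field(tibble::tibble(
    t_index = 1, time_s = 1, scale = 5, seg_hr = seq(100, 160, 1),
    alpha = ifelse(seq(100, 160, 1) <= 124, 1.0, 0.2)
  )))
  expect_equal(compute_baseline(prof2)$b, 1.0)

  # fewer occupied bins than requested: use all, warn
  prof3 <- bin_by_hr(make_field(tibble::tibble(
    t_index = 1, time_s = 1, scale = 5, seg_hr = seq(100, 109, 1), alpha = 0.9
  )))
  expect_warning(b3 <- compute_baseline(prof3), "fewer than 25")
  expect_equal(b3$b, 0.9)
  expect_equal(b3$n_bins_used, 10L)
})

test_that("smoothing subtracts the baseline and mean-filters over occupied bins", {
  hr <- seq(100, 180, 1)
  prof <- bin_by_hr(make_field(tibble::tibble(
    t_index = 1, time_s = 1, scale = 5, seg_hr = hr, alpha = 1.0
  )))
  base <- compute_baseline(prof)
  sm <- smoothed_alpha(prof, base)
  expect_true(all(abs(sm$alpha_tilde) < 1e-12)) # identical to baseline

  # step profile: the smoothed curve ramps across the step over ~kernel bins
  prof2 <- bin_by_hr(make_field(tibble::tibble(
    t_index = 1, time_s = 1, scale = 5, seg_hr = hr,
    alpha = ifelse(hr < 150, 1.0, 0.0)
  )))
  base2 <- compute_baseline(prof2)
  sm2 <- smoothed_alpha(prof2, base2)
  crossing <- sm2$bin[which(sm2$alpha_tilde < -0.5)[1]]
  expect_lte(abs(crossing - 150), 5) # within kernel/2 of the step

  # unoccupied interior bins are skipped, not zero-filled
  hr3 <- c(100:130, 150:170)
  prof3 <- bin_by_hr(make_field(tibble::tibble(
    t_index = 1, time_s = 1, scale = 5, seg_hr = hr3, alpha = 1.0
  )))
  sm3 <- smoothed_alpha(prof3, compute_baseline(prof3))
  expect_equal(nrow(sm3), length(hr3))
  expect_true(all(abs(sm3$alpha_tilde) < 1e-12))

  expect_error(
    smoothed_alpha(prof3, compute_baseline(prof2)),
    NA
  ) # same scales: fine
})

test_that("threshold rules scan for stable runs below the levels", {
  bins <- 140:180
  ramp <- make_curve(bins, -(bins - 140) / 40)
  th <- ddfa_thresholds(ramp, skip = 0)
  expect_equal(th$t1_bpm, 141) # first bin strictly below 0
  expect_equal(th$t2_bpm, 161) # first bin strictly below -0.5

  # oscillation with runs of <= 9 negative bins never stabilises
  osc <- make_curve(100:179, rep(c(-0.1, -0.1, -0.1, -0.1, 0.1), 16))
  th2 <- ddfa_thresholds(osc, skip = 0)
  expect_true(is.na(th2$t1_bpm))
  expect_true(length(attr(th2, "diagnostics")$unstable_t1) > 0)

  # monotone: uniformly lowering the curve never raises a threshold
  for (delta in c(0.1, 0.3)) {
    lower <- make_curve(bins, ramp$alpha_tilde - delta)
    th_l <- ddfa_thresholds(lower, skip = 0)
    expect_lte(th_l$t1_bpm, th$t1_bpm)
    expect_lte(th_l$t2_bpm, th$t2_bpm)
  }

  # when both are defined the aerobic threshold cannot exceed the anaerobic
  expect_lte(th$t1_bpm, th$t2_bpm)

  # the baseline region is excluded from the search
  th3 <- ddfa_thresholds(ramp, skip = 25)
  expect_equal(th3$t1_bpm, 165) # search starts at the 26th occupied bin
})

test_that("maximal-HR percentages give the textbook thresholds", {
  expect_equal(unlist(hrmax_thresholds(200)[, c("t1_bpm", "t2_bpm")],
    use.names = FALSE
  ), c(140, 170))
  expect_equal(hrmax_thresholds(100)$t1_bpm, 70)
  expect_equal(hrmax_thresholds(100)$t2_bpm, 85)
  expect_error(hrmax_thresholds(350), "30, 300")
  expect_error(hrmax_thresholds(200, p1 = 0.9, p2 = 0.85), "ordering")
})

make_track <- function(hr, a1) {
  out <- tibble::tibble(
    time_s = seq_along(hr) * 5, alpha1 = a1, seg_hr = hr,
    n_beats = 200
  )
  class(out) <- c("dfa_alpha1_track", class(out))
  out
}

test_that("alpha1 regression thresholds solve the fitted line analytically", {
  hr <- seq(60, 200, 1)
  tr <- make_track(hr, 1.6 - 0.01 * hr)
  th <- dfa_alpha1_thresholds(tr)
  expect_equal(th$t1_bpm, 85)
  expect_equal(th$t2_bpm, 110)
  d <- attr(th, "diagnostics")
  expect_lt(abs((0.75 - d$intercept) / d$slope - 85), 0.01)
  expect_lt(abs((0.5 - d$intercept) / d$slope - 110), 0.01)
  expect_gt(d$r_squared, 0.999)

  # thresholds undefined when alpha1 never declines into the band
  flat <- make_track(hr, rep(0.9, length(hr)))
  expect_true(is.na(dfa_alpha1_thresholds(flat)$t1_bpm))

  # rising alpha1 in the band: slope not negative, undefined with reason
  rise <- make_track(hr, 0.4 + 0.0015 * hr)
  th_r <- dfa_alpha1_thresholds(rise)
  expect_true(is.na(th_r$t1_bpm))
  expect_match(attr(th_r, "diagnostics")$reason, "decline")
})

test_that("alpha1 band regions bridge small gaps of out-of-band points", {
  # two band clusters separated by 3 out-of-band points: one region
  hr <- seq(100, 100 + 19)
  a1 <- c(
    rep(0.7, 5), rep(0.9, 3), rep(0.6, 5), # 3 interveners, bridged
    seq(0.45, 0.2, length.out = 7)
  )
  th <- dfa_alpha1_thresholds(make_track(hr, a1))
  expect_gte(attr(th, "diagnostics")$n_points, 13)
})

test_that("lactate thresholds follow the interpolated two-line construction", {
  cur <- tibble::tibble(
    step_t = c(3, 6, 9, 12, 15, 18) * 60,
    lactate = c(1.2, 1.1, 1.3, 1.9, 2.9, 4.5),
    hr = c(110, 120, 130, 140, 150, 160)
  )
  th <- lactate_thresholds(cur)
  d <- attr(th, "diagnostics")
  expect_equal(d$lt1_time_s / 60, 9.5) # 9 + 3 * (0.1 / 0.6)

  # closed-form oracle: line through (9.5, 1.4) and (12, 1.9) crossed with
  # the least-squares line through the 12, 15, 18 min points
  a_s <- (1.9 - 1.4) / (12 - 9.5)
  a_i <- 1.4 - a_s * 9.5
  bf <- stats::lm(c(1.9, 2.9, 4.5) ~ c(12, 15, 18))
  t2_oracle <- (a_i - stats::coef(bf)[[1]]) / (stats::coef(bf)[[2]] - a_s)
  expect_equal(d$lt2_time_s / 60, t2_oracle, tolerance = 1e-12)

  # flat curve: no rise above min + 0.3, both undefined
  flat <- tibble::tibble(
    step_t = (1:6) * 180, lactate = rep(1, 6), hr = seq(110, 160, 10)
  )
  th_f <- lactate_thresholds(flat)
  expect_true(is.na(th_f$t1_bpm) && is.na(th_f$t2_bpm))

  expect_error(lactate_thresholds(flat[1:3, ]), "4 lactate")
})

test_that("a planted piecewise-linear breakpoint is recovered exactly", {
  g <- gen_lactate_curve(lt1_time = 570, lt2_time = 1260)
  d <- attr(lactate_thresholds(g), "diagnostics")
  expect_equal(d$lt1_time_s, 570, tolerance = 1e-9)
  expect_equal(d$lt2_time_s, 1260, tolerance = 1e-9)
})

test_that("hr_at_time interpolates inside the trace and errors outside", {
  trace <- data.frame(time_s = c(0, 1620), hr_bpm = c(100, 190))
  expect_equal(hr_at_time(810, trace), 145)
  const <- data.frame(time_s = c(0, 100, 200), hr_bpm = rep(150, 3))
  expect_equal(hr_at_time(37, const), 150)
  expect_error(hr_at_time(2000, trace), "outside")
})
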