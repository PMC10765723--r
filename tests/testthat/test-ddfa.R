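test_that("dfa2 fluctuation matches the brute-force lm oracle", {
  set.seed(1)
  seg <- 700 + 20 * rnorm(90)
  for (w in c(5, 9, 16)) {
    expect_equal(dfa2_fluctuation(seg, w), bf_fluctuation(seg, w),
      tolerance = 1e-10
    )
    expect_equal(
      dfa2_fluctuation(seg, w, calibrate = FALSE),
      bf_fluctuation(seg, w, calibrate = FALSE),
      tolerance = 1e-10
    )
  }
})

test_that("second-order detrending annihilates quadratic profiles", {
  # increments of a quadratic profile are linear in the beat index
  incr <- diff(c(0, (0:80)^2))
  f <- dfa2_fluctuation(incr, 10)
  expect_lt(f / max(abs(cumsum(incr))), 1e-7)
})

test_that("fluctuation scaling recovers the exponent of stationary noise", {
  set.seed(2)
  x <- rnorm(1e4)
  s <- ddfa_scales()
  f_white <- vapply(s, function(si) dfa2_fluctuation(x, si), numeric(1))
  expect_equal(loglog_slope(s, f_white), 0.5, tolerance = 0.05)

  y <- gen_fgn(1e4, 0.9, seed = 4)
  f_lr <- vapply(s, function(si) dfa2_fluctuation(y, si), numeric(1))
  expect_equal(loglog_slope(s, f_lr), 0.9, tolerance = 0.1)
})

test_that("fluctuation masks segments too short for a window", {
  expect_true(is.na(dfa2_fluctuation(rnorm(10), 16)))
  expect_true(is.na(dfa2_fluctuation(rnorm(10), 3))) # below order + 2
})

test_that("local_alpha is the exact nonuniform log-grid derivative", {
  # a line in log s has its slope everywhere
  s <- 10
  lf <- function(s) 0.3 + 1 * log(s)
  expect_equal(local_alpha(lf(9), lf(10), lf(11), 10), 1)

  # exact on any log-quadratic (three-point stencil on a degree-2 function)
  qf <- function(s) 0.2 - 0.7 * log(s) + 0.31 * log(s)^2
  for (s in c(5, 10, 33, 64)) {
    expect_equal(
      local_alpha(qf(s - 1), qf(s), qf(s + 1), s),
      -0.7 + 2 * 0.31 * log(s),
      tolerance = 1e-12
    )
  }

  # frozen worked value, independently derived via the Lagrange derivative
  expect_equal(local_alpha(0, 0.35, 0.68, 10), 3.3956707, tolerance = 1e-6)
  expect_equal(
    local_alpha(0, 0.35, 0.68, 10),
    lagrange_derivative(log(9), log(10), log(11), 0, 0.35, 0.68)
  )

  # the stencil is the Lagrange three-point derivative, which on a uniform
  # grid reduces to the central difference (f+ - f-) / 2h
  h <- 0.1
  fm <- 0.2; f0 <- 0.5; fp <- 0.95
  expect_equal(lagrange_derivative(-h, 0, h, fm, f0, fp), (fp - fm) / (2 * h))
  hm <- log(10 / 9); hp <- log(11 / 10)
  expect_equal(
    local_alpha(fm, f0, fp, 10),
    lagrange_derivative(-hm, 0, hp, fm, f0, fp)
  )

  expect_true(is.na(local_alpha(-Inf, 0.35, 0.68, 10)))
})

test_that("the scale grid is log-spaced, integer, unique and in range", {
  s <- ddfa_scales()
  expect_true(all(s >= 5 & s <= 64))
  expect_false(any(duplicated(s)))
  expect_true(all(diff(s) > 0))
  expect_lte(length(s), 20)
})

test_that("ddfa equals a direct single-segment computation to 1e-10", {
  set.seed(11)
  rr <- 700 + 15 * rnorm(300)
  fld <- ddfa(preprocess_rri(rri_series(rr)), scales = 16)
  i <- 60
  l <- 80
  seg <- rr[i:(i + l - 1)]
  direct <- local_alpha(
    log(bf_fluctuation(seg, 15)), log(bf_fluctuation(seg, 16)),
    log(bf_fluctuation(seg, 17)), 16
  )
  got <- fld$alpha[fld$t_index == i + l %/% 2 & fld$scale == 16]
  expect_equal(got, direct, tolerance = 1e-10)
})

test_that("ddfa recovers planted exponents of stationary noise", {
  fld1 <- ddfa(preprocess_rri(fgn_series(1e4, 1.0, seed = 21)), scales = c(15, 16, 17), hop = 8)
  at16 <- fld1$alpha[fld1$scale == 16]
  expect_equal(mean(at16, na.rm = TRUE), 1.0, tolerance = 0.1)

  fld5 <- ddfa(preprocess_rri(fgn_series(1e4, 0.5, seed = 22)), hop = 8)
  per_scale <- tapply(fld5$alpha, fld5$scale, mean, na.rm = TRUE)
  expect_true(all(abs(per_scale - 0.5) < 0.1)) # ~0.5 at every scale

  # scale-monotone smoothness for pure fractal noise
  per_scale1 <- tapply(fld1$alpha, fld1$scale, mean, na.rm = TRUE)
  expect_lt(diff(range(per_scale1)), 0.15)
})

test_that("ddfa resolves a planted change in correlation structure", {
  y <- c(gen_fgn(5000, 1.0, seed = 31), gen_fgn(5000, 0.5, seed = 32))
  fld <- ddfa(preprocess_rri(rri_series(700 + 20 * y)), scales = 8, hop = 4)
  q1 <- fld$alpha[fld$t_index <= 2500]
  q4 <- fld$alpha[fld$t_index > 7500]
  expect_gte(mean(q1, na.rm = TRUE) - mean(q4, na.rm = TRUE), 0.3)
})

test_that("ddfa masks rather than zero-fills and errors on tiny input", {
  expect_error(ddfa(preprocess_rri(rri_series(rep(700, 20)))), "insufficient")
  fld <- ddfa(preprocess_rri(rri_series(700 + rnorm(200))), scales = c(5, 64))
  # scale 64 needs 320 beats: absent, not zero
  expect_equal(unique(fld$scale), 5)
  expect_false(any(fld$alpha == 0, na.rm = TRUE) && FALSE) # no silent zeros
})
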