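test_that("permutation Pearson test reports r and a one-sided add-one p", {
  x <- c(1, 3, 2, 5, 4, 7, 6, 9, 8, 10)
  res <- pearson_permutation(x, x, n_perm = 999, seed = 1)
  expect_equal(res$r, 1)
  expect_equal(res$p, 1 / 1000)

  # identical seeds give identical p-values
  y <- rev(x) + rnorm(10)
  p1 <- pearson_permutation(x, y, n_perm = 999, seed = 7)$p
  p2 <- pearson_permutation(x, y, n_perm = 999, seed = 7)$p
  expect_identical(p1, p2)

  expect_error(pearson_permutation(rep(1, 5), 1:5), "variance")
})

test_that("Bland-Altman limits are mean +/- 1.96 sample sd", {
  expect_equal(bland_altman(rep(0, 5)), list(mu_diff = 0, loa_lo = 0, loa_hi = 0))

  ba <- bland_altman(c(-1, 1))
  expect_equal(ba$mu_diff, 0)
  expect_equal(ba$loa_hi, 1.96 * sqrt(2))
  expect_equal(ba$loa_lo, -1.96 * sqrt(2))

  # translation equivariance
  set.seed(2)
  d <- rnorm(12)
  b0 <- bland_altman(d)
  b5 <- bland_altman(d + 5)
  expect_equal(b5$mu_diff, b0$mu_diff + 5)
  expect_equal(b5$loa_lo, b0$loa_lo + 5)
  expect_equal(b5$loa_hi, b0$loa_hi + 5)

  expect_error(bland_altman(1), "at least 2")
})

test_that("the Monte-Carlo slope test flags strong trends and not flat ones", {
  hr <- seq(120, 180, length.out = 15)
  p_strong <- slope_mc_test(hr, 0.5 * hr + rnorm(15, sd = 0.01),
    n_mc = 999, seed = 3
  )
  expect_lt(p_strong, 0.01)

  expect_equal(slope_mc_test(hr, rep(2, 15), n_mc = 99, seed = 4), 1)
  expect_error(slope_mc_test(rep(150, 5), rnorm(5)), "degenerate")
})

test_that("BCa intervals cover and degrade gracefully", {
  set.seed(5)
  x <- rnorm(15)
  ci <- bca_ci(x, mean, n_boot = 1999, seed = 6)
  expect_lt(ci$lo, mean(x))
  expect_gt(ci$hi, mean(x))
  # interval width on the familiar sqrt(n) scale for a normal sample
  width <- ci$hi - ci$lo
  expect_gt(width, 0.5 * 2 * 1.96 * sd(x) / sqrt(15))
  expect_lt(width, 2.0 * 2 * 1.96 * sd(x) / sqrt(15))

  expect_warning(d <- bca_ci(rep(3, 10), mean, n_boot = 99), "degenerate")
  expect_equal(d$lo, d$hi)
})

test_that("comparison against itself is perfect agreement", {
  tab <- reference_thresholds()
  tab$self_t1 <- tab$lt1
  tab$self_t2 <- tab$lt2
  res <- compare_table(
    tab[, c("lt1", "lt2", "self_t1", "self_t2")],
    n_perm = 199, n_boot = 199, n_mc = 199, seed = 1
  )
  expect_equal(res$r, c(1, 1))
  expect_equal(res$mu_diff, c(0, 0))
  expect_equal(res$loa_lo, c(0, 0))
  expect_equal(res$loa_hi, c(0, 0))
  expect_equal(res$p_slope, c(1, 1))
})

test_that("comparison statistics are invariant to subject order", {
  tab <- reference_thresholds()
  res1 <- suppressWarnings(
    compare_table(tab, n_perm = 199, n_boot = 199, n_mc = 199, seed = 9)
  )
  perm <- sample(nrow(tab))
  res2 <- suppressWarnings(
    compare_table(tab[perm, ], n_perm = 199, n_boot = 199, n_mc = 199, seed = 9)
  )
  expect_equal(res1$mu_diff, res2$mu_diff)
  expect_equal(res1$r, res2$r)
  expect_equal(res1$loa_lo, res2$loa_lo)
})

test_that("missing cells skip the affected subjects with a warning", {
  tab <- reference_thresholds()
  tab$ddfa_t1[3] <- NA
  w <- capture_warnings(
    res <- compare_table(tab, n_perm = 99, n_boot = 99, n_mc = 99, seed = 2)
  )
  expect_true(any(grepl("missing cells", w)))
  expect_equal(res$n[res$method == "ddfa" & res$threshold == 1], 14L)
})
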