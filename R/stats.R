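# Agreement and consistency statistics for threshold estimates: permutation
# Pearson tests, Bland-Altman limits of agreement, a Monte-Carlo slope test
# for trend in the differences, and BCa bootstrap intervals. All resampling
# honours an explicit seed; permutation and Monte-Carlo p-values use the
# add-one estimator and are therefore never exactly zero.

with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  code
}

#' One-sided permutation test for Pearson correlation
#'
#' Tests positive correlation against the null of no correlation by
#' randomly permuting one vector. The p-value uses the add-one estimator
#' `(1 + #\{r* >= r\}) / (n_perm + 1)`.
#'
#' @param x,y Equal-length numeric vectors (>= 3) with nonzero variance.
#' @param n_perm Number of random permutations (default 10^4).
#' @param seed Optional seed for reproducible permutations.
#' @return A list with elements `r` and `p`.
#' @export
pearson_permutation <- function(x, y, n_perm = 1e4, seed = NULL) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance: correlation undefined", call. = FALSE)
  }
  r <- stats::cor(x, y)
  xc <- x - mean(x)
  yc <- y - mean(y)
  denom <- sqrt(sum(xc^2) * sum(yc^2))
  r_star <- with_seed(seed, vapply(seq_len(n_perm), function(i) {
    sum(xc[sample.int(length(xc))] * yc) / denom
  }, numeric(1)))
  list(r = r, p = (1 + sum(r_star >= r)) / (n_perm + 1))
}

#' Bland-Altman limits of agreement
#'
#' @param diff Numeric vector of paired differences (BPM), length >= 2.
#' @return A list with `mu_diff` and the 95% limits of agreement
#'   `loa_lo`/`loa_hi` (`mu_diff` -/+ 1.96 sample standard deviations).
#' @export
bland_altman <- function(diff) {
  if (length(diff) < 2) stop("need at least 2 differences", call. = FALSE)
  mu <- mean(diff)
  s <- stats::sd(diff)
  list(mu_diff = mu, loa_lo = mu - 1.96 * s, loa_hi = mu + 1.96 * s)
}

#' Monte-Carlo test for trend in the differences
#'
#' The statistic is the absolute OLS slope of the differences against HR.
#' Null draws keep the HR abscissae fixed and replace the differences with
#' iid normal values of the observed standard deviation; high p-values mean
#' the slope is consistent with trend-free differences.
#'
#' @param hr_mean HR abscissae (BPM), nonzero variance.
#' @param diff Paired differences (BPM), same length >= 3.
#' @param n_mc Number of Monte-Carlo draws (default 10^4).
#' @param seed Optional seed.
#' @return The p-value `(1 + #\{|slope*| >= |slope|\}) / (n_mc + 1)`.
#' @export
slope_mc_test <- function(hr_mean, diff, n_mc = 1e4, seed = NULL) {
  stopifnot(length(hr_mean) == length(diff), length(diff) >= 3)
  if (stats::sd(hr_mean) == 0) {
    stop("degenerate abscissae: slope undefined", call. = FALSE)
  }
  hc <- hr_mean - mean(hr_mean)
  ssx <- sum(hc^2)
  s <- stats::sd(diff)
  if (s == 0) return(1) # zero slope can never be exceeded
  obs <- abs(sum(hc * diff) / ssx)
  null_slopes <- with_seed(seed, {
    z <- matrix(stats::rnorm(n_mc * length(diff), sd = s), nrow = length(diff))
    abs(colSums(hc * z) / ssx)
  })
  (1 + sum(null_slopes >= obs)) / (n_mc + 1)
}

#' Bias-corrected and accelerated bootstrap interval
#'
#' BCa interval for a statistic of a sample, resampling rows when the
#' sample is a data frame (so paired observations stay paired) and elements
#' when it is a vector. Delegates to the `boot` package.
#'
#' @param sample A numeric vector or data frame (>= 3 observations).
#' @param stat Function of a resample (vector or data-frame subset)
#'   returning one number.
#' @param n_boot Number of bootstrap resamples (default 10^4).
#' @param level Confidence level (default 0.95).
#' @param seed Optional seed.
#' @return A list with `lo` and `hi`. A statistic that is constant across
#'   resamples yields a degenerate interval (`lo == hi`) with a warning.
#' @export
bca_ci <- function(sample, stat, n_boot = 1e4, level = 0.95, seed = NULL) {
  n <- if (is.data.frame(sample)) nrow(sample) else length(sample)
  stopifnot(n >= 3)
  take <- if (is.data.frame(sample)) {
    function(d, i) stat(d[i, , drop = FALSE])
  } else {
    function(d, i) stat(d[i])
  }
  bs <- with_seed(seed, boot::boot(sample, take, R = n_boot))
  if (stats::sd(bs$t[, 1]) == 0) {
    warning("statistic constant across resamples: degenerate interval",
      call. = FALSE
    )
    return(list(lo = bs$t0[1], hi = bs$t0[1]))
  }
  ci <- boot::boot.ci(bs, conf = level, type = "bca")
  list(lo = unname(ci$bca[1, 4]), hi = unname(ci$bca[1, 5]))
}

#' Agreement statistics of threshold methods against a benchmark
#'
#' For each estimator column and threshold index, compares the estimates
#' with the benchmark lactate thresholds across subjects: Pearson r with a
#' BCa bootstrap lower confidence bound (subjects resampled as pairs) and a
#' one-sided permutation p-value, the mean difference with Bland-Altman
#' limits of agreement, the Monte-Carlo slope test for trend of the
#' differences over HR, and the Shapiro-Wilk normality p-value of the
#' differences.
#'
#' @param table A data frame shaped like a per-subject threshold table:
#'   columns `lt1`, `lt2` (the benchmark) plus `<method>_t1` / `<method>_t2`
#'   columns for each estimator (e.g. `vt_t1`, `hrmax_t1`, `alpha1_t1`,
#'   `ddfa_t1`), >= 3 complete subjects per comparison.
#' @param n_perm,n_boot,n_mc Resampling sizes (default 10^4 each).
#' @param seed Optional seed governing all resampling.
#' @param slope_abscissa `"pair-mean"` (default) regresses the differences
#'   on the mean of method and benchmark HR (the Bland-Altman convention);
#'   `"benchmark"` uses the benchmark HR alone.
#' @return A tibble with one row per (method, threshold): `r`, `r_lb95`,
#'   `p_corr`, `mu_diff`, `loa_lo`, `loa_hi`, `p_slope`, `p_norm`, `n`.
#'   Comparisons with missing cells are skipped with a warning.
#' @export
compare_table <- function(table, n_perm = 1e4, n_boot = 1e4, n_mc = 1e4,
                          seed = NULL, slope_abscissa = c("pair-mean", "benchmark")) {
  slope_abscissa <- match.arg(slope_abscissa)
  stopifnot(all(c("lt1", "lt2") %in% names(table)), nrow(table) >= 3)
  methods <- sub("_t1$", "", grep("_t1$", names(table), value = TRUE))
  grid <- tidyr::expand_grid(method = methods, threshold = 1:2)
  seeds <- if (is.null(seed)) {
    rep(list(NULL), nrow(grid))
  } else {
    as.list(seed + seq_len(nrow(grid)))
  }
  rows <- purrr::pmap(
    list(grid$method, grid$threshold, seeds),
    function(m, th, sd_i) {
      est <- table[[paste0(m, "_t", th)]]
      bench <- table[[paste0("lt", th)]]
      ok <- is.finite(est) & is.finite(bench)
      if (any(!ok)) {
        warning(sprintf(
          "skipping %d subject(s) with missing cells for %s threshold %d",
          sum(!ok), m, th
        ), call. = FALSE)
      }
      est <- est[ok]
      bench <- bench[ok]
      if (length(est) < 3) return(NULL)
      d <- est - bench
      corr <- pearson_permutation(bench, est, n_perm = n_perm, seed = sd_i)
      lb <- if (stats::sd(d) == 0) {
        list(lo = 1, hi = 1) # method identical to benchmark
      } else {
        bca_ci(
          data.frame(x = bench, y = est),
          function(df) stats::cor(df$x, df$y),
          n_boot = n_boot,
          seed = if (is.null(sd_i)) NULL else sd_i + 1000L
        )
      }
      ba <- bland_altman(d)
      hr_x <- if (slope_abscissa == "pair-mean") (est + bench) / 2 else bench
      p_s <- slope_mc_test(hr_x, d,
        n_mc = n_mc,
        seed = if (is.null(sd_i)) NULL else sd_i + 2000L
      )
      p_n <- if (stats::sd(d) == 0) NA_real_ else stats::shapiro.test(d)$p.value
      tibble::tibble(
        method = m, threshold = th, n = length(d),
        r = corr$r, r_lb95 = lb$lo, p_corr = corr$p,
        mu_diff = ba$mu_diff, loa_lo = ba$loa_lo, loa_hi = ba$loa_hi,
        p_slope = p_s, p_norm = p_n
      )
    }
  )
  out <- dplyr::bind_rows(rows)
  class(out) <- c("comparison_stats", class(out))
  out
}
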