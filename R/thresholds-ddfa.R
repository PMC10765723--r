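# From the alpha(t, s) field to the smoothed, baseline-subtracted exponent
# curve over integer heart-rate bins, and the threshold rules on it.

#' Bin a DDFA field by heart rate
#'
#' Assigns every defined field entry to its nearest-integer HR bin (ties
#' round half to even, R's default) and averages the scaling exponents per
#' bin and scale.
#'
#' @param field A `ddfa_field` from [ddfa()].
#' @return A tibble of class `hr_bin_profile` with columns `bin` (BPM),
#'   `scale`, `alpha_bin`, `n` (segments in the bin).
#' @export
bin_by_hr <- function(field) {
  ok <- dplyr::filter(field, is.finite(.data$alpha), is.finite(.data$seg_hr))
  if (nrow(ok) == 0) stop("DDFA field has no defined entries", call. = FALSE)
  out <- ok |>
    dplyr::mutate(bin = as.integer(round(.data$seg_hr))) |>
    dplyr::group_by(.data$bin, .data$scale) |>
    dplyr::summarise(
      alpha_bin = mean(.data$alpha), n = dplyr::n(), .groups = "drop"
    ) |>
    dplyr::arrange(.data$bin, .data$scale)
  class(out) <- c("hr_bin_profile", class(out))
  out
}

#' Per-scale baseline exponent from the lowest-HR bins
#'
#' The individual baseline `b(s)` is the mean binned exponent over the
#' `n_bins` occupied bins with the lowest HR, separately per scale. It
#' anchors the exponent curve to the subject's own low-intensity scaling
#' behaviour. If a scale has fewer occupied bins than `n_bins`, all its bins
#' are used and a warning is emitted.
#'
#' @param profile An `hr_bin_profile` from [bin_by_hr()].
#' @param n_bins Number of lowest-HR bins defining the baseline (default 25).
#' @return A tibble of class `baseline_profile` with columns `scale`, `b`,
#'   `n_bins_used`.
#' @export
compute_baseline <- function(profile, n_bins = 25) {
  stopifnot(nrow(profile) > 0)
  out <- profile |>
    dplyr::group_by(.data$scale) |>
    dplyr::slice_min(.data$bin, n = n_bins, with_ties = FALSE) |>
    dplyr::summarise(
      b = mean(.data$alpha_bin), n_bins_used = dplyr::n(),
      bin_max = max(.data$bin), .groups = "drop"
    )
  if (any(out$n_bins_used < n_bins)) {
    warning(sprintf(
      "fewer than %d occupied HR bins at some scales; baseline uses all available bins",
      n_bins
    ), call. = FALSE)
  }
  class(out) <- c("baseline_profile", class(out))
  out
}

#' Smoothed baseline-subtracted exponent curve
#'
#' Subtracts the per-scale baseline, averages over scales within each HR
#' bin, and smooths the result with a mean filter spanning `kernel` occupied
#' bins (unoccupied interior bins are skipped, not zero-filled; the window
#' shrinks at the curve's ends). For an even kernel the window extends
#' `kernel/2` bins left and `kernel/2 - 1` bins right of the centre bin.
#'
#' @param profile An `hr_bin_profile`.
#' @param baseline A `baseline_profile` over the same scales.
#' @param kernel Mean-filter width in occupied HR bins (default 10).
#' @return A tibble of class `alpha_curve` with columns `bin` and
#'   `alpha_tilde`.
#' @export
smoothed_alpha <- function(profile, baseline, kernel = 10) {
  if (!setequal(unique(profile$scale), baseline$scale)) {
    stop("profile and baseline must share the same scales", call. = FALSE)
  }
  per_bin <- profile |>
    dplyr::left_join(baseline, by = "scale") |>
    dplyr::select(-dplyr::any_of("bin_max")) |>
    dplyr::group_by(.data$bin) |>
    dplyr::summarise(alpha = mean(.data$alpha_bin - .data$b), .groups = "drop") |>
    dplyr::arrange(.data$bin)
  a <- per_bin$alpha
  n <- length(a)
  left <- kernel %/% 2L
  right <- kernel - 1L - left
  sm <- vapply(seq_len(n), function(i) {
    w <- max(1L, i - left):min(n, i + right)
    mean(a[w])
  }, numeric(1))
  out <- tibble::tibble(bin = per_bin$bin, alpha_tilde = sm)
  if ("bin_max" %in% names(baseline)) {
    attr(out, "baseline_max_bin") <- max(baseline$bin_max)
  }
  class(out) <- c("alpha_curve", class(out))
  out
}

new_threshold_result <- function(method, t1, t2, diagnostics = list()) {
  out <- tibble::tibble(
    method = method,
    t1_bpm = if (is.null(t1) || is.na(t1)) NA_real_ else round(t1),
    t2_bpm = if (is.null(t2) || is.na(t2)) NA_real_ else round(t2)
  )
  attr(out, "diagnostics") <- diagnostics
  class(out) <- c("threshold_result", class(out))
  out
}

#' @export
print.threshold_result <- function(x, ...) {
  if (is.null(x$method) || is.null(x$t1_bpm) || is.null(x$t2_bpm)) {
    return(NextMethod())
  }
  cat(sprintf(
    "<threshold_result> %s: T1 = %s BPM, T2 = %s BPM\n", x$method,
    ifelse(is.na(x$t1_bpm), "undefined", x$t1_bpm),
    ifelse(is.na(x$t2_bpm), "undefined", x$t2_bpm)
  ))
  invisible(x)
}

# First occupied bin opening a run of `run` consecutive occupied bins that
# all satisfy `cond`; also returns the unstable candidates that failed.
stable_run_start <- function(bins, cond, run, from = 1L) {
  n <- length(cond)
  unstable <- integer(0)
  i <- from
  while (i <= n) {
    if (cond[i]) {
      j <- i
      while (j < n && cond[j + 1L]) j <- j + 1L
      if (j - i + 1L >= run) {
        return(list(bin = bins[i], unstable = bins[unstable]))
      }
      unstable <- c(unstable, i)
      i <- j + 1L
    }
    i <- i + 1L
  }
  list(bin = NA_real_, unstable = bins[unstable])
}

#' Aerobic and anaerobic thresholds from the exponent curve
#'
#' The first threshold is the lowest HR bin that opens a run of at least
#' `run` consecutive occupied bins with the smoothed exponent below the
#' baseline (`alpha_tilde < 0`); the second threshold is the lowest bin
#' opening such a run with `alpha_tilde < level` (default -0.5, i.e. the
#' drop from baseline-level long-range correlation into anticorrelated
#' dynamics). The search starts above the baseline region -- after `skip`
#' occupied bins (default 25) and, when the curve carries the baseline's
#' extent, above the highest HR bin any scale's baseline used -- because
#' there the curve is ~0 by construction and may dip negative spuriously.
#' Unstable crossings are reported in the diagnostics; a threshold with no
#' stable run is undefined (`NA`).
#'
#' @param curve An `alpha_curve` from [smoothed_alpha()].
#' @param run Required run length in occupied bins (default 10).
#' @param level Exponent drop defining the second threshold (default -0.5).
#' @param skip Occupied bins excluded from the start of the search
#'   (default 25, the baseline region).
#' @return A one-row tibble of class `threshold_result` (`method = "ddfa"`),
#'   diagnostics attached as an attribute.
#' @export
ddfa_thresholds <- function(curve, run = 10, level = -0.5, skip = 25) {
  stopifnot(nrow(curve) > 0)
  from <- min(skip + 1L, nrow(curve) + 1L)
  base_max <- attr(curve, "baseline_max_bin")
  if (!is.null(base_max)) {
    from <- max(from, which(curve$bin > base_max)[1], na.rm = TRUE)
    if (is.na(from)) from <- nrow(curve) + 1L
  }
  r1 <- stable_run_start(curve$bin, curve$alpha_tilde < 0, run, from = from)
  r2 <- stable_run_start(curve$bin, curve$alpha_tilde < level, run, from = from)
  new_threshold_result(
    "ddfa", r1$bin, r2$bin,
    diagnostics = list(
      unstable_t1 = r1$unstable, unstable_t2 = r2$unstable,
      run = run, level = level, n_bins = nrow(curve)
    )
  )
}
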