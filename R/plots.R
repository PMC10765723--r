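# ggplot2 views of the result objects.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a dynamical-DFA field
#'
#' Scaling exponent as a colour map over segment HR (or time) and scale,
#' the time- and scale-resolved picture the threshold rules summarise.
#'
#' @param object A `ddfa_field` from [ddfa()].
#' @param x `"hr"` (default) or `"time"` on the horizontal axis.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot ddfa_field
#' @export
autoplot.ddfa_field <- function(object, x = c("hr", "time"), ...) {
  x <- match.arg(x)
  df <- dplyr::filter(object, is.finite(.data$alpha))
  xs <- if (x == "hr") rlang::sym("seg_hr") else rlang::sym("time_s")
  ggplot2::ggplot(df, ggplot2::aes(!!xs, .data$scale, fill = .data$alpha)) +
    ggplot2::geom_tile() +
    ggplot2::scale_y_log10() +
    ggplot2::scale_fill_gradient2(
      midpoint = 0.5, low = "#2166ac", mid = "#f7f7f7", high = "#b2182b",
      name = expression(alpha)
    ) +
    ggplot2::labs(
      x = if (x == "hr") "heart rate (BPM)" else "time (s)",
      y = "scale (beats)"
    ) +
    ggplot2::theme_minimal()
}

#' Plot the smoothed exponent curve with its thresholds
#'
#' @param object An `alpha_curve` from [smoothed_alpha()].
#' @param thresholds Optional `threshold_result` whose T1/T2 are drawn as
#'   vertical lines.
#' @param level The exponent drop marking the second threshold (drawn as a
#'   horizontal guide, default -0.5).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot alpha_curve
#' @export
autoplot.alpha_curve <- function(object, thresholds = NULL, level = -0.5, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(.data$bin, .data$alpha_tilde)) +
    ggplot2::geom_hline(yintercept = c(0, level), linetype = "dashed",
      colour = "grey60") +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = "heart rate bin (BPM)",
      y = expression(tilde(alpha) * "(HR)")
    ) +
    ggplot2::theme_minimal()
  if (!is.null(thresholds)) {
    v <- stats::na.omit(c(thresholds$t1_bpm, thresholds$t2_bpm))
    if (length(v)) {
      p <- p + ggplot2::geom_vline(xintercept = v, colour = "#2c7fb8")
    }
  }
  p
}

#' Plot a short-term DFA exponent track
#'
#' @param object A `dfa_alpha1_track` from [alpha1_track()].
#' @param ... Unused.
#' @return A ggplot of alpha1 against window HR with the 0.75 / 0.5
#'   reference levels.
#' @method autoplot dfa_alpha1_track
#' @export
autoplot.dfa_alpha1_track <- function(object, ...) {
  ggplot2::ggplot(
    dplyr::filter(object, is.finite(.data$alpha1)),
    ggplot2::aes(.data$seg_hr, .data$alpha1)
  ) +
    ggplot2::geom_hline(yintercept = c(0.75, 0.5), linetype = "dashed",
      colour = "grey60") +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::labs(x = "heart rate (BPM)", y = expression(alpha[1])) +
    ggplot2::theme_minimal()
}

#' Bland-Altman plot of a method against the benchmark
#'
#' @param table A per-subject threshold table as in [compare_table()].
#' @param method Method prefix (e.g. `"ddfa"`).
#' @param threshold 1 or 2.
#' @return A ggplot of the per-subject differences against the pairwise
#'   mean HR, with the mean difference and the 95% limits of agreement.
#' @export
plot_bland_altman <- function(table, method, threshold = 1) {
  est <- table[[paste0(method, "_t", threshold)]]
  bench <- table[[paste0("lt", threshold)]]
  d <- est - bench
  ba <- bland_altman(d)
  df <- tibble::tibble(hr_mean = (est + bench) / 2, diff = d)
  ggplot2::ggplot(df, ggplot2::aes(.data$hr_mean, .data$diff)) +
    ggplot2::geom_hline(yintercept = ba$mu_diff, colour = "grey30") +
    ggplot2::geom_hline(
      yintercept = c(ba$loa_lo, ba$loa_hi),
      colour = "grey70", linetype = "dashed"
    ) +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = "mean of method and benchmark (BPM)",
      y = "method - benchmark (BPM)",
      title = sprintf("%s vs lactate, threshold %d", method, threshold)
    ) +
    ggplot2::theme_minimal()
}
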