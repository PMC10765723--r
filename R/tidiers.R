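# broom-style accessors for the result objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' Tidy a threshold result
#'
#' @param x A `threshold_result`.
#' @param ... Unused.
#' @return A long tibble with one row per threshold (`method`, `threshold`,
#'   `hr_bpm`).
#' @method tidy threshold_result
#' @export
tidy.threshold_result <- function(x, ...) {
  tibble::tibble(
    method = rep(x$method, 2),
    threshold = 1:2,
    hr_bpm = c(x$t1_bpm, x$t2_bpm)
  )
}

#' @rdname tidy.threshold_result
#' @return For `glance()`: a one-row tibble of the method's diagnostics
#'   (scalar entries only).
#' @method glance threshold_result
#' @export
glance.threshold_result <- function(x, ...) {
  d <- attr(x, "diagnostics")
  d <- d[vapply(d, function(v) is.atomic(v) && length(v) == 1, logical(1))]
  dplyr::bind_cols(tibble::tibble(method = x$method), tibble::as_tibble(d))
}

#' Tidy a pipeline report
#'
#' @param x A `threshold_report` from [run_pipeline()].
#' @param ... Unused.
#' @return All methods' thresholds in long form.
#' @method tidy threshold_report
#' @export
tidy.threshold_report <- function(x, ...) {
  x$thresholds |>
    tidyr::pivot_longer(
      c("t1_bpm", "t2_bpm"),
      names_to = "threshold", values_to = "hr_bpm"
    ) |>
    dplyr::mutate(threshold = ifelse(.data$threshold == "t1_bpm", 1L, 2L))
}

#' @rdname tidy.threshold_report
#' @method glance threshold_report
#' @export
glance.threshold_report <- function(x, ...) x$filter_report
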