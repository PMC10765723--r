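#' Pipeline configuration
#'
#' Collects every numeric constant of the analysis with its default:
#' preprocessing (range 200--2000 ms, median kernel 7 beats, 10% deviation),
#' the dynamical-DFA engine (20 log-spaced integer scales on 5--64 beats,
#' segment factor 5, hop 1), threshold detection (25 baseline bins,
#' smoothing kernel 10 bins, stability run 10 bins, level -0.5), the
#' short-term alpha1 track (120-s window every 5 s, smoothness priors
#' lambda 500, band 0.5--0.75, gap 4), HRmax percentages (0.70 / 0.85) and
#' resampling sizes (10^4).
#'
#' @param ... Named overrides of the defaults.
#' @return A named list of class `run_config`.
#' @export
run_config <- function(...) {
  cfg <- list(
    lo = 200, hi = 2000, kernel = 7, frac = 0.10, exclude = integer(),
    n_scales = 20, s_min = 5, s_max = 64, seg_factor = 5, hop = 1,
    anchor = "centre", hr_mean = "arithmetic", calibrate = TRUE,
    baseline_bins = 25, smooth_kernel = 10, run = 10, level = -0.5,
    window_s = 120, step_s = 5, lambda = 500, alpha1_scales = 4:16,
    order = 2, band = c(0.5, 0.75), gap_n = 4,
    p1 = 0.70, p2 = 0.85,
    n_perm = 1e4, n_boot = 1e4, n_mc = 1e4, seed = NULL
  )
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown config fields: ", paste(bad, collapse = ", "), call. = FALSE)
  cfg[names(over)] <- over
  class(cfg) <- "run_config"
  cfg
}

#' Run the whole threshold-estimation pipeline
#'
#' Preprocesses the RR-interval series, computes the dynamical-DFA field,
#' bins it by HR, subtracts the individual baseline, smooths, and detects
#' the DDFA thresholds; then estimates the comparison thresholds for every
#' method whose inputs are available (alpha1 always; HRmax when `hr_max` is
#' given; lactate when a curve is given). Per-method failures degrade to
#' undefined thresholds, never abort the run.
#'
#' @param series An [rri_series()] (raw; preprocessing is applied here).
#' @param lactate Optional lactate curve (`step_t`, `lactate`, `hr`).
#' @param hr_max Optional measured maximal HR (BPM).
#' @param config A [run_config()].
#' @return A list of class `threshold_report`: `thresholds` (one row per
#'   method), `filter_report`, `curve` (the smoothed exponent curve),
#'   `field` (the DDFA field), `alpha1` (the alpha1 track), `config`.
#' @export
run_pipeline <- function(series, lactate = NULL, hr_max = NULL,
                         config = run_config()) {
  series <- preprocess_rri(series,
    lo = config$lo, hi = config$hi,
    kernel = config$kernel, frac = config$frac, exclude = config$exclude
  )
  field <- ddfa(series,
    scales = ddfa_scales(config$n_scales, config$s_min, config$s_max),
    seg_factor = config$seg_factor, hop = config$hop,
    anchor = config$anchor, hr_mean = config$hr_mean,
    calibrate = config$calibrate
  )
  profile <- bin_by_hr(field)
  base <- compute_baseline(profile, n_bins = config$baseline_bins)
  curve <- smoothed_alpha(profile, base, kernel = config$smooth_kernel)
  results <- list(ddfa_thresholds(curve,
    run = config$run, level = config$level, skip = config$baseline_bins
  ))

  a1 <- tryCatch(
    alpha1_track(series,
      window_s = config$window_s, step_s = config$step_s,
      lambda = config$lambda, scales = config$alpha1_scales,
      order = config$order, calibrate = config$calibrate
    ),
    error = function(e) {
      warning("alpha1 track unavailable: ", conditionMessage(e), call. = FALSE)
      NULL
    }
  )
  if (!is.null(a1)) {
    results <- c(results, list(
      dfa_alpha1_thresholds(a1, band = config$band, gap_n = config$gap_n)
    ))
  }
  if (!is.null(hr_max)) {
    results <- c(results, list(
      hrmax_thresholds(hr_max, p1 = config$p1, p2 = config$p2)
    ))
  }
  if (!is.null(lactate)) {
    results <- c(results, list(tryCatch(
      lactate_thresholds(lactate),
      error = function(e) {
        warning("lactate thresholds unavailable: ", conditionMessage(e),
          call. = FALSE
        )
        new_threshold_result("lactate", NA, NA, list(reason = conditionMessage(e)))
      }
    )))
  }

  out <- list(
    thresholds = dplyr::bind_rows(results),
    filter_report = filter_report(series),
    curve = curve,
    field = field,
    alpha1 = a1,
    config = config
  )
  class(out) <- "threshold_report"
  out
}

#' @export
print.threshold_report <- function(x, ...) {
  cat("<threshold_report>\n")
  print(tibble::as_tibble(x$thresholds))
  invisible(x)
}

#' Write a threshold report as JSON
#'
#' Serialises the per-method thresholds, the filter report and the smoothed
#' exponent curve at full precision.
#'
#' @param report A `threshold_report` from [run_pipeline()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  payload <- list(
    schema = "ddfathresh-report/1",
    thresholds = report$thresholds,
    filter_report = report$filter_report,
    curve = report$curve
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' Read a lactate CSV
#'
#' Expects columns `step_end_s`, `lactate_mmol_l`, `hr_bpm` (or already
#' tidy `step_t`, `lactate`, `hr`).
#'
#' @param path CSV path.
#' @return A tibble with columns `step_t`, `lactate`, `hr`.
#' @export
read_lactate <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (all(c("step_end_s", "lactate_mmol_l", "hr_bpm") %in% names(df))) {
    df <- dplyr::rename(df,
      step_t = "step_end_s", lactate = "lactate_mmol_l", hr = "hr_bpm"
    )
  }
  stopifnot(all(c("step_t", "lactate", "hr") %in% names(df)))
  df
}

#' Reference threshold table of a 15-subject incremental test
#'
#' Per-subject aerobic (T1) and anaerobic (T2) threshold estimates, in BPM,
#' from an incremental cyclo-ergometer study of 15 subjects: benchmark
#' lactate thresholds (`lt*`), ventilatory thresholds (`vt*`), fixed HRmax
#' percentages (`hrmax_*`), the short-term-DFA regression method
#' (`alpha1_*`) and the dynamical-DFA method (`ddfa_*`). Shaped for
#' [compare_table()].
#'
#' @return A 15-row tibble.
#' @export
reference_thresholds <- function() {
  path <- system.file("extdata", "incremental_test_thresholds.csv",
    package = "ddfathresh", mustWork = TRUE
  )
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}
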