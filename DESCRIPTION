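Package: ddfathresh
Title: Exercise Thresholds from Dynamical Detrended Fluctuation Analysis of
    RR Intervals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates the aerobic and anaerobic exercise thresholds from
    beat-to-beat RR-interval recordings using time- and scale-resolved
    detrended fluctuation analysis (dynamical DFA). Includes RR-interval
    artifact filtering, second-order DFA fluctuation functions in maximally
    overlapping windows, finite-difference scaling exponents alpha(t, s),
    heart-rate binning with individual baseline subtraction, and threshold
    detection from the smoothed exponent curve. Provides three comparison
    estimators (windowed short-term DFA alpha1 with smoothness-priors
    detrending, fixed percentages of maximal heart rate, and the two-slope
    blood-lactate method), an agreement-statistics toolkit (permutation
    Pearson tests, Bland-Altman limits of agreement, Monte-Carlo slope
    tests, BCa bootstrap intervals), and a synthetic generator of
    incremental-exercise RR-interval series with planted scaling-exponent
    schedules for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    boot,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Matrix,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr
Suggests:
    optparse,
    yaml,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
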