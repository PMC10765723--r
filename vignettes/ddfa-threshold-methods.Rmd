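---
title: "Exercise thresholds from dynamical correlation properties of heart rate variability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Exercise thresholds from dynamical correlation properties of heart rate variability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

Beat-to-beat fluctuations of the RR interval carry information about
autonomic cardiac control. At rest they resemble long-range-correlated
1/f noise: the detrended fluctuation analysis (DFA) exponent — the
log-log slope of the fluctuation function F(s) against window size s —
sits near 1. As exercise intensity rises, vagal withdrawal and
sympathetic drive progressively destroy these correlations; at high
intensity the series becomes anticorrelated (exponent well below 0.5).
This package estimates the aerobic and anaerobic thresholds from the
*location on the heart-rate axis* of that collapse.

The estimator is time- and scale-resolved ("dynamical") DFA. For each
integer scale $s$ on a grid of 20 logarithmically spaced values in
$[5, 64]$ beats (rounded and de-duplicated, so slightly fewer than 20
distinct scales), a segment of $l = 5s$ beats slides along the series
one beat at a time. Within each segment the second-order DFA fluctuation
function is evaluated at $s-1$, $s$, $s+1$ from maximally overlapping
windows (stride 1), and the local exponent is the three-point
finite-difference derivative of $\tilde F = \log F$ on the non-uniform
log-scale grid,

$$\alpha(t, s) \approx
 \frac{h_-^2 \tilde F(s{+}1) + (h_+^2 - h_-^2)\tilde F(s) - h_+^2 \tilde F(s{-}1)}
      {h_- h_+ (h_+ + h_-)},$$

with $h_- = \log s - \log(s{-}1)$ and $h_+ = \log(s{+}1) - \log s$. This
stencil is exactly the derivative of the Lagrange quadratic through the
three points; on a uniform grid it reduces to the central difference, and
it is exact for any $\tilde F$ quadratic in $\log s$.

Thresholds are then read from the exponent as a function of heart rate:
every defined $\alpha(t,s)$ is assigned to the nearest-integer-HR bin of
its segment's mean HR ($60000/\overline{RR}$; ties round half to even); a
per-scale individual baseline $b(s)$ — the mean over the 25 occupied bins
with the lowest HR — is subtracted to remove the subject's resting
scaling level and any residual per-scale bias; the result is averaged
over scales and smoothed with a 10-bin mean filter, giving
$\tilde\alpha(\mathrm{HR})$. The aerobic threshold is the first bin where
$\tilde\alpha$ drops below 0 and remains negative for at least 10
consecutive occupied bins; the anaerobic threshold uses the same
stability rule at the level $-0.5$, the drop from baseline-level
correlation into anticorrelated dynamics. Either threshold may be
undefined; unstable crossings are kept in the diagnostics. The search
begins above the baseline region — past the 25 skipped bins and past the
highest bin any scale's baseline used — because there
$\tilde\alpha \approx 0$ holds *by construction* and sign flips carry no
information. Since a run below $-0.5$ is also a run below $0$, the two
thresholds are automatically ordered.

## Comparison estimators

*Short-term exponent regression.* The conventional short-term exponent
$\alpha_1$ (scales 4–16 beats) is evaluated every 5 s in trailing 120-s
windows, after smoothness-priors detrending of the window's intervals
(the trend solves $(I + \lambda^2 D_2^\top D_2)\,\tau = z$ with
$\lambda = 500$; $\lambda = 0$ degenerates to zero output). The decline
of $\alpha_1$ with HR is localised algorithmically: select points with
$0.5 \le \alpha_1 \le 0.75$, bridge gaps of at most 4 out-of-band points,
keep the largest region, and greedily extend it one point at a time from
either end while the regression's $R^2$ improves. The fitted line's
crossings of 0.75 and 0.5 give the two thresholds; a non-negative slope
leaves them undefined. The DFA polynomial order inside this track
defaults to 2 for consistency with the dynamical engine; order 1 is
available for strict replication of the classic short-term exponent.

*Maximal-HR percentages.* 70% and 85% of a measured HRmax, the fractions
most wearables assume.

*Two-slope lactate construction.* The aerobic threshold is where the
lactate curve first rises 0.3 mmol/L above its minimum (linearly
interpolated between step-end samples on the rising side). Line A passes
exactly through that interpolated point and the following measurement
(two points determine it; no regression). Line B is the least-squares fit
through the points of every exercise step whose increment exceeds
0.8 mmol/L, each qualifying step contributing both endpoints and shared
points counted once. The anaerobic threshold is the crossing of the two
lines; parallel lines or fewer than two qualifying points leave it
undefined. Times convert to BPM through linear interpolation of the
30-s-averaged HR trace.

## Numerical design

The sliding-window computation is exact and fast. For a fixed window
length $w$, the residual sum of squares of an order-2 fit in every
window equals the moving sum of squared profile values minus squared
moving dot products with an orthonormal polynomial basis — three
convolutions per scale. Because per-segment mean subtraction changes the
profile only by constant and linear terms inside any window, which the
quadratic fit annihilates, per-window residuals computed once on the
global profile are identical to segment-wise recomputation, and segment
fluctuation functions reduce to moving averages of per-window mean
squared residuals. The profile is preconditioned by subtracting its own
global polynomial fit of the detrending degree (also annihilated
window-wise), which removes the catastrophic cancellation the raw
cumulative sum would cause; a brute-force per-window `lm()` oracle agrees
to better than $10^{-10}$ relative error even mid-exercise.

On a finite scale range DFA sits in a crossover regime: with the
textbook normalisation, white noise measures a 5–64-beat slope near
0.57, and the local exponent at $s = 5$ exceeds 1. We therefore
calibrate the fluctuation function by the *exact* white-noise
expectation of the window residuals,
$E[\mathrm{RSS}] = \operatorname{tr}(L^\top (I - P) L)$ with $L$ the
cumulative-sum operator and $P$ the polynomial hat matrix, so that
uncorrelated increments scale exactly as $s^{1/2}$ at every scale. With
this calibration the mean dynamical exponent recovers planted exponents
0.5, 0.9 and 1.0 within ±0.05 and varies by less than 0.15 across the
scale grid. The raw convention remains available (`calibrate = FALSE`).
Masking is explicit throughout: segments that do not fit are absent from
the long-format field, never zero-filled, and a zero fluctuation (log
undefined) yields `NA`.

For the even smoothing kernel the extra tap goes to the left of the
centre bin; windows shrink at the curve ends rather than reflecting
data. The median artifact filter likewise shrinks its window
symmetrically at the series ends (minimum 3 beats) and computes medians
over retained beats only, in one pass, so that a range-filtered spike
cannot corrupt its neighbours' medians. Manual exclusions — standing in
for removals by visual inspection, which cannot be automated — are an
explicit index list.

## The synthetic generator

Real incremental-test recordings are not distributable, so validation
rests on a generator that emulates their statistical structure: a
monotone HR ramp (default 110 → 200 BPM over 25 min), beat-to-beat
Gaussian fluctuations whose local scaling exponent follows a prescribed
exponent-versus-HR schedule (default: 1.0 below 145 BPM, declining
linearly to 0 at 195 BPM), and injected missed-beat (two intervals
merged) and extra-beat (one interval split uniformly) artifacts.

Fluctuations are Fourier-synthesised with a power-law spectrum
$f^{-\beta}$. The spectral slope is calibrated so that the *expected
in-band* DFA exponent — computed exactly from the trace form
$E[\mathrm{RSS}] = \operatorname{tr}(K\Sigma)$ with the process
autocovariance $\Sigma$ — equals the requested exponent. This honours
the generator's contract (the DFA exponent over scales 5–64 equals the
target) across the whole range $(0, 1.2]$, including the anticorrelated
regime where the asymptotic and in-band exponents differ substantially;
the finite scale range cannot resolve exponents below about 0.03.
Nonstationarity is produced by overlap-adding windows of twice the
60-beat cross-fade length at half-window hop with triangular power
weights, which preserves local variance through every cross-fade and
avoids directional bias in the schedule's position. Fluctuation
amplitude defaults to 15 ms at the ramp start and scales with the mean
interval (a constant coefficient of variation), mirroring the
contraction of beat-to-beat variability during exercise; artifact-free
intervals stay inside 200–2000 ms, so every preprocessing removal is
attributable to a planted artifact.

What the generator does *not* emulate: respiratory coupling, baroreflex
dynamics, ectopy morphology, step-wise power increments (the HR ramp is
smooth), or inter-subject variability. Passing the planted-recovery
tests therefore shows that the pipeline inverts its own statistical
model of exercise HRV, not that it is validated on physiological
recordings.

## Statistics

Agreement between estimators follows the usual small-sample toolkit:
one-sided permutation tests for the Pearson correlation (add-one
estimator, never exactly zero), Bland–Altman mean difference with
95% limits of agreement at ±1.96 *sample* standard deviations,
a Monte-Carlo test for trend that compares the observed absolute
regression slope of the differences against slopes of iid normal
differences with the observed standard deviation at the same abscissae,
Shapiro–Wilk for normality of the differences (delegated to `stats`),
and BCa bootstrap intervals (delegated to `boot`) resampling subjects as
pairs. The slope test's abscissa defaults to the pairwise mean of method
and benchmark (the Bland–Altman convention); regressing on the
benchmark alone is available by flag, as the choice is genuinely open.
All resampling honours an explicit seed, and calibration simulations in
the test suite confirm type-I error within [0.03, 0.07] at nominal 0.05.

## Validation problem sizes

The shipped tests and the acceptance script use series of $10^4$ beats
for estimator calibration, 25-minute synthetic exercise recordings with
10 generator seeds for planted-threshold recovery, and 500 replicates
(499 resamples each) for the type-I calibration of the resampling tests.
With those sizes the recovered thresholds centre within about 2 BPM of
the planted knots with a per-seed spread of 2–4 BPM.

## Known limitations

- On a knife-edge schedule (exponent exactly at baseline until the
  aerobic knot), the first threshold's stability rule can fire a few BPM
  early when correlated estimator noise dips the plateau below zero; the
  10-bin run requirement bounds but does not eliminate this.
- The anaerobic rule reports the first bin of the stable run, which sits
  one to three bins above the $-0.5$ crossing under noise.
- Reported thresholds are integer BPM, matching how such tables are
  printed; sub-BPM information is available in the diagnostics.
- The per-scale baseline requires 25 occupied low-HR bins; recordings
  that start at high intensity fall back to all available bins with a
  warning, weakening the baseline.
- The lactate construction assumes at least four step-end samples and a
  curve that eventually rises; pathological curves leave thresholds
  undefined rather than guessing.
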