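---
title: "Community mobility and gait from raw sensor streams: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Community mobility and gait from raw sensor streams: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mobgait)
```

## The problem

Community mobility of older adults — how far, how often and how smoothly a
person moves through their life space — is an established marker of
functional health and fall risk. `mobgait` implements a complete analysis
chain for a one-day protocol in which each participant carries a trunk-worn
smartphone recording

* GPS fixes at one per minute, and
* triaxial trunk acceleration (vertical VT, mediolateral ML,
  anteroposterior AP) at 50 Hz,

over roughly eight waking hours, starting away from home (e.g. at a
community centre). From those two raw streams the package derives eight
life-space metrics and sixteen gait metrics per subject, compares faller
and non-faller groups non-parametrically, and classifies faller status with
three model families under three feature conditions. A synthetic cohort
generator with fully recorded ground truth stands in for the study data,
which are not publicly deposited.

## Life-space metrics

Stays are detected by the incremental-centroid run method: fixes join a run
while they remain within 100 m of the run's running centroid, and runs
spanning at least 15 minutes become stays (both constants from the study
protocol). Stay locations are grouped by density clustering (DBSCAN with a
100 m neighbourhood); *home* is the cluster with the largest cumulative
dwell time, ties broken by earliest arrival (the home rule is not defined
by the protocol and is configurable). The metrics are:

* **Activity space** $A_{\mathrm{MCP}}$: area of the minimum convex polygon
  of all fixes, by the closed shoelace formula on the hull of the locally
  projected points. The printed source formula omits the wrap-around term
  and absolute value; the standard closed form is used.
* **SDE compactness** $4\pi A_{\mathrm{SDE}} / P_{\mathrm{MCP}}^2$, where
  $A_{\mathrm{SDE}} = \pi\sigma_1\sigma_2$ is the area of the one-standard-
  deviation principal-axis ellipse (the SD multiplier is unstated in the
  source; 1 SD chosen) and $P_{\mathrm{MCP}}$ the hull perimeter.
* **Visited places** $N_{places}$: distinct non-noise stay clusters,
  excluding home (whether the study counted home is unstated; exclusion is
  the default and configurable).
* **Time outside home** $T_{outside}$: trajectory span minus home dwell.
* **Maximum distance** $D_{max}$ and **cumulative path**
  $D_{total} = \sum_i d_{geo}(P_i, P_{i+1})$, both via Vincenty's inverse
  on the WGS84 ellipsoid.
* **Turning radius**: per consecutive triplet the circumradius
  $R = \ell / (2\sin\theta)$ with $\ell$ the chord between the outer points
  (this is the law-of-sines circumradius, so the estimator recovers a
  circle's radius exactly); finite values are averaged over travel fixes.
  Whether the study averaged or summed is unstated.
* **K radius of gyration**: implemented *exactly as printed* —
  $R_g = \sqrt{\tfrac1n\sum_i (d_i - \bar d)^2}$, the population SD of
  per-fix distances to home — although the conventional radius of gyration
  is the RMS distance about the centroid (`conventional = TRUE` provides
  the latter).

Areas and angles are computed in a local equirectangular projection about
the point-cloud centroid (exact inverse; adequate below ~100 km). Stay
detection, stay clustering and the GPS speed series use a planar
approximation with WGS84 curvature radii, which differs from the full
geodesic by under 0.1% at sub-10 km scales (asserted by test); all distance
*metrics* use full Vincenty.

## Gait metrics

All three axes are band-passed at 0.5–20 Hz with a zero-phase order-4
Butterworth. Mechanically this is done by multiplying the spectrum of the
odd-reflection-padded signal by the squared magnitude response of the
bilinear-designed digital filter — numerically the same pass/stop behaviour
as forward–backward IIR filtering, without start-up transients.

Steps are local maxima of the filtered vertical axis at least 0.5 (the
study's threshold, unit left unstated there; interpreted as m/s² and
configurable) with pairwise separation at least fs/2 samples, higher peak
winning on conflict. Walking bouts are maximal peak runs with inter-peak
gaps ≤ 2.5 s (the continuity rule; unstated in the source) containing at
least 30 peaks and co-occurring with mean GPS speed below 5 km/h (vehicle
exclusion).

Step times feed the timing metrics exactly as printed: mean step time;
CV $\sigma_T/T_{mean}$ (population SD); step regularity $1/\sigma_T$
(capped when $\sigma_T$ is numerically zero); symmetry
$1 - \overline{|T_{i+1}-T_i|}/T_{mean}$. Stride regularity — named but not
defined in the source beyond a citation of autocorrelation procedures — is
the normalised unbiased autocorrelation of the vertical axis at the stride
lag ($2T_{mean}$), clamped to $[-1, 1]$. Walking speed uses the study's
fixed 0.7 m step length over the pooled qualifying-bout time. RMS and
histogram entropy (32 equal-width bins, natural log; both unstated) are
computed per axis; the harmonic ratio is the even:odd stride-harmonic
energy ratio with the *same* orientation on every axis, as printed (gait
literature inverts ML; `invert = TRUE` exists).

### Sub-sample step times

At 50 Hz, integer peak indices quantise step times to ±10 ms, which is the
same order as the step-time SD at a CV of 1–3%. The pipeline therefore
refines each peak to sub-sample resolution by aligning the waveform around
it with the average peak waveform (one Woody realignment round, then a
Gauss–Newton shift fit against a spline-interpolated template). Refinement
runs on the **raw** vertical axis: the band-pass impulse response extends
over ±2 s and mixes neighbouring-step content into each apex, which was
measured to shrink estimated step-time SD by ~5% if the filtered axis is
used. With refinement, the noiseless recovery bias of $T_{mean}$ and CV is
below 5% across cadences 0.6–1.4 s and CVs 0.01–0.08 (acceptance
criterion 3). Under sensor noise the refinement floor is ~1–3 ms per step;
at a CV of 0.01 and slow cadence that still inflates estimated CV by
5–13% — an intrinsic limit of a 50 Hz chain, which is why the recovery
grid is run noiseless.

### Harmonic-ratio estimation

Step-timing jitter broadens the spectral lines at the stride harmonics in
proportion to the harmonic index. A strict nearest-bin readout then samples
only the fluctuating line centre and was unstable by a factor ~2 on
50-step bouts; the estimator instead integrates the periodogram over
±0.35 stride frequencies around each of the first 20 harmonics
(`band_frac = 0` restores nearest-bin). On steady constructed signals the
two agree; on jittered bouts the banded estimator recovers the generator's
ratio to a few percent.

## The synthetic cohort generator

The generator is first-class, tested code: it is the only way to validate
the chain end-to-end, because the study data are unavailable.

**Gait signals** are sums of cosine harmonics of a stride phase
$\theta(t)$ that advances by $2\pi$ per step. Because every component is a
cosine of $m\theta/2$, every harmonic has an extremum exactly at each step
event, so peaks stay at the planned (jittered) step times for any harmonic
mix. Jitter is drawn per step (SD = CV × mean, alternating ±asymmetry,
floored at 0.52 s ≈ 115 steps/min — faster walking is running, and the
floor also keeps every true interval above the detector's fs/2
separation so the process is identifiable). Between events the phase
follows a C³ smoothstep with the rate pinned at the nominal cadence, so
the waveform *shape* around each event is identical regardless of jitter —
a linear phase would put a rate kink at each event and bias sub-sample
refinement. Bouts are framed by a half-step, a constant trough hold and a
2 s raised-cosine taper, which suppresses band-pass ringing at walk/rest
transitions; rests are Gaussian noise at `noise_sd`.

**Even:odd energy.** The profile's `even_odd_energy_ratio` is realised
*within the 0.5–20 Hz analysis band*: odd energy goes to stride harmonics
{1,3,5} (or {3,5,7} when the stride fundamental sits at or below the
0.5 Hz edge, whose inverse-gain-inflated amplitude would otherwise ring
for seconds past the bout) with post-filter amplitudes along
$(2,-3,1)/\sqrt{14}$ resp. $(3,-5,2)/\sqrt{38}$ — the unique directions
whose value *and* curvature cancel at every step event. Peak heights and
sharpness therefore stay at the even base regardless of the odd budget.

A consequence worth stating plainly: the published faller harmonic-ratio
medians (~0.7–0.8) are **jointly infeasible** with the published faller
step time (1.24 s) under the study's own fixed 0.5 peak threshold —
odd-dominant energy at slow cadence necessarily creates above-threshold
mid-step structure outside the detector's blocking radius. The default
profiles therefore keep the groups' HR *contrast* (3.36 vs 2.46, same
ratio as printed) at detectable levels; every significant group difference
reproduces the published direction, but HR magnitudes are not the printed
ones.

**Trajectories** place `n_places` dwell locations around home (pairwise
separation enforced so stays do not merge), start away from home, dwell
≥16.5 min per place (passing the 15-min gate), travel at `trip_speed_kmh`,
and end with a long home dwell; fixes are sampled per minute with 8–10 m
jitter, far below the 100 m stay radius. The planned stay log, home, and
farthest-point distance are returned as ground truth.

**Cohorts.** Default group profiles target the published group contrasts:
step time 0.73 vs 1.24 s, CV 0.030 vs 0.042, time outside 1.63 vs 1.30 h,
smaller faller activity space and maximum distance, higher faller RMS,
lower faller harmonic ratio. Per-subject parameters are drawn around the
group values (`heterogeneity`, default 0.25; lognormal dispersions chosen
so within-group spreads are comparable to the published IQRs, which are of
the order of the medians). Without heterogeneity every classifier is
trivially perfect; with it, the qualitative ordering of the published
classification results — GPS-only weakest, accelerometer strong, combined
strongest — emerges from the generated world. Per-subject RNG seeds are
drawn through R's generator from the cohort seed; an arithmetic seed
schedule measurably inflated between-group variance under the null and was
replaced.

**What a green test does not establish.** The generator emulates dwell/
travel structure, cadence, jitter, band-limited harmonic content and
sensor noise. It does not emulate GPS dropouts or multipath, urban road
networks, vehicle vibration, device re-orientation, multi-day variation,
or any physiological correlation structure between gait and mobility
parameters beyond their group labels. Passing tests certify that the
*chain recovers a known stated world*, not that the published accuracies
would replicate on real data.

### Null calibration of the comparison

With identical group profiles and independent per-subject seeds the two
groups are exchangeable by construction, so the Mann–Whitney comparison is
exactly level; this was verified both by label permutation within
generated cohorts and by independent seed blocks (overall rejection
~0.045–0.055 at a nominal 0.05). Note that a per-variable rejection-rate
estimate from 200 cohorts has binomial SE ~0.015, so individual variables
will fall outside a ±0.02 band in any given run even under perfect
calibration — the acceptance test reports this honestly for its frozen
seed block. Two generator seed-derivation bugs that *did* break
exchangeability (arithmetic subject-seed schedules; positional stream
correlation across nearby cohort seeds) were caught by exactly these
diagnostics and fixed.

## Group statistics

Each variable gets a per-group Shapiro–Wilk screen and a two-sided
Mann–Whitney U comparison: exact (via the exact U distribution) for
combined n ≤ 12 without ties, otherwise the normal approximation with tie
and continuity correction. Medians and IQRs use linear-interpolation
quartiles (type 7); no multiple-testing correction by default, matching
the per-variable α = 0.05 reporting (a Holm option exists).

## Classification

Three models — random forest, C-SVM, and KNN — are tuned over exactly the
published grids (48, 27 and 40 combinations) by leave-one-out grid search
on a stratified 70% training split and evaluated once on the held-out 30%.
Choices the source leaves open, resolved here:

* Grid-search scoring is macro-F1 of the **pooled** LOOCV predictions
  (per-fold F1 on single observations is degenerate).
* Missing values: median imputation; standardisation: z-score; both fit on
  training data only. SVM/KNN refit them inside every LOOCV fold; for the
  random forest the scaler is immaterial (trees are invariant to monotone
  transforms) and imputation medians come from the whole training split.
* The LOOCV accuracy SD reported alongside test accuracy is the sample SD
  of the winning configuration's per-fold 0/1 accuracy indicators.
* ROC/AUC come from the test-split scores of the single final fit (vote
  fraction for RF, decision value for SVM, weighted vote for KNN), without
  retraining; AUC is the rank statistic.
* The faller class is positive throughout; grid ties go to the first row
  in enumeration order; the 70/30 split is stratified.
* Indefinite SVM kernels (sigmoid, some polynomial settings) make the dual
  non-convex; the QP is solved after shifting the spectrum just past
  positive semidefinite, a standard convexified surrogate.
* RF tree counts nest — the first *k* trees of a 300-tree forest are a
  valid *k*-tree forest — so the three tree-count settings share one pass
  of the compiled LOOCV grid search.

## Numerical choices and degenerate inputs

* Population SD (divisor n) everywhere the source is silent.
* Step regularity capped at 10⁶ 1/s when σ_T < 1 µs.
* Harmonic ratio capped at 10⁶ with a `capped` attribute when odd energy
  is numerically zero; entropy of a constant signal is 0.
* Fewer than 3 distinct/non-collinear points give zero hull area with a
  warning; zero-variance clouds give zero compactness.
* All-noise stay tables raise an explicit no-home error; a trajectory
  needs ≥ 2 fixes.
* Stay intervals are half-open [arrival, departure); timestamps are UTC
  seconds.

## Known limitations

* Single-day, single-subject-day streams; no multi-day stitching.
* The step detector cannot see intervals below fs/2 (0.5 s); the generator
  respects this by construction, real data may not.
* Harmonic-ratio magnitudes depend on bout length and jitter; only
  contrasts should be interpreted.
* The published headline accuracies (97/95/74%) are not reproduction
  targets — they depend on the unreleased dataset; the package reproduces
  the qualitative ordering on synthetic cohorts.

## A worked example

```{r example, eval = FALSE}
spec <- default_cohort_spec(n_per_group = 20, seed = 1)
tab <- cohort_features(spec)          # 40 subjects x 24 features
cmp <- compare_all(tab)               # medians/IQR, U, p per variable
head(cmp[order(cmp$p_value), c("variable", "median_1", "median_2",
                               "p_value")])
rep <- fit_evaluate(tab, "combined", "rf", split_seed = 42)
rep
```
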