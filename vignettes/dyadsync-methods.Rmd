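---
title: "Quantifying dyadic interpersonal synchrony and classifying dyad type"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying dyadic interpersonal synchrony and classifying dyad type}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dyadsync)
```

## The problem

Autistic adults differ from non-autistic adults in how they *adapt* to a
conversation partner: how much and how quickly facial expressions, head
motion and body motion follow the partner's. `dyadsync` implements a
complete pipeline for quantifying this reciprocity from per-frame behavioral
time series and for asking whether it carries diagnostic signal. The unit of
analysis is the *dyad*: a pair of interactants who conversed for two
ten-minute tasks (a hobbies conversation and a collaborative meal-planning
task) recorded at 30 frames per second. A dyad pairing one autistic (ASD)
and one non-autistic (TD) adult is a *mixed* dyad; a TD-TD pair is a
*control* dyad. Both interactants of a dyad receive the same classification
label — the classifier judges the interaction, not the individual, which
mirrors a diagnostic setting where one interactant is effectively the
clinical rater.

The pipeline has five stages, each an exported module surface:

1. **Signals** — OpenFace-style action-unit (AU) intensities and head-pose
   angles, and motion-energy analysis (MEA) of video frames within regions
   of interest (`motion_energy_series()`).
2. **Synchrony** — windowed cross-lagged correlations, per-window peak
   ("maximum synchrony") profiles, their seven summary statistics, and
   leading/following decomposition (`windowed_cross_lagged_correlation()`,
   `interpersonal_following_summary()`).
3. **Features** — five base feature sets per participant
   (`assemble_feature_set()`).
4. **Classification** — dyad-grouped, stratified, repeated nested
   cross-validation around class-weighted linear SVMs optimized on balanced
   accuracy (`nested_cv_run()`).
5. **Inference** — dyad-paired permutation tests, decision-score stacking,
   feature-importance maps (`permutation_test()`, `stack_models()`,
   `importance_map()`).

Because the clinical recordings such a study rests on cannot be shared, the
package carries a first-class synthetic generator (`simulate_study()`)
whose outputs exercise every stage end to end.

## Motion energy

MEA quantifies movement as the grayscale pixel change between consecutive
frames inside a fixed region of interest (head or upper body), which is a
valid movement proxy when the camera and lighting are fixed. Frames are
converted with the BT.601 luminance weights (0.299, 0.587, 0.114); absolute
differences below a noise threshold (default 10 gray levels, configurable)
are suppressed as sensor noise; the remaining changes are summed and, by
default, divided by the ROI pixel area so differently sized head and body
regions are comparable (a raw-sum mode exists). The first frame's energy is
defined as 0 so the series keeps the length of its stack. ROIs are given in
0-based, half-open pixel coordinates; no published ROI geometry exists, so
ROI placement is user configuration.

## Windowed cross-lagged synchrony

For two equal-length series the core statistic is a windows-by-lags grid of
Pearson correlations: window length `W`, hop `step`, and lags `k` from
`-L` to `+L` frames. The sign convention is fixed pipeline-wide and
asserted in tests: **positive lag means the second argument trails the
first**. Windowing is *full-overlap*: a window is only placed where the
lagged segment at the extreme lags still lies entirely within the series,
so no cell is ever computed against zero-padding; the number of windows is
exactly `floor((T - W - 2L)/step) + 1`.

Each window is then reduced to its peak correlation — by default the most
positive value (`max_positive`), reading synchrony as in-phase adaptation;
a `max_absolute` rule is available. Restricting the scan to nonnegative
lags yields the *following* profile of the second series (it trails the
first); nonpositive lags yield *leading*; lag 0 belongs to both halves,
since a simultaneous match is both. A participant's **following summary**
— the degree of imitating the partner — is the peak profile of
`windowed_cross_lagged_correlation(partner, self)` over nonnegative lags,
reduced to seven statistics: mean, median, sample (n−1) standard deviation,
minimum, maximum, skewness (g1) and excess kurtosis (g2). Defining it on
the partner-first matrix makes the role swap exact: exchanging the two
participants exchanges their summaries identically. Shape moments of a
constant profile are undefined and propagate as `NA`; imputation happens
only inside the cross-validated training loop, never at assembly.

Three decisions here were genuinely open and are resolved as package
conventions: correlations are summarized on the raw r scale (no Fisher-z);
the peak rule defaults to `max_positive`; and window/step/lag defaults are
5 s / 1 s / ±2 s for facial and head channels and 10 s / 2 s / ±5 s for the
slower body channel — values in line with the windowed cross-lagged
correlation literature, all configurable per channel group. The
configuration validator accepts `W = 2L` (the body default at any frame
rate) and rejects windows shorter than that.

*Intrapersonal* coordination cross-correlates one participant's own global
head movement with their body motion energy, pooling both lag directions.
A pooled peak taken from a single matrix is not exactly symmetric in its
arguments once `step > 1` (the swapped matrix samples different
window-lag pairs), so `intrapersonal_summary()` scans both argument orders
per window and takes the better peak — making the statistic exactly
symmetric by construction.

Missing data are handled before synchrony: frames with tracking confidence
below 0.8 are invalidated; interior gaps of at most 10 frames (a third of a
second at 30 fps) are linearly interpolated and revalidated; longer gaps
stay invalid and any window-lag cell with fewer than 80% valid overlapping
pairs is missing. A channel whose *pre-interpolation* invalid fraction
exceeds 10% is flagged unusable — the extent of missingness, not its
reparability, decides exclusion — and every downstream summary of it is
`NA` with a reason attached.

As a chance reference, `pseudo_dyad_baseline()` scores random pairings of
participants who never interacted (real partners are never paired),
yielding a surrogate null distribution for observed synchrony.

## Feature sets and labels

Each participant's feature vector concatenates both tasks:

| model     | content                                              | width |
|-----------|------------------------------------------------------|-------|
| FACEsync  | following summaries of 12 retained AUs × 7 × 2       | 168   |
| HEADsync  | global head movement, pitch, yaw, roll × 7 × 2       | 56    |
| BODYsync  | body motion energy × 7 × 2                           | 14    |
| INTRAsync | intrapersonal head–body × 7 × 2                      | 14    |
| MovEx     | total head movement, total body movement, expressiveness × 2 | 6 |

The retained-AU set is forced to 12 channels by the FACEsync width; which
12 survive missingness screening in real data is not recoverable, so the
default set (AU01, 04, 06, 07, 10, 12, 15, 17, 20, 25, 26, 45) covers the
AUs most prominent in facial-synchrony work and is overridable. Global
head movement is the per-frame Euclidean norm of the (pitch, yaw, roll)
change vector. Total movement and expressiveness are valid-frame *rates*
(sums divided by valid-frame counts), so partial tracking loss does not
deflate them. Assembly enforces the expected widths and fails fast on any
configuration that breaks them.

Cohort tables compare the diagnosis groups with Wilcoxon rank-sum tests
(normal approximation) for age and the two IQ measures,
Benjamini–Hochberg-adjusted across the three tests, and a Yates-corrected
chi-square for sex by group. A Welch t-test variant is provided for users
who prefer a variance-robust parametric test.

## Nested cross-validation

Folds are assigned to *dyads*, never individuals, so both interactants
always share a fold at every level. Assignment is stratified by largest
remainder: each class spreads its dyads as evenly as possible over folds,
remainders going to the currently lightest folds, which keeps per-fold
class counts within one dyad of proportionality and per-fold totals
balanced (44 dyads over 11 folds gives exactly 4 dyads — about 9% of 88
participants — per test fold). The outer level (11 folds × 10
permutations by default) only ever measures generalization; per outer
training set, features are z-standardized, then median-imputed, and the
regularization constant is chosen by mean balanced accuracy over an inner
10-fold dyad-grouped CV — all fitted strictly on training rows, which a
dedicated test asserts by corrupting held-out rows and checking the fitted
fold is bit-identical. The C grid defaults to 11 points log-spaced over
2⁻⁶…2⁴, ties resolved toward stronger regularization. SVMs are
class-weighted (inverse class frequency, normalized to mean 1) linear
C-SVCs fitted through libsvm via `e1071`; decision scores are oriented so
positive always points at the positive class. Out-of-fold scores are
aggregated across outer permutations by their mean and thresholded at 0 —
the aggregation rule is a package convention, as is the preprocessing
order. Metrics are sensitivity, specificity, their mean (balanced
accuracy, the optimization criterion throughout), rank-based AUC with
midrank ties, PPV and NPV.

Significance uses a dyad-paired permutation test: dyad-type labels are
shuffled across dyads (members always move together, class sizes preserved
exactly), the full nested CV is rerun, and
`p = (1 + #{null BAC ≥ observed}) / (1 + n_perm)` — the add-one estimator,
which can never return 0. A full analysis uses 1000 permutations at
α = 0.05 (results are also annotated at the stricter 0.005); a
reduced-cost mode (one outer permutation per rerun, optionally a
single-value C grid that skips inner tuning) exists for desk-scale
calibration studies. Stacking wraps a Gaussian-kernel SVM over the base
models' out-of-fold decision scores in the identical CV framework, with
the kernel width grid set by the median heuristic times
{0.25, 0.5, 1, 2, 4}. Feature importance is reported as the
cross-validation ratio (mean weight across all CV models divided by its
standard error; infinite ratios from zero SEs are surfaced, not hidden)
and sign-based consistency (largest fraction of CV models agreeing on a
weight's sign, which is 1 for perfectly stable features and 0.5 at chance).

## The synthetic generator

`simulate_study()` emulates the study conditions: a roster of 28 mixed and
16 control dyads (88 participants), two tasks of 600 s at 30 fps, 12 AU
channels on the OpenFace 0–5 intensity scale, three head-pose channels and
one body motion-energy channel, written if desired in bit-exact
OpenFace/MEA CSV formats. Per channel the generative model is a lagged
feedback system on unit-variance AR(1) latents (coefficient 0.95 for
smooth, behavior-like drift at 30 fps): member X's latent at frame *t* is
`c_X · partner[t − lag] + (1 − c_X) · ownAR(1)[t]`, plus Gaussian
measurement noise (sd 0.1), with a default adaptation lag of 0.5 s.
Coupling to the partner's *realized* signal (not their base process)
matters: it gives mutually coupled members genuinely shared dynamics,
while one-sided unit coupling with zero noise still reproduces an exactly
lag-shifted copy — both properties are under test. Body latents mix with
the member's own head latents (weight 0.3) to create intrapersonal
coordination. Observation maps clip AUs to [0, 5] and motion energy at 0.

The dyad-type contrast encodes the direction of the effect under study
without claiming its magnitude: control members' coupling is drawn around
0.6 (sd 0.1) in both directions; in mixed dyads the TD member draws around
0.6 but the ASD member around 0.2, with doubled spread — elevated *and more
variable* adaptation asymmetry in mixed interactions. No published effect
sizes exist for these couplings; they are stated defaults, chosen once,
not estimates. Covariate distributions default to the matched adult cohort
(ASD age 37.2 ± 13.1 vs TD 31.5 ± 10.8; crystalline IQ ≈ 114 ± 17 in both
groups; non-verbal IQ 119.8 ± 23.4 vs 117.0 ± 17.4; female proportion
18/28 vs 26/60). All randomness descends from a single integer seed
through an isolated generator; no global RNG state is touched.

What the generator does *not* emulate — and therefore what passing tests do
not show about real data: non-stationarity over a conversation (topic
shifts, monologues), cross-channel dependence beyond the head–body mixing,
realistic tracking-loss bursts correlated with motion, camera or lighting
artifacts, and any true relationship between diagnosis and behavior. A
pipeline that is well calibrated and powerful on these synthetic conditions
is necessary, not sufficient, for trust on clinical recordings.

## Numerical choices

The windowed correlation grid is computed from cumulative sums (O(n) per
lag) after globally centering both series — centering leaves window
correlations unchanged but avoids the catastrophic cancellation of
two-pass moment formulas on offset signals; agreement with a naive
triple-loop oracle is asserted to 1e−10 and observed at machine precision.
Zero-variance segments yield missing cells rather than NaNs, and every
reported correlation is clamped to [−1, 1]. SVM solver tolerance is 1e−6.
Degenerate inputs fail loudly: single-class training sets, misaligned
rosters, out-of-bounds ROIs and non-integer frame lags are errors, not
warnings.

## Problem sizes used in the shipped checks

The package's own test and acceptance runs scale the study down where full
scale adds nothing to the property under test: synchrony oracles use
600-frame series (window 90, lag ±30); calibration studies use the full
88-participant roster with 2 outer permutations, a 3-point C grid and 20
seeds (null mean BAC), and 100 repetitions of a 99-permutation test with a
fixed C (test size); the end-to-end separation check simulates 60 s per
task with one AU channel and classifies head-motion synchrony features.
These sizes are the package's reproducibility contract; a full-scale
analysis simply raises the same knobs (600 s, 10 outer permutations,
11-point grid, 1000 permutations).

## Known limitations

Correlation-based synchrony is blind to nonlinear or time-warped
coordination; no dynamic time warping, wavelet or phase-based measures are
provided, and no time-varying synchrony curves beyond the windowed profile.
The linear SVM is the only base learner by design (high
feature-to-sample ratios punish complex kernels), and the stacker is the
only nonlinear element. The stacking layer cannot repair highly correlated
base models — combining them does not necessarily improve performance, and
the redundant-input test asserts exactly that. Exact window/lag choices,
the retained-AU set and the preprocessing chain inside the original
MATLAB tooling are unpublished; the package states its own defaults and
makes every one configurable.
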