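# dyadsync

Interpersonal synchrony features and dyad-labeled classification for
naturalistic social interaction.

`dyadsync` is for researchers studying non-verbal reciprocity in
face-to-face conversation — for example, whether the way autistic and
non-autistic adults adapt to a partner's facial expressions and movements
carries diagnostic signal. It takes per-frame behavioral time series
(OpenFace-style action-unit intensities and head pose; motion-energy
analysis of video frames) and turns them into dyad-level classification
results with honest, leakage-free uncertainty estimates.

## What it computes

**Synchrony.** For two series \(x, y\) the core statistic is the windowed
cross-lagged correlation: Pearson correlations \(r_{w,k}\) of window \(w\)
of \(x\) against \(y\) shifted by lag \(k \in [-L, L]\) frames (positive
lag = \(y\) trails \(x\); full-overlap windows only). Each window's peak
over the lags where one partner trails the other is that partner's
*following* (imitation) strength; per channel and task the peak profile is
reduced to seven statistics — mean, median, sd, min, max, skewness,
kurtosis. Intrapersonal coordination cross-correlates a person's own head
movement against their body motion energy. Pseudo-dyads (random
non-partner pairings) provide a chance baseline.

**Classification.** Five base feature sets per participant (both tasks
concatenated): `FACEsync` (12 AUs × 7 × 2 = 168 features), `HEADsync`
(global head movement, pitch, yaw, roll; 56), `BODYsync` (14),
`INTRAsync` (14) and `MovEx` (total head/body movement and facial
expressiveness; 6). Both members of a dyad share a label (mixed ASD-TD vs
control TD-TD). Models are class-weighted linear SVMs inside a
dyad-grouped, stratified, repeated nested cross-validation (11 outer folds
× 10 permutations; 10 inner folds for tuning), optimized and reported on
balanced accuracy, BAC = (sensitivity + specificity)/2. Inference is by
dyad-paired permutation testing (members permuted together;
add-one p-value), decision-score stacking with a Gaussian-kernel SVM, and
feature-importance maps (cross-validation ratio, sign-based consistency).

**Synthetic dyads.** Because clinical recordings are not shareable, the
package ships a generator: lag-coupled AR(1) feedback systems per channel
whose coupling distribution differs by dyad type, rendered if needed into
OpenFace/MEA CSVs or frame stacks. Every pipeline stage is tested end to
end against it.

## Worked example

Simulate a small study (18 dyads, 60 s per task at 30 fps), extract
head-motion synchrony features, and classify dyad type:

```r
library(dyadsync)

roster <- generate_roster(n_mixed = 10, n_control = 8, seed = 7)
labels <- dyad_labels(roster)

bundles <- simulate_study(roster, seed = 8, duration = 60, fps = 30,
                          n_au_channels = 1)
feats <- compute_sync_features(bundles, roster, au_set = "AU01_r")
head_sync <- assemble_feature_set("HEADsync", roster, feats$sync)
head_sync
#> <feature_set HEADsync> 36 participants x 56 features (0.0% missing)

scheme <- build_cv_scheme(labels, outer_folds = 8, outer_permutations = 2,
                          seed = 9)
result <- nested_cv_run(head_sync, labels, scheme, C_grid = 2^c(-4, 0, 4),
                        seed = 10)
result
#> <model_result> 36 participants, 2 outer permutations (linear kernel)
#> BAC 83.8% | AUC 0.83 | sens 80.0% spec 87.5% | PPV 88.9% NPV 77.8%

perm <- permutation_test(head_sync, labels, n_perm = 99, seed = 11,
                         outer_folds = 8, C_grid = 1)
perm
#> <permutation_result> observed BAC 71.9%, p = 0.02 (99 permutations) *significant at 0.05

imp <- importance_map(result$fold_weights)
head(imp[order(-abs(imp$cv_ratio)), ], 3)
#>                        feature mean_weight          se  cv_ratio sign_consistency
#> 52   pose_Rz.mealplanning.mean  -0.1655202 0.003935571 -42.05747                1
#> 53 pose_Rz.mealplanning.median  -0.1861256 0.005118634 -36.36235                1
#> 51    pose_Rz.mealplanning.max  -0.2603049 0.008126653 -32.03100                1
```

Out-of-fold balanced accuracy is 83.8%: head-motion following separates
the two dyad types well above chance under the generator's default
coupling contrast (control members couple at ~0.6 both ways; in mixed
dyads the ASD member couples at ~0.2 with doubled spread). The permutation
test reruns the pipeline under 99 dyad-paired label shuffles in its
reduced-cost configuration (one outer permutation, fixed C — hence its
slightly different observed BAC) and rejects the null at p = 0.02. The
importance map shows which features drive the separation and how stable
their signs are across the 16 CV models.

`report()` assembles metric tables and permutation p-values from a run
directory written with `write_model_result()`; `stack_models()` combines
several base models' decision scores under the identical CV scheme.

## Documentation

The methods vignette (`vignettes/dyadsync-methods.Rmd`) documents the
model and its assumptions, every tunable parameter with its default and
rationale, what the synthetic generator does and does not emulate, and the
package's numerical conventions.
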