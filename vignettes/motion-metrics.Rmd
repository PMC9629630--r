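---
title: "Motion metrics and skill credentialing: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Motion metrics and skill credentialing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Competency assessment in laparoscopic training is traditionally done by an
expert watching a trainee and filling a rating scale. When the training box
is instrumented with motion capture, every instrument tip yields a 30 Hz
trajectory, and skill becomes something one can try to measure: experienced
surgeons finish sooner, travel shorter paths, keep instruments close to the
target, and move with brisker (higher-velocity, higher-jerk) but more
economical strokes than novices. `lapskill` implements the full analysis
chain for this setting:

1. **simulate** two-handed instrument trajectories with controllable
   expertise effects (`generate_cohort()`),
2. **smooth and differentiate** tip tracks with a Savitzky-Golay filter
   (`smooth_and_differentiate()`),
3. **compute** a suite of kinematic metrics per trial
   (`compute_features()`),
4. **screen** metrics with Kruskal-Wallis/Mann-Whitney rank tests and
   summarize with PCA (`screen_metrics()`, `pca_fit()`),
5. **discriminate** experience levels with SVM, PCA-SVM and gradient-boosted
   trees under nested repeated k-fold cross-validation
   (`run_discrimination()`), comparing models with Friedman and Wilcoxon
   signed-rank tests (`compare_models()`).

Experience groups follow the conventional caseload rule: at least 50 prior
laparoscopic surgeries makes an expert, 10-49 an intermediate, 0-9 a novice
(`assign_group()`); the two-level scheme pools the latter two as
non-experts.

## The trajectory simulator

No public recordings exist for this kind of wet-lab motion data, so the
package ships a generative model rich enough to exercise every downstream
stage. It is a **minimum-jerk submovement** model, the standard primitive of
human reaching in motor control: between goal points drawn uniformly in a
100 x 80 x 60 mm workspace, the tip follows
$p(t) = p_0 + (p_1 - p_0)(10\tau^3 - 15\tau^4 + 6\tau^5)$, $\tau = t/T$,
which has zero velocity and acceleration at both ends and peak speed
$1.875\,D/T$. Skill is a scalar $s \in [0,1]$, mapped from caseload
log-linearly ($s = \log_{10}(1+n)/\log_{10}(501)$, saturating as learning
curves do), and acts through monotone parameter maps
(`synthetic_cohort_config()`):

| map | novice ($s=0$) | expert ($s=1$) | units | what it models |
|---|---|---|---|---|
| `duration_scale` | 1.7 | 0.8 | - | hesitant vs brisk reaches |
| `corrective_rate` | 2.5 | 0.25 | per goal | overshoot-and-fix submovements |
| `pause_duration` | 1.4 | 0.3 | s | dwell between actions |
| `tremor_rms` | 0.05 | 0.01 | mm | physiological tremor (8 Hz low-passed) |
| `depth_excursion` | 6 | 0.5 | mm | poor depth perception |
| `roll_fidget` | 12 | 3 | deg/s | shaft-roll adjustments |
| `timing_jitter` | 0.35 | 0.05 | s | bimanual desynchronization |
| `spurious_grip_rate` | 0.05 | 0.005 | 1/s | task-irrelevant gripper cycles |

These defaults were fixed once, when the generator was designed, so that the
planted effects point in the directions reported for real cohorts:
efficiency metrics (time, path length, depth path length) decrease and speed
metrics (mean velocity/acceleration/jerk) increase with expertise. Two
values deserve comment. The tremor amplitude is deliberately small
(sub-0.1 mm at the tip): tremor enters the jerk estimate multiplied by
$\omega^3$, so amplitudes much above 0.1 mm RMS would let novice tremor
dominate the voluntary-movement jerk and invert the expected ordering -
physically plausible for a hand-held stylus, but not for a long instrument
pivoting at a trocar, where the direction reported in wet-lab cohorts
(experts jerkier) indicates that voluntary movement dominates. The depth excursion (6 mm down
to 0.5 mm) is sized so the depth path length separates groups cleanly above
the movement-intrinsic depth component.

What the simulator does **not** emulate: tissue interaction and its forces,
endoscope motion, instrument exchanges mid-phase, learning within a session,
or the heavy-tailed trial-duration distributions of real trainees. Passing
tests on synthetic cohorts therefore demonstrate that the pipeline recovers
*planted* effects of realistic magnitude and direction - not that any
particular accuracy level will transfer to human recordings.

A `zero_effect_config()` flattens every skill map to its midpoint; this
null configuration is used to calibrate the screening false-positive rate
and chance-level classification.

## Smoothing and derivatives

Tracks are smoothed with a Savitzky-Golay filter, and velocity,
acceleration and jerk come from the same local polynomial fit (derivative
orders 1-3 scaled by the sample rate), not from finite differences of the
smoothed signal. Defaults are a 9-sample window (0.3 s at 30 Hz) and cubic
polynomial: the shortest window that stabilizes third derivatives while
remaining exact for cubics - the filter reproduces any polynomial up to the
fit order exactly, which the tests exploit as an oracle. Boundary samples
are produced by the polynomial fitted to the first/last window rather than
by reflection padding, so a linear track has exactly constant estimated
velocity out to the ends. Attitude angles are unwrapped (the
&plusmn;180&deg; seam removed) before smoothing; results should always be
read alongside the window/order setting, which `run_config()` carries
explicitly.

## The metric suite

Per instrument (prefixes `G_`, `S_`, `C_` for grasper, scissors, clip
applier in the dissection task; `R_`, `L_` for the needle holders in the
suturing task):

- **Efficiency**: operative time `OT` (trial-level), path length `PL`,
  depth path length `DPL` (projection of travel onto the viewing axis),
  working area `WA` (convex-hull area of the tip cloud in the plane
  perpendicular to the depth axis).
- **Speed**: time-means of the derivative norms `v_mean`, `a_mean`,
  `j_mean`, and depth velocity `DV`.
- **Attitude**: mean gripper angle `AGRA`, mean `Roll`/`Pitch`/`Yaw`,
  angular lengths `AL_Roll` (total variation of roll - rotation about the
  shaft axis) and `AL_PitchYaw` (accumulated great-circle angle of the
  shaft direction vector).
- **Bimanual** (one set per trial): `BD` - Pearson correlation of the two
  hands' speed profiles on their common timebase (an optional config switch
  uses the maximum cross-correlation within a lag window instead); `ROB`
  and `RPLB` - right/left ratios of gripper event counts and path lengths;
  `ADB` and `ADBO` - mean inter-tip distance overall and at gripper
  open/close events.

The published source for these metrics gives names and motivating
hypotheses but not closed formulas; each definition here is a documented
reconstruction from the metric's name and its stated hypothesis (e.g.
"working area" is taken perpendicular to the depth axis precisely because
it is contrasted with the depth metrics). One further metric appearing only
in a figure of the original work ("L_High") has no recoverable definition
and is deliberately not implemented. Gripper events use a threshold of
20&deg; with 5&deg; hysteresis, which suppresses chatter from noise smaller
than the hysteresis band (a property the tests check explicitly). Ratios
with empty denominators, and correlations of constant series, are flagged
`NA` rather than returned as infinities; affected trials are excluded
listwise per metric in screening and entirely in classification.

In the dissection task the right-hand trajectory is split in time between
scissors and clip applier, so those two tracks cover different windows of
the trial; bimanual metrics pair the left grasper with the right-hand track
that overlaps it longest (the scissors in practice).

## Normalization, screening, PCA

All metrics are scaled by the robust Z-score
$z = (x - \tilde{x}) / (0.7414 \cdot IQR)$, whose normalized interquartile
range is a consistent estimate of the standard deviation under normality
but insensitive to outliers. Quartiles use linear interpolation (type 7) so
the transform is bit-reproducible; zero-IQR columns map to zeros and are
flagged. Screening retains a metric when the Kruskal-Wallis omnibus test
across the three groups is significant at $\alpha = 0.05$ (the community
default; the source reports "significant differences" without a stated
level), with pairwise Mann-Whitney tests reported for retained metrics
only. No multiple-testing correction is applied across metrics by default,
mirroring the apparent per-metric convention; a Holm option exists in
`run_config()`.

PCA is computed on the covariance of the robust-Z-scaled metrics - *not*
re-standardized to unit variance, since the data were already normalized
once. Loadings are eigenvector times the square root of the eigenvalue with
the sign fixed so each component's largest loading is positive. Because
NIQR-scaled columns need not have unit variance, loadings can legitimately
exceed 1 for heavy-tailed metrics; the test suite verifies this is possible
rather than asserting any specific human-data loading values.

## Classification and validation

Three classifiers are compared: a radial-kernel SVM, the same SVM after
reducing dimension to the leading principal components (PCA-SVM), and a
gradient-boosted decision tree ensemble (GBDT, implemented with xgboost;
the "leaf count" grid of the boosted-tree literature is expressed as tree
depths 3-5, and small-sample exact splits are used so decision thresholds
fall at midpoints of the class gap). Hyperparameter grids: SVM cost
{0.1, 1, 10, 100} x kernel scale {0.001, 0.01, 0.1, 1}; PCA-SVM adds
retained variance {0.7, 0.8, 0.9, 0.95}; GBDT learning rate {0.05, 0.1} x
trees {50, 100, 200} x depth {3, 4, 5}. These grids are reconstructions:
the original grid tables are not in the available text.

Validation is nested repeated k-fold cross-validation: stratified outer
folds estimate generalization, an inner stratified grid search on each
outer-training portion picks hyperparameters (ties go to the first grid
point, for determinism), the winner is refit on the full outer-training
portion, and the whole scheme is repeated with fresh partitions. Repetition
accuracy is pooled over outer test folds (invariant to unequal fold sizes).
Stratification is a design choice the source leaves open: unstratified
10-fold splitting of 70 trials with an 18-member class risks folds missing
a class entirely. Robust-Z parameters and the PCA rotation are estimated
from training rows only, and an audit mode records exactly which rows
informed every scaling and fitting call (`audit = TRUE`,
`count_leakage_violations()`).

The three classifiers run on identical fold sequences (partitions are drawn
from the per-repetition seed before any model fitting), so their accuracy
vectors are paired; `compare_models()` applies Friedman and pairwise
Wilcoxon signed-rank tests to them. A statistical caveat is worth stating
plainly: repeated-CV accuracies are resamplings of the same 70 trials, not
independent blocks, so these p-values describe sensitivity to partition
choice - they mirror the field's reporting convention rather than an
endorsement of it.

## Problem sizes and numerical choices

The package's own test and acceptance runs use desk-scale versions of the
validation: 10 outer folds, 3-5 inner folds, 10-20 repetitions on 70-trial
cohorts (the full protocol of record is 10 x 10 with 100 repetitions;
nothing in the implementation limits it - `run_config(repetitions = 100,
inner_k = 10)` reproduces it, at proportionally higher cost). Chance-level
calibration uses a near-balanced zero-effect cohort (24/23/23) with a
*fresh* label permutation in every repetition (`permutation_null_cv()`): a
single fixed permutation can carry a chance feature-label association that
a flexible model exploits consistently across repetitions, displacing the
null median from chance. The chance band is the 95% interval of a binomial
chance accuracy at the cohort size. Permutation-null CV accuracies also
tend to sit slightly *below* the nominal chance rate (training and test
class counts anti-correlate across folds), which is why the band is taken
on the per-draw scale rather than on the much tighter scale of a median
over repetitions - the latter would reject any faithful CV implementation.

Other numerical decisions: time grids are validated to 1 microsecond
spacing tolerance; track CSVs are written with 10 significant digits so a
write/read round-trip is stable to 1e-9 relative error; Mann-Whitney
p-values are exact for small tie-free samples and normal-approximated with
tie/continuity corrections otherwise; the Wilcoxon signed-rank test falls
back to full sign-pattern enumeration (up to 15 nonzero pairs) when ties
among absolute differences rule out the standard exact distribution; convex
hull areas use the shoelace formula on `chull()` vertices, with degenerate
(collinear) clouds reporting zero area.

## Known limitations

- Synthetic effect *magnitudes* are package choices; only directions are
  anchored in the literature. Classifier accuracies on synthetic cohorts
  are therefore not comparable to published human-data accuracies.
- Arithmetic (not circular) means are used for attitude angles, following
  the unwrapped-angle convention; for trials spinning through many turns a
  circular mean would differ.
- `BD` is a zero-lag correlation by default; genuinely asynchronous but
  coordinated bimanual strategies would be better served by the lag-window
  variant.
- The trial-splitting convention for the dissection task (scissors first,
  clip applier second, split at 60% of goals) is a simplification of real
  instrument exchange patterns.
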