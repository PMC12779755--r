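---
title: "Decoding passive-movement kinematics from simulated event-related fMRI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding passive-movement kinematics from simulated event-related fMRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kinedecode)
```

## The scientific problem

Robotic passive finger movement permits factorial manipulation of the
kinematics of proprioceptive stimulation — amplitude (fraction of the
subject's maximum thumb–index aperture), velocity, and direction (extension
vs flexion) — while BOLD fMRI records the cortical and subcortical response.
Two questions drive the analysis. First, *where* in the brain are kinematic
features encoded, asked two complementary ways: as mean activation
differences across levels (univariate GLM contrasts) and as decodable
multivoxel patterns (searchlight MVPA). Second, *how to keep stimulus
duration from contaminating the answer*: because a displacement of amplitude
$a$ at velocity $v$ mechanically lasts $a/v$ seconds, trial duration is
confounded with condition by construction, and either analysis can mistake
time-on-task effects for kinematic coding.

`kinedecode` reimplements this analysis pipeline over a synthetic BOLD
generator, so every stage — from the event schedule to the zero-inflated
count model — is verifiable against known ground truth.

## The synthetic-data generator

`experiment_spec()` encodes the two study designs: a fast event-related
3×3×2 design (amplitudes 10/20/40 %, velocities 20/40/80 %/s, 8 repetitions
per combination per run, inter-trial interval 4 ± 2 s, 400 volumes at
TR = 2 s) and a slow 2×2×2 design (10/40 %, 5/20 %/s, 5 repetitions, ITI
12 ± 2 s, 306 volumes). `sample_events()` draws a balanced pseudorandom
schedule; trial durations are $a/v$ with a ±10 % uniform multiplicative
jitter (the duration variability of a real robot is device-specific; the
jitter fraction is a configuration parameter). ITIs are uniform on
mean ± half-range, the natural reading of "4 ± 2 s". The slow design's
schedule is tight (about 605 of 612 scanned seconds in expectation), so the
sampler redraws an infeasible randomisation up to 100 times before failing —
the in-silico analogue of rejecting an unusable schedule before scanning.

`simulate_run()` builds the BOLD forward model: per condition, a neural
boxcar train convolved with the canonical double-gamma HRF; voxelwise
response amplitude `univariate_gain + pattern_strength × pattern`; AR(1)
noise (ρ = 0.3, unit marginal SD by default); two slow cosine drifts
(periods 256 s and 384 s, beyond the 128 s high-pass cutoff, so the filter
is genuinely exercised); and a constant baseline of 100 that makes
global-signal masking meaningful. The `duration_scaling` switch selects the
two neural scenarios the modelling literature distinguishes: activity that
lasts as long as the stimulus, or a fixed 0.5 s epoch regardless of trial
duration (chosen shorter than typical trials so the scenarios are
distinguishable). Zero-mean condition patterns are the multivariate-only
signal: each condition's pattern vector is centred across the region, so
region-mean activation carries no condition information while the spatial
configuration does. Patterns are drawn per subject by default — emulating
multivoxel codes that do not generalise across individuals — and can be
shared (`shared_pattern`) to model a stable across-subject code. A
spatially uniform `region_gain` provides the complementary univariate-only
manipulation. Per-subject maximum apertures are drawn from N(96, 13) mm,
which puts the group-mean displacement near 9.6 mm at the
10 % amplitude level, the scale such robots produce; the aperture affects only the recorded millimetre
metadata, since durations are amplitude/velocity ratios.

What the generator does **not** emulate: head-motion image displacement
(motion enters only as optional nuisance time courses), slice-timing
effects, physiological noise, and spatial noise correlations. Passing tests
therefore demonstrate correctness of the estimators under the stated noise
model, not robustness to every artefact of real acquisitions.

## First-level model

`build_design_matrix()` constructs, per run: one constant regressor per
factorial combination — boxcars at the trial onsets with the run's mean
stimulus duration — plus duration parametric modulators, all convolved at
microtime resolution (16 bins per TR) and sampled at scan times; a
discrete-cosine high-pass set (cutoff 128 s; `K = ceiling(2·T/cutoff)`
non-constant cosines, so 13 functions for 400 scans — the highest order
sits marginally past the nominal cutoff rather than under-covering the
band); optional motion regressors; and an intercept. Two modulator
layouts are provided:

* **non-interaction** (the canonical duration-covariate model): a single
  modulator over all trials, heights centred on the *run grand mean*
  duration. Between-condition duration differences are credited to the
  modulator, which is what protects condition contrasts from time-on-task
  effects.
* **full interaction**: one modulator per condition, heights centred
  *within condition and run*. This per-regressor centring (the convention
  of the standard SPM implementation) keeps each (constant, modulator)
  pair well conditioned. The alternative — grand-mean centring of
  condition-specific modulators — is untenable here: within-condition
  duration jitter is tiny against between-condition offsets, the pairs
  become near-collinear, and per-condition beta SDs inflate by two orders
  of magnitude. Worse, the resulting condition-dependent variance
  signature of the betas is itself decodable, poisoning any downstream
  MVPA. We measured both facts and chose the centring accordingly.

The **variable-epoch** mode gives each trial a boxcar of its own duration
and no modulators.

`fit_glm_ar1()` is a two-pass prewhitened fit. The pooled lag-1
autocorrelation of OLS residuals is severely biased on short runs — the
hat matrix removes exactly the low-frequency structure that carries the
autocorrelation (we measured ρ = 0.3 estimated as ≈ 0.05 on 90-scan runs,
inflating first-level type-I error to ~0.10). The estimate is therefore
bias-corrected by matching the raw ratio against its expectation
$\mathrm{tr}(MLMV(\rho))/\mathrm{tr}(MV(\rho))$ under AR(1) noise, solved
by 1-D root finding; the corrected estimate recovers ρ = 0.30 without
visible bias. ρ is pooled across in-mask voxels (one value per run), in
the spirit of pooled non-sphericity estimation, which also stabilises
small grids.

### False-positive control

The headline methodological property: with duration confounded with
condition and *no* condition effect, the amplitude main-effect F-test
(Kronecker-product contrast) should reject at the nominal 5 % under both
neural scenarios. `fp_control_experiment()` measures this over seeded
simulated runs of a reduced 2×2×2 design (durations 0.25–2 s, 135 volumes,
27 voxels pooled for ρ, neural gain 10 — a 2 s event peaks near 4 noise
SD, the strong somatosensory-response regime). The duration-covariate
model is calibrated in both scenarios; the variable-epoch model is
calibrated when activity scales with duration but rejects in roughly
three-quarters of runs when it does not; and the full-interaction variant
rejects almost always under the scaling scenario — its within-condition
centring leaves between-condition duration responses on the betas. This
last number is reported, not asserted, as a property worth knowing about
the model family.

A related, subtler finding shaped the group-level studies. Under the
fixed-epoch scenario, the modelled epoch (mean stimulus duration ≈ 0.94 s)
and the true neural epoch (0.5 s) differ in shape. In the *fast* schedule a
trial's duration shifts its successor's onset, and this interaction leaves
a small deterministic level-difference bias on the betas (≈ −1.4 % of the
gain, measured noise-free) that is common to all subjects and therefore
inflates group false positives slightly. The *slow* schedule removes the
overlap and the bias with it — the same estimation argument that motivates
slow event-related designs in general. The dissociation study below uses
the slow variant for exactly this reason.

## Decoding

`sphere_offsets()` enumerates integer voxel offsets within the searchlight
radius with an inclusive center-to-center comparison; this convention
yields 81 voxels at 8 mm and 19 at 5 mm on a 3 mm grid — the sphere
sizes the analysis is built around. `loro_cv_accuracy()` is leave-one-run-out
cross-validation with a linear SVM at C = 1 (libsvm via `e1071`, one-vs-one
voting for three classes, the libsvm default; the multiclass decomposition
is a recorded convention of this implementation).
Fold accuracies are averaged (folds are balanced by design); confusion
matrices pool test predictions and are row-normalised to percent. Optional
min–max feature scaling to [0, 1] is estimated on training folds only.
`searchlight_map()` assigns accuracy-minus-chance to each in-mask centre,
clipping spheres at the mask boundary; the resulting subject maps are
6-mm Gaussian-smoothed before group statistics, while unsmoothed betas feed
the decoding itself.

## Group inference

One-sample t-maps (accuracy above chance) and Welch unequal-variance
ANOVA maps (activation differences across levels) are thresholded by
**max-statistic permutation FWE**: sign flips of subject maps for the
one-sample case, within-subject level-label permutations for the ANOVA,
with `p_fwe(v)` the proportion of permutation volume-maxima at or above
the observed statistic. This replaces parametric random-field-theory
correction deliberately: the permutation test is exact under
exchangeability, needs no smoothness estimation, and remains valid at
desk-scale grids; output metadata records the substitution. Both the
default 0.05 and the strict 5×10⁻⁵ voxel thresholds are honoured as
presets. `report_clusters()` reports 26-connectivity clusters of at least
10 voxels with greedily selected peaks separated by more than 20 mm,
mirroring the whole-brain table format.

The dissociation study (`dissociation_experiment()`) runs both routes on
datasets with a single ground-truth effect confined to a central 3×3×3
region: zero-mean patterns (multivariate-only) or a uniform amplitude gain
step (univariate). Over seeded replicate groups (6 subjects each),
pattern effects are detected by the searchlight route in every seed and by
the univariate route at its false-positive rate, while gain effects are
detected by both — operationalising the interpretation that
multivariate-only effects reflect condition information carried by
spatially heterogeneous responses.

## ROI analyses and stability

`roi_voxels()` selects in-mask voxels within 5 mm (19 voxels) or 8 mm
(81 voxels) of literature MNI coordinates (`roi_table()`: contralateral
S1, SMA, bilateral S2, thalamus, ipsilateral cerebellum).
`bootstrap_cell_significance()` resamples subjects with replacement
(study-scale default 10⁵ resamples) and forms percentile confidence
intervals per confusion cell at level 1 − α/n_cells (α divided by 4 or 9
cells); a cell is significant when chance falls outside its interval.
Percentile rather than BCa intervals are used; the procedure needs only
an interval from the bootstrapped distribution. Calibration is
checked by simulation: with subject accuracies centred exactly on chance,
the proportion of significant cells stays below α.

`roi_univariate_anova()` collapses betas over ROI voxels, runs and the
non-target factors (collapsing to one value per subject and level is this package's
reading of "average beta per unique combination, then one-way ANOVAs per
feature"),
then fits a subject-blocked repeated-measures ANOVA with paired,
Sidak-adjusted pairwise comparisons ($p_{adj} = 1-(1-p)^m$). The paired
form is chosen because the design is within-subject; unpaired comparisons
are a defensible alternative and would be more conservative here.

`loso_stability()` trains on all subjects but one and tests on the
holdout. No statistical test is attached (a single group-level confusion matrix
supports none) — only a stability flag (smallest diagonal cell above the
largest off-diagonal cell). With the generator's default subject-unique
patterns the flag is false; with a shared pattern it is true.

## Voxel counts and the zero-inflated model

Subject MVPA maps are thresholded at ≥ 10 percentage points above chance
(inclusive, so a map exactly at the margin is flagged); subject univariate
maps are thresholded by cluster-forming p < 0.001 with a label-permutation
maximum-extent null and Benjamini–Hochberg cluster FDR at 0.05. Counts per
ROI are compared across kinematic features with a zero-inflated Poisson
mixed model — `count ~ feature + (1|subject)` with a constant
zero-inflation term — fitted by `glmmTMB`, with Tukey-adjusted pairwise
contrasts from `emmeans` and a Bonferroni family of 14 omnibus tests
(7 ROIs × 2 analysis types). ZIP is the default family, with zero-inflated negative binomial
(`nbinom2`) exposed as an option. Parameter
recovery is verified over 100 seeded datasets at 20 subjects: feature
offsets of −0.7 and −1.4 on the log scale are recovered with mean absolute
bias well inside ±0.15.

## Problem sizes and numerical choices

The seeded studies run at deliberately small sizes chosen as the package's
own benchmark conditions: 500 runs per scenario for type-I calibration
(binomial 95 % interval ±0.019 around 0.05), 6-subject groups on 6×6×6
grids with 20 seeds for the dissociation study, 200 simulated ROIs for
bootstrap calibration, 100 seeds for count-model recovery. Determinism is
end-to-end: every stochastic stage consumes an explicit seed, derived
seeds are folded through a fixed 32-bit chain, and generators save and
restore the global RNG state.

Degenerate inputs are handled explicitly rather than silently: empty
condition cells, schedule overflows, rank-deficient designs (named
collinear columns), empty masks and ROIs, labels missing from a
cross-validation fold, too few permutable units, and zero across-subject
variance (an infinite-t sentinel with a degeneracy flag).

## Known limitations

Real acquisitions bring spatially correlated, non-stationary noise, motion
artefacts and susceptibility dropout that the generator does not model;
the ROI fixture coordinates only index the simulated grid once it is
enlarged to brain scale; and the full-interaction model's residual
time-on-task confound under duration-scaling neural activity (quantified
above) means its betas should be interpreted cautiously whenever
conditions differ strongly in duration — a caveat that applies to the
modelling approach itself, not only to this implementation.
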