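---
title: "Brain-age modeling of AD/LB co-pathology: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Brain-age modeling of AD/LB co-pathology: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The scientific problem

Alzheimer's disease (AD) and Lewy-body (LB) pathology frequently co-occur,
and cerebrospinal-fluid assays now allow both to be detected in vivo: AD
positivity from the p-tau181/A&beta;42 ratio (threshold 0.021, with the
boundary value counted as positive) and LB positivity from the
&alpha;-synuclein seed amplification assay (SAA), whose readout is positive,
negative, or intermediate; intermediate records are excluded. Crossing the
two markers yields four cognitively impaired subgroups (AD-LB-, AD-LB+,
AD+LB-, AD+LB+) beside the cognitively unimpaired (CU) reference.

The package's central quantity is the *brain-age gap* (BAG): a 3D
convolutional network regresses chronological age (CA) from a T1-like
volume of a cognitively unimpaired brain; applied to impaired individuals,
the difference between predicted brain age (BA) and CA measures deviation
from normative aging. Because regression dilution makes raw gaps
age-dependent, a linear bias model `BA = a * CA + b` is fitted on held-out
unimpaired validation data and every downstream gap is corrected as
`(BA - b)/a - CA`. On the fitting set this correction has exactly zero mean
and zero ordinary-least-squares slope against CA; both are asserted to
1e-8 in the tests.

## Pipeline

1. **Synthetic cohorts** (`generate_cohort`, `render_volume`,
   `generate_trajectories`, `generate_volumetrics`) emulate the study
   conditions end to end.
2. **Quality control** (`run_qc`) screens volumes with robust intensity
   statistics, PCA + Mahalanobis distance, and an Isolation Forest, each
   applied separately within every subgroup.
3. **Cohort handling** (`classify_subgroup`, `select_first_scan`,
   `stratified_split`, `balance_check`).
4. **Brain-age regression** (`net_config`, `build_model`, `staged_train`,
   `predict_brain_age`) — a 3D DenseNet implemented natively in R.
5. **Bias correction and group statistics** (`fit_bias`, `correct_bag`,
   `group_stats`, `sexwise_stats`, `compute_metrics`).
6. **Saliency** (`saliency_volume`, `group_mean_saliency`,
   `difference_map`, `region_summary`).
7. **Longitudinal trajectories** (`fit_baseline_glm`, `fit_lmm`,
   `select_model_bic`, `pairwise_contrasts`).

## The network

The regressor is a 3D DenseNet: a 5×5×5 stem convolution, four dense
blocks of 3/6/12/8 layers separated by transition blocks, a final 3×3×3
convolution, global average pooling, and a single linear output (years).
Each dense layer runs normalization → ReLU → 1×1×1 bottleneck →
normalization → ReLU → 3×3×3 convolution and concatenates `growth_rate`
channels onto the block's running feature map. The bottleneck width scales
with the current in-channel count `c` (it maps `c` to `s·c` channels)
rather than being a fixed multiple of the growth rate.

The full-scale reference configuration is frozen in
`inst/extdata/reference_config.yaml`: stem width 120, growth rate 56,
bottleneck scale 2, compression 0.5, final convolution width 7,848, biases
on the stem and final convolutions only (the convolutions not followed by a
normalization layer), and no normalization between the last block and the
final convolution. Of the architectural degrees of freedom the description
above leaves open, this is the configuration whose closed-form trainable-
parameter count equals 251,098,737 exactly; it was found once by
enumerating (stem width, growth rate, bottleneck scale, compression, final
width, bias/normalization toggles) with `count_parameters` — the search is
reproducible via `resolve_reference_config`. `count_parameters` (closed
form) and `model_parameter_count` (summation over instantiated tensors)
must agree for every configuration; a property test checks 50 random
architectures.

Because no deep-learning framework is available to R here, the network is
implemented directly: convolutions as an im2col gather followed by one
BLAS matrix product (index plans cached per layer, batch and shape);
batch-style normalization with running statistics; backward passes written
against each forward; Adam on mean-absolute-error loss (years). Input
gradients — needed only for saliency — are verified against central finite
differences.

### Training protocol

`train_config()` defaults encode the staged protocol: 5 cycles × 15
epochs, mini-batch 8, MAE loss, Adam at initial learning rate 5e-6, decay
factor 0.7 applied at a cycle boundary whose completed cycle produced no
new best validation loss, early stopping after 6 consecutive
non-improving epochs (the counter is epoch-global and resets only on
improvement), seed 42, and checkpointing on every improvement. The
controller logic is factored into `training_controller()` so the
patience/decay rules are testable on synthetic loss traces. Desk-scale
experiments use a tiny configuration (stem 8, growth 4, scale 1, blocks
2/2, stem stride 2 with a parameter-free average pooling after the stem)
and a larger learning rate (1e-3), appropriate for a network four orders
of magnitude smaller than the reference; the head bias is initialized at
the mean training age so optimization starts from the constant-mean
predictor it must beat.

## The synthetic generator

The generator plants a known ground truth that the pipeline must recover.

* **Effective age.** Each subject's brain age at follow-up year `t` is
  `CA0 + t + offset(group) + slope(group)·t` plus optional Gaussian noise.
  Offsets default to the reported subgroup means of the corrected gap
  (0, 2.08, 2.40, 4.64, 6.93 years vs CU) and slopes to the reported
  yearly rates (0, 0.03, 0.14, 0.29, 0.54 yr/yr). The noise SD defaults to
  3.7 years, the subgroup standard deviation implied by the reported
  standard errors (SE·√n ≈ 3.6–4.0 across subgroups).
* **Morphology.** A volume is a unit ball of tissue with a cortical shell
  that thins linearly with effective age and a central cavity whose radius
  grows linearly with effective age. Both features are monotone in age,
  measurable by voxel counting (the cavity radius estimated as the cube
  root of the cavity voxel count correlates > 0.99 with CA in the
  noise-free tests), and learnable by a small CNN. Grids smaller than 16³
  are rejected because the structures would not be resolvable.
* **Biomarkers.** AD-positive subjects draw ratios in
  [1.2, 5]×threshold and AD-negative in [0.1, 0.8]×threshold — a guard
  band that keeps labels exactly recoverable; a configurable fraction of
  extra subjects receives an intermediate SAA readout to exercise the
  exclusion path.
* **Trajectories.** Outcomes follow
  `baseline + baseline_beta(g) + (slope + slope_beta(g))·t +
  quad_beta(g)·t² + b0 + b1·t + ε` with per-subject random intercepts and
  slopes. Defaults echo the reported fitted effects for the BAG, the MTL,
  basal-ganglia, occipital and middle-temporal ICV-normalized composites
  and two global cognitive scores; where a contrast was reported as
  non-significant the default is zero or small. Visit schedules are
  annual with 1–6 visits per subject.

What the generator does **not** emulate: MRI physics (bias fields, motion,
scanner effects), realistic anatomy or registration error, demographic
covariance between age, sex and pathology, and informative dropout.
Passing tests therefore demonstrate that the algorithms are implemented
correctly and recover planted effects under their own assumptions — not
that the pipeline would reach the same effect sizes on real cohorts.

## Quality control

Intensity screening flags scans whose global mean or SD deviates by more
than 3 robust z-units (median/MAD) from their stratum, or whose fraction
of voxels beyond `2·z_thresh` pooled SDs exceeds 1%. With zero spread
(identical volumes) nothing is flagged, and an infinite threshold disables
all three criteria. After normalization, scans are projected onto the
principal components capturing 95% of variance; squared Mahalanobis
distances in component space (using the PCA eigenvalues, with diagonal
loading if nearly singular) are cut at the χ² 0.999 quantile with k
degrees of freedom. An Isolation Forest (implemented in the package:
random axis-parallel splits, anomaly score `2^(-E[h]/c(n))`) runs on the
same component scores and flags the `⌈contamination·n⌉` most isolable
scans, default contamination 0.02, deterministic given the seed. All
detectors run separately per subgroup so that a flag reflects anomaly
relative to the scan's own clinical context; the union of flags is the
manual-review set. The thresholds (3.0, 0.95, 0.999, 0.02) are
configurable defaults chosen where the procedure description leaves them
open.

A note on the Isolation Forest's feature space: on isotropic
high-dimensional features a single-coordinate extreme is intrinsically
hard for the canonical algorithm (confirmed against the scikit-learn
implementation during development), but volume cohorts are low-rank after
PCA, where the detector performs as expected; the tests use low-rank
fixtures for this reason.

## Splits and statistics

`stratified_split` discretizes age into 5-year bins (width configurable;
unspecified in the source description) and allocates records so the global
sizes are exactly `round(0.8N)` / `floor(0.1N)` / remainder — the rule
that reproduces the published 3,484/435/436 partition of 4,355 records —
with per-bin quotas assigned by floor plus largest remainder and seeded
within-bin shuffling.

Group comparisons residualize the corrected gap on CA before a one-way
ANOVA and Holm–Šídák step-down pairwise tests; an ANCOVA formulation
(CA as a nuisance regressor) is available via `adjust = "ancova"` and
agrees with the residualization F up to the usual degrees-of-freedom
bookkeeping. Sex comparisons are Welch t-tests within subgroups,
Holm–Šídák corrected, plus per-sex ANOVAs.

Longitudinal models are linear mixed models with per-subject random
intercepts and slopes, fitted by maximum likelihood (not REML) so BIC is
comparable across fixed-effect structures; the quadratic variant adds
`group × time²`. Covariates are baseline age, sex, cognitive state
(MCI/dementia; CU records are not part of the impaired models) and
education, with constant columns dropped automatically. The random-effect
covariance is unstructured with a diagonal fallback on non-convergence
(flagged in the output). Group levels are ordered canonically
(reference first), independent of locale collation, so contrast
directions are stable. Pairwise contrasts are Benjamini–Hochberg adjusted
within each term family (baseline, slope, acceleration); model order is
chosen by lower BIC with ties resolved to linear. Which order wins on any
given outcome is data-dependent, so the package asserts only selection
*consistency* on clearly linear and clearly quadratic generators, not a
particular outcome's choice.

Composites (MTL = hippocampus + entorhinal + amygdala + parahippocampal;
basal ganglia; occipital; middle temporal, all bilateral) aggregate
ICV-normalized constituent volumes by sum (mean available via a flag); a
scan missing a constituent yields a missing composite rather than a
silently partial sum.

## Saliency

Saliency is the gradient of the scalar brain-age output with respect to
the input voxels, computed in evaluation mode (running normalization
statistics, hence batch-invariant), taken in absolute value by default —
the maps rank importance, and the sign convention is a documented choice
with signed maps behind a flag — and smoothed with a separable Gaussian
(default σ = 2 voxels, reflecting boundaries, which preserves the map
total). The head is a single scalar, so the "most contributing output" is
that scalar by construction. Group means, signed difference maps
(A − B > 0 where A is more salient), and per-region means over an integer
label atlas complete the module; at desk scale the atlas is the
generator's own three-zone × octant parcellation.

## Numerical choices and problem sizes

* Convolution index plans are cached per (shape, batch); the scatter-add
  adjoint decomposes per kernel offset, which is exact because each offset
  maps output to input voxels injectively.
* Normalization uses ε = 1e-5 and momentum 0.1; biased batch variance in
  the normalizer, unbiased in the running estimate.
* The finite-difference gradient oracle uses an all-positive-weight
  network so the piecewise-linear model is locally linear along the ±ε
  path; kink crossings, not implementation error, otherwise dominate the
  comparison.
* Test problem sizes are chosen to make each check sharp but quick: the
  calibration Monte-Carlos use 200–400 replicates (type-I error bands
  [0.03, 0.08] at α = 0.05); slope-recovery and coverage simulations use
  the published group sizes 195/46/396/166 with 1–6 annual visits;
  the end-to-end echo trains on 200 volumes of 32³ voxels with the tiny
  configuration and evaluates subgroup ordering on 10 independently
  seeded cohorts of 40 CU + 30 + 30 scans.

## Limitations

The 3D DenseNet here runs on CPU at toy scale; the full-scale reference
configuration is instantiated for parameter bookkeeping but not trained.
Statistical conclusions about real AD/LB cohorts require the original
controlled-access data; this package provides the tested machinery and a
faithful synthetic harness, not a reproduction of cohort-specific effect
sizes. The bias correction implements the linear rule only; age-level
(Cole-style) or quadratic corrections are out of scope.
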