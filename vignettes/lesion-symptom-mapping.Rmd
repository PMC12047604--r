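---
title: "Individualized lesion-symptom mapping with occlusion attribution: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Individualized lesion-symptom mapping with occlusion attribution: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

White matter hyperintensities (WMH) are confluent vascular lesions of the
cerebral white matter whose cognitive impact depends on *where* they sit,
not only on how much tissue they cover. Lesion-symptom mapping (LSM)
relates the spatial pattern of binary lesion masks, co-registered to a
common template, to a per-subject cognitive score across a cohort, in
order to find "strategic" locations. Classical mass-univariate and
multivariate (support vector regression) LSM operate at the group level;
this package implements an individualized alternative: a 3D convolutional
network (CNN) is trained to predict the cognitive score from the raw
lesion mask, and a perturbation-based explainable-AI step (occlusion)
converts the trained model into a voxelwise attribution map for each
individual patient. SVR beta-maps and the weight map of a single-layer
fully connected network (FNN) serve as group-level benchmarks.

Because real cognitive scores are only partially explained by lesions and
carry no ground truth for strategic locations, the package's validation
is built on *simulated* cognitive scores computed from real-shaped lesion
geometry: cuboid regions of interest (ROIs) placed inside the cohort's
lesion-prevalence map define the ground truth, per-subject scores are
derived from ROI lesion loads, and every attribution method is scored
against the known ROIs.

# The score simulation model

For subject $i$ and ROI $k$ the lesion load $LL_{i,k}$ is the lesioned
fraction of the ROI's voxels. The raw score is the weighted sum

$$\mathrm{score}_i = \sum_k w_k \, LL_{i,k},$$

with unit weights in the basic setting and $\{1,2,1\}$ / $\{1,4,1\}$
variants that make the middle ROI strategically dominant. All score
variants end with population min–max normalization, so the worst-affected
subject scores exactly 1 and the least-affected exactly 0 (the convention
is "higher = more lesion burden in strategic locations"; positive
attribution therefore marks locations driving a *higher* predicted
score).

Noise robustness is probed with the mixture

$$\mathrm{noisy}_i = (1 - nf)\,\mathrm{basic}_i + nf \cdot \eta_i,
\qquad \eta_i \sim \mathcal N(0, \sigma_\mathrm{basic}),$$

followed by re-normalization. Because re-normalization is affine, the
squared correlation between basic and noisy scores has the closed form
$(1-nf)^2 / ((1-nf)^2 + nf^2)$, which the test suite verifies by Monte
Carlo at $n = 10^5$. The standard deviation uses the population ($n$)
denominator by default (`sdType = "sample"` switches to $n-1$; at cohort
sizes of interest the difference is negligible).

ROI placement enumerates every axis-aligned cuboid whose voxels all have
lesion prevalence at or above a minimum subject count (default 10), then
draws the requested number of mutually disjoint cuboids at random
(sequential draws with rejection of overlapping candidates, capped at
10,000 attempts). Placement failure is a hard error, never silently
relaxed.

# The models

* **SVR**: radial-basis epsilon-SVR on flattened voxel features. Feature
  preprocessing is volume correction — each lesioned voxel carries
  $1/\sqrt{V}$ with $V$ the subject's lesioned-voxel count, so
  $\sum_v x_v = \sqrt{V}$ — followed by mass-univariate feature selection
  (one-sided Welch t-test per voxel, lesioned vs spared subjects,
  uncorrected $p < 0.05$, tested only where the lesioned count is at
  least 10 and at most $n-10$), fit on training subjects only within each
  fold. Hyperparameters are tuned by an inner 5-fold grid search
  maximizing the Pearson correlation between inner-fold predictions and
  truth; ties break by enumeration order (cost fastest, epsilon slowest).
* **FNN**: one linear layer followed by ReLU on the same features — the
  closest neural analogue of SVR. Its per-feature weights are the
  attribution map.
* **CNN**: two 3×3×3 convolution blocks, flatten, one linear output unit
  (the *simple* architecture used on simulated scores). The *regularized*
  variant for noisy real-world scores adds spatial dropout in each block,
  2×2×2 max pooling after each block, and a second linear layer, and is
  typically trained with the combined loss $2\cdot\mathrm{MSE} +
  \mathrm{L1}$, both terms on the prediction error. The CNN consumes the
  full binary map without volume correction or selection (a network can
  learn the volume effect itself); with real scores, mass-univariate
  nulling (`applyNulling`) reduces input dimensionality instead.

Both networks train with decoupled-weight-decay Adam (AdamW). The
reference configuration is 200 epochs, batch size 2, learning rate 5e-5 (1e-4
plus reduce-on-plateau for real data), MSE loss. The convolution engine
is implemented in compiled code (im2col gather + BLAS products with an
exactly mirrored backward pass); training is bit-reproducible for a fixed
config seed on one machine.

The combined loss reads "L1" as the mean absolute *prediction* error, not
a weight penalty: it appears among the loss definitions on prediction
error, and `loss = "mse"` vs `"mse2_plus_l1"` keeps the choice
switchable.

# Attribution

* **Occlusion (CNN)**: a window slides over a stride lattice; each
  placement is zeroed — for binary lesion masks the natural baseline,
  "the lesion is absent here" — and
  $\Delta(W) = f(x) - f(x_{W \leftarrow 0})$ is recorded. A voxel's
  attribution is the mean of $\Delta(W)$ over all placements covering it
  (overlapping windows average; placements clip at the grid edge so every
  voxel is covered). Positive attribution means occlusion lowered the
  predicted score. On any linear model this definition has an analytic
  closed form, which the tests use as an exact oracle (tolerance 1e-6).
  Zeroing an all-zero window is a no-op, so such placements are skipped
  without evaluating the model — an exactness-preserving shortcut that
  makes cohort-scale occlusion cheap on sparse masks.
* **SVR beta-map**: dual back-projection
  $\beta_v = \sum_j \alpha_j x_{j,v}$ over support vectors; for a linear
  kernel this is exactly the primal weight vector (tested through the
  primal-dual prediction identity).
* **FNN weight map**: the linear layer's weights placed at their voxels.

Group-level maps apply the positive part first, then the voxelwise mean —
over every patient's test-fold occlusion map for the CNN (each patient
appears exactly once across the 5 folds), and over the 5 per-fold maps
for SVR/FNN.

# Evaluation

Predictive performance is the per-fold $R^2$ of the ordinary
least-squares regression of true on predicted scores (the squared Pearson
correlation; a constant prediction scores 0). Attribution accuracy uses:

* **PR-AUC**: descending thresholds over the attribution values inside
  the analysis mask; ROI voxels are the positives; step-wise area of
  precision over recall (all unique values, capped at 512 quantiles —
  exact on small maps, bounded cost on large ones). The analysis mask
  defaults to voxels lesioned in at least one subject: the universe of
  locations any lesion-based model could attribute to. A random
  attribution scores the in-mask ROI prevalence, the natural null.
* **Attribution ratio**: with only values above 10% of the map maximum
  kept, the kept mass inside ROIs over the kept mass outside (sums by
  default, means by option; a zero denominator reports `Inf`, never an
  error). The dilated variant counts a 5 mm Euclidean neighbourhood
  (honouring anisotropic voxels) as inside and reports the ratio factor.
* **Dice** of the 10%-thresholded map against the ROI union, and the
  list of **false-negative ROIs** (no supra-threshold voxel).

# The synthetic cohort generator

The generator stands in for restricted clinical WMH maps; it defines the
study conditions and is not tuned per experiment. Its pieces:

* **Prior field**: four "periventricular cap" Gaussians (left/right ×
  anterior/posterior horns) joined by weaker ventricle-body bands, inside
  a brain-shaped ellipsoid, with a seeded, mirror-symmetric low-frequency
  modulation (±10%) so different seeds give different but comparable
  populations. Intensity below 1% of the maximum is truncated to zero.
* **Per-subject volumes**: log-normal matched on the log scale to a
  median of 8 ml and an IQR of 3.2–20.9 ml — the right-skewed volume
  distribution typical of memory-clinic cohorts.
* **Lesion growth**: `1 + Poisson(4)` seeds drawn with probability
  proportional to the squared prior, then 6-connected region growing with
  accretion probability proportional to the cubed prior, until the
  target voxel count is reached. The powers concentrate lesions at the
  caps the way real WMH concentrate periventricularly; they were fixed
  once so that the documented feasibility invariant holds — at $n \ge
  100$ under defaults, at least three disjoint ROIs satisfy the
  per-voxel prevalence-≥10 constraint.

What the generator does *not* emulate: anatomical tissue boundaries,
lesion texture, registration error, scanner effects, or any non-lesional
determinant of cognition. Passing tests therefore demonstrate that the
pipeline recovers *planted* lesion-score structure under realistic
geometry and volume statistics — not clinical performance on real
cohorts.

# Desk-scale configuration

Nothing in the method depends on absolute resolution, so the default
experiment preset runs on a 1/10-scale head: an 18×22×18 grid at 10 mm
isotropic voxels (7128 voxels; 1 voxel = 1 ml), cohorts of 200 subjects,
and 2×2×2-voxel ROIs. At this scale the full three-model experiment with
attribution and evaluation completes in a few minutes on one CPU, which
is the problem size the test suite and the acceptance script use. The
choices worth knowing:

* **ROI size**: 2³ voxels. A 27-voxel cube at 10 mm cannot satisfy a
  per-voxel prevalence of 10 under an 8 ml median volume at n of a few
  hundred; an 8-voxel cube matches the prevalence the caps actually
  reach, while keeping the ROI:window geometry close to the reference
  configuration.
* **Occlusion geometry**: window 2³, stride 2³ in the experiment preset.
  The reference 5³/3³ geometry is defined for a 1 mm grid, where it spans
  half an ROI edge; at 10 mm voxels the same window would span 2.5 ROI
  edges and smear the attribution. The 5³/3³ defaults remain on
  `occlusionAttribution()` itself and are what the linear-model oracle
  tests exercise.
* **CNN preset**: channels 2→4, batch 8, learning rate 1e-3, 40 epochs;
  **FNN preset**: 300 epochs, batch 32, learning rate 5e-3, weight decay
  1. The elevated FNN decay is deliberate: volume correction makes the
  simulated score nonlinear in the features, and an unregularized linear
  fit of ~100 correlated features on 160 subjects interpolates training
  data (train $R^2$ ≈ 0.98) while generalizing poorly; decoupled decay
  plays the role SVR's cost parameter plays. All presets are plain
  arguments, and the reference values remain available through
  `trainingConfig()`.

# Numerical and degenerate-input decisions

* Binarization on load: `value > 0.5`, tolerating float-encoded masks.
* Grids must match exactly across a cohort; no resampling is attempted.
* Min–max normalization of a constant vector is an error, not a silent
  pass-through; an all-zero attribution map is likewise an error in the
  accuracy metrics.
* An empty lesion map volume-corrects to an all-zero map.
* If mass-univariate selection returns no voxel (possible at high noise),
  the fold falls back to the lesion-support mask so the pipeline remains
  total; the screen's type-I behaviour is tested separately.
* Tie-breaks: SVR grid search takes the first maximum in enumeration
  order; `makeFolds` sizes differ by at most one.
* Seeds: every stochastic stage derives its seed from the master seed via
  a fixed affine hash (`deriveSeed`), so stages re-run in isolation
  reproduce exactly.

# Known limitations

* The regularized CNN and the combined loss are implemented and tested on
  synthetic stand-ins; no real cohort ships with the package.
* SVR beta-maps use the customary dual back-projection, which is exact
  only for the linear kernel; for RBF it is an approximation whose
  interpretation is inherited from the LSM literature.
* The mass-univariate screen is a Welch t-test; other test families used
  in the LSM literature (e.g. rank-based) are not yet options.
* Occlusion cost grows with the number of lesion-containing windows;
  on dense masks at full 1 mm resolution a GPU implementation would be
  preferable — the package targets desk-scale validation, not
  production-scale imaging pipelines.
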