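# wmhlsm — individualized lesion-symptom mapping with occlusion attribution

`wmhlsm` is an R package for lesion-symptom mapping (LSM) of white matter
hyperintensities (WMH): relating *where* vascular white-matter lesions sit
to a per-subject cognitive score, and — beyond classical group-level LSM —
producing per-patient maps of the lesion locations that drive each
individual's predicted cognitive impairment.

It is aimed at neuroimaging researchers who have (or want to simulate)
cohorts of co-registered binary 3D lesion masks plus a scalar cognitive
score per subject, and who want to compare three LSM model families under
a controlled, ground-truth validation:

* **RBF support vector regression (SVR)** on volume-corrected, flattened,
  mass-univariately selected voxel features — the conventional
  multivariate LSM benchmark, with dual-coefficient **beta-maps** as
  attribution;
* a single-linear-layer + ReLU **fully connected network (FNN)** on the
  same features, with its **weight map** as attribution;
* a **3D convolutional neural network (CNN)** on the raw masks, made
  interpretable by **occlusion**: a sliding window is zeroed ("the lesion
  is removed here") and the prediction drop, averaged over covering
  windows, becomes a voxelwise attribution map — individually per
  patient.

## The core model

Validation is built on simulated cognitive scores with known ground
truth. For subject *i* and cuboid ROI *k* placed inside the cohort's
lesion-prevalence map (every ROI voxel lesioned in ≥ 10 subjects), the
lesion load `LL_ik` is the lesioned fraction of the ROI, and

```
score_i = Σ_k w_k · LL_ik        (then population min–max normalized)
noisy_i = (1 − nf)·score_i + nf·N(0, sd(score))   (then re-normalized)
```

Models are trained in 5-fold cross-validation; performance is the
per-fold OLS R² between predicted and true scores; attribution maps are
scored against the ROI ground truth by precision-recall AUC, the ratio
of supra-threshold (>10% of max) attribution mass inside vs outside the
ROIs (plain and with 5 mm ROI dilation), Dice, and false-negative ROIs.
A synthetic-cohort generator (periventricular-cap prior, log-normal
volumes with median 8 ml / IQR 3.2–20.9 ml, seeded region growing)
stands in for restricted clinical data.

## Worked example

```r
library(wmhlsm)

cfg <- experimentConfig(n = 200, masterSeed = 11)   # desk-scale preset
res <- runExperiment(cfg)
compareReports(res$reports)
```

which prints (masterSeed 11):

```
  model   r2_mean       r2_sd    pr_auc     ratio  dice n_false_negative
1   svr 0.9684480 0.007337794 0.9075846 0.7582983 0.374                0
2   fnn 0.8782234 0.043336893 0.5096356 0.4567637 0.366                0
3   cnn 0.9590075 0.015032093 0.8133089 1.3360919 0.357                0
```

Reading this: all three models recover the simulated scores out of
sample (R² ≈ 0.88–0.97, mean ± sd over the 5 test folds). The CNN's
occlusion attribution concentrates the most mass inside the ground-truth
ROIs (in/out ratio 1.34 versus ≈ 0.46–0.76 for the benchmarks), no model
misses an ROI entirely, and PR-AUCs are an order of magnitude above the
random-attribution null (the in-mask ROI prevalence, ≈ 0.07 here).

Per-patient maps are in `res$groupAttribution` (group) or come from
`occlusionAttribution(model, map)` for one subject; everything is
exportable as NIfTI (`writeVolume`) for inspection in any viewer.

A thin command-line front end with verbs `simulate-cohort`,
`run-experiment`, `evaluate` and `compare` is installed under
`inst/scripts/wmhlsm`.

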