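---
title: "Subregion heterogeneity and wavelet feature maps for lymph-node prediction: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Subregion heterogeneity and wavelet feature maps for lymph-node prediction: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(petlnm)
```

## The scientific problem

Epithelial ovarian cancer is markedly heterogeneous: uneven vascular supply
produces tumor subregions ("habitats") with distinct microenvironments and
distinct metabolic signatures on 18F-FDG PET. The hypothesis this package
operationalises is that the *relationships between* intensity subregions
inside the tumor — not the raw texture of any one subregion — carry
information about the tumor's biological aggressiveness, and in particular
about whether pelvic or para-aortic lymph nodes harbour metastases at the
time of staging surgery.

The pipeline therefore builds two complementary views of every tumor ROI:

1. **Subregion heterogeneity features.** ROI voxels are clustered by gray
   value with a Gaussian mixture model, and the *quality* of that clustering
   is summarised by three validity indices — the Calinski–Harabasz index,
   the mean silhouette coefficient, and a Davies–Bouldin index. A tumor
   whose intensity distribution splits into crisp, well-separated components
   scores differently from a homogeneous one, and the indices quantify that
   directly while remaining invariant to intensity scaling and shifts.
2. **Wavelet texture feature maps.** A representative axial slice is
   decomposed with a separable 2D discrete wavelet transform; the LL, LH and
   HL subbands are normalized, resized and stacked into a 3-channel image fed
   to a small residual convolutional network.

The network embedding and the screened validity features are fused in a
support-vector machine, and the fused classifier is evaluated with ROC/AUC
(bootstrap confidence intervals), sensitivity, specificity, and calibration
curves.

Because no patient imaging cohort is publicly deposited for this problem,
the package ships a first-class synthetic phantom generator so the entire
pipeline is exercisable and testable end to end.

## The phantom generator: what it emulates and what it does not

`generate_phantom()` builds an ellipsoidal "tumor" on a 3D grid. ROI voxels
are drawn from K Gaussian intensity components arranged either as
concentric equal-volume shells (`nested_shells`, the default — mimicking
core/rim habitat architecture, with contiguous subregions) or as Voronoi
cells around random seed voxels (`random_blobs`, for robustness tests).
Additive Gaussian noise is applied to the whole grid. The PET noise model is
a deliberate simplification: real PET noise is approximately Poisson-like
and spatially correlated by reconstruction; additive Gaussian noise is
sufficient for testing the pipeline's statistical machinery, which never
assumes a noise model.

`generate_cohort()` links a binary node label to heterogeneity through one
scalar knob: per sample, the gaps between consecutive subregion means are
multiplied by `separation_positive` (label 1) or `separation_negative`
(label 0). The defaults — 200 samples, half positive, separation 3.0 versus
1.0, a 20³ grid with semi-axes (7, 7, 7), K = 3 shells with base means
(2, 4.5, 8), within-subregion SD 0.8 and image noise SD 0.3 — were fixed
once as a plausible PET-like contrast regime: at separation 1 the component
gaps are 3–4 pooled SDs (resolvable but overlapping, as in a relatively
homogeneous tumor), while at separation 3 they are 9–13 SDs (crisp
habitats). No clinical dataset quantifies the true effect size of
heterogeneity differences between node-positive and node-negative tumors;
the planted effect is a simulation parameter, not an estimate, and passing
the end-to-end tests demonstrates that the pipeline *can recover a planted
signal of this magnitude*, not that real cohorts carry such a signal.

Determinism is a hard contract throughout: one global seed is fanned out to
every stage by a multiplicative-congruential scheme (`derive_seed`), every
stage logs its derived seed in the run manifest, and identical configs
reproduce bit-identical outputs in single-threaded mode.

## Segmentation

Clustering is **one-dimensional by design**: each ROI voxel is represented
by its gray value alone, never by its spatial coordinates. The EM fit uses
k-means++-style seeding, five restarts (best final log-likelihood wins),
a relative log-likelihood tolerance of 1e-4, at most 200 iterations, and a
variance floor of 1e-6 times the sample variance to prevent component
collapse. Components are relabelled by ascending mean so the labeling is
reproducible across restarts; the default K = 3 reflects the core/rim/
periphery habitat picture and is configurable. If a component captures no
voxels at assignment time, the voxel with the lowest maximum responsibility
is reassigned to it with a warning — the validity indices require nonempty
clusters. Before extraction, volumes are denoised with a separable 3D
Gaussian (SD 1 voxel, edge-replicated boundaries) by default; median and
identity filters are available and the choice is recorded in the run
manifest.

## The validity indices, exactly as defined

With clusters $C_1 \dots C_K$, sizes $n_k$, cluster means $c_k$, global mean
$c$, and Euclidean distances (absolute differences in 1D):

* **Calinski–Harabasz:**
  $CH = \dfrac{\sum_k n_k \lVert c_k - c\rVert^2 /(K-1)}
              {\sum_k \sum_{i \in C_k} (x_i - c_k)^2 /(N-K)}$ — higher is
  better separated.
* **Silhouette:** per point, $s_i = (b_i - a_i)/\max(a_i, b_i)$ with $a_i$
  the mean distance to own-cluster mates and $b_i$ the smallest mean
  distance to another cluster; the feature is the mean over points, in
  $[-1, 1]$. Singleton clusters contribute $s_i = 0$ (the usual convention).
* **Davies–Bouldin:**
  $DB = \frac{1}{K}\sum_i \max_{j \ne i}
  \frac{avg(C_i) + avg(C_j)}{d_{cen}(C_i, C_j)}$ where
  $avg(C) = \frac{2}{|C|(|C|-1)} \sum_{i<j} dist(x_i, x_j)$ is the **mean
  pairwise intra-cluster distance** — *not* the mean distance to the
  centroid used by most library implementations. The two variants differ
  numerically (on the fixture {0,1} vs {5,6}: 0.4 pairwise, 0.2 centroid);
  the pairwise form is the pipeline default and the test suite pins its
  value, with the centroid form available behind `variant = "centroid"` for
  comparison. Because the pairwise form divides by $|C|(|C|-1)$, clusters
  with fewer than two members raise an error rather than silently guessing.

Every index is verified against an independently written brute-force
evaluation on random instances to 1e-9 relative, and all three are
invariant to cluster relabeling, point reordering, positive scaling and
translation — the last two matter because PET intensity units are treated
as arbitrary throughout (no SUV normalization is assumed).

## Wavelet feature maps

The 2D transform applies an orthonormal 1D DWT to every row, then to every
column, giving LL/LH/HL/HH. The filter family defaults to Haar at level 1
(db2 is also provided); no published choice exists to follow here, so the
family is recorded config. The transform is **periodized** (odd dimensions
are first extended by replicating the last sample): this keeps the analysis
operator exactly orthogonal, so perfect reconstruction and Parseval energy
conservation hold to machine precision — properties the test suite asserts.
Wraparound artifacts are immaterial because slices are zeroed outside the
ROI mask, making the boundary flat.

One feature map is built per patient (policy `max_roi_area`: the axial
slice with the largest in-mask area, ties to the lowest index), which keeps
the 70/30 split a patient-level split with no slice-level leakage;
`all_roi_slices` and `central` policies exist for sensitivity analyses. LL,
LH and HL are each min-max normalized to [0, 1] independently (their
dynamic ranges differ by orders of magnitude; a constant subband maps to
zeros), bilinearly resized to the target size, and stacked in the fixed
order (LL, LH, HL). HH is computed and retained in the subband set but
excluded from the map. The pipeline default target size is 32 pixels to
match the desk-scale network; 224 is the natural choice for the full-size
preset.

## The residual network

No deep-learning framework is part of this package's dependency stack, so
the network is implemented directly on R matrix algebra: convolutions as
im2col matrix products, exact backpropagation (validated against numerical
differentiation in the tests), Adam on mean binary cross-entropy, and
inverted dropout on the pooled embedding. The architecture follows the
residual pattern: a 3×3 stem convolution, stages that open with a
projection-shortcut convolutional block and continue with identity blocks,
global average pooling, dropout, and a single sigmoid unit. Batch
normalisation is omitted; at the small widths and depths of the desk-scale
preset, plain He initialisation with Adam trains stably, and omitting it
keeps the forward pass free of train/test statistics mismatches.

Two presets exist. `tiny` (stem 8, stages 8/16 with 2 blocks each, 32-pixel
input, ~11k parameters) is the pipeline default and what the tests train.
`resnet50` reproduces the canonical large-network stage layout — 3/4/6/3
blocks at widths 64/128/256/512 on 224-pixel input (~21M parameters, built
with basic two-conv blocks) — for architectural fidelity and parameter-count
comparisons; training it is out of desk scope and its published weights are
not available, so transfer learning is deliberately a non-goal. Training
carves a stratified 20% validation split out of the training partition,
records per-epoch train/validation loss and accuracy, and returns the
best-validation-accuracy checkpoint.

## Fusion, screening and leakage control

Tabular features are screened by point-biserial correlation with the label
(|r| ≥ 0.3 by default — "strong correlation" made concrete), computed on
the training partition only; zero-variance features are dropped with a
warning. The fused classifier concatenates the CNN's pooled embedding (or
its output probability, by config) with the screened features, standardises
with training-set statistics, and fits an RBF SVM. Probabilities come from
a Platt calibration of the SVM decision values, fitted on the training
partition with the standard regularized targets; this is deterministic and
learns the margin's sign rather than assuming it. A dedicated test asserts
that shuffling test-partition labels before fitting leaves test predictions
bit-identical — the structural guarantee that no test information reaches
any fitted component.

The 70/30 split rounds half-up (157/67 at n = 224) and stratifies by
largest remainder, preserving class proportions to within one sample. The
held-out 30% is treated strictly as a test set: it is never touched during
training or model selection. (The alternative reading — a validation set
monitored during training — is handled inside the training partition by the
internal validation split instead.)

## Evaluation

AUC is computed from midranks (the Mann–Whitney pairwise statistic, ties
one half) and independently as the trapezoidal area under the empirical ROC
curve; the two agree to 1e-12 on random instances by construction and the
suite asserts it. Confidence intervals default to a stratified bootstrap
percentile interval (2000 resamples; positives and negatives resampled
separately so no resample is degenerate), with the asymptotic DeLong method
available as an alternative; no published method choice exists to follow.
Sensitivity, specificity and accuracy are reported at a fixed 0.5 threshold
by default — a Youden-optimal threshold is available but always reported
together with the threshold used, since an operating point chosen on the
same data flatters both rates. Calibration uses 10 equal-width bins on
[0, 1], reporting mean predicted probability, observed positive fraction
and count per occupied bin.

## Problem sizes used by the tests and the acceptance script

The shipped simulations use 200-phantom cohorts on 20³ grids (≈1,470 ROI
voxels per tumor), 32-pixel feature maps, the `tiny` preset at 12 epochs,
2000-resample bootstrap CIs in the pipeline reports, and 200 replicates ×
500 resamples for the CI coverage study. These sizes make every planted
effect detectable with comfortable margins while keeping a full run in the
minutes range on one core; they are the package's reference study
conditions, and all of them are config, not constants.

## Known limitations

* The phantom emulates intensity architecture, not PET physics: no
  attenuation, scatter, partial-volume or reconstruction correlation
  structure. Passing tests demonstrate pipeline correctness, not clinical
  validity.
* Clustering ignores spatial contiguity by construction; a tumor with
  salt-and-pepper intensity mixing and one with clean shells can score
  identically on the validity indices.
* K is fixed (default 3), not selected per tumor; model selection over K is
  an explicit non-goal.
* No patient imaging cohort for this prediction task is publicly deposited,
  so clinical performance cannot be reproduced or benchmarked here; the
  shipped checks anchor on worked examples, oracles and planted-signal
  simulations instead.
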