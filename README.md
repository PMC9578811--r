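# petlnm

PET-radiomics pipeline for predicting pathological lymph-node metastasis in
ovarian cancer from intratumoral heterogeneity.

## What it does

Whether lymph nodes harbour metastases decides the surgical stage, the
extent of dissection and the adjuvant regimen for ovarian-cancer patients,
yet preoperative imaging assessment of nodes is unreliable. This package
implements a pipeline that predicts node status from the **primary tumor's
own heterogeneity** on 18F-FDG PET, combining two views of the tumor ROI:

1. **Subregion (habitat) heterogeneity.** ROI voxels are clustered by gray
   value with a Gaussian mixture model into K subregions, and the clustering
   is scored by three validity indices used as features:
   - Calinski–Harabasz: `CH = [Σ_k n_k‖c_k − c‖²/(K−1)] / [Σ_k Σ_{i∈C_k}(x_i − c_k)²/(N−K)]`
   - mean silhouette: `s_i = (b_i − a_i)/max(a_i, b_i)`, averaged, in [−1, 1]
   - Davies–Bouldin with **mean pairwise** intra-cluster distance,
     `avg(C) = 2/(|C|(|C|−1)) Σ_{i<j} dist(x_i, x_j)`,
     `DB = (1/K) Σ_i max_{j≠i} [avg(C_i)+avg(C_j)]/d_cen(C_i, C_j)`
2. **Wavelet texture.** A separable 2D DWT of the largest-area axial slice
   yields LL/LH/HL subbands, normalized and stacked into a 3-channel feature
   map classified by a residual CNN (implemented natively in R).

The CNN embedding and the correlation-screened validity features are fused
in an SVM; evaluation reports accuracy, AUC with bootstrap confidence
intervals, sensitivity, specificity and calibration curves.

Because no patient cohort is publicly deposited, the package includes a
synthetic phantom generator that plants label-linked subregion structure,
so every stage is testable end to end. See the methods vignette
(`vignettes/petlnm-methods.Rmd`) for the full model description and design
rationale.

## Worked example

```r
library(petlnm)

# a 200-tumor synthetic cohort: node-positive tumors get 3x the subregion
# mean gaps of node-negative ones
res <- run_pipeline(run_config(seed = 7))
res$test_report
#> Evaluation (n = 60, threshold = 0.5)
#>   accuracy    1.0000
#>   AUC         1.0000  (95% CI 1.0000-1.0000)
#>   sensitivity 1.0000
#>   specificity 1.0000

head(res$features, 3)
#>   sample_id      chi silhouette       dbi K    N node_label
#> 1     S0001 5455.164  0.5838245 0.6398650 3 1472          0
#> 2     S0002 4957.395  0.5602002 0.6508457 3 1472          0
#> 3     S0003 6928.659  0.6764233 0.5548149 3 1472          1
```

The planted separation (3.0 vs 1.0) is an easy regime by construction: the
Calinski–Harabasz index alone separates the classes nearly perfectly, and
the fused model should reach a test AUC near 1. A null cohort
(`cohort_spec(separation_positive = 1.5, separation_negative = 1.5)`)
yields chance-level AUC.

Individual stages are plain functions:

```r
s   <- generate_phantom(phantom_spec(seed = 1))
vol <- denoise_volume(s$volume, "gaussian", width = 1)
vs  <- extract_voxel_sample(vol, s$mask)
seg <- fit_gmm_segmentation(vs, gmm_config(K = 3, seed = 1))
compute_cluster_features(vs, seg)
#> $chi        [1] 4863
#> $silhouette [1] 0.56
#> $dbi        [1] 0.637
```

Here the tumor's intensity histogram splits into three well-separated
subregions (high Calinski–Harabasz, silhouette well above 0, moderate
Davies–Bouldin); in a cohort these three numbers per tumor are the
heterogeneity features that feed screening and fusion.

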