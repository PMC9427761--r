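---
title: "Peritumoral-ring radiomics for tumor immune microenvironment prediction: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Peritumoral-ring radiomics: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The scientific problem

The immune milieu inside and immediately around a tumor — the tumor immune
microenvironment (TIME) — carries prognostic and treatment-predictive
information. One summary of it is the neutrophil-to-lymphocyte ratio (NLR),
counted from stained tissue separately in the intratumoral and peritumoral
regions and thresholded at 1 in each:

* **NLR-High**: ratio ≥ 1 in both regions;
* **NLR-Mix**: ratio ≥ 1 in exactly one region;
* **NLR-Low**: ratio < 1 in both.

Obtaining the label requires tissue. The hypothesis behind this package is
that contrast CT texture inside the tumor and in a thin shell around it
carries a readable imprint of that immune state, so that a **radiomics
score (RS)** — a sparse linear combination of image features — can predict
NLR status noninvasively, and through it stratify survival and anti-PD-1
response.

`ringomics` implements the full analysis pipeline — peritumoral ring
construction, a 584-feature IBSI-style pool, mRMR + cross-validated LASSO
signature fitting, and survival/response evaluation — and, because real
patient CT cohorts of this kind are not publicly available, ships a
synthetic phantom cohort generator that plants a controllable class signal
so every stage is testable end to end.

# Ring geometry

The peritumoral ROI is the band of signed Euclidean distance
$d(x) \in (-d_\text{in}, +d_\text{out}]$ around the tumor boundary, by
default 1 mm inward and 2 mm outward — a 3 mm shell capturing the invasive
margin. We compute $d(x)$ as the difference of two anisotropic Euclidean
distance transforms (distance to the nearest tumor voxel centre minus
distance to the nearest background voxel centre; exactly one term is
nonzero per voxel), evaluated with a separable lower-envelope algorithm in
millimetres, so anisotropic spacing is handled exactly. The boundary is
placed at the voxel-face interface: centre-to-centre distances are shifted
toward the boundary by half the smallest voxel pitch, so a voxel
immediately inside the tumor sits at about −h/2 rather than −h — without
the shift, a 1 mm inner band would be empty on a 1 mm grid. The test suite
checks the transform against full pairwise
enumeration, and the measured radial thickness of the ring on a 20 mm
digital sphere at 0.5 mm spacing against the nominal 3 mm band within one
voxel diagonal.

The **intratumoral ROI is the full tumor mask**; the ring's inner 1 mm band
intentionally overlaps it. Nothing in the method description we follow
indicates the tumor ROI is eroded, so we kept the full mask and treat the
alternative (tumor minus inner shell) as an open design question.

Air cavities, vessels and adjacent structures are excluded from the ring by
Hounsfield thresholds (default: exclude < −500 HU or > +300 HU). These
thresholds are a deliberate simplification — in clinical practice such
exclusions are drawn manually — and are exposed in the configuration rather
than fixed.

# The feature pool

Each region contributes 292 features, 584 in total:

| family | count | notes |
|---|---|---|
| first-order | 14 | mean, median, min, max, range, variance, SD, skewness, kurtosis, energy, entropy (fixed 64-bin), MAD, RMS, uniformity |
| shape | 8 | volume, surface area, surface/volume, sphericity, max 3D diameter, major/minor axis, elongation |
| texture | 45 × 6 bins = 270 | 24 GLCM + 16 GLRLM + 5 NGTDM at bin counts 8, 16, 32, 64, 128, 256 |

The texture catalogue is a reconstruction: the source feature list is not
itemized publicly, but the three named families with their standard IBSI
feature sets (24 + 16 + 5 = 45) tile 270 exactly over six discretizations,
and this composition is configuration-overridable. Note the GLCM set uses
24 distinct statistics: *dissimilarity* is omitted as a separate entry
because, for a merged symmetric co-occurrence matrix, it is mathematically
identical to *difference average*.

Numerical conventions worth knowing:

* **Discretization** is fixed bin *count* over the ROI's own [min, max]
  (not fixed bin width): robust to the HU ranges of synthetic cohorts and
  one of the two standard IBSI options. A constant ROI maps to level 1.
* **GLCM/GLRLM direction handling** is merge-then-normalize over the 13
  unique 3D offsets ("merged" aggregation), giving a single deterministic
  value per feature and invariance to 90° grid rotations on isotropic
  grids. Run percentage is normalized by 13 × (ROI voxel count) so it stays
  in (0, 1].
* **Degenerate conventions**: skewness/kurtosis of a constant ROI are 0;
  GLCM correlation and the information-correlation features are 0 when the
  relevant variance or entropy vanishes; NGTDM coarseness is capped at 1e6
  on constant ROIs.
* **Surface area** uses a triangulated isosurface extracted by marching
  tetrahedra at the 0.5 level of the binary mask smoothed with a small
  Gaussian (0.8 voxels). Meshing the raw binary surface overestimates a
  sphere's area by ~8% (sphericity ≈ 0.92); the light smoothing removes
  that voxelization bias (digital-sphere sphericity ≈ 0.99) while leaving
  volume — computed as voxel count × voxel volume — untouched.
* **Maximum 3D diameter** is the largest centre-to-centre distance between
  surface voxels, computed exactly after reducing candidates to per-column
  extremes (a superset of the convex hull vertices).

# Synthetic cohorts: what is emulated, what is not

The generator produces, per case, a CT-like phantom: a smooth
abdominal-like background (~40 HU), a randomly perturbed ellipsoidal tumor
(default mean radius 8–12 mm), and stationary Gaussian random fields
filling the tumor interior and its 0–4 mm shell. Fields are white noise
smoothed by a separable Gaussian kernel whose width is the configured
correlation length, rescaled to unit variance before applying the class's
SD and mean, and the volume is clamped to [−1024, 3071] HU.

**The planted class signal lives in the correlation length**: 4 mm
(NLR-High) vs 2 mm (NLR-Low) in both regions at equal SD (15 HU) and mean
(60 HU). The Mix class interpolates halfway (3 mm) in the intratumoral
region only, matching its one-region-affected label semantics. Correlation
length was chosen as the planted axis because co-occurrence and gray-tone
difference statistics respond smoothly and monotonically to it, giving a
controllable effect without trivially separable first-order differences.

Clinical records are linked to the latent class:

* **NLR ratios** come from class-conditioned neutrophil/lymphocyte count
  draws constructed to satisfy the labeling rule exactly (Mix sub-types
  chosen with equal probability). The count distributions are placeholders
  — no public distributional information about real in-tissue NLR counts
  exists to calibrate against.
* **Survival** follows a Weibull proportional-hazards model (shape 1.2,
  scale 36 months) with class log-hazard-ratios (0 / 0.5 / 1.0 for
  Low / Mix / High, i.e. a High-vs-Low HR of e ≈ 2.7, inside the reported
  clinical range) plus a small age effect. OS = DFS + an independent
  exponential residual (mean 6 months), guaranteeing DFS ≤ OS. Censoring is
  uniform on (0, c); the horizon c is solved numerically so a baseline
  subject's censoring probability equals the configured rate (default 0.3).
* **Response** is a plain categorical draw per class with probabilities
  anchored to the reported objective-response and disease-control rates of
  low- vs high-RS groups; no tumor-volume dynamics are simulated.

What the phantoms do **not** emulate: anatomy, organ boundaries, contrast
phases, scanner/reconstruction effects, segmentation error, or any
nonstationarity of real tumor texture. Passing tests on these cohorts
therefore demonstrates that the pipeline's machinery is correct and can
recover a planted texture–class association at realistic sample sizes — not
that the clinical effect size would be reproduced on real patients.

# Signature fitting

Training labels are **NLR-High = 1 vs NLR-Low = 0, Mix excluded**: the
primary discrimination target is the High-vs-Low contrast, with
High-vs-rest treated as an evaluation-only secondary contrast.

1. **mRMR pre-selection** (FCD variant): relevance is the one-way ANOVA
   F-statistic against the label, mapped onto the correlation scale as the
   point-biserial correlation √(F/(F+n−2)) so that it is commensurable with
   the redundancy term (a raw F minus a correlation would let relevance
   swamp redundancy by two orders of magnitude); redundancy is the mean
   absolute Pearson correlation with already-selected features; greedy
   selection of the top k = 30, ties broken by catalogue order. The variant
   and k are not dictated by the source method description; they were
   chosen for determinism on continuous features and are
   configuration-exposed.
2. **LASSO logistic regression** on the z-scored top-k (training means and
   SDs; standardization is refit with the model, which makes the RS
   invariant to affine rescaling of any raw feature). The penalty minimizes
   mean binomial deviance over seeded, label-stratified 5-fold
   cross-validation (the minimum rule, not 1-SE: the criterion named is the
   expected generalization error, and the minimum is its direct estimate).
3. The **RS** is the fitted linear predictor; tertiles of the training RS
   (boundaries closed on the lower-group side: RS ≤ q1 → RS-Low) define the
   three RS groups.

An all-zero coefficient vector at the chosen penalty raises an explicit
`signature_empty_error` pointing at the cross-validation curve rather than
returning a degenerate signature.

Honest discrimination is estimated by `oof_auc()`: an outer 5-fold loop
refits the *entire* selection-and-fit pipeline per fold and pools held-out
scores into one AUC, so feature selection never sees the evaluation fold.

# Evaluation

* **ROC/AUC**: Mann–Whitney AUC with tie credit 0.5; DeLong 95% CI (the
  variance method is unstated in the source; DeLong is the field default).
* **Survival**: Kaplan–Meier product-limit curves with Greenwood variance;
  K-group log-rank tests; univariate Cox screens (likelihood-ratio p <
  0.05) feeding a multivariate Cox model with Efron tie handling (ties
  method unstated in the source; Efron is the standard default).
* **C-index**: Harrell's concordance with a seeded 1000-draw bootstrap
  percentile CI (CI method unstated in the source).
* **Nomogram**: the multivariate model's linear predictor rescaled so the
  largest single-covariate effect range spans 100 points and a case at all
  reference levels scores 0; only this linear-predictor scoring is
  implemented, not the graphical chart.
* **Response tables**: objective response = CR+PR, disease control =
  CR+PR+SD, rates per RS group (empty groups report NA, never 0%);
  chi-square on the group × response table; two-tailed unpaired t-tests of
  RS between response groups. No multiple-testing correction is applied
  across subgroup analyses, matching the source analysis; interpret
  secondary p-values accordingly.

# Problem sizes and determinism

The shipped study conditions use 240-case cohorts (80 per class) on 48³
grids at 1 mm spacing — large enough for stable selection and AUC
estimation, small enough for a desk-scale rerun; the package-level checks
use a 64³ case for the feature-pool count and an 89³ half-millimetre sphere
for ring geometry. Every stochastic step (cohort draw, fold assignment,
bootstrap) is seeded, and cohort generation is a pure function of its
config, which the pipeline manifest records alongside MD5 checksums of all
outputs; rerunning with the same config and seed reproduces the checksums
bit for bit.

# Known limitations

* The texture catalogue is a plausible reconstruction of an unpublished
  feature list; absolute feature values need not match any other
  implementation (direction merging, binning and degenerate conventions
  all vary across radiomics software), although each feature follows its
  standard IBSI definition.
* HU-threshold exclusion cannot remove isodense adjacent organs; true
  anatomical exclusion would need segmentation.
* The phantom texture model is stationary and Gaussian; real tumor texture
  is neither, so effect sizes on phantoms say nothing quantitative about
  clinical discrimination.
* DICOM ingestion, 2D slice-wise analysis, wavelet/LoG filtered features,
  competing risks and time-dependent AUC are out of scope.
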