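# ringomics

Peritumoral-ring CT radiomics for predicting the tumor immune
microenvironment, in R.

## What problem this solves

The balance of neutrophils and lymphocytes inside and immediately around a
tumor — summarized as the per-region neutrophil-to-lymphocyte ratio (NLR),
thresholded at 1 — stratifies prognosis and anti-PD-1 immunotherapy
response, but measuring it requires stained tissue. `ringomics` implements
a noninvasive surrogate: a **radiomics score (RS)** built from paired
intratumoral and peritumoral CT texture features that predicts NLR status
(High: both regions ≥ 1; Mix: exactly one; Low: neither) and is then
evaluated against survival and treatment response.

The package is aimed at quantitative-imaging researchers who want a tested,
fully seeded reference implementation of this class of pipeline. Since
clinical CT cohorts with in-tissue NLR labels are not publicly available,
the package includes a synthetic phantom cohort generator with a planted,
tunable texture–class effect, so the entire pipeline runs and is validated
without any data download.

## The method in brief

1. **Ring geometry** — the peritumoral ROI is the signed-distance band
   (−1 mm, +2 mm] around the tumor boundary (a 3 mm shell), computed with
   an anisotropic Euclidean distance transform; air/vessel voxels are
   excluded by HU thresholds. The intratumoral ROI is the full tumor mask.
2. **Feature pool** — 292 features per region, 584 per case: 14 first-order
   + 8 shape + 270 texture (24 GLCM + 16 GLRLM + 5 NGTDM at six fixed bin
   counts: 8–256), per IBSI-style definitions with merged 13-direction
   aggregation.
3. **Signature** — mRMR (F-statistic relevance, Pearson redundancy, top 30)
   followed by LASSO logistic regression (NLR-High vs NLR-Low) with the
   penalty minimizing 5-fold cross-validated binomial deviance; the RS is
   the linear predictor

   RS = β₀ + Σᵢ βᵢ · (xᵢ − μᵢ)/σᵢ

   over the selected features, and training-RS tertiles define the RS-Low /
   RS-Middle / RS-High groups.
4. **Evaluation** — ROC/AUC with DeLong CI, Kaplan–Meier + log-rank,
   univariate/multivariate Cox (Efron ties, p < 0.05 entry), Harrell's
   C-index with bootstrap CI, nomogram linear-predictor points, RECIST
   response-rate tables with chi-square and two-tailed unpaired t-tests.

## Worked example

```r
library(ringomics)

# a seeded 60-case phantom cohort with the default planted texture effect
cfg <- cohort_config(n_cases = 60, seed = 7)
cohort <- generate_cohort(cfg, balanced = TRUE)
table(cohort$clinical$nlr_status)
#> High  Low  Mix
#>   20   20   20

# rings + 584-feature table
features <- extract_cohort(cohort$cases)
dim(features)
#> [1]  60 585

# fit the signature on High vs Low
hl  <- cohort$clinical$nlr_status %in% c("High", "Low")
x   <- as.matrix(features[, -1])
sig <- rs_fit(x[hl, ], as.integer(cohort$clinical$nlr_status[hl] == "High"),
              k = 30, nfolds = 5, seed = 7)
print(sig)
#> Radiomics signature (mRMR + LASSO logistic regression)
#>   training cases: 40  folds: 5  lambda: 0.0005375
#>   selected features (8):
#>     peri_glcm_information_correlation_2_b128 +3.4925
#>     peri_glcm_inverse_variance_b8            -0.4522
#>     peri_glcm_information_correlation_2_b64  +0.5842
#>     intra_ngtdm_complexity_b128              -0.5929
#>     peri_glcm_information_correlation_1_b256 -1.2783
#>     peri_first_order_range                   -0.9285
#>     peri_glrlm_run_length_variance_b32       +0.2354
#>     intra_ngtdm_complexity_b32               -1.0895
#>   intercept: +0.0088
#>   RS tertile cutoffs: -7.2930 / 7.3675

# honest out-of-fold discrimination (refits the whole pipeline per fold)
oof_auc(x[hl, ], as.integer(cohort$clinical$nlr_status[hl] == "High"),
        seed = 7)$auc
#> [1] 1

# survival evaluation of the RS
rs <- compute_rs(sig, x)
cx <- cox_fit(cbind(cohort$clinical, rs = rs), "dfs_time", "dfs_event",
              c("rs", "age"), entry_p = 1)
print(cx)
#> Cox proportional hazards (Efron ties)
#>   multivariate covariates: rs, age
#>     rs                       HR 1.045 (1.004-1.088) p=0.03189
#>     age                      HR 1.009 (0.983-1.035) p=0.4999
#>   C-index 0.599 (SE 0.045)
```

The selected features concentrate in the co-occurrence and gray-tone
difference families — exactly where the planted correlation-length
difference between NLR-High and NLR-Low texture (4 mm vs 2 mm) is
expressed — and the RS hazard ratio reflects the survival effect planted
through the class log-hazard-ratios. On this strong default effect the
out-of-fold AUC saturates at 1.0; shrink the class gap in
`cohort_config()`'s `texture_params` to explore harder regimes.

One call runs every stage (simulate → ring → extract → fit → evaluate)
with CSV outputs and a checksummed manifest:

```r
manifest <- run_pipeline(default_run_config(seed = 1), "out/")
```

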