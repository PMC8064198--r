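# stilquant

Automated quantification of stromal tumor-infiltrating lymphocytes
(sTIL) on H&E-stained tissue images, and the downstream
genotype–sTIL–survival analysis used in cancer-cohort epidemiology.

Tumor-infiltrating lymphocytes reflect the immune microenvironment of a
tumor; the *stromal* fraction — lymphocytes scattered in the stroma
between tumor cells, not in direct contact with them — is a
reproducible prognostic biomarker, but manual scoring by pathologists is
subject to inter-observer variability. `stilquant` implements an
unsupervised three-step scoring algorithm plus the statistics that turn
per-patient sTIL values and SNP genotypes into prognostic conclusions:

1. **Quantization** — Gaussian-mixture decomposition of each RGB
   channel (EM), k-means clustering of the pooled mixture components
   into K quantization classes with the class count chosen by the Dunn
   criterion, and semantic annotation of classes into nucleus /
   cytoplasm / stroma / other.
2. **Lymphocyte identification** — connected nucleus segments are
   classified by five features: relative nuclear size, roundness
   4&pi;A/P&sup2;, eccentricity, nucleus-to-cell size ratio, and
   staining variation; lymphocytes are rebuilt from nucleus plus
   attributed cytoplasm.
3. **Scoring** — restricted to tumor regions, the sTIL percentage is
   100 × (stromal lymphocyte area) / (stroma area).

Downstream, the package provides tie-corrected Kruskal–Wallis
genotype–sTIL screens with rank-sum post-hoc pairs, chi-square
independence tests, Kaplan–Meier / log-rank / Cox proportional-hazards
DFS models (reference and dominant genotype codings, treatment-stratified
fits, configurable adjustment sets), and a train/test ROC comparison of
a combined clinical + sTIL + SNP risk model against a clinical-only
model using DeLong's test for paired AUCs.

Real slides and patient data are rarely shareable, so the package also
ships generators for synthetic H&E-like tiles with exact ground-truth
masks and for cohorts with Hardy–Weinberg genotypes, genotype-dependent
sTIL shifts and proportional-hazards DFS — every accuracy claim is
validated against these.

## Worked example

Score a synthetic tile end to end:

```r
library(stilquant)

sim <- render_tile(tile_sim_config(seed = 7), target_stil_percent = 30)
sim$truth$true_stil_percent
#> [1] 30.49407

q <- quantify_tile(sim$tile, seed = 107, K_range = 2:6,
                   tumor_mask = sim$truth$tumor_mask)
q
#> <stil_quantification> K = 4 classes; 372 nuclei, 294 lymphocytes
#> <stil_result> tile: sTIL 30.37% (9916 / 32650 px; tumor region: provided)
```

The Dunn criterion picked K = 4 quantization classes (the tile has four
color populations); 294 of 372 nucleus segments passed the five
lymphocyte criteria, and their stromal area inside the tumor region
gives an sTIL of 30.4% against a ground truth of 30.5%.

Simulate a cohort and ask whether genotypes shift sTIL and survival:

```r
co <- simulate_cohort(cohort_sim_config(n_patients = 969, seed = 1))
sw <- snp_sweep(co, c("snp01", "snp02", "snp05"))
sw$tests[, c("snp", "H", "p", "significant")]
#>     snp        H            p significant
#> 1 snp01 30.58750 2.280386e-07        TRUE
#> 2 snp02 10.04998 6.571644e-03        TRUE
#> 3 snp05  4.72189 9.433105e-02       FALSE

fit <- adjusted_snp_analysis(co, "snp03", model = "dominant",
                             combine = "A/A")
fit$table[1, c("term", "hr", "ci_lo", "ci_hi", "p")]
#>            term       hr   ci_lo   ci_hi            p
#> 1 snp03:A/C+C/C 1.667088 1.35831 2.04606 1.006901e-06

cmp <- compare_models(co,
  clinical_covariates = c("age", "sex", "grade", "treatment", "bmi", "tea"),
  full_covariates = c("age", "sex", "grade", "treatment", "bmi", "tea",
                      "stil", "snp02", "snp03", "snp04"),
  seed = 9)
cmp
#> <roc_comparison> AUC combined 0.726 vs clinical 0.621 (delta 0.106,
#> DeLong p = 0.0123; n_test = 186, horizon 1095 d)
```

`snp01` and `snp02` carry simulated sTIL shifts and are flagged by the
Kruskal–Wallis screen while the null SNP is not; the dominant-coded
`snp03` hazard ratio recovers its simulated prognostic effect; and
adding sTIL + SNPs to the clinical Cox model raises the 3-year
test-set AUC, with DeLong's test quantifying the improvement.

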