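# mrix

Margin Risk Index (MRIx) scoring and survival validation for surgical
margins after neoadjuvant immunochemotherapy (NICT) in HPV-negative head
and neck squamous cell carcinoma (HNSCC).

## What problem this solves

After NICT, resections routinely pass through the original tumor bed, and
the anatomical definition of a "negative" margin (millimetres of tumor-free
tissue) stops tracking the biology that actually drives recurrence. The
MRIx replaces the binary margin call with a weighted composite of four
margin-biology domains, each scored 0 (favorable), 1 (intermediate) or 2
(adverse):

| Domain | Markers | Weight |
|---|---|---|
| Histopathology | TLS density (/mm²) | 0.30 |
| Tumor burden | Pan-CK⁺ foci (/mm²), Ki-67 (%) | 0.25 |
| Molecular MRD | driver mutations (TP53/NOTCH1), PD-L1 RNA fold-change | 0.25 |
| Immune contexture | CD8⁺/FoxP3⁺ ratio, Granzyme B⁺ (/mm²) | 0.20 |

$$\mathrm{MRIx} = 0.30H + 0.25T + 0.25M + 0.20I \in [0,2]$$

with categories low (0–0.8), intermediate (0.9–1.4) and high (1.5–2.0)
after half-up rounding to one decimal, and a margin distance ≤ 2 mm forcing
the high-risk category outright. The package provides:

* the **scoring engine** (`score_cohort()`, `compute_mrix()`) with every
  threshold configurable and the published values as defaults;
* a **synthetic cohort generator** (`generate_cohort()`) reproducing the
  study's marginal biomarker/covariate frequencies and
  proportional-hazards outcomes at configurable true effect sizes, with a
  baseline hazard calibrated by bisection to target event rates;
* **survival kernels written in the package** — Kaplan–Meier with
  Greenwood variance, k-sample log-rank, Cox regression with Efron ties
  (Newton–Raphson, score norm < 1e-8), Harrell's C (brute-force and
  Fenwick-tree paths), LRT/AIC model comparison, Breslow baseline,
  fixed-horizon Hosmer–Lemeshow calibration, Benjamini–Hochberg
  adjustment — cross-checked against the `survival` package in the tests;
* the **analysis pipeline**: baseline tables, per-domain log-rank
  analyses, the adjusted multivariable MRIx model, the nested
  model-performance comparison, and the frozen-score external-validation
  workflow (`validate_external()`).

Intended users: biostatisticians and translational researchers who want to
stratify post-NICT cohorts with the published rubric, or to study the
index's statistical behaviour under a controlled data-generating process.

## Worked example

Score a patient and analyse a study-sized synthetic cohort:

```r
library(mrix)

patient <- data.frame(
  tls_density = 0.8, panck_foci = 2.1, ki67_pct = 12,
  n_driver_mutations = 1, pdl1_fold = 1.4,
  cd8_foxp3_ratio = 1.5, gzmb_density = 120, margin_mm = 7)
score_cohort(patient)[, c("mrix_score", "mrix_category", "override_applied")]
#>   mrix_score mrix_category override_applied
#> 1        1.3  intermediate            FALSE
```

The TLS-poor margin scores 2 on histopathology and 1 elsewhere, giving
0.30·2 + 0.25·1 + 0.25·1 + 0.20·1 = 1.30: intermediate risk, no override
(margin 7 mm > 2 mm).

```r
co <- generate_cohort(training_sim_config(n_patients = 144, seed = 1))
table(co$mrix_category)
#>          low intermediate         high
#>           40           76           28

fit_adjusted_mrix_model(co, "lrc")
#> Cox proportional-hazards fit (efron ties)
#> n = 144 , events = 29 , loglik = -134.334 , AIC = 280.669
#>                                  coef    se   hr lower upper      p
#> differentiation_moderate        0.454 0.539 1.57 0.547  4.53 0.4004
#> differentiation_poor            0.865 0.495 2.37 0.900  6.26 0.0807
#> pathologic_response_mPR_not_pCR 0.171 0.484 1.19 0.459  3.07 0.7242
#> pathologic_response_no_mPR      0.383 0.506 1.47 0.544  3.95 0.4491
#> mrix_category_intermediate      0.635 0.520 1.89 0.681  5.23 0.2218
#> mrix_category_high              0.918 0.581 2.50 0.801  7.82 0.1144
```

At the study's n = 144 (29 locoregional events) the high-risk hazard ratio
is estimated at 2.50 with a wide interval — single-cohort estimates at this
size are noisy, which is why the recovery checks below use n = 20,000.
`compare_models(co, "lrc")` fits the Clinical → Clinical+margin →
Clinical+MRIx chain on identical rows and reports C-index, AIC and
likelihood-ratio statistics; `validate_external()` applies a frozen scoring
configuration to an independent cohort and returns Kaplan–Meier
stratification, C-index, adjusted hazard ratios and 36-month calibration.

See `vignettes/mrix-methods.Rmd` for the model, its assumptions, and every
numerical design choice.

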