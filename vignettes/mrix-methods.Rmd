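---
title: "Methods behind the Margin Risk Index (MRIx) pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods behind the Margin Risk Index (MRIx) pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrix)
```

## The problem

After neoadjuvant immunochemotherapy (NICT) for HPV-negative head and neck
squamous cell carcinoma, resections are routinely carried out inside the
original tumor bed. An anatomical margin — millimetres of tumor-free tissue —
then says little about the biology left *in situ*: a "clear" margin can hide
persistent oncogenic drivers and an exhausted immune microenvironment, while
tissue containing scattered residual cells can be immunologically controlled.
The Margin Risk Index (MRIx) replaces the binary positive/negative call with
a weighted composite of four margin-biology domains, each graded 0
(favorable), 1 (intermediate) or 2 (adverse):

* **Histopathology** — tertiary lymphoid structure (TLS) density:
  $\ge 3/\mathrm{mm}^2 \to 0$, $[1,3) \to 1$, $<1 \to 2$.
* **Tumor burden** — Pan-CK$^+$ foci ($0 \to 0$, $(0,5) \to 1$, $\ge 5 \to 2$)
  and Ki-67 index ($<5\% \to 0$, $5\!-\!20\% \to 1$, $>20\% \to 2$).
* **Molecular MRD** — driver-mutation count on a TP53/NOTCH1 panel
  ($0/1/\ge2$) and PD-L1 RNA fold-change versus normal mucosa
  ($<1$, $[1,2]$, $>2$).
* **Immune contexture** — CD8$^+$/FoxP3$^+$ ratio ($\ge 2$, $[1,2)$, $<1$)
  and Granzyme B$^+$ density ($>200$, $[50,200]$, $<50$ cells/mm$^2$).

The composite is

$$\mathrm{MRIx} = 0.30\,H + 0.25\,T + 0.25\,M + 0.20\,I \in [0, 2],$$

categorized as low (0–0.8), intermediate (0.9–1.4) or high (1.5–2.0) risk,
with a resection margin $\le 2$ mm forcing the high-risk category regardless
of the numeric score. The weights are treated as fixed constants of the
index; re-deriving them from data is out of scope.

## Scoring design choices

Several aspects of the rubric are under-determined by its prose definition;
the package resolves them once, as follows.

* **Category gaps.** The printed cut points omit the achievable composites
  0.85 and 1.45. The composite is therefore rounded half-up to one decimal
  before the category lookup (0.85 → 0.9, intermediate; 1.45 → 1.5, high),
  which matches the one-decimal bin labels and preserves monotonicity. The
  raw score is kept unrounded (`mrix_score`), and is always an exact
  multiple of 0.05 because the weighted sum is evaluated in integer
  hundredths.
* **Discordant sub-criteria.** Domains with two markers (tumor burden,
  molecular, immune) take the *maximum* (worse) sub-criterion level — a
  risk-conservative rule, since only concordant archetypes are defined.
* **Band gaps.** Wording gaps are closed half-open and risk-conservatively:
  Pan-CK $(0,5)$ intermediate, Ki-67 exactly 20 intermediate, PD-L1 exactly
  1- or 2-fold intermediate, Granzyme B exactly 50 or 200 intermediate,
  CD8/FoxP3 $[1,2)$ intermediate (covering the 1.9–2.0 gap), TLS bands
  $[3,\infty)/[1,3)/[0,1)$. The high-risk TLS definition follows the
  frequency table ("$<1$/mm$^2$") rather than the stricter "complete
  absence" phrasing, because the cohort counts attach to the former.
* **Undefined ratios.** A CD8$^+$/FoxP3$^+$ ratio of $\infty$ (regulatory
  cells absent, cytotoxic cells present) maps to level 0; 0/0 (`NaN`, no
  cytotoxic infiltrate at all) maps to level 2.
* **Override vs margin class.** The $\le 2$ mm override is independent of
  the traditional close ($\le 5$ mm) / clear ($>5$ mm) classification; both
  are stored separately and the override never lowers a category.

## The synthetic cohort generator

No patient-level data accompany the index, so the package ships a generator
(`generate_cohort()`) that emulates the *statistical structure* the analysis
assumes. It is study-conditions code, not a tuning knob: its defaults are
fixed at the published marginal frequencies and effect sizes.

* **Biomarker bands** are drawn per marker at the training-cohort
  frequencies (e.g. TLS 51/63/30 out of 144), then a raw value is drawn
  uniformly within the band's interval, so re-scoring recovers the drawn
  band exactly. Unbounded bands use documented finite caps (TLS high
  $[3,10]$, Pan-CK high $[5,15]$, Ki-67 high $(20,60]$, PD-L1 high $(2,8]$,
  ratio low band $[0,1)$, Granzyme B top band $(200,500]$; mutation counts
  2–4 in the $\ge 2$ band). Marginals are carried per marker because the
  frequency table reports marker-level, not domain-level, bands; domain
  scores then follow from the max rule.
* **Clinical covariates** are sampled independently at the baseline-table
  frequencies. Only marginals are reported, so independence across
  covariates and across domains is an explicit modelling assumption — real
  margins surely correlate TLS density with the CD8/FoxP3 ratio, for
  example. Passing tests therefore demonstrate internal consistency of the
  pipeline, not performance on correlated real data.
* **Survival outcomes** follow a proportional-hazards model. The linear
  predictor sums configured log hazard ratios over each patient's
  non-reference levels; the defaults are the logs of the published adjusted
  HRs (training: intermediate/high MRIx 1.89/3.15 for locoregional control
  and 2.18/3.54 for distant-metastasis-free survival, plus the
  differentiation and pathologic-response effects; validation: high-risk
  2.95/3.22). The MRIx category entering the hazard is the *final* category
  including any close-margin override, i.e. exactly the covariate the
  downstream models use. Two values the validation model needs are not
  published and were chosen once: the intermediate-category effects reuse
  the training values, and the close-margin adjustment term uses HR 1.6;
  recovery of the high-risk coefficient is insensitive to both.
* **Baseline hazard.** Event rates, not hazards, are reported (18.1% for
  locoregional recurrence, 21.5% for distant metastasis over follow-up
  24–72 months). The default baseline is exponential with the rate
  calibrated by bisection so the mean closed-form event probability of the
  realized linear predictors under the censoring window equals the target
  rate. A Weibull family is available when a non-constant hazard is wanted.
* **Censoring** is administrative, uniform on [24, 72] months (the stated
  follow-up range), with an optional independent exponential dropout rate
  (0 by default). Endpoint times are drawn independently given the shared
  covariates; their joint dependence is unspecified in the source material.
  Competing risks, informative censoring and covariate-dependent censoring
  are deliberately out of scope.

## Survival kernels

The estimation machinery is implemented in the package (the `survival`
package serves as an independent cross-check in the test suite, not as the
implementation):

* **Kaplan–Meier** product-limit curves with Greenwood variance; with no
  censoring the curve equals the empirical survival function exactly.
* **Log-rank** k-sample statistic with the hypergeometric covariance and a
  pseudo-inverse guard for degenerate designs (identical groups give
  $\chi^2 = 0$, $p = 1$).
* **Cox regression** maximizes the partial likelihood with Efron's tie
  correction (Breslow optional) by Newton–Raphson from $\beta = 0$ with
  step-halving, to a score-norm below $10^{-8}$ or 100 iterations.
  Standard errors come from the inverse observed information. Ties default
  to Efron because follow-up is recorded in months and tied event times are
  common. Confidence intervals are Wald, $\exp(\hat\beta \pm 1.96\,se)$;
  the asymmetric intervals printed alongside the published HRs cannot be
  reproduced from any stated method and are treated as display-only.
  Separation and non-convergence are flagged on the result rather than
  silently accepted.
* **Harrell's C.** An ordered pair is usable when the shorter time is an
  event (or times are tied between an event and a censored subject);
  tied-time event pairs are unusable; risk-score ties count one half.
  Brute-force pair enumeration is used up to $n = 2000$ and an equivalent
  Fenwick-tree $O(n \log n)$ path above; equality of the two paths is
  asserted exhaustively in tests. No analytic CI is attached by default —
  `compare_models(boot_ci = B)` provides a bootstrap percentile interval on
  request, because no interval method is stated for the published
  C-indexes.
* **Model comparison.** The chain Clinical → Clinical + traditional margin
  → Clinical + MRIx is fitted on an identical complete-case row set so AIC
  ($-2\ell + 2k$) and likelihood ratios are comparable. The MRIx model does
  not nest the margin model; their "versus previous" comparison is reported
  as the plain twice-log-likelihood difference, flagged `nested = FALSE`,
  while the two comparisons against the clinical reference are formal LRTs.
* **Calibration** at a fixed horizon (36 months by default, matching the
  3-year outcome assessment) groups patients into deciles of predicted
  event probability; the observed group probability is $1 - \hat S_{KM}$
  at the horizon within the group (robust to censoring), and the
  Hosmer–Lemeshow statistic uses $g - 2$ degrees of freedom. Groups with
  degenerate mean predictions are merged into a neighbor and counted.
* **Multiplicity.** The domain-level log-rank family (4 domains × 2
  endpoints) is adjusted with the Benjamini–Hochberg step-up.

## External validation workflow

`validate_external()` applies a *frozen* scoring configuration — no
re-estimation of thresholds, weights or cuts — to an independent cohort and
reports, per endpoint: three-group Kaplan–Meier stratification with the
log-rank test, the C-index of the continuous score, the adjusted Cox model
(differentiation, pathologic response, traditional margin class, MRIx
category, the stated validation adjustment set) and fixed-horizon
calibration. Predicted probabilities for calibration come from the adjusted
model's own Breslow baseline, $\hat S(t\mid x) = \exp(-\hat H_0(t)e^{x'\hat\beta})$.

## Problem sizes and numerical choices

The test suite runs everything it asserts: oracle comparisons against the
`survival` package on cohorts of 150–400, coefficient-recovery checks at
5,000 per arm, Wald-coverage sweeps of 200 replicates at $n = 1000$,
calibration operating characteristics over 200 replicates of $n = 2000$,
null-uniformity checks over 500 replicates, and full-pipeline recovery of
the published high-risk hazard ratios on cohorts of $n = 20{,}000$ — sizes
chosen so that Monte-Carlo error is small relative to the 10% recovery
tolerance while a desktop run stays in minutes. `scripts/acceptance.R`
re-runs the $n = 20{,}000$ recoveries from scratch at a user-supplied seed.

Numerical conventions worth knowing: half-up rounding is implemented as
$\lfloor 10x + 0.5 + 10^{-9}\rfloor/10$ (the nudge protects binary halves);
probability triples must sum to 1 within $10^{-9}$; weights within
$10^{-12}$; the bisection calibrator runs 80 halvings from a bracketed
rate, making cohort generation fully deterministic given the seed.

## Known limitations

* Independence of domains, markers and clinical covariates is assumed; an
  optional correlation structure is a natural extension point.
* The published real-data discrimination (C-index 0.72/0.75 training,
  0.67/0.70 validation) and AIC values depend on the unavailable patient
  data and are not reproduced; the package validates the estimators by
  construction-based simulation instead.
* Only right censoring is modelled; no competing risks, time-varying
  covariates, frailty or stratified baselines.
* The rubric applies to HPV-negative disease treated with NICT; nothing in
  the package addresses HPV-driven tumors.
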