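---
title: "Adiposity indexes as diagnostic markers for metabolic syndrome: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adiposity indexes as diagnostic markers for metabolic syndrome: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metsdx)
```

# The problem

Metabolic syndrome (MetS) is a cluster of cardiometabolic risk factors
— central obesity, hyperglycemia, hypertension and atherogenic
dyslipidemia — that multiplies the risk of type 2 diabetes and
cardiovascular disease. In women with severe obesity, clinicians want a
cheap bedside screen: a single anthropometric or lipid-based index whose
value flags probable MetS before full biochemistry and blood-pressure
work-up. `metsdx` implements the complete evaluation pipeline for five
candidate indexes and the diagnostic-accuracy machinery to rank them.

# The indexes

For a subject with waist circumference WC (cm), hip circumference HC
(cm), stature H, body mass, fat-mass fraction FM, triglycerides TG and
HDL cholesterol (both converted internally to mmol/L):

* **WHR** = WC / HC and **WtHR** = WC / H(cm): purely anthropometric
  central-adiposity ratios.
* **BMFI** = BMI (kg/m²) × FM × WC (m), units kg/m. The fat-mass term
  is a *fraction* in [0, 1], not a percentage: with typical cohort
  means (BMI ≈ 43.6, FM ≈ 0.509, WC ≈ 1.21 m) the fraction convention
  gives ≈ 26.9 kg/m, the same order as reported BMFI distributions
  (≈ 27.6), while a percent convention would inflate the index a
  hundred-fold. `bmfi()` therefore rejects values above 1.
* **VAI** (women) = [WC / (36.58 + 1.89 BMI)] × (TG / 0.81) ×
  (1.52 / HDL). Index formula lines are often typeset ambiguously;
  we use the female-specific parenthesisation of the index's original
  definition, in which WC is divided by the whole linear BMI term —
  the only reading that produces scores on the scale of published VAI
  distributions (unit score at WC = 36.58 + 1.89·BMI, TG = 0.81,
  HDL = 1.52). Only the female branch is implemented; the `sex`
  argument is reserved.
* **CMI** = WtHR × TG / HDL.

Unit conversions use fixed factors (mg/dL per mmol/L): glucose 18.016,
triglycerides 88.57, cholesterol 38.67. These reproduce the familiar
dual-unit criterion thresholds exactly after rounding (100 mg/dL =
5.55 mmol/L glucose; 150 mg/dL = 1.7 mmol/L TG; 50 mg/dL =
1.3 mmol/L HDL) and round-trip to better than 1e-9 relative error.

# The reference standard

`classify_mets()` applies the International Diabetes Federation
risk-factor thresholds for women: WC ≥ 80 cm, fasting glucose
≥ 100 mg/dL, SBP ≥ 130 or DBP ≥ 85 mmHg, TG ≥ 150 mg/dL, HDL-C
< 50 mg/dL, each alternatively satisfiable by the corresponding
drug-treatment flag. Boundary semantics are taken literally: inclusive
`>=` everywhere except the strict `<` for HDL. Glucose is compared in
mg/dL, its source unit, so conversion rounding can never move a subject
across the boundary.

Two operationalisations are provided. The default (`variant =
"any3"`) labels MetS when **any three or more** of the five criteria
hold, with central obesity counted as an ordinary criterion — the rule
as studies in this literature commonly operationalise it. The textbook
IDF rule (`variant = "canonical"`) instead makes central obesity
mandatory plus at least two of the remaining four. In a cohort of women
with severe obesity the two coincide almost everywhere, because the WC
criterion is met universally; the switch matters for reuse in leaner
populations.

# Diagnostic accuracy engine

All accuracy machinery is implemented in the package (pROC serves only
as an independent cross-check in the test suite):

* **ROC / AUC.** `roc_curve()` traces the empirical curve over every
  distinct score value plus an infinite sentinel, and integrates by the
  trapezoid rule. On the empirical curve this equals the Mann–Whitney
  probability that a random positive outscores a random negative with
  ties at half credit; `auc_mann_whitney()` computes that probability
  by brute-force pair enumeration and the equality is asserted to
  1e-12 in the tests.
* **DeLong inference.** Variances and covariances of the empirical
  AUCs use the structural-components estimator, computed with the
  midrank formulation (O(n log n)), so confidence intervals at
  n = 10,000 per class take milliseconds. `compare_auc_delong()` gives
  the paired two-sided test for two markers on the same subjects.
  Pairwise p-values in the evaluation report are deliberately
  unadjusted for multiplicity, and the report says so.
* **Cutoffs.** Positivity is *strictly greater than* the cutoff,
  matching the "> cutoff" convention of published optimal cutpoints.
  `youden_optimal_cutoff()` maximises J = Se + Sp − 1 over all
  distinct score values plus −Inf (so J ≥ 0 always); ties are broken
  toward the smallest maximising cutoff, and a float-noise tolerance
  of 1e-12 keeps that tie-break deterministic when two cutoffs are
  mathematically tied.
* **Summary measures.** `diagnostic_summary()` derives Se, Sp, PPV,
  NPV, PLR, NLR and Youden's J either from a confusion matrix or from
  stated Se/Sp plus a prevalence. PPV/NPV follow Bayes' rule; at the
  empirical prevalence the Bayes form coincides with the count ratios
  TP/(TP+FP) and TN/(TN+FN) to machine precision. Ratios with zero
  denominator are reported as `Inf` (or `NaN` for 0/0), never as a
  silently clipped number. Se/Sp carry exact Clopper–Pearson intervals
  (reported, not part of any headline claim).
* **Descriptive statistics.** Group comparisons use Welch's
  unequal-variance t-test by default — the two MetS groups differ in
  both size and spread, and nothing in the analysis requires the
  pooled assumption — with a `pooled` option. Pearson correlations
  report r and R² with the t-transform p-value. The outlier screen
  flags values more than 4.5 sample SDs from the sample mean (moments
  over the full sample, flagged point included).

# The synthetic cohort generator

Raw subject-level data for cohorts like this are not publicly
deposited, so `simulate_cohort()` generates cohorts with the same
two-group statistical structure, and every pipeline stage is exercised
against them.

The default spec (`default_cohort_spec()`) encodes n = 876 women,
MetS prevalence target 0.62, and per-group means/SDs of age, stature,
body mass, waist and hip circumference, fat-mass fraction, blood
pressures, fasting glucose, triglycerides and HDL-C transcribed from
the descriptive statistics of a severe-obesity cohort of that size
(e.g. MetS+ TG 153.3 ± 68.4 mg/dL, MetS− HDL-C 56.7 ± 12.0 mg/dL).
Design choices:

* **Gaussian copula with mixed marginals.** Published tables give only
  means and SDs. Triglycerides and glucose are drawn log-normally —
  lipid and glycemic panels are right-skewed and strictly positive —
  with parameters moment-matched analytically so the natural-scale
  mean and SD equal the printed values to 1e-9
  (`lognormal_params()`). All other variables are normal.
* **Correlation structure.** One within-group correlation matrix
  couples the eleven continuous variables: waist–body-mass 0.8,
  waist–hip 0.7, mild positive correlations (0.1–0.4) among the other
  anthropometric/pressure pairs, TG–HDL −0.3. Published tables do not
  report within-group correlations, so this matrix is an assumption,
  versioned in the spec object and checked positive semi-definite at
  validation.
* **Truncation by resampling.** Physiologic bounds (stature
  1.30–2.00 m, age 18–83 y, HDL ≥ 5 mg/dL, …) are enforced by
  redrawing out-of-bounds subjects whole rather than clipping, which
  would distort the marginal shape; redrawing is capped at 1,000
  rounds before an explicit error.
* **Drug-treatment flags.** Per-group Bernoulli probabilities were
  calibrated once, analytically (closed-form tail probabilities of the
  marginals), so the generated per-criterion prevalences match the
  reported cohort-level figures — elevated BP ≈ 73%, elevated TG
  ≈ 35%, hyperglycemia ≈ 33% — giving MetS+ (glucose 0.05, BP 0.65,
  TG 0.12, HDL 0.02) and MetS− (0.01, 0.20, 0.01, 0.01). The BP
  figure is plausible clinically: the criterion itself counts treated
  hypertension.
* **Labels.** Downstream evaluation labels come from applying
  `classify_mets()` to the *generated measurements*, never from the
  latent group, so labels and features are always consistent. On the
  default spec the latent group and the classifier agree for ≈ 83% of
  subjects and classified prevalence lands near 61%.

What the generator does **not** emulate — and hence what passing tests
cannot show about real data: the reduced-HDL criterion prevalence
comes out near 50% rather than the reported 57%, because in real data
the group boundary is partly *defined* by the HDL criterion, a
dependence a two-group copula with normal HDL marginals cannot fully
reproduce (and HDL-raising drug treatment is too rare to bridge the
gap honestly); fat mass in kg is derived as fraction × body mass, so
printed kg SDs are not independently matched; measurement error,
digit-preference heaping, intra-subject BP averaging and longitudinal
change are absent. Accordingly the synthetic end-to-end checks assert
the *qualitative* structure — VAI and CMI dominate the purely
anthropometric indexes by AUC, prevalence near 62% — not the published
AUC decimals, which belong to the unavailable raw cohort.

# Numerical and reporting conventions

Determinism: every source of randomness flows from the single seed
passed to `simulate_cohort()` (Mersenne-Twister, inversion normals);
the same seed yields byte-identical cohort CSVs. Reports render at the
conventional table precisions (AUC 2 d.p., proportions 1 d.p. as
percent, likelihood ratios 2 d.p.) while JSON output keeps full
precision; p-values are kept at machine precision internally.

Problem sizes used in the shipped checks: 500 random tied instances
(n ≤ 50) for the AUC-equivalence and Youden-oracle properties; a
10,000 + 10,000 binormal sample with mean shift 1.19 for the DeLong
closed-form check (true AUC Φ(1.19/√2) ≈ 0.8); n = 876 synthetic
cohorts for end-to-end evaluation and parameter recovery (CLT bound,
|z| ≤ 4); 2,000 null replicates at n = 30 per group for t-test
type-I calibration.

# Known limitations

* Published accuracy tables for cohorts of this kind occasionally
  contain internally inconsistent entries (a Youden index or NLR that
  does not match the printed Se/Sp under J = Se + Sp − 1 and
  NLR = (1 − Se)/Sp). The package reproduces the identity-consistent
  values and does not replicate transcription artefacts.
* Reported MetS+ counts can differ between a paper's text and its
  tables (544 vs 542 of 876 in the motivating cohort); prevalence here
  is always data-driven, and the accuracy-table identity checks use
  542/876 where a fixed prevalence is needed.
* The male VAI branch, alternative MetS definitions beyond the
  canonical-IDF switch, BMI-class stratification and smoothed/binormal
  ROC fitting are out of scope.
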