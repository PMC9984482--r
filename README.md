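# ppvstroke

Pulse-pressure variability (PPV) and functional outcome after acute
ischemic stroke: index computation, outcome labelling, and the full
inference battery, as a tested, reusable R pipeline.

Blood pressure is monitored every 4 h for 72 h after stroke admission.
Pulse pressure, PP = SBP − DBP (mmHg), is the pulsatile component of
blood pressure; its within-patient variability is a candidate predictor
of 30- and 90-day functional outcome measured on the modified Rankin
Scale (mRS, 0–6; mRS ≥ 3 = dependence or death). The package is aimed at
stroke and hypertension researchers who want these analyses to be
reproducible and testable rather than locked in a point-and-click
statistics suite.

## What it computes

Seven per-patient summaries of the PP series x₁,…,xₙ:

- mean PP, and SD = √( Σ(xᵢ − x̄)² / (n−1) )
- CV = 100·SD/x̄ (%)
- SV = √( Σ(xᵢ₊₁ − xᵢ)² / (n−1) ) (successive variation)
- ARV = Σ|xᵢ₊₁ − xᵢ| / (n−1) (average real variability)
- DMM = max x − min x
- MSC = maxᵢ |xᵢ₊₁ − xᵢ| (maximal successive change)

and the inference suite relating them to outcome:

- Spearman rank correlation (midranks, t-approximation p-values);
- Mann–Whitney U (exact enumeration for small groups, tie- and
  continuity-corrected normal approximation otherwise);
- logistic models M1–M4 reporting odds ratios per 10 mmHg with Wald 95%
  CIs (M1 unadjusted; M2 + thrombolysis + mean PP; M3 as M2 with the
  severity-adjusted outcome, which grades mRS against admission NIHSS;
  M4 = M2 + age + sex + prior myocardial infarction);
- ROC analysis: empirical AUC, DeLong 95% CI and test of AUC = 0.5,
  Youden's index, and a cut-off that is always an observed value.

A synthetic cohort generator (`generate_cohort()`) emulates the cohort
structure — serial PP readings with controllable within-patient
fluctuation, dropout, baseline covariates, and outcomes drawn from a
logistic link to a chosen PPV index — so the whole chain is testable
without patient-level data. `run_ppv_pipeline()` orchestrates
ingest → sampling validation → indices → outcome labelling → the four
result tables, deterministically. A thin CLI lives at
`inst/cli/ppvstroke.R` (`simulate` / `indices` / `analyze`).

## Worked example

```r
library(ppvstroke)

summarize_ppv(c(60, 70, 50, 60))
#> # A tibble: 1 × 8
#>   mean_pp    sd    cv    sv   arv   dmm   msc n_readings
#>     <dbl> <dbl> <dbl> <dbl> <dbl> <dbl> <dbl>      <int>
#> 1      60  8.16  13.6  14.1  13.3    20    20          4
```

A 60/70/50/60 mmHg series has mean PP 60 mmHg, SD 8.16 mmHg, CV 13.6%,
SV 14.1 mmHg, ARV 13.3 mmHg, and a 20 mmHg range that is entirely
attained in one successive swing (DMM = MSC = 20).

```r
sim <- generate_cohort(cohort_spec(seed = 1))     # 203 patients, 72 h
idx <- ppv_indices(sim$readings)                  # validate + summarise
cohort <- dplyr::left_join(sim$cohort, idx, by = "patient_id") |>
  dplyr::filter(accepted)                         # 201 of 203 accepted

run_model_suite(cohort, "sd", "30d")
#>   model    or ci_low ci_high  p_value converged
#>   M1     5.78   3.29   10.2  1.10e-09 TRUE
#>   M2     5.42   3.07    9.57 5.90e-09 TRUE
#>   M3     5.07   2.89    8.91 1.64e-08 TRUE
#>   M4     5.41   3.06    9.55 5.93e-09 TRUE
```

Each row is the odds ratio for unfavorable outcome per 10 mmHg increase
in PP SD under one adjustment set; this cohort was generated with a true
OR of 4.8, and all four intervals cover values near it.

```r
roc_analysis(cohort$sd, dichotomize_mrs(cohort$mrs_30d))
#> ROC: AUC 0.773 (95% CI 0.708-0.838), p = 2.087e-16
#>   Youden 0.44 at cut-off 14.9 (sens 0.69, spec 0.75); 87 pos / 114 neg
```

PP SD discriminates unfavorable outcome with AUC 0.77; predicting
"unfavorable" when SD ≥ 14.9 mmHg maximizes sensitivity + specificity.

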