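---
title: "Pulse-pressure variability and stroke outcome: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pulse-pressure variability and stroke outcome: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ppvstroke)
```

## The scientific problem

Blood pressure fluctuates substantially in the first days after an acute
ischemic stroke, and excessive fluctuation is suspected to harm the
ischemic penumbra through alternating hypo- and hyperperfusion. Pulse
pressure (PP = SBP − DBP, mmHg) is the pulsatile component of blood
pressure and a marker of arterial stiffness; its variability (PPV) over a
monitoring window is a candidate predictor of functional outcome.
`ppvstroke` implements the full analysis chain for this question:
variability indices computed from serial PP readings, functional-outcome
labelling from the modified Rankin Scale (mRS), and the inference battery
that relates the two — rank correlation, group comparison, logistic
regression with odds ratios per 10 mmHg, and ROC analysis.

Because per-patient clinical data of this kind are typically not publicly
deposited, the package also ships a synthetic-cohort generator that
reproduces the statistical structure the analysis assumes, so every stage
is testable end to end.

## The PPV indices

For a PP series $x_1,\dots,x_n$ read in temporal order:

* mean: $\bar x = \frac1n \sum x_i$
* standard deviation: $SD = \sqrt{\frac{1}{n-1}\sum_{i=1}^n (x_i-\bar x)^2}$
* coefficient of variation: $CV = 100\,SD/\bar x$ (percent)
* successive variation: $SV = \sqrt{\frac{1}{n-1}\sum_{i=1}^{n-1}(x_{i+1}-x_i)^2}$
* average real variability: $ARV = \frac{1}{n-1}\sum_{i=1}^{n-1}|x_{i+1}-x_i|$
* max–min difference: $DMM = \max_i x_i - \min_i x_i$
* maximal successive change: $MSC = \max_i |x_{i+1}-x_i|$

SD uses the $n-1$ denominator; SV and ARV divide the $n-1$ successive
differences by $n-1$, so ARV is the plain mean absolute successive
difference. These conventions imply the order relations
$ARV \le SV$, $ARV \le MSC \le DMM$ and $SD \le DMM$ (power-mean and
range inequalities), which the test suite checks on randomized series
against an independent loop-oracle. All dispersion indices are invariant
to adding a constant and scale linearly under positive scaling (CV is
scale-invariant); all seven are invariant to reversing the series.

Readings are used exactly as recorded: no interpolation, no resampling
onto the nominal grid, and PP values are kept as reals until display
rounding. A series needs at least two readings; `cv` is `NaN` when the
mean is zero (impossible for valid readings, which require SBP > DBP).

## Sampling validity

The nominal schedule is one reading every 4 h from hour 0 through hour
72 — 19 slots, endpoints inclusive. Clinical series have interruptions,
and series with inadequate sampling should not contribute variability
estimates. How much is "adequate" is a genuinely open design point; the
package makes it an explicit, configurable `sampling_policy()`:

* `min_fraction = 0.8`: at least 80% of the expected slot count
  (i.e. ≥ 15.2, so 16 of 19 readings);
* `max_gap_hours = 8`: no interruption longer than twice the nominal
  interval.

Count is checked before gaps, so a sparse *and* gappy series reports
`too_few_readings`. The alternative slot count of 18 (excluding one
endpoint) can be obtained by setting `window_hours = 68` or adjusting
`min_fraction`; none of the index formulas depend on the choice.

## Outcome rules

Two labelling rules are implemented, both emitting 1 = unfavorable:

* **Dichotomized mRS**: unfavorable iff mRS ≥ 3 (dependence or death).
* **Severity-adjusted**: the residual disability is graded against
  admission stroke severity (NIHSS): unfavorable when mRS 2–6 with
  NIHSS ≤ 7, mRS 3–6 with NIHSS 8–14, or mRS 4–6 with NIHSS > 14.
  The integer bands are read inclusively (`> 14` as ≥ 15), which tiles
  the 0–42 NIHSS range without gap or overlap.

The severity-adjusted rule is deliberately literal: mRS 3 after a severe
stroke (NIHSS > 14) matches no branch and is favorable. The exhaustive
7 × 43 truth table and monotonicity in mRS are pinned by tests. The rule
is used for logistic Model 3 at both horizons (30 and 90 days); the
dichotomized rule everywhere else.

## The inference battery

**Spearman correlation** is the Pearson correlation of midrank-transformed
vectors, with a two-sided p-value from the $t$ approximation on $n-2$
degrees of freedom. It is the first-pass association measure between each
index and the raw 0–6 mRS score.

**Mann–Whitney U** is computed from midrank sums and reported as
$U = \min(U_a, U_b)$. The two-sided p-value uses exact enumeration of
group assignments when both groups have ≤ 8 observations (valid under
ties, since the enumeration permutes the observed midranks) and otherwise
the normal approximation with tie correction and a 0.5 continuity
correction.

**Logistic regression** is a binomial GLM fitted by IRLS (coefficient
tolerance 1e-8, 100 iterations). The index of interest is divided by 10
before fitting, so its exponentiated coefficient is directly the odds
ratio per 10 mmHg (per 10 percentage points for CV). Confidence
intervals and p-values are Wald with $z = 1.96$ — the conventional
reporting style for this literature; profile-likelihood intervals would
differ slightly in small samples. Singular designs (constant or
collinear columns) error; quasi-separation is flagged as
`converged = FALSE` rather than silently reported. Missing data are
handled complete-case per model. The model suite is:

| Model | Outcome | Covariates besides the index |
|-------|---------------------|------------------------------|
| M1 | dichotomized mRS | — |
| M2 | dichotomized mRS | thrombolysis, mean PP |
| M3 | severity-adjusted | thrombolysis, mean PP |
| M4 | dichotomized mRS | thrombolysis, mean PP, age, sex, prior myocardial infarction |

**ROC analysis** builds the empirical ROC over observed score values
(higher score predicts unfavorable). The AUC is the Mann–Whitney
concordance probability with ties counted ½, identical to the trapezoid
area; its variance, 95% CI and the test of AUC = 0.5 use DeLong
placement values. Youden's index maximizes sensitivity + specificity − 1
over thresholds of the form "positive if score ≥ t"; when several
thresholds attain the maximum the smallest observed score is reported,
so the cut-off is always a value actually seen in the data (interval
midpoints, as some ROC software reports, are not observed values and
round ambiguously).

## The synthetic cohort generator

`generate_cohort()` emulates a single-center cohort of 203 acute
ischemic stroke patients monitored 4-hourly for 72 h:

* Per-patient mean PP ~ Normal(57, 14²) mmHg (truncated below at
  25 mmHg), bracketing the 54.5 ± 15.5 / 57.9 ± 13.7 mmHg subgroup
  means a cohort of this kind exhibits; within-patient fluctuation SD
  drawn uniformly from 5–25 mmHg, bracketing reported PP-SD levels of
  roughly 11–14 mmHg.
* Readings are mean + noise per nominal slot — independent Gaussian by
  default, optionally stationary AR(1) with configurable lag-1
  correlation for sensitivity analyses — plus an optional linear drift,
  floored at 5 mmHg, with per-slot dropout (default 5%, a guess: real
  reading-count distributions are rarely reported).
* SBP/DBP are reconstructed around a drawn mean arterial pressure as
  $SBP = MAP + \tfrac23 PP$, $DBP = MAP - \tfrac13 PP$, so the standard
  clinical identity holds and SBP − DBP reproduces the simulated PP
  exactly (values are kept real-valued rather than rounded to integer
  mmHg, so the identity is exact).
* The unfavorable outcome is Bernoulli with logit
  $\alpha + \beta\,\mathrm{index}_i + \dots$, evaluated at the
  **realized** index of the simulated (post-dropout) series — so a
  logistic fit of outcome on the computed index is correctly specified,
  which is what makes coverage testable. Defaults: $\beta$ on PP SD of
  $\log(4.8)/10$ per mmHg, all confounder coefficients zero, intercept
  solved so the expected prevalence is 0.40 (≈ 82/203) at the midpoint
  fluctuation scale. A shared logistic latent links the 30- and 90-day
  outcomes (the 90-day linear predictor is shifted by −0.1, slightly
  fewer late unfavorable outcomes), and mRS 0–6 and admission NIHSS are
  deterministic-plus-noise maps of the same latent, so the
  severity-adjusted rule is exercised across all three NIHSS bands.
* Covariate marginals (age 68 ± 13, 47% female, comorbidity rates
  0.09–0.66, 20% thrombolysed) follow typical baseline tables for such
  cohorts.

What the generator does **not** emulate: circadian BP rhythm, treatment
effects on BP, correlation between comorbidities and outcome (unless
requested via the outcome-model betas), informative dropout, and
integer-quantized monitor output. Passing tests therefore demonstrate
the correctness of the computational chain and its statistical
calibration under the assumed model — not clinical validity on real
monitoring data.

Cohorts are pure functions of the spec (seed mandatory): identical specs
are bit-identical, and generation restores the caller's RNG state.

## Numerical and design choices

* Ranks use midranks throughout (ties in Spearman, U, AUC).
* The Youden tie-break is toward the lower score, making cut-offs
  deterministic.
* DeLong variance uses sample variances of placement values; a
  degenerate variance (perfect separation) reports p = 0 (or 1 when
  AUC = 0.5 exactly).
* The pipeline's analysis path consumes no randomness; identical config
  and data give byte-identical result tables. Tables are written both at
  machine precision and at display precision (1 decimal for means,
  3 for ORs/AUCs/p-values, integer cut-offs).
* Exclusion accounting is conservative: every cohort patient lands in
  exactly one of {analyzed, too_few_readings, gap_too_large,
  missing_followup}.

## Simulation sizes used in validation

The packaged checks use 1,000 random series for the index oracle and
inequality properties, 500 tie-free instances for the AUC–U identity,
200 cohorts of 203 patients for parameter recovery (mean OR per
10 mmHg within 15% of the true 4.8; 95% Wald coverage expected in
0.93–0.97), and 500 null cohorts for p-value uniformity
(Kolmogorov–Smirnov). These sizes give Monte-Carlo error comfortably
below the tested tolerances while keeping a full validation run in
minutes on one core.

## Worked example

```{r}
pp <- derive_pulse_pressure(make_fixture("worked_series"))$pp
pp
summarize_ppv(pp)
```

```{r}
sim <- generate_cohort(cohort_spec(seed = 1))
idx <- ppv_indices(sim$readings)
cohort <- dplyr::left_join(sim$cohort, idx, by = "patient_id") |>
  dplyr::filter(accepted)
run_model_suite(cohort, "sd", "30d")
roc_analysis(cohort$sd, dichotomize_mrs(cohort$mrs_30d))
```

## Known limitations

* Wald inference only; no profile-likelihood or Firth correction for
  small or separated samples (separation is flagged, not repaired).
* The severity-adjusted rule is applied with admission NIHSS at both
  horizons; no re-assessment of severity at follow-up is modelled.
* No multiplicity correction across the six indices and two horizons,
  matching the single-study reporting convention the package mirrors.
* PP-only variability: SBP/DBP/MAP variability indices and
  beat-to-beat/ABPM weighting schemes are out of scope.
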