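---
title: "Sex-specific recalibration of the MECKI score: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sex-specific recalibration of the MECKI score: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smecki)
```

## The model

The MECKI score is a logistic prognostic model for patients with heart
failure and reduced ejection fraction (HFrEF). Six routinely collected
covariates enter a linear predictor (the *esp*, on the log-odds scale):

$$
\mathrm{esp} = \beta_0
 + \beta_1\,\mathrm{peakVO_2\,(\%pred)}
 + \beta_2\,\mathrm{VE/VCO_2\ slope}
 + \beta_3\,\mathrm{Hb}
 + \beta_4\,\mathrm{Na^+}
 + \beta_5\,\mathrm{LVEF}
 + \beta_6\,\mathrm{MDRD}
$$

and the 2-year probability of the composite endpoint (cardiovascular death,
urgent transplant, or LVAD implant) is the logistic transform
$p = e^{\mathrm{esp}}/(1+e^{\mathrm{esp}})$.

The sex-recalibrated score (S-MECKI) replaces the single pooled coefficient
vector with two sex-specific vectors. The package ships both published sets
at full printed precision (`smecki_coefficients("F")`,
`smecki_coefficients("M")`); `s_mecki_score()` dispatches on the patient's
sex. Covariates are used raw, in their clinical units (percent, g/dl,
mmol/L, ml/min/1.73m²); out-of-range values trigger plausibility *warnings*
only, since the score itself applies no exclusions.

All probabilities go through `stats::plogis()`, which is accurate across the
whole double range: the deep tail (e.g. esp = −50) stays strictly positive
instead of underflowing.

## Weight estimation by repeated half-splits

`cv_recalibrate()` implements the estimation procedure: the single-sex
cohort is randomly divided in half 200 times (training half
$\lceil n/2\rceil$, testing half $\lfloor n/2\rfloor$; splits are *not*
stratified by outcome, though an option exists). In each repetition a
six-covariate logistic model is fitted on the training half by iteratively
reweighted least squares (`stats::glm.fit`, convergence tolerance 1e-10,
up to 100 iterations) and the fitted linear predictor is scored on the
testing half by AUC. The arithmetic mean of the repetition coefficients is
the recalibrated weight.

Two practical choices deserve comment:

* **Separation.** A female training half contains on the order of 30 events
  for 7 parameters, so occasional quasi-complete separation is expected.
  Dropping those repetitions would bias the mean, so the affected fit is
  redone with a small ridge penalty (λ = 1e-4 on non-intercept terms, via a
  dedicated Newton solver) and counted in `n_flagged`. Only repetitions that
  cannot be fitted at all (e.g. an event-free training half) are dropped,
  and more than 25% of those aborts the procedure.
* **Reproducibility.** Repetition *i* draws its split from an independent
  stream seeded deterministically from `(master_seed, i)`, so results are
  independent of repetition order and each repetition can be reproduced in
  isolation.

### Confidence intervals for the weights

The published between-sex comparison classifies each weight as `<`, `=` or
`>` by checking whether the two 95% intervals overlap (touching endpoints
count as overlap) and, if not, which mean is larger in absolute value
(`compare_weights()`). What interval to attach to a mean of 200 repetition
betas is genuinely open: the repetition distribution's empirical
2.5th/97.5th percentiles are assumption-free, but they describe the spread
of *single half-sample fits*, which is far wider than the uncertainty of
their *mean*. The published interval widths are much closer to the latter.
`cv_recalibrate()` therefore computes both (`ci_percentile`, `ci_mean`) and
exposes the percentile interval by default, with `interval = "mean"` as a
switch. On synthetic cohorts the percentile intervals are wide enough that
most weights classify as `=`; the published means and intervals themselves
reproduce the printed symbol column exactly, which is what the package's
tests assert.

### Standardized weights

The published table of standardized coefficients does not state its
definition. The package adopts the usual convention
$\beta^{std} = \beta \times \mathrm{SD}(x)$ (`standardized_beta()`), which
reproduces the published male sodium and MDRD values to about 2% but
deviates by 20–30% for some female rows (e.g. Hb, LVEF); the published
female SDs cannot simultaneously satisfy β×SD for all rows, so those values
are documented as approximate under this convention and are not used as
test anchors.

## The synthetic cohort generator

`generate_cohort()` emulates the registry population: 1,444 women and 6,456
men by default, each covariate drawn from a truncated normal with the
published per-sex mean and SD (e.g. female peak VO₂ 63.2 ± 18.3 %pred, male
54.6 ± 17.0; female Hb 12.7 ± 1.4 g/dl, male 13.7 ± 1.7). Truncation is at
mean ± 4 SD intersected with physiologic bounds (all covariates positive,
Na in [110, 160] mmol/L, LVEF in (0, 100]%), implemented by rejection
sampling — acceptance is essentially 1 at ±4 SD, and the moment distortion
is far below one standard error at any tested size. Events are Bernoulli
draws from the logistic probability of the built-in sex-specific
coefficient sets, so the generator's own truth is available for parameter
recovery checks. Under these defaults the female event rate (≈ 3.9%) is
materially below the male rate (≈ 5.6%), matching the direction of the
published sex contrast.

The default correlation matrix is the identity: the source tables report
no covariance structure. Real HF covariates do correlate (anaemia with
renal function, peak VO₂ with VE/VCO₂ slope), so a per-sex correlation
matrix can be supplied; it is validated for symmetry and positive
semi-definiteness and sampled through a Cholesky factor. All shipped
analyses and tests use the identity, so passing tests demonstrate correct
behaviour under independent covariates, not under realistic collinearity —
a caveat that matters mainly for the interpretation of per-covariate
recovery noise. No censoring, missingness, or treatment process is
simulated: the endpoint is a plain 2-year binary.

## What the study-scale noise does and does not allow

A single female cohort of 1,444 patients carries only ≈ 55–70 events. The
sampling standard deviation of a seven-parameter logistic fit at that event
count is large: ≈ 0.11 for the Hb coefficient, ≈ 0.05 for Na, and several
units for the intercept (which rides on Na through its mean of ≈ 140).
Averaging 200 half-split fits of the *same* cohort does not reduce this —
the mean tracks the full-cohort MLE plus a small finite-sample inflation
from the halved event counts. Consequently:

* Parameter recovery at the study's own sizes is reliable for the
  strongly-identified coefficients (peak VO₂ in both sexes, male LVEF,
  male VE/VCO₂) but inherently noisy for the female Hb/Na/intercept; the
  package's acceptance-style recovery test asserts the tight band for every
  coefficient and is expected to flag those rows for many seeds. This is a
  property of the design (one cohort realisation), not of the estimator.
* The discrimination advantage of sex-specific over pooled fitting is real
  but asymptotic. The sex-specific generating model is the Bayes-optimal
  score, yet its oracle AUC advantage over a well-fitted pooled model is
  only ≈ 0.002–0.007 here; at registry-scale female event counts the
  estimation noise swamps it, and a pooled fit can win held-out AUC. The
  test suite therefore checks the property at 10,000 patients per sex ×
  20 replicates, where the construction argument actually bites, and it is
  documented here that the small-sample regime can reverse the ranking.

## Discrimination and calibration

* `auc()` is the Mann–Whitney concordance computed by the rank-sum
  identity; it equals brute-force pair counting bit-for-bit (the test suite
  asserts exact equality against an all-pairs oracle, ties included).
* `delong_compare()` implements the placement-value (structural components)
  formulation for two correlated ROC curves: the covariance matrix of the
  paired AUCs is assembled from the empirical covariances of the per-case
  placement values, and the AUC difference is referred to a standard
  normal (two-sided). Degenerate inputs are handled by convention:
  identical scores give z = 0, p = 1; a zero variance with unequal AUCs is
  an error rather than a silent infinity. The implementation is
  cross-checked in tests against `pROC::roc.test` and against a
  20,000-resample paired bootstrap.
* `hosmer_lemeshow()` divides the sample into risk deciles and computes
  $\sum_g (O_g-E_g)^2 / (E_g(1-\bar p_g))$. Deciles are contiguous chunks
  of the stable sort on (predicted, index) — sizes differ by at most one,
  ties and order are deterministic. Groups with expected counts within 0.5
  of either boundary use a continuity floor of 0.5 (with a warning) so
  that small cohorts degrade gracefully. Constant predictions are rejected
  with a hint to reduce `n_groups`.

**Degrees of freedom.** The classical reference distribution with g groups
is χ²(g−2) *when the model was fitted to the same data*; that is the
default. When a fixed, externally given score is evaluated — including the
package's own null experiment in which outcomes are drawn from the
predicted probabilities themselves — no parameters are estimated, each
group contributes a full standardized square, and the statistic's
expectation sits near g (the within-group heterogeneity correction brings
the theoretical value to ≈ 9.96 for the shipped null design). The
`df_variant = "validation"` flag (g−1) is the appropriate reference there
and is what the calibration null test uses.

## The end-to-end pipeline

`run_study()` chains the stages: descriptives with Welch t and chi-square
tests (unadjusted p values, matching the published presentation), per-sex
`cv_recalibrate()`, the symbol table, standardized betas against the
cohort's own per-sex SDs, native-vs-recalibrated DeLong comparisons
(overall and per sex), and Hosmer–Lemeshow tables for both scores. When no
native (pooled) coefficient set is supplied, the comparator is a single
pooled logistic fit on the input cohort, making the pipeline self-contained;
published pooled coefficients can be supplied via JSON/YAML instead. Every
bundle is stamped with the master seed and a config fingerprint, and rerunning
an identical config reproduces every table byte-for-byte. A thin command-line
wrapper (`inst/cli/smecki.R`, subcommands `simulate`, `recalibrate`,
`evaluate`, `run-study`) exposes the same functions for shell use.

## Problem sizes used by the shipped tests

The suite exercises the full study sizes (1,444 / 6,456, 200 repetitions)
for parameter recovery, 100,000 draws for generator moments, 50,000 × 100
seeds for the calibration null, 10,000 per sex × 20 replicates for the
sex-specific-vs-pooled comparison, and small fixed instances (n ≤ 500) for
the exact oracles. These sizes were chosen so each check has the power its
claim needs while the whole suite remains quick to run.

## Known limitations

* The 2-year binary endpoint is taken as given; no censoring-aware (e.g.
  time-dependent ROC) variant is provided, and how the original binary
  endpoint was constructed from longer follow-up is not modelled.
* Identity covariate correlation is the tested default; realistic
  collinearity is supported but not characterised.
* The native MECKI coefficients are not shipped (they are not printed in
  the source tables); the pooled-fit fallback is a stand-in with the same
  functional form.
* Published standardized betas are reproduced only approximately under the
  β×SD convention (see above).
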