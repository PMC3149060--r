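---
title: "Model-based surveillance of drain-related meningitis: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model-based surveillance of drain-related meningitis: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The surveillance problem

Patients with an external ventricular (EVD) or lumbar (ELD)
cerebrospinal-fluid drain are at substantial risk of drain-related
meningitis (DRM). Conventional surveillance — manual chart review
against standardized healthcare-associated-meningitis criteria — is
labor-intensive and subject to inter-rater variation. `drmdetect`
implements the alternative: a logistic prediction model over
episode-level predictors derived automatically from routine data, used
either to triage charts (high-sensitivity probability cut-off) or to
estimate infection rates at the group level directly from summed
predicted probabilities, with no manual confirmation at all.

## Surveillance episodes

An episode runs from the day of first drain placement to
`min(last removal + 7 days, discharge)`. All day values are integer
offsets from admission (day 0) — day granularity matches how such data
are recorded, and offsets avoid carrying calendar dates. A readmission
within 30 days of discharge is folded back into the parent episode
(its events contribute to feature extraction through an additional
surveillance window); later readmissions are excluded. Exclusion
criteria (all evaluated, all triggered reasons logged): death within
one day of placement (`death_day − start_day ≤ 1`), age under 18,
pre-existing CNS infection, more than one simultaneous drain,
placement in another centre, admission shorter than one day,
readmission beyond 30 days, external referring site. Drain intervals
are half-open `[insertion, removal)`: a drain exchanged on the day of
removal is not "simultaneous" — same-day exchange is routine practice.
The pre-existing-infection and other-centre criteria are input flags,
since they are not derivable from the modeled event streams.

## Predictor derivation

For each marker the value *most indicative of infection* during the
episode is taken: maxima for CRP, blood leukocytes, thrombocytes, CSF
leukocytes/erythrocytes/neutrophils and CSF protein; minima for
hemoglobin and CSF glucose. The direction table is fixed in code; it
follows the direction in which each marker separates infected from
uninfected episodes.

Other rules:

* **Culture contamination correction** — a culture growing
  coagulase-negative staphylococci (CoNS, the dominant skin
  contaminant) is reclassified negative unless an antibiotic was
  started between one day before and three days after the culture;
  non-CoNS results are never altered. An episode with no culture at
  all yields `NA` (cultures are only taken on clinical suspicion;
  the missing result is imputed with everything else). A strict mode
  (`no_culture = 0`) treats untaken as negative.
* **Empiric therapy** — vancomycin + ceftazidime both started on
  day ≥ 4, or ceftriaxone + flucloxacillin both started on day ≤ 4,
  with first starts within one day of each other. The one-day
  simultaneity window is our operationalization of "simultaneous";
  prescriptions of a protocol pair are typically written together.
* **Antibiotic count** — distinct systemic agents first started inside
  the episode (a surrogate for concomitant infections). Counting
  distinct agents rather than start events is a deliberate choice;
  restarting the same drug should not raise an episode's apparent
  infectious burden.
* **CRP polynomial** — `crp`, `(crp/10)²`, `(crp/100)³`; the scalings
  keep the three terms on comparable numeric ranges.
* **CSF leukocytes** — natural log of `count + 1` (counts in 100/µL;
  zero counts occur, hence the offset; both base and offset are simple
  conventions and the offset is configurable).
* The screening-only binary CSF leukocyte indicator uses a
  configurable threshold (default 5 × 100/µL ≈ the order of magnitude
  separating the group medians); no canonical definition exists, so it
  never enters the default candidate set.

## Multiple imputation and pooling

Missing predictors are imputed by chained equations with *m* = 10
imputations and 10 sweeps per chain: predictive mean matching (type-1,
posterior-drawn coefficients, 5 donors) for continuous variables —
imputations stay on the support of the observed data — and
posterior-drawn logistic draws for binaries. The outcome is included
as a predictor of missingness, as is standard for imputation feeding a
prognostic model. Deterministic transforms (CRP polynomial terms, log
CSF leukocytes) are recomputed from their imputed parents, never
imputed independently. Per-imputation sub-seeds derive from the master
seed, so the whole set is reproducible. Per-coefficient pooling uses
Rubin's rules: mean estimate, total variance
`W̄ + (1 + 1/m)B`, small-sample degrees of freedom
`(m−1)(1 + W̄/((1+1/m)B))²`. Scoring a *new* patient requires complete
predictors: single-patient imputation is not meaningful, and
`predict_probability()` raises an error instead of guessing.

## Model development

Candidates passing univariate screening (χ² for binaries, *t* for
variables tagged normal, Mann–Whitney otherwise; p < 0.05 in the
cell-wise mean dataset, majority vote for binary cells with ties going
to the positive class) enter backward selection on Rubin-pooled Wald
p-values: the largest p ≥ 0.05 is removed iteratively, *except that the
linear CRP term is never removed while a squared or cubic CRP term
remains* (polynomial hierarchy). Selection operates once on pooled
statistics rather than per-imputation with vote counting — pooling
precedes selection in the procedure this package automates.

Overfitting is corrected by bootstrap calibration-slope shrinkage: 100
resamples per imputation set, model refit in each, and the slope of
the outcome on the bootstrap model's linear predictor over the
original data averaged into a shrinkage factor; coefficients are
multiplied by it and the intercept re-estimated (offset logistic fit)
to restore calibration-in-the-large. Bootstrap refits use plain
maximum likelihood even though the final fit falls back to Firth-type
penalization under separation: a separated resample produces extreme
linear predictors whose near-zero slope is precisely the optimism
signal, and penalizing inside the bootstrap would mute it. The AUC is
reported apparent and optimism-corrected (mean of bootstrap-minus-test
AUC differences subtracted); the corrected AUC never exceeds the
apparent one, and the shrinkage factor is clamped to (0, 1] — a slope
marginally above 1 is sampling noise, not evidence of underfitting.

Separation (possible at small n with predictors as strong as a
positive culture) is detected by non-convergence or unbounded
coefficients and handled by an in-package Firth-type penalized IRLS
(hat-diagonal score correction), flagged in the result.

## Evaluation and group-level surveillance

* Classification at a cut-off is strict: flagged means
  `P(DRM) > cutoff`.
* All proportion intervals are exact Clopper–Pearson, computed by
  beta-quantile inversion; `lower = 0` at x = 0 and `upper = 1` at
  x = n.
* Report percentages are shown to one decimal, with the reporting
  convention that a proportion strictly below 1 never displays as
  100.0% (an exact upper bound of 0.9997 prints as 99.9) — matching
  how surveillance reports print near-perfect bounds.
* AUC is the Mann–Whitney rank statistic with midrank tie handling;
  its confidence interval is DeLong's (default) or stratified
  bootstrap.
* Calibration uses equal-frequency bins (default 10) with exact
  binomial intervals on the observed proportions.
* Group-level surveillance: per period, expected infections = Σ p̂ᵢ and
  predicted rate = 1000·Σ p̂ᵢ / Σ days-at-risk. Days at risk default to
  total drainage days (sum of drain durations); an episode-length mode
  exists because "days at risk" has no single formal definition.
  Interval estimates: normal approximation with Poisson-binomial
  variance Σ p̂ᵢ(1 − p̂ᵢ) for the expected count, exact Poisson for the
  observed count.

## The synthetic cohort generator

No public data exist for this problem, so the generator is the
package's test bed. It emulates, at the *episode summary* level:

* prevalence 15.3% (Bernoulli latent infection flag);
* per-group distributions of worst-in-episode laboratory values,
  solved from published group medians and IQRs — log-normal for
  strictly positive skewed labs (`meanlog = log(median)`,
  `sdlog = IQR-on-log-scale / (2·z₀.₇₅)`), logit-normal for the CSF
  neutrophil percentage, normal for age;
* counts by negative binomial (antibiotic starts; group medians 1 vs
  4) and shifted Poisson (drains placed), with parameters chosen as
  the *central* member of the set matching the target quartiles, so
  the fitted distribution never sits on a quantile knife-edge;
* culture positivity 45/455 vs 61/82, with CoNS organisms assigned
  only where an antibiotic start covers the contamination-correction
  window (a genuine infection must survive the correction), plus
  planted CoNS contaminants *without* antibiotic coverage in a
  configurable fraction of negative episodes, which the correction
  must remove;
* missingness as whole-measurement-set deletion ("never measured") at
  the published pre-imputation rates (CRP 11.2%, blood leukocytes
  8.4%, hemoglobin 6.1%, thrombocytes 11.2%, CSF panels ≈ 29–31%,
  cultures 19.9%), MCAR for blood panels and MAR-on-outcome for CSF
  panels and cultures (deletion odds for infected episodes scaled by
  OR 0.15, marginal rate preserved by root-finding) — CSF is sampled
  only on clinical suspicion, so infected episodes rarely lack it;
* time-series realism is minimal by design: 1–5 measurements per
  analyte, the extremum placed at a uniform in-episode day and the
  remaining values scattered on the non-infectious side of it, since
  only the per-episode extremum feeds the model;
* calendar years assigned uniformly (or by configured weights) to
  support yearly surveillance summaries.

Correlation between predictors is induced through the latent infection
flag (conditional independence), with one deliberate exception:
admission length and total drainage time share a latent severity
quantile within patient, because drawing them independently would
frequently produce drain chains longer than the hospital stay and
clamping would distort both calibrated distributions. Flags tied to
in-episode timing (any start after day 4, the late empiric pair) can
be truncated by episodes that end before day 5, so their realized
rates run one to two points under the configured ones.

What the generator does **not** emulate — and hence what passing tests
cannot show about real data: joint correlation structure among
laboratory markers beyond the latent flag, autocorrelated time series,
drain re-insertion policy, antibiotic dosing or duration, seasonal or
secular trends, and the chart-review reference standard itself (ground
truth is the latent flag). Parameter recovery and concordance results
on synthetic data demonstrate the statistical machinery is correct,
not that the published model transfers to another hospital.

## Rule-based simulation

For parameter-recovery and concordance checks the generating mechanism
must be the logistic model itself: `simulate_from_rule()` draws
features from the configured marginals (mixture across the latent
groups, indicator discarded), calibrates the intercept by root-finding
so the mean event probability equals the target prevalence, then draws
outcomes from the rule. CRP is capped at 500 mg/L here so the cubic
term cannot produce astronomically large linear predictors in the far
tail. The published-rule mode of `build_prediction_rule()` uses the
same intercept calibration, because the original rule's intercept was
never reported.

## Numerical choices and degenerate inputs

* Imputation design matrices drop constant columns and ridge-stabilize
  near-singular cross-products (`1e-8` on the diagonal); posterior
  draws fall back to the point estimate if a covariance factorization
  fails.
* Firth IRLS caps step length (norm 5) and stops at `1e-8`; weights
  are floored at `1e-10`.
* `uniroot` tolerances for intercept calibration and MAR rate solving
  are `1e-10`/`1e-12`.
* Zero-variance screening variables are reported and never selected;
  all-missing columns abort imputation with a named error.
* Empty culture/antibiotic sets yield `NA`/0 features, never errors;
  empty confusion inputs and single-class ROC inputs abort.

## Problem sizes used by the test-suite

Generator calibration is checked on one cohort of 20 000 admissions
(tolerance 3 bootstrap SEs of each sample median), parameter recovery
on 5 000 episodes with the full ten-predictor rule, selection and
concordance properties on 100 seeded replicates each (n = 5 000 and
537), and the end-to-end pipeline at the development cohort's size
(537 admissions, m = 10, B = 100). These sizes keep every Monte-Carlo
tolerance at 3 SEs while the full suite runs in a few minutes.

## Known limitations

* Backward selection on synthetic cohorts of ~537 episodes is
  unstable across seeds (as variable selection at ~80 events always
  is); the selected set varies while discrimination stays high.
* The bootstrap shrinkage estimate at very small n is dominated by
  separated resamples and can be severe; it is a feature of the
  optimism estimand, not a bug, but warrants the configurable
  AUC-only correction mode.
* The generator's conditional-independence structure makes
  discrimination slightly optimistic relative to real cohorts, where
  collinear predictors share information.
* Post-discharge infections surface only through the 30-day
  readmission rule, exactly as in the surveillance design the package
  automates.
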