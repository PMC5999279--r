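---
title: "Case-mix- and reliability-adjusted quality indicators for ICU benchmarking"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Case-mix- and reliability-adjusted quality indicators for ICU benchmarking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The benchmarking problem

Intensive care units are compared on three outcome-based quality
indicators: in-hospital mortality, readmission to the ICU within 48 hours
of ICU discharge, and ICU length of stay (LOS). Raw unit-level rates are
unusable for comparison for two reasons. First, units admit different
patients: a unit with many high-severity admissions will show high
mortality however good its care is (*case mix*). Second, unit-level
estimates from few admissions are noisy: a 200-bed-year unit's observed
rate carries far more sampling error than a 2,000-bed-year unit's
(*reliability*). `icubench` implements the standard two-step remedy and
the analysis layer on top of it — the pairwise association of the three
indicators across units, overall and within clinically defined subgroups.

The three indicators are:

* **SMR** — standardized in-hospital mortality ratio;
* **SRR** — standardized 48-h ICU readmission ratio, computed on the
  *risk set*: admissions that survived the ICU stay and were discharged
  to a ward in the same hospital (a death in the ICU, or a discharge home
  or to another hospital, cannot produce an observable 48-h ICU
  readmission);
* **SLOSR** — standardized ICU length-of-stay ratio, on the fractional-day
  scale.

A value of 1 means "as expected given case mix"; the reliability
adjustment pulls small units toward 1.

## The two-step model

Fitting a mixed model per subgroup *and* estimating case-mix coefficients
inside each subgroup fails in small subgroups. The two-step approach
decouples the problems.

**Step 1 — fixed-effect case-mix models on the full cohort.**

* *Mortality*: each admission arrives with a severity-of-illness
  probability \(p^{raw}_i\) (in practice from a published severity model
  such as APACHE IV; the generator emits it directly). It is recalibrated
  by logistic regression with intercept and slope,
  \(\operatorname{logit} P(D_i = 1) = \gamma_0 + \gamma_1
  \operatorname{logit} p^{raw}_i\). Slope-and-intercept recalibration
  (rather than intercept-only) is used because a severity model ported to
  a new registry typically needs both location and spread corrected.
* *Readmission*: logistic regression of the 48-h readmission flag on
  first-24-hour covariates, fitted on the risk set. The covariate list is
  configuration, not contract: the procedure is the point, and any named
  columns can be supplied.
* *LOS*: ordinary least squares on \(\log(\text{LOS})\). Day-scale
  expectations are recovered with Duan's smearing factor — the mean of the
  exponentiated residuals — which is consistent without assuming normal
  log-scale errors. We deliberately model the log and smear back rather
  than fitting a Gaussian GLM with log link; the former matches the
  established LOS-prediction practice this pipeline follows, keeps
  residual diagnostics on the scale where the noise is roughly symmetric,
  and still yields the day-scale expectation the mixed step needs.

Model performance is reported with the scaled Brier score
\(1 - \overline{(p_i - y_i)^2} / (\bar y (1 - \bar y))\) and the
concordance index (ties counted half) for the binary models, the squared
Pearson correlation between predicted and observed day-scale LOS for the
LOS model, and a 50-group calibration table (subjects sorted by
prediction, split into contiguous groups whose sizes differ by at most
one, remainder in the last groups; ties broken by input order).

**Step 2 — random-intercept mixed models per subgroup.**

Within each subgroup, the outcome is regressed on its case-mix
expectation with a random intercept \(u_j \sim N(0, \sigma_b^2)\) per ICU
\(j\):

* binary: \(\operatorname{logit} P(y_{ij} = 1) = \beta_0 + \beta_1
  \operatorname{logit} \hat p_{ij} + u_j\);
* LOS (day scale): \(y_{ij} = \beta_0 + \beta_1 \hat y_{ij} + u_j +
  \varepsilon_{ij}\).

The prediction enters as a covariate with an *estimated* slope, not as an
offset. Benchmarking practice varies on this point; we estimate the slope
because it additionally absorbs subgroup-level miscalibration of the
cohort-wide fixed model, and the package exposes the empirical-Bayes
intercepts either way.

The empirical-Bayes intercept \(\hat u_j\) (posterior mode for the
logistic model, BLUP for the Gaussian one) shrinks a unit's deviation
toward 0 in proportion to its imprecision. In the Gaussian case the
closed form is explicit:
\[
\hat u_j = \frac{\sigma_b^2}{\sigma_b^2 + \sigma_e^2 / n_j}\,
\bar r_j,
\]
with \(\bar r_j\) the unit's mean fixed-part residual — the shrinkage
factor goes to 0 as \(n_j \to 0\) and to 1 as \(n_j \to \infty\).

Ratios are then built on the subgroup's own crude rate \(\bar y\) (or
mean LOS \(\bar \ell\)):
\[
\text{SMR}_j = \frac{\operatorname{logit}^{-1}(\operatorname{logit}
\bar y + \hat u_j)}{\bar y}, \qquad
\text{SLOSR}_j = \frac{\bar \ell + \hat u_j}{\bar \ell},
\]
and identically for the SRR on the risk set. Using the subgroup-specific
rate for all three indicators (rather than anchoring the mortality ratio
on the cohort-wide rate) is a deliberate harmonization: it makes
\(u_j = 0\) map to exactly 1 *within every subgroup*, which is the only
convention under which subgroup tables are internally comparable. The
unadjusted sensitivity analysis (`reliability_adjustment = FALSE`)
replaces all of step 2 by raw observed/expected ratios.

**Associations.** For every subgroup and each pair of indicators, the
Pearson correlation across ICUs is tested with the exact t transform
\(t = r\sqrt{(n-2)/(1-r^2)}\) on \(n - 2\) degrees of freedom, two-sided
(two-sidedness is assumed; the convention is implied rather than stated
in the sources), at \(\alpha = 0.01\); Spearman's rank correlation is the
outlier-robust sensitivity analysis, with the same t transform applied to
the rank correlation (adequate at ~80 units; an exact permutation option
exists for \(n \le 10\)). Missing indicator cells use pairwise-complete
deletion.

## Subgroups and exclusions

The exclusion cascade removes, in order: cardiac-surgery admissions,
admissions excluded by the severity model's criteria, admissions
discharged to another ICU (truncated LOS), and admissions with missing
covariates. Attribution is first-rule-wins, so the log reads like a
patient-flow diagram. Subgroups are: the full cohort; admission type
(medical, urgent surgery, elective surgery); mortality-risk strata on the
*recalibrated* probability with half-open boundaries [0, 0.3), [0.3,
0.7), [0.7, 1] (a boundary value falls in the upper stratum — the literal
reading of "greater than or equal to"); and diagnostic groups (CAP,
sepsis, OHCA). An ICU with no admissions in a subgroup gets a missing
indicator, never the shrunk value 1, so "no data" and "average
performance" remain distinguishable.

## The synthetic registry generator

No admission-level ICU registry of this kind is public, so the package
ships a seeded generator with known unit-level truth. Its defaults
emulate a national registry year: 83 ICUs with 205–2,282 admissions
each; crude in-hospital mortality 14.3%; 48-h readmission 2.4% in the
risk set; right-skewed fractional-day LOS with median ≈ 1.2 d and mean ≈
3.3 d; and exclusion rates chosen once so that ≈ 82% of admissions
survive the cascade (4% cardiac surgery, 10% severity-model exclusions,
3% transfers among ICU survivors, 2% missing covariates — the individual
rates are not published, only the retained fraction is). Unit effects on
the three outcomes are drawn from a trivariate normal with SDs
`sd_mort = 0.2`, `sd_readm = 0.3` (logit scale), `sd_los = 0.4` (days)
and a configurable correlation matrix. The SD defaults were back-computed
once from the indicator spreads the generator is meant to reproduce
across 83 units (an SMR spread of roughly 0.6–1.5 at a base rate of
14.3% corresponds to unit effects of roughly ±0.45 logits, i.e. an SD
near 0.2) and are not revisited.

Construction details that matter downstream:

* **Severity.** \(p^{raw}\) is logit-normal with spread 1.7 logits; the
  location is calibrated by Gauss–Hermite quadrature and root finding so
  the *realized* death rate (including unit effects) hits the target.
  The spread reproduces an APACHE-like right-skewed risk mix in which
  roughly 2% of admissions exceed a 0.7 death probability. An optional
  per-ICU severity shift (`sd_severity_shift`, default 0) creates
  between-unit case-mix differences; the true between-unit severity
  distribution is unknown, so it is off by default.
* **Risk-set structure.** Death in the ICU (70% of in-hospital deaths)
  and discharge destination are drawn first; the readmission flag is
  sampled only for ward discharges of ICU survivors, so risk-set
  eligibility is structural rather than flagged.
* **LOS.** Lognormal baseline plus the unit effect *added on the day
  scale* (truncated below at 0.02 d ≈ 30 min), matching the estimand of
  the day-scale linear mixed model. Values are recorded to 1e-4 d, the
  resolution of admission timestamps, which also makes the CSV format an
  exact round trip.
* **Independence.** Given the unit effects, the three outcomes are drawn
  independently within an admission. Real data couple them at patient
  level (dying patients have atypical LOS; readmitted patients are
  sicker). The generator therefore supports clean null-calibration and
  sign-recovery experiments — under independent unit effects the
  indicator association tests must be null-calibrated — but passing them
  says nothing about patient-level outcome coupling, which the
  unit-level association analysis does not model either.
* **Determinism.** A single seed drives one root generator in a fixed,
  documented draw order (sizes, unit effects, severity shifts, then
  admission columns); identical parameters give bit-identical registries.

## Numerical choices

* Logistic mixed models are fitted with `lme4::glmer` under the Laplace
  approximation, with derivative-free convergence checks disabled and the
  `nloptwrap` optimizer (identical estimates to the defaults on this
  model class, at roughly 2.5× speed — this matters for the replicate
  studies). The package carries its own evaluator of the marginal
  log-likelihood (`binary_marginal_loglik`) in both Laplace and 40-node
  adaptive Gauss–Hermite form; on small fixtures with moderate
  between-unit SD (≲ 0.4 logits, the regime of this application) the two
  agree to better than 1e-3, and the Laplace value also matches
  `lme4`'s to ~1e-6. The agreement degrades to ~1e-2 when the fitted SD
  approaches 1 — an intrinsic property of the Laplace approximation at
  such sizes, documented here so that fixture choices are understood.
* Gaussian variance components are estimated by REML; BLUPs are computed
  from the fixed-part residuals through the Woodbury identity (linear
  time), which reduces exactly to the scalar shrinkage law above and is
  verified against a dense matrix-algebra oracle to 1e-10.
* A subgroup whose mixed model cannot be fitted (single-class outcomes,
  a single ICU, non-convergence) yields missing cells for that subgroup
  and outcome, recorded in the table's `failures` attribute; other cells
  are unaffected. A fitted \(\sigma_b = 0\) is legitimate (all ratios
  exactly 1) and such constant indicators are omitted from association
  tests with a warning.
* A negative adjusted mean LOS (\(\bar\ell + \hat u_j < 0\)) is floored
  at 0 with a warning; with realistic unit effects it does not occur.
* Calibration-group ties are broken by input order; group sizes differ by
  at most one with the remainder in the last groups.

## Simulation-study problem sizes

The package's property checks run replicate studies at these sizes,
chosen to keep the full suite affordable on a single CPU while leaving
the statistical conclusions sharp: parameter recovery uses 20 replicates
at full registry scale (83 ICUs, sizes uniform on [205, 2282],
`sd_mort = 0.3`); the null-calibration study uses 500 replicates at a
reduced 83 × 100 size; the sign-recovery study uses 200 replicates per
direction at 83 × 250 — the smallest size at which measurement-noise
attenuation (reliability ≈ 0.5 for the mortality intercepts, ≈ 0.34 for
LOS) still leaves an induced effect correlation of ±0.6 clearly signed,
at roughly ±0.26, across 83 units. At the
reduced size the LOS variance component is only weakly identified and a
small fraction of replicates (≈ 8%) fit \(\sigma_b = 0\), leaving a
constant indicator and no computable correlation; such replicates carry
no test and are excluded from the calibration summaries, with the
effective count reported.

## Limitations

* The severity model itself is out of scope: the generator emits a
  severity probability directly, and nothing is learned here about
  building one.
* Admissions are anonymized and unlinked; repeated hospitalizations of
  one patient are separate rows, and only the 48-h readmission flag
  connects stays.
* Exclusion flags are missing-completely-at-random; the generator does
  not model *why* a record is excluded, only how many are.
* Subgroup labels for the diagnostic groups are generator-assigned;
  real diagnostic definitions are registry-specific and not modeled.
* Competing risks of the 48-h readmission outcome (death or hospital
  discharge shortly after ICU discharge) are not modeled, in the
  generator or the analysis.
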