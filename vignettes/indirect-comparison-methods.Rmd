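---
title: "Methods: propensity-matched indirect comparison of two antipsychotic trial programs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: propensity-matched indirect comparison of two antipsychotic trial programs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(psbridge)
```

## The problem

Two antipsychotics — an extended-release compound and an older
immediate-release comparator — were each tested against placebo in their own
short-term (4- to 8-week) acute-schizophrenia programs, but never against
each other. With patient-level records from six placebo-controlled trials
(three per program), an indirect comparison is possible if the two treated
populations can first be made comparable on observed baseline
characteristics. `psbridge` implements that full analysis as a reusable,
testable pipeline: propensity-score matching to construct the comparison
population, LOCF endpoint analysis for efficacy, and clamped
placebo-adjusted differentials for spontaneously reported adverse events.

Because the underlying trial databases are proprietary, the package ships a
calibrated synthetic six-trial generator with the published group structure,
so that every downstream stage can be exercised and its operating
characteristics measured without any real data. The published summary
tables themselves are packaged as plain-text fixtures, and every derivable
printed cell is recomputed exactly by `reproduce_fixtures()`.

## Analysis population

Eligibility mirrors the pooled analysis: adults 18–65 inclusive, comparator
modal dose capped at 8 mg/day, and (for the one comparator trial run after
second-generation agents reached the market) exclusion of subjects whose
prior treatment was exclusively atypical. Treatment groups are defined by
modal daily dose: the extended-release compound at 6–12 mg/day, the
comparator at 2–4 and at 4–6 mg/day, and the two program-specific placebo
groups. A modal dose of exactly 4 mg/day belongs to *both* comparator dose
groups; `group_members()` exposes the two groups as overlapping views over
one underlying subject set, and no contrast ever contains the same subject
twice as two rows.

## Propensity model and matching

Each matching step fits a maximum-likelihood logistic regression of a binary
group indicator on six baseline covariates common to all six protocols: age,
sex, race (white vs all other), BMI, CGI-S severity, and PANSS total. The
propensity score is the fitted probability, and the caliper (0.05 by
default) operates on that probability scale — the natural reading when
scores are defined as probabilities. Subjects with a missing model covariate
are dropped from matching and logged; we do not impute (whether the original
analysis did is unknowable from the publication, and complete-case fitting
is the conservative default for a six-covariate model).

Matching is 1-to-many, greedy, and pass-structured: in every pass each case
(visited in ascending id order) claims its nearest still-unclaimed control
within the caliper; passes repeat — one additional control per case per
pass — until a pass adds nothing. Two deliberate determinism rules close
gaps the verbal description leaves open: equidistant controls go to the
lower control id, and case iteration order is ascending id. A `max_ratio`
argument caps controls per case; the default is unlimited, since nothing in
the source fixes a cap. "Cases" are always the smaller group of a pairing
step, which maximizes retention under 1-to-many growth.

The population is built in three steps (`build_matched_population()`):
comparator actives (all doses pooled) vs their placebo group; the other
program's actives vs theirs; then a *freshly refit* cross-program model on
the step-1/step-2 active survivors, with compound program as the dependent
indicator. Refitting, rather than reusing step-1/2 scores, is the natural
reading of "pairing from the resulting groups": the third step asks a new
question (which program?) of a new population. All cross-program matched
subjects enter the final sample; the placebo groups retained in steps 1–2
carry forward unchanged.

Before any pooled-placebo efficacy analysis, `placebo_poolability()` runs
the pre-specified gate: baseline covariates compared by Welch t and
proportion chi-square tests, and endpoint LOCF changes (PANSS total and five
factors) by the same baseline-adjusted contrast the efficacy module uses.
Pooling is allowed only when every endpoint-change p-value exceeds 0.05.
Adverse-event comparisons never use a pooled placebo group — each program's
own placebo column is the correction reference — mirroring the asymmetric
handling in the published tables.

## Efficacy analysis

Endpoints are changes from baseline to the trial-specific endpoint week
(week 4 for the 4-week study, week 8 for the 8-week study, week 6
otherwise) under last observation carried forward. Subjects with no
post-baseline observation of a measure are excluded from that measure's
change analysis and logged, never errored.

Contrasts come from analysis of covariance: `change ~ group + baseline`,
homogeneous slopes (the minimal model consistent with "baseline as the
covariate"), adjusted means at the grand baseline mean, model-based standard
errors, two-sided t-distribution p-values, and no multiplicity adjustment.
Two numerical choices: a zero-variance baseline drops the covariate with a
warning instead of failing (so degenerate inputs stay analyzable, and the
adjusted means collapse to raw change means); a baseline collinear with the
group factor is a hard error naming the deficiency. Because the two
comparator dose groups overlap in the 4 mg/day subjects, the pipeline fits
each pairwise contrast as its own two-group model rather than one
many-group model.

Responders show a decrease of at least 30% of their own baseline PANSS
total, boundary inclusive, computed in integer-exact arithmetic so a
decrease of exactly 30% counts. Response percentages use the LOCF analysis
set as denominator (the publication does not say which denominator it used;
the LOCF set is the population in which response is defined). Response
rates are compared with Pearson chi-square tests without continuity
correction.

## Adverse-event differentials

Incidence uses distinct-subject counting and one-decimal percentages
rounded *half away from zero* — the only rounding rule consistent with every
checkable printed cell. The placebo-adjusted differential between programs
is

d = max(act_ris − plc_ris, 0) − max(act_pali − plc_pali, 0)

computed **on the already-rounded percentages**. Order matters: for
somnolence the rounded inputs give 7.3 while raw fractions give 7.2, and
only the round-then-difference order reproduces the printed cells. A term
enters the safety table when any active or placebo group reaches 5%
incidence, and a differential is reported when its magnitude reaches 2
percentage points, with the direction recorded before taking the magnitude.
One published row (akathisia, maximum incidence 4.7%) sits below the
stated 5% entry gate; `flag_ae_table()` keeps the stated gate, and
`reproduce_fixtures()` therefore recomputes differentials for the published
row selection without re-applying the gate, since that selection is not
itself derivable from the printed numbers.

Placebo-adjusted completion rates are differences of the rounded group
percentages, in the same spirit. No statistical tests are attached to
adverse-event rates, and none are attached to the adjusted completion
contrasts (the publication reports p-values for those without stating a
test; we emit the rates and leave the gap explicit).

## The synthetic-data generator

`default_suite()` encodes the study conditions: six trials with the
published arm structures; per-group baseline covariate moments (age, sex,
race, BMI, PANSS, CGI-S); endpoint effects, completion rates, adverse-event
incidences and weight changes set to the published group values. Continuous
covariates are truncated normals (inverse-CDF sampling, truncation to
plausibility limits and each trial's PANSS entry window), binary covariates
Bernoulli. The earliest comparator trial carries no PANSS factor scores and
the 4-week trial no CGI-S, as in the source protocols.

Design choices worth stating explicitly:

* **Trajectory.** Each subject has a latent endpoint improvement drawn
  normal around the arm target; the observed value at week *t* is baseline
  plus the fraction *t/W* of that improvement plus independent visit noise.
  Linear gain is the minimal assumption; no trajectory shape is published.
  PANSS factor scores are generated directly (not item-level) with the
  total equal to the factor sum at every visit; arm-level factor shares
  partition the total change, so item-level simulation would add nothing
  testable.
* **Dropout.** A constant discrete-time hazard per week, solved so that
  survival to the endpoint equals the arm's completion rate
  (missing-completely-at-random by default). An optional
  `mar_improvement` mechanism makes the weekly hazard depend logit-linearly
  on current latent improvement, for stress-testing LOCF.
* **LOCF calibration.** Under linear gain and dropout, the LOCF arm mean is
  an attenuated fraction of the full-course improvement (dropouts carry
  partial gains forward). Since the published endpoint changes *are* LOCF
  estimates, the generator rescales the latent improvement by the
  reciprocal of the expected carried-forward fraction (closed form from the
  hazard), so the expected LOCF arm mean equals `endpoint_effect`.
  A documented corollary is completers-only bias: completers improve more
  than the arm target.
* **Dose-level parameters.** The 63 subjects at 4 mg/day belong to both
  comparator dose groups, so group-level targets cannot be assigned
  per-arm directly. The 4 mg arm takes the mean of the two group targets
  and the 2 mg and 6 mg levels are solved so the subject-weighted group
  means equal the published group values — yielding a monotone
  dose-response as a by-product.
* **Factor shares.** The placebo groups' published hostility/excitement
  changes are worsenings (positive) against a negative total; since shares
  are defined non-negative, those shares clamp to zero and the rest
  renormalize.
* **Adverse events** are independent Bernoulli per term per subject (the
  source reports marginal incidences only), with onset uniform over the
  subject's observed weeks.

Fixed `(suite, seed)` reproduces cohorts byte-identically.

### What the generator does and does not emulate

It reproduces group sizes, covariate moments, completion rates, LOCF effect
means, adverse-event incidences and weight changes — the quantities the
pipeline's operating characteristics depend on. It does **not** emulate:
item-level PANSS structure; correlated adverse events; informative dropout
(by default); between-trial heterogeneity beyond entry windows and visit
schedules; or the skewed change distributions real PANSS data show. A
visible consequence of the last point: with normal changes at the published
means and standard errors, absolute responder rates come out lower than the
published ones (the mean change sits below the 30%-of-baseline threshold),
although group orderings are preserved. Passing tests on synthetic data
therefore validate the *pipeline arithmetic and its statistical operating
characteristics*, not the clinical conclusions of any real dataset.

Calibration targets treat the published covariate-adjusted means as raw arm
means; with baseline covariates generated independently of improvement the
two coincide in expectation, so the approximation is benign here.

## Problem sizes used by the validation suite

The packaged tests run: matching-oracle equivalence on all generated
instances up to 6 cases × 8 controls (100 instances, tie-heavy grids
included); ANCOVA against an explicit normal-equations solution on toy sets
to 1e-6; contrast recovery at the published scale (179 vs 113 subjects,
100 replicates); type-I error of the contrast under a null suite (two arms
of 50, 600 replicates, band 0.03–0.07 at nominal 0.05); completion-rate
calibration over 20 replicates of the full six-trial suite against binomial
99% bands; and covariate-balance shrinkage on confounded assignments over
20 seeded runs. These sizes were chosen to make Monte-Carlo error small
relative to the tested tolerances while keeping the default suite quick to
run.

## Known limitations

* LOCF is kept because it is what the source analysis used; it is not a
  robust estimator under informative dropout, and the generator's
  `mar_improvement` switch exists precisely to demonstrate that.
* The matched population depends on the tie-break and case-ordering rules
  wherever scores tie; results are deterministic but other orderings are
  equally defensible.
* The poolability gate runs six correlated tests at 0.05 each, so with
  truly poolable groups it still (correctly) refuses pooling in a minority
  of replicates; the pipeline then falls back to program-specific placebo
  contrasts.
* Extrapyramidal rating scales, prolactin, and MedDRA re-coding are out of
  scope; adverse events arrive pre-coded.
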