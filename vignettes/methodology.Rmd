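---
title: "Relating methodological quality of prediction models to performance at external validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Relating methodological quality of prediction models to performance at external validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(probastmeta)
```

## The question

Clinical prediction models are routinely developed with methodological
shortcuts — small derivation cohorts, stepwise selection, weak internal
validation — and then validated in new settings. `probastmeta` implements a
meta-epidemiological pipeline for asking whether those shortcuts show up as
degraded discrimination when the models meet new patients: it scores the
methodological quality of each development study, quantifies the change in
discrimination between derivation and each external validation, and
regresses that change on quality while respecting the clustering of repeated
validations of the same model. The motivating application is prognostic
models for functional outcome after moderate and severe traumatic brain
injury (TBI), where an evidence base of 10 development studies (18 models)
and roughly 245 external validations exists; the packaged fixture
(`table1_fixture()`) transcribes the per-study assessments of that evidence
base.

## Risk-of-bias rollup (PROBAST)

PROBAST judges a development study on 20 signaling questions grouped into
four risk-of-bias domains (participant selection, predictors, outcome,
analysis) and three applicability domains. Each answer is one of
Y/PY/PN/N/NI. The package applies the rollup mechanically:

* **Domain rule** (`judge_domain()`): any N or PN answer makes the domain
  high risk; otherwise any NI makes it unclear; otherwise low.
* **Overall rule** (`overall_rob()`, `overall_applicability()`): any high
  domain makes the study high risk; otherwise any unclear domain makes it
  unclear; otherwise low.

PROBAST formally permits reviewers to override a mechanical domain
judgment. The engine therefore accepts an `override` and records its
provenance (`source = "reviewer_override"`); the mechanical rule is the
default because the published per-study judgments in the fixture are exactly
reproducible from it, and a tool should not silently overrule humans in
either direction.

The monotonicity of the rollup — worsening any single domain can never
improve the overall judgment — is verified in the test suite by exhaustive
enumeration over all 3^4 domain combinations.

### The short form

An 8-question subset of PROBAST has been proposed as a high-sensitivity
screen for high risk of bias. The published sources we reproduce do not
enumerate the 8 items, so the subset is configuration
(`probast_config(short_form_ids = ...)`) with a documented default
(`1.1, 2.3, 3.5, 4.1, 4.2, 4.3, 4.8, 4.9`) weighted toward the analysis
domain, which dominates high-risk judgments in practice. Tests rely only on
properties that hold for any subset (a short-form high implies a full-form
high whenever the triggering question is in the subset; unclear studies
whose NI answers fall outside the subset screen as low) plus the configured
default. `short_form_rob()` applies the same mechanical rule restricted to
the subset.

### Events per parameter

The sample-size signaling question is operationalized as events per
parameter (`epp()`): the number of events in the smaller outcome group
divided by the total degrees of freedom consumed by all candidate
predictors — continuous predictors contribute 1, categorical predictors
their number of categories (`total_df()`, default convention `categories`).
That counting convention follows the source analysis literally; the
conventional dummy-coding alternative (`categories_minus_one`) is
selectable, because reproducing the published assessment takes precedence
over adjudicating the convention. The threshold is EPP ≥ 10, inclusive at
the boundary. Whether an adequate EPP maps to Y or PY on the signaling
question is left to the answer mapping in configuration; the function
returns the ratio and a boolean.

## Rubrics

* **Relatedness** (`classify_relatedness()`): three binary domains — the
  validation meets the development study's setting, inclusion criteria, and
  outcome assessment/timing. All three met: `related`; setting unmet but
  inclusion and outcome met: `moderately`; inclusion and/or outcome unmet:
  `distantly` (setting is then irrelevant). A "setting not specified" in an
  extraction must be resolved upstream, conservatively to `FALSE`. Severity
  is monotone: flipping any met domain to unmet never decreases it.
* **Usability** (`usable_research()`, `usable_practice()`): usable in
  research if the full equation (or intercept plus coefficients) is
  reported; usable in practice if any alternative presentation (nomogram,
  score chart, web calculator, other) exists.
* **Design similarity** (`design_similarity()`): the development-to-
  validation design transition (`similar`, `cohort_to_trial`,
  `trial_to_cohort`), a proxy for case-mix heterogeneity differences —
  cohorts are typically more heterogeneous than trials. A model developed on
  pooled cohort-and-trial data is treated as design-similar to either
  validation design, since both designs contributed to derivation.

`tally()` reproduces the summary table: study-level counts (one per distinct
study) for risk of bias, applicability and usability, and record-level
counts for design similarity and relatedness, with unclassifiable records
excluded from the denominator and reported in a `not_classified` row.

## Change in discrimination

Discrimination above chance is `AUC - 0.5`. The percent change between
derivation and validation is

$$\mathrm{dAUC}\% \;=\; 100 \times
\frac{(\mathrm{AUC}_{val}-0.5)-(\mathrm{AUC}_{dev}-0.5)}
     {\mathrm{AUC}_{dev}-0.5},$$

so a drop from 0.70 to 0.60 is a 50% loss, −100% is a fall to chance, and a
validation AUC below 0.5 drops below −100%. The denominator involves only
the development AUC; records with a development AUC at or below 0.5 (or
missing, or with no development AUC for the validated outcome) are excluded
with a logged reason in the run manifest rather than crashing the pipeline —
observed validation AUCs below 0.5 do occur in real evidence bases, and one
malformed record should not abort a synthesis. When a study reports AUCs for
both mortality and unfavorable outcome, a validation is paired with the
development AUC of the *same* outcome; mismatches are logged exclusions.

`summarize_by_stratum()` reports the median and interquartile range of the
development AUC, validation AUC, absolute change, and percent change, per
overall risk-of-bias class (fixed order low, high, unclear). Published
tables rarely state their quartile convention and IQR endpoints cannot
adjudicate it, so the convention is fixed to linear interpolation
(`stats::quantile` type 7) and exposed as `quartile_type` for sensitivity
checks.

## Clustered meta-regression

The synthesis regresses per-record dAUC% on risk-of-bias class (reference:
low) and design similarity (reference: similar), clustering validations of
the same **model**. The source analysis names generalized estimating
equations (GEE) as its method while a table note mentions a random intercept
per model; these are different estimators — marginal versus conditional. We
implement the marginal GEE, the method named in the analysis description,
and note that with an identity link and approximately exchangeable
correlation the two give similar point estimates; a conditional
(mixed-effects) estimator is deliberately out of scope for this version.

`fit_gee()` implements Gaussian identity-link estimating equations:
iterate (1) a weighted least-squares solve for the coefficients under the
working correlation with (2) a moment update of the exchangeable correlation
$\hat\alpha$ from standardized within-cluster residual cross-products, until
the largest coefficient change is below `tol` (default 1e-8, default
`max_iter` 100; non-convergence returns a flagged fit, never a silent one).
The exchangeable inverse has the closed form
$R^{-1} = \tfrac{1}{1-\alpha}\left(I - \tfrac{\alpha}{1+(n_i-1)\alpha}J\right)$,
so cluster solves reduce to column sums and the scalar factors cancel in
both the coefficient solve and the sandwich. Variance is the cluster
sandwich $B^{-1} M B^{-1}$; confidence intervals are z-based
(estimate ± 1.96 robust SE). Design choices:

* z rather than small-sample t or bias-corrected sandwich, matching the
  symmetric intervals conventional in this literature; with few clusters the
  sandwich is anticonservative, so fits with fewer than 10 clusters warn.
  (The motivating evidence base has only 18 clusters; its intervals should
  be read with that warning in mind.)
* Whether the published analysis used an exchangeable or independence
  working correlation is not stated; both are available
  (`working_corr`), exchangeable is the default, and with one record per
  cluster either reduces exactly to ordinary least squares — a property the
  tests exploit, alongside a cross-check of the independence-case sandwich
  against an independently implemented cluster-robust estimator.
* Covariate levels absent from a data set drop their column with a warning
  (preserving rank) rather than failing; with evidence bases of ~10 studies
  an absent level is a routine draw, not an anomaly.

Parameter recovery is verified by simulation: data generated with known
intercept, risk-of-bias and design effects (+9, −30, −13, −18, 0 on the
percent scale), a cluster random intercept (SD 5) and record noise (SD 10)
at 200 models × 10 validations are refit 500 times; all five coefficients
recover with |bias| < 0.5 percentage points and 93–97% empirical coverage of
the nominal 95% intervals, and $\hat\alpha$ recovers the generating
intra-model correlation. These problem sizes make the whole recovery run a
few seconds while leaving Monte-Carlo error well below the tolerances.

## The synthetic evidence-base generator

`generate_evidence_base()` exists so that every downstream stage is testable
end to end without any external data. It emulates the *structure* the
analysis assumes, with magnitudes that are scenario parameters, not
empirical claims:

* each model has a true validation-population AUC (uniform on
  `true_auc_range`), mapped to a binormal score separation via
  $\mathrm{AUC} = \Phi(\delta/\sqrt2)$;
* its development study has a risk-of-bias class (multinomial
  `rob_probs`, default 20/60/20 low/high/unclear, the mix of the motivating
  evidence base) materialized as consistent domain judgments and signaling
  answers, so the PROBAST rollup reproduces the class;
* the reported development AUC is the true AUC plus class-specific optimism
  (`optimism_by_rob`, default −0.02/+0.06/+0.015 for L/H/U: high-risk
  development inflates apparent discrimination, while the low-risk default
  is slightly negative so that low-risk models gain discrimination at
  validation, the pattern seen in the motivating evidence base) plus
  reporting noise;
* each validation draws finite binormal cohorts (`n_pos` cases, `n_neg`
  non-cases) at the true AUC shifted by a design-transition case-mix effect
  (`casemix_shift`) and within-model heterogeneity (`within_model_sd`), and
  records the empirical Mann–Whitney AUC, so sampling error scales correctly
  with cohort size.

Optimism attaches to the risk-of-bias class directly rather than
mechanistically to EPP: the association, not the mechanism, is what the
analysis asserts. Shifts act on the AUC scale with truncation into
[0.51, 0.99] — simple, and adequate for recovery tests; a logit-scale model
would behave differently only near the boundaries. Relatedness flags are
independent Bernoulli draws with defaults chosen so about two thirds of
records classify as distantly related. Randomness is organized as one
model-level stream plus per-model record substreams whose seeds are drawn up
front, so enlarging `validations_per_model` never perturbs model-level
draws, and output is byte-identical given `(config, seed)`.

What the generator does **not** emulate: calibration drift, correlation
between relatedness and case-mix shift, publication asymmetries (in real
evidence bases better models are validated more often), outcome-specific
case mix, or patient-level covariate structure beyond the binormal score
model. Passing recovery tests therefore demonstrates the estimator and
plumbing are correct under the stated generative assumptions — not that the
substantive association holds in any real evidence base.

## Degenerate inputs and numerical choices

* AUCs are validated into the open interval (0, 1) at read time, with row
  numbers in error messages; missing numerics are empty cells, never
  sentinel values.
* Empirical AUC uses mid-ranks (ties count one half), exactly the pairwise
  count.
* $\hat\alpha$ is clamped to [0, 0.99]; with all-singleton clusters there
  are no residual pairs and $\hat\alpha$ is 0.
* A singular design is an error naming the collinear columns; an absent
  factor level is a warning and a dropped column.
* An empty stratum keeps its summary row with `n = 0` and missing
  statistics; an empty validation table is valid input.

## Reproducing a full run

```{r, eval = FALSE}
eb <- generate_evidence_base(simulation_config(seed = 1))
out <- run_synthesize(eb$studies, eb$validations, "synthesis_out")
out$by_stratum
out$gee_table
```

The fixture-based assessment path (`run_assess(table1_dev_table(), ...)`)
reproduces the published per-study overall judgments and the summary tally
(6 high / 2 low / 2 unclear risk of bias; 3 high-applicability studies; 4
research-usable and 9 practice-usable models). Every number quoted in this
vignette is recomputed by the test suite or by `scripts/acceptance.R`.
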