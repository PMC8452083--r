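---
title: "Methods: Bayesian cost-effectiveness of topical sevoflurane for painful leg ulcers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Bayesian cost-effectiveness of topical sevoflurane for painful leg ulcers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sevocea)
```

## The analysis in one paragraph

Two arms are compared over a one-year horizon from the public payer's
perspective: conventional analgesia alone (n = 26) versus conventional
analgesia plus domiciliary topical sevoflurane (n = 38) for painful,
nonrevascularizable leg ulcers. Effectiveness is the SPID pain statistic;
costs are annual per-patient direct medical costs in 2016 euros. A bivariate
normal regression of (log cost, SPID) on six baseline covariates is fitted
by Gibbs sampling under diffuse priors, and the treatment coefficients are
transformed into a costs ratio, an incremental effectiveness, dominance
probabilities, and a cost-effectiveness acceptability curve.

## SPID and its time weighting

SPID sums, over follow-up visits, the difference between baseline pain and
the visit's pain, weighted by the time since the previous evaluation. The
published description of the weight ("fraction of time elapsed") is
ambiguous: if the weights were fractions of total follow-up (summing to 1),
SPID could never exceed 10 NRS points, yet the observed group means are
41.5 and 13.1. We therefore weight by interval length **in months**, giving
the plausible −120..120 range; the horizon argument makes the unit
configurable. Baseline is the pain at the time-0 (first Pain Clinic) visit.

Patients who die or lose the leg before month 12 contribute their last
observed score for the remaining time (last observation carried forward,
`carry_forward_final_pain()`), which matches the stated handling of
incomplete follow-up and makes a constant-pain patient contribute exactly 0.

## Costing

Every consumed resource is multiplied by its unit cost and CPI-adjusted to
reference-year euros. Three conventions deserve note:

* **Syringe filling** is costed from pharmacist time: one hour (2016 €41)
  fills 200 syringes, i.e. €0.205 per syringe.
* **Sevoflurane** is costed per mL (€0.30) by default. The published
  resource table's printed mean costs are not exactly quantity × unit cost
  (8784 mL × 0.30 ≠ 3240), and whether whole 250 mL bottles were costed
  cannot be reconciled from the text; a per-bottle option
  (`bottle_costing = TRUE`, ceiling of bottles) is provided and the printed
  means are treated as non-binding.
* **Admissions** use DRG tariffs with/without complications; sensitivity
  variants override the complication flag, restrict admissions to those
  attributed to the ulcers or to ulcer pain (attributions are nested:
  pain ⊂ ulcer ⊂ any; non-matching admissions are zeroed, patients are kept),
  or switch to per-diem × length-of-stay costing.

Ulcer-cleansing costs have no category at all: they were excluded from the
analysis as a common expenditure already contained in visit costs. DRG
tariffs, per-diem rates and opioid-conversion factors are user-supplied
tables; the package defaults (DRG €8000/€5000 with/without complications,
per-diem €550/day) are **synthetic** stand-ins of realistic Spanish-2016
magnitude chosen once for the generator, not official tariffs.

## The bivariate model and priors

With `y_i = (log cost_i, SPID_i)` and
`x_i = (1, AHT, UlcerDuration, min(UlcerNumber, 4), UlcerDepth, UlcerPain,
Treatment)`:

* coefficients: independent N(0, 10⁵) per entry of each equation's 7-vector
  (a priori independent across equations);
* error precision Σ⁻¹ ~ Wishart(2, I₂) in the BUGS `dwish(R, k)`
  convention. The published wording says "prior for the variance-covariance
  matrix", but the BUGS-family software used for the analysis parameterizes
  the Wishart on the **precision**; we follow the software convention and
  validate the sampler against the conjugate closed form rather than the
  wording.

The Gibbs sampler alternates the two full conditionals — a 14-dimensional
normal for the coefficients given the precision, and a Wishart with
df = 2 + n and scale (I + E′E)⁻¹ given the coefficients — in compiled code,
driven by R's RNG so a seed fixes the chain bit-for-bit. Defaults are a
10,000-draw burn-in and 100,000 kept draws, single chain, as in the source
analysis; no convergence diagnostics gate the run (the posterior is
effectively conjugate and mixes in a handful of iterations).

Natural logs are used for costs; any other base would only shift the
intercept, and exp(β₁₇) is base-consistent with the natural log.

## CEA outputs and the retransformation convention

The costs ratio is summarized as the **mean of exp(β₁₇) over draws** (not
the exponential of the mean), with equal-tailed 2.5–97.5% credible
intervals throughout. Dominance probabilities are draw fractions:
P(cheaper) = P(β₁₇ < 0), P(more effective) = P(β₂₇ > 0), and their joint
fraction is P(dominant), which can never exceed either margin.

A euro-scale incremental cost (for the ICER and the CEAC) requires
retransforming the log-scale model. The package's convention evaluates the
lognormal mean at the conventional-arm covariate means per draw,
`exp(x̄'β₁ + σ₁₁/2)`, and multiplies by `exp(β₁₇) − 1`; observed comparator
mean cost can be substituted via the `baseline_cost` argument. Dominance
probabilities are invariant to this choice (the incremental cost's sign is
β₁₇'s sign). Under dominance the ICER is a negative-over-positive ratio and
is flagged uninformative rather than headline-reported. The CEAC default
grid spans €0–2000 per SPID unit in 101 steps, covering the curve's full
rise at the study's magnitudes.

## Sensitivity scenarios

Three mutually exclusive families, one scenario active at a time: the
hospitalization-costing variants above; a subgroup excluding patients with
death or amputation events; and the extreme scenario multiplying costs by
1.25 / 0.75 and SPID by 0.75 / 1.25 for the sevoflurane / conventional arms
(the 25% figure is data, chosen post hoc in the source analysis by rounding
up the 95% confidence limits, and is a config default here). Each scenario
is refit with a fresh chain whose seed derives deterministically from the
master seed and the scenario name, so suites are reproducible without
artificially correlating scenarios. Whether the one-way variants should
also reclassify nonscheduled-consultation costs is not documented; only
admission costs are varied.

## The synthetic generator: what it emulates, what it does not

`generate_analysis_rows()` draws covariates matching the published baseline
marginals (AHT 73%, depth-beyond-dermis 28%, lognormal ulcer duration with
mean ≈ 21 months, raw ulcer counts 1–6, integer baseline NRS around
6.8 ± 1.5) and then (log cost, SPID) from the bivariate normal the model
assumes. Default truth: β₁ = (7.5, 0.4, 0.02, 0.3, 1.0, 0, −0.65),
β₂ = (−22, 1.5, 0.1, 0.5, 1.5, 4.5, 28), residual SDs 1.0 (log cost) and
14 (SPID), correlation −0.2 — round numbers at the magnitudes of the fitted
posterior, chosen once before any acceptance measurement. They imply a true
costs ratio exp(−0.65) ≈ 0.52 and arm-level SPID means near 41 vs 13.

`generate_cohort()` additionally back-constructs the two lower record
levels. Pain trajectories use a two-segment device: the required mean pain
difference d = SPID/12 is split between the two integer NRS levels
bracketing it, with the switch time placed so the time-weighted average is
exactly d — so outcomes computed from the generated visits reproduce the
drawn SPID **exactly** for event-free patients despite integer scores.
Patients with a death/amputation month may not accommodate the switch time;
they fall back to a constant rounded difference, bounding the closure error
by 0.5 × horizon (6 NRS-point·months). SPID draws infeasible for the drawn
baseline pain (outside ±(0..baseline) × 12) are resampled and counted.
Resource quantities are back-solved from the drawn cost by fixed category
shares (admissions-heavy, 60%, mirroring the dominance of hospitalization
costs; sevoflurane shares only in the treated arm), so base-case costing
reproduces the drawn cost to rounding.

The generator does **not** emulate: real DRG class frequencies, correlation
between resource mix and covariates, visit-schedule irregularity beyond the
constructed anchors, or informative censoring (events are independent of
pain). A green end-to-end test therefore establishes the pipeline's internal
consistency and the estimator's frequentist calibration at the stated truth
— not agreement with the original study's data, which are not
redistributable.

## Numerical choices

* Quantiles are type-7 (R default); credible intervals are equal-tailed.
* The design matrix is checked for collinearity up front (SVD ratio
  < 1e−10) so the error names the problem before sampling.
* Costs must be strictly positive to enter the log model; a zero-cost
  patient is an input error identified by id.
* Full precision is kept internally; euros are rounded only in printed
  summaries.
* Seeds: every stochastic entry point takes an explicit seed; scenario
  seeds are `(master × 7919 + hash(name) × 104729) mod (2³¹ − 1)`.

## Known limitations

* The study's own dataset is not included, so published data-derived values
  (costs ratio 0.54, incremental effectiveness 28.15, dominance 99%) are
  recovery targets for the synthetic truth, not reproduced constants.
* Single-chain sampling with no gating diagnostics mirrors the source
  analysis; for other likelihoods this would be inadequate.
* The posterior for group-level euro costs depends on the retransformation
  convention; only the default convention is implemented as a euro-scale
  summary.
* XLSX ingestion is not provided (no reader among the package's
  dependencies); the ingestion path is delimited text with a `column_map`.
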