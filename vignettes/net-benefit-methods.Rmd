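---
title: "Net-benefit regression for household-survey cost-effectiveness analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Net-benefit regression for household-survey cost-effectiveness analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nbcea)
```

## The problem

Two rural health districts are compared on one binary outcome per
household — did the woman deliver in a health facility? — after one district
received a community-mobilisation package promoting skilled care. The
standard summary is the incremental cost-effectiveness ratio

$$\mathrm{ICER} = \frac{\Delta C}{\Delta E},$$

the extra societal cost per extra facility delivery. The ICER is a point
estimate with notoriously awkward sampling behaviour (a ratio whose
denominator can approach zero), it offers no natural way to adjust for
covariates, and a decision maker cannot read from it the probability that
the intervention is worth buying at a given willingness to pay.

The net-benefit framework linearises the problem. For a ceiling ratio
$R_o$ — the most a payer will spend for one extra facility delivery — each
household $i$ contributes a net benefit

$$NB_i = E_i \, R_o - C_i,$$

with $E_i \in \{0, 1\}$ the delivery indicator and $C_i$ the household's
societal-perspective cost. Ordinary least squares on the treatment dummy,

$$NB_i = \alpha + \delta\, SCI_i + \varepsilon_i,$$

gives $\hat\delta$ = the incremental net benefit at $R_o$, with a standard
error, a t statistic, and a p-value coming along for free. $\hat\delta > 0$
at a given $R_o$ is exactly the statement $\mathrm{ICER} < R_o$ (when
$\Delta E > 0$), so sweeping $R_o$ over a grid profiles the
cost-effectiveness decision across every willingness to pay, covariates can
enter the regression, and treatment-by-covariate interactions measure how
cost-effectiveness varies at the margin across subgroups.

## Cost attribution

Households report out-of-pocket costs only when they delivered in a
facility. The societal cost per household is constructed from two
components — the out-of-pocket cost and the incremental cost to the health
system of supporting the intervention (an external input, estimated by a
separate costing exercise):

| district | facility delivery | societal cost |
|---|---|---|
| intervention | yes | out-of-pocket + system incremental cost |
| intervention | no | system incremental cost |
| comparison | yes | out-of-pocket |
| comparison | no | 0 |

The system incremental cost is charged to *every* intervention-district
household because the programme (community mobilisation) reaches the whole
district, not only its users; the standard cost of care common to both
districts cancels from all increments and is never attributed. An
alternative mode charging it only to delivering households exists behind
`cost_config(attribute_to = "deliveries_only")` but is not the default.
Currency stays in CFA throughout; international dollars (167 CFA = I\$1
here) are a reporting-boundary conversion, integer-rounded half away from
zero.

## Treatment coding

`sci = 1` marks intervention-district households. With that coding the
constant of the simple model is the comparison-district mean net benefit
and $\hat\delta$ the incremental net benefit, so at $R_o = 0$ (net benefit
= minus cost) the pair $(\hat\alpha, \hat\delta)$ equals minus the
comparison mean cost and minus the cost increment. Published tables of this
analysis follow the same convention, and the sign of $\hat\delta$ carries
the cost-effectiveness verdict, so the coding is fixed rather than
configurable.

## From regression to acceptability curves

OLS p-values on $\hat\delta$ are two-sided, but the decision question is
one-sided — is the incremental net benefit positive? The curve therefore
uses the halving rule: for $\hat\delta < 0$ the probability the
intervention is cost-effective is $p/2$; for $\hat\delta \ge 0$ it is
$1 - p/2$. Plotting that probability against $R_o$ gives the
cost-effectiveness acceptability curve (CEAC). The curve crosses one half
where $\hat\delta$ changes sign, i.e. at the sample ICER, and the $R_o$
values where it crosses 0.025 and 0.975 bracket a 95% confidence interval
for the ICER — the package reads them off by linear interpolation
(`ci_from_ceac()`), with a refinement of the grid available when tighter
brackets are needed. We use the t distribution with $n - k$ degrees of
freedom for the p-values; at tens of thousands of households this is
indistinguishable from the normal, and no multiple-testing correction is
applied across the grid because the sweep profiles a single statistic
rather than testing a family of hypotheses.

`analytic_ceac()` is the closed-form counterpart built from arm-level
increments alone: $\,\mathrm{INB}(R_o) = \Delta E \, R_o - \Delta C$,
$\mathrm{se}(R_o) = \sqrt{R_o^2\,\mathrm{se}_E^2 + \mathrm{se}_C^2 - 2 R_o\,
\mathrm{cov}_{EC}}$, probability $\Phi(\mathrm{INB}/\mathrm{se})$. Two of
its defaults deserve comment.

* `se_c = 0`: when only district mean costs are published (no cost
  dispersion), the curve carries all uncertainty on the effect increment.
* `cov_ec = 0`: increments treated as independent. On household data this
  is an approximation — the societal cost *contains* the delivery cost, so
  effect and cost increments are positively correlated, and ignoring that
  overstates the net-benefit variance near the ICER. On cohorts of 20,000+
  households per arm we observe the independence default agreeing with the
  regression curve to about 0.03 probability at the worst grid point,
  while supplying the empirical covariance tightens the agreement to under
  0.002 (this is the package's own measurement, exercised in the test
  suite). The independence default is kept because it matches the
  information actually available from published tables.

With both standard errors zero the analytic curve degenerates into a step
function at the ICER (0 below, 1 above, one half at), and the CEAC interval
collapses onto the ICER.

On the cost-effectiveness plane, a zero effect increment with positive cost
increment is placed on the north-east boundary and the ICER flagged
undefined with a "no effect gain" status rather than reported as infinite;
the net-benefit regression remains well defined there, which is precisely
the framework's selling point.

## The synthetic cohort generator

No raw survey data are distributable, so the package ships a two-district
generator (`generator_config()`, `generate_cohort()`) used by every test
and example. It emulates:

* covariates — distance to the nearest facility (gamma, default shape 2,
  scale 3 km, so the 5-km near/far split is well populated on both sides),
  head-of-household education (Bernoulli, default 0.35 "some"), asset
  quintiles (uniform by default, optionally tilted by distance to induce
  the distance-asset collinearity the diagnostics are meant to catch);
* institutional delivery — a logistic model in arm, far-distance,
  education, linear asset quintile, and optional treatment-by-covariate
  interactions (the study-calibrated conditions use intercept
  $\mathrm{logit}(0.315)$ and arm effect
  $\mathrm{logit}(0.44)-\mathrm{logit}(0.315)$);
* out-of-pocket delivery costs — gamma, right-skewed and non-negative like
  out-of-pocket expenditure, arm-specific means 3,000/3,308 CFA and CV 0.5
  (the source tables publish no cost dispersion; the CV is a stated
  assumption, not a reproduced fact).

`mode = "exact"` replaces sampling with construction: each arm gets exactly
`round(n * p)` deliveries (assigned to the arm's first households) at the
arm's fixed mean cost, so district proportions and mean costs hit their
targets to machine precision. `calibrate_to_summaries()` inverts the cost
attribution to recover the system incremental cost from published district
means — with intervention societal mean 4,576 CFA, delivery proportion
0.44 and out-of-pocket mean 3,000 CFA it returns
$4{,}576 - 0.44 \times 3{,}000 = 3{,}256$ CFA — and checks the
comparison-district identity $1{,}042 \approx 0.315 \times 3{,}308$.
The `table1_exact` scenario packages this calibration at 10,000 households
per arm; at that size the deterministic regression column at $R_o = 0$
reproduces the published $(-1{,}042, -3{,}534)$ to the printed integer.
Note the exact cohort's effect increment is 12.5 percentage points where
the source prints 12.4 (their unrounded proportions are not published), so
ratio quantities derived from it sit within about half a percent of the
printed ones (ICER 28,272 vs 28,430 CFA).

Determinism: one integer master seed; each arm draws from a sub-seed
derived from it, so resizing one arm cannot reshuffle the other, and the
global RNG state is saved and restored around generation.

What passing tests on these cohorts do **not** show: robustness to
clustered sampling designs (villages), non-logistic delivery processes,
cost distributions with point masses or heavier tails than gamma, item
non-response beyond single missing costs, or measurement error in distance
— real survey data have all of these.

## Numerical and design choices

* Classical (homoskedastic) OLS standard errors by default — the published
  analysis is plain OLS — with HC1 robust errors behind
  `se_type = "robust"`. The net-benefit variance genuinely differs across
  arm-by-covariate cells (different delivery probabilities and cost
  means), yet with the cell sizes in play here both versions give
  interaction-CI coverage within Monte-Carlo noise of 95% (measured over
  500 replicates in the test suite).
* Rank deficiency in any design is an error naming the offending columns;
  an arm with zero effect variance is allowed (the regression is still
  defined).
* Variance inflation factors are computed as the diagonal of the inverse
  correlation matrix of the non-intercept design columns; constant columns
  get an undefined VIF and a flag instead of an error.
* A household exactly 5 km from the facility is "near": the far stratum is
  strictly greater than the threshold, fixed once here because published
  stratum labels are ambiguous about the boundary.
* Stratified ICERs hold the overall cost increment fixed across strata by
  default — matching the convention of publishing one district-level cost
  increment — with per-stratum increments behind
  `delta_c = "stratum"`.
* Missing out-of-pocket cost for a delivering household: strict mode
  errors naming the rows; lenient mode imputes the arm-specific mean among
  observed delivering households and warns. With no donor in the arm,
  lenient mode also errors.
* The default ceiling-ratio grid is 0-60,000 CFA in 1,000-CFA steps, wide
  enough to cover the published discussion range (up to about I\$360).

## Problem sizes used in validation

The deterministic calibration runs at 10,000 households per arm (the
printed district figures are scale-free, so arm size only sharpens the
standard errors); stochastic-moment checks use 50,000 households in one
arm; the regression-vs-analytic CEAC agreement uses 20,000 per arm; the
type-I-error and interaction-coverage studies use 500 replicates of 2,000
households per arm. These sizes were chosen so every Monte-Carlo band
(3 sampling SDs, or 2 binomial SEs on a coverage proportion) is narrow
enough to be informative.

## Known limitations

* Effects are binary and costs a single scalar; time costs, component
  itemisation, and continuous effects are out of scope.
* No clustered standard errors: the sampling structure of the emulated
  survey (household listing within villages) is not modelled, so SEs on
  real clustered data would be optimistic.
* The CEAC here is frequentist (p-value based); Bayesian acceptability
  curves from joint cost-effect posteriors, acceptability frontiers and
  value-of-information measures are deliberately not implemented.
* The adjusted-model fit statistics depend on covariate structure the
  source does not publish, so only the model mechanics — not any published
  adjusted R² — are reproduced.
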