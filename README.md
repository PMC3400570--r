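# nbcea

Net-benefit regression and cost-effectiveness acceptability curves for
two-arm health interventions observed through household surveys.

## The problem

A maternal-health programme (community mobilisation promoting skilled
care) runs in one rural district; a second district keeps the standard
package. Each surveyed household contributes a binary effect — did the
woman deliver in a health facility? — and a societal cost assembled from
out-of-pocket spending and the health system's incremental cost. The
traditional summary, the incremental cost-effectiveness ratio

```
ICER = ΔC / ΔE
```

(extra CFA per extra facility delivery), has no easy confidence interval,
no covariate adjustment, and no direct answer to "how likely is this to be
worth buying at willingness-to-pay Ro?".

The net-benefit framework answers all three with one regression. Each
household's effect is monetised at a ceiling ratio Ro:

```
NB_i = E_i * Ro - C_i
NB_i = α + δ·SCI_i + ε_i          (simple model)
NB_i = α + Σ β_j x_ij + δ·SCI_i (+ Σ γ_j SCI_i x_ij) + ε_i
```

OLS gives δ̂ — the incremental net benefit, positive exactly when
ICER < Ro — with full inference; sweeping Ro over a grid and halving the
two-sided p-values yields the cost-effectiveness acceptability curve
(CEAC), whose 0.025/0.975 crossings bracket a 95% CI for the ICER, and
treatment-by-covariate interactions (γ_j) show how cost-effectiveness
varies across subgroups such as households near vs far from a facility.

`nbcea` implements the whole pipeline: CSV household-table validation,
district-specific societal cost attribution, overall and stratified ICERs
with cost-effectiveness-plane classification, simple / adjusted /
interaction net-benefit regressions over a ceiling-ratio grid (classical
or HC1 SEs, collinearity diagnostics), regression-based and analytic
CEACs, CEAC-derived confidence intervals, a calibrated synthetic
two-district cohort generator, broom-style `tidy()`/`glance()` methods,
`autoplot()` graphics, and a one-call `run_pipeline()` with a CLI
front-end (`inst/scripts/nbcea.R`).

## Worked example

The built-in `table1_exact` scenario is a deterministic 10,000-household-
per-arm cohort calibrated to the district figures of the motivating study
(delivery proportions 44% vs 31.5%; societal mean costs 4,576 vs ~1,042
CFA; system incremental cost 3,256 CFA per intervention household).

```r
library(nbcea)

cfg    <- scenario_library("table1_exact")
cohort <- generate_cohort(cfg)
rows   <- build_analysis_rows(cohort, cost_config(cfg$system_incremental_cost))

icer_from_rows(rows)
#>   stratum delta_c delta_e delta_e_se icer_cfa icer_intl quadrant    ...
#> 1 <NA>      3534.   0.125    0.00680   28272.       169 NE-tradeoff ...
```

The intervention district spends 3,534 CFA more per household and delivers
12.5 percentage points more babies in facilities: 28,272 CFA (≈ I$169) per
additional facility delivery, in the north-east ("more effective, more
costly") quadrant of the cost-effectiveness plane.

```r
grid <- nb_regression_grid(rows, c(0, 15000, 25000, 35000))
nb_grid_table(grid)
#>   quantity         ro_0   ro_15000    ro_25000    ro_35000
#> 1 (Intercept) -1042.     3683.     6833.       9983.
#> 2 sci         -3534.    -1659.     -409.        841.
#> 3 F           27273.      424.        7.58       15.1
#> 4 adj_R2          0.577     0.0207    0.000329    0.000703
```

At Ro = 0 the net benefit is minus cost, so the constant is minus the
comparison-district mean cost (−1,042) and the treatment coefficient is
minus the cost increment (−3,534). δ̂ rises linearly in Ro and changes
sign between 25,000 and 35,000 CFA — the ICER lives there.

```r
curve <- ceac_curve(rows, seq(0, 60000, 1000))
ci_from_ceac(curve)
#>   level ro_low ro_high
#> 1  0.95 25714.  31401.

autoplot(curve)   # acceptability curve, 0.5 line at the ICER
```

A payer willing to spend less than ~25,700 CFA per extra facility delivery
can be 97.5% sure the programme is *not* cost-effective; above ~31,400 CFA,
97.5% sure it is.

## Layout

- `R/` — household table IO/validation, cost attribution, ICER +
  stratification, OLS net-benefit machinery, CEAC construction, generator,
  pipeline, plots
- `tests/testthat/` — unit, property and end-to-end acceptance suites
- `vignettes/net-benefit-methods.Rmd` — the model, its assumptions, and
  every numerical design choice
- `inst/scripts/nbcea.R` — `Rscript` CLI (`simulate`, `icer`, `regress`,
  `ceac`, `report`)
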