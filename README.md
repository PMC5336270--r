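# dietmix

Cost-effectiveness analysis of insect mass-rearing diets by constrained
three-component mixture experiments and response-surface modelling.

Mass-rearing facilities that produce sterile insects for area-wide pest
control (the sterile insect technique, SIT) spend a large share of their
budget on larval diet, and the protein source — inactive dried yeast — is
typically the most expensive ingredient. `dietmix` implements the full
statistical workflow for asking *how far can the expensive ingredient be
reduced without hurting the insects*: a constrained mixture design over
yeast, corn flour and corncob fractions; Scheffé polynomial response
surfaces for the biological responses (pupation, larval duration, pupal
weight, adult emergence); a linear ingredient-cost model; and an overlay
optimization that intersects confidence-limit criteria on every response
to find the *area of operability* and the maximum-savings blend. The
package ships the design space, blends, fitted coefficient surfaces and
cost anchors of the *Anastrepha ludens* (Mexican fruit fly) mass-rearing
diet study it reimplements, so the headline results can be recomputed
from scratch.

## The model

The three variable ingredients occupy a fixed 30.3% (by weight) of the
whole diet, constrained by 3% ≤ yeast ≤ 6%, 5.3% ≤ corn flour ≤ 8.3%,
19% ≤ corncob ≤ 22%. On the L-pseudocomponent scale

    z_i = (x_i − L_i) / (T − ΣL),   Σ z_i = 1,

the corner blends map to the unit vectors, so the linear coefficients of
any Scheffé polynomial

    E[y] = Σ_i β_i z_i + Σ_{i<j} β_ij z_i z_j + …  (no intercept)

are the predicted responses at the three corner blends. Models are fitted
by least squares over the ladder mean → linear → quadratic → special
cubic → cubic → special quartic → quartic, compared by sequential Type I
F tests, lack of fit against pure error, PRESS / predicted R², and
adequate precision, then simplified by hierarchical backward elimination.
Influence diagnostics (externally studentized residuals, Cook's distance,
DFFITS, DFBETAS, Box–Cox profiles) drive a capped outlier-exclusion
workflow. Ingredient cost is linear in the blend, so percent savings
relative to the standard blend is itself a Scheffé linear surface.

## Worked example

```r
library(dietmix)

# ingredient prices solved from the three published cost anchors
spec <- solve_unit_prices()
#> Cost spec: yeast 4.204/kg, cornflour 0.4437/kg, corncob 0.9569/kg ; 1730.29 t/yr (USD)

# published-coefficient surfaces + criteria + 0.01-point grid search
rep <- reproduce_study(step = 0.01)
rep$criteria
#> Optimization criteria:
#>   pupation      >= 0.7  (reference-CI)
#>   duration      <= 9.46  (reference-CI)
#>   pupal_weight  >= 16.39  (reference-CI)
#>   emergence     >= 0.8  (stated-limit)
rep$region
#> Area of operability: 1207 lattice blends
#>                 min   max
#> yeast_pct      5.27  6.00
#> cornflour_pct  5.30  6.03
#> corncob_pct   19.00 19.71
#> max savings 6.00% (47496.48/yr) at blend (5.27, 6.03, 19.00)
#> binding constraints: duration
```

Read: of the 45,451 candidate blends on the 0.01-percentage-point
lattice, 1,207 keep all four biological responses within the 95%
confidence limits predicted for the standard blend. Yeast can drop from
6% to 5.27% of the diet; the larval-duration constraint (≤ 9.46 days) is
what stops it falling further. The cheapest acceptable blend
(5.27 / 6.03 / 19.00) saves 6.0% of the standard mixture's ingredient
cost — US$27.45 per ton, US$47,496 per year at 1,730.29 t of diet.

The same machinery runs on raw data: `read_run_table()` loads a run-table
CSV, `run_pipeline()` performs selection → diagnostics/exclusion →
reduction → optimization end-to-end, and `simulate_runs()` /
`recovery_experiment()` generate seeded synthetic run tables from known
coefficient surfaces for validation.

## Layout

- `R/` — design space & pseudo-coding, Scheffé term sets and fitting,
  diagnostics, cost model, overlay optimizer, synthetic data, I/O.
- `tests/testthat/` — unit, property and reproduction tests (brute-force
  leave-one-out oracles for every influence statistic).
- `vignettes/diet-mixture-optimization.Rmd` — the methods vignette.
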