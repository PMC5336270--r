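---
title: "Mixture-design diet optimization: models, diagnostics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mixture-design diet optimization: models, diagnostics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dietmix)
```

## The problem and the model

A larval mass-rearing diet for *Anastrepha ludens* holds 69.7% of its
weight fixed (water, sugar, preservatives, gums) while three ingredients —
inactive dried yeast, corn flour and corncob fractions — share the
remaining 30.3%. Because the three proportions sum to a constant, their
effects are not separately estimable in an ordinary polynomial: the
natural model family is the Scheffé canonical form, an intercept-free
polynomial in the mixture proportions. `dietmix` works on the
L-pseudocomponent scale,

$$z_i = \frac{x_i - L_i}{T - \sum_j L_j},$$

with $L = (3, 5.3, 19)$ percent and $T = 30.3$ percent, which maps the
constrained design region onto the unit simplex. Two consequences drive
everything downstream: the three *corner blends* — (6, 5.3, 19), the
standard formulation; (3, 8.3, 19); (3, 5.3, 22) — become the pure
pseudo-components, and the linear coefficients of any fitted Scheffé model
equal the predicted responses at those corners. All blend arithmetic is in
percent of the whole diet, never fractions.

Assumptions inherited from the least-squares approach: responses have
(approximately) constant error variance on the modelling scale, and runs
are independent. Adult emergence, a proportion near its upper boundary,
is modelled after the arcsine square-root transform
$y' = \arcsin\sqrt{y}$ and back-transformed through $\sin^2(\cdot)$ after
clamping the linear predictor to $[0, \pi/2]$. Pupation, larval duration
(days) and pupal weight (mg) are modelled untransformed — a choice the
Box–Cox profile supports for these data scales. Proportions are modelled
by least squares, not by a binomial GLM, deliberately: the aim is to
reproduce the response-surface workflow, and the variance distortion at
cohort size 25 is mild.

## The model ladder and its statistics

Model orders are fitted in the fixed sequence mean, linear, quadratic,
special cubic (adds $ABC$), cubic (adds the difference terms
$AB(A{-}B)$ etc.), special quartic (quadratic base plus $A^2BC$, $AB^2C$,
$ABC^2$), and full quartic (15 terms). Each order is judged by the Type I
sequential F test of its sum-of-squares increment *over its nested base
model*. One subtlety is worth stating: on the simplex the special
quartic's span does not contain the cubic difference terms, so an
increment "over the previous order" can be negative. The package
therefore measures the special quartic against the quadratic (its actual
base) and every other step against the preceding order; the telescoping
conservation of Type I sums of squares then holds exactly along the
nested chain, and the test-suite asserts it.

Model sums of squares are corrected by the mean; since the linear blend
terms absorb the implicit intercept, a $p$-term Scheffé model has
$p - 1$ model degrees of freedom (a 3-term linear model on 40 runs gives
$F_{2,37}$). Per-term Type III tests refit without one column at a time;
the three linear terms are tested jointly as the 2-df "linear mixture"
contrast against the intercept-only span.

The remaining statistic family follows the standard definitions. Lack of
fit pools pure error within groups of runs with identical blends
(proportions matched at 4 decimals, which is robust to CSV round-trips)
and contrasts the residual remainder against it. PRESS uses the
hat-matrix identity $\sum_i (e_i/(1-h_{ii}))^2$, which the tests verify
against literal leave-one-out refits; predicted $R^2$ is
$1 - \mathrm{PRESS}/SS_\text{total}$. Adequate precision is the
fitted-value range over $\sqrt{p\hat\sigma^2/n}$, with values above 4
conventionally deemed adequate for prediction.

Model choice encodes the study's qualitative criteria as a documented
rule: aliased (rank-deficient) orders are discarded; among orders whose
sequential step is significant at $\alpha = 0.05$, those with a
non-significant lack of fit are preferred; the highest qualifying order
wins; and a gap above 0.2 between adjusted and predicted $R^2$ raises a
reliability warning rather than a rejection. Like any
highest-significant-step rule it keeps a roughly 5% chance of upgrading
one order past the generating model on pure noise — the tests therefore
check rule-consistency against the recorded ladder table, not truth
recovery. Backward elimination then removes, one at a time, the
removable term with the largest Type III $p \ge \alpha$; linear terms are
never removed, and a term is removable only when no retained higher-order
term contains it (so $AB$ survives while $AB^2C$ is in the model).

## Influence diagnostics and exclusion

All leave-one-out statistics use their closed forms — internally and
externally studentized residuals, Cook's distance, DFFITS, and DFBETAS
from the rank-one downdate — and each is tested to $10^{-8}$ against a
brute-force oracle that actually refits without each run. Flag
thresholds are conventional and configurable: $|t_i| > 3$ (outlier),
Cook's $D > 1$, $|\mathrm{DFFITS}| > 2\sqrt{p/n}$,
$|\mathrm{DFBETAS}| > 2/\sqrt{n}$ (influence). A run becomes an
*exclusion candidate* only when the outlier rule fires together with at
least one influence rule — exclusion should require both an aberrant
value and leverage on the conclusions. The workflow removes the single
worst candidate, refits, and stops at a configurable cap defaulting to
one exclusion per response; wholesale trimming is not what the procedure
is for. When a fit interpolates exactly (residual scale below
$10^{-10}$ of the response scale) all statistics are reported as zero
rather than as ratios of rounding noise.

The Box–Cox profile is computed directly from the geometric-mean-scaled
transform, $\ell(\lambda) = -\tfrac n2\log(\mathrm{RSS}(\lambda)/n)$,
over a default grid $\lambda \in [-3, 3]$ in steps of 0.1, with the 95%
region cut at $\chi^2_1/2$ below the maximum; "no transform" is
recommended whenever $\lambda = 1$ lies inside it. The test-suite
cross-checks the profile shape against `MASS::boxcox` as an independent
oracle.

## The cost model and anchor inversion

A ton of finished diet contains $10\,x_i$ kg of ingredient $i$, so the
costed part is $\text{cost/ton} = 1000\sum_i (x_i/100)\,p_i$ over the
three variable ingredients only — the fixed 69.7% cancels out of every
comparison, which is exactly the scope of the study's savings
definition. Cost is affine in the blend, so percent savings relative to
the standard blend is itself a linear Scheffé surface whose corner values
are 0.00, 24.65 and 21.29 percent.

Per-kg prices are not printed in the publication text; three published
figures pin them down instead: the standard blend's annual ingredient
cost (US\$791,716), the high-corn-flour corner's annual cost
(US\$596,525), and the high-corncob corner's saving (21.29%), all at
1,730.29 t/yr. Because the three corner blends are affinely independent,
these anchors give a nonsingular 3×3 linear system whose solution —
4.204, 0.444, 0.957 \$/kg for yeast, corn flour and corncob — reproduces
all three anchors to rounding. That the implied corncob price exceeds
the corn-flour price is a property of the printed anchors; the package
reports it as-is. User-supplied prices take precedence over
anchor-derived ones when available.

## Overlay optimization

Acceptance criteria are one-sided: each "keep it high" response
(pupation, pupal weight, emergence) must stay at or above the *lower*
95% confidence limit predicted for the standard blend, and larval
duration at or below the *upper* limit. The one-sided reading is what
reproduces the study's stated limits (0.70, 16.39 mg, 0.80, 9.46 days);
since the standard blend is a corner, those limits are the confidence
bounds of the linear yeast term. The packaged emergence limit is the
stated 0.80: the published proportion-scale interval for that term is
degenerate (a lower bound of 0), an artifact of back-transforming
interval endpoints near the boundary. Emergence feasibility may be
evaluated on either scale — the clamped $\sin^2$ back-transform is
monotone, so comparing back-transformed predictions against 0.80 is
equivalent to comparing transformed predictions against
$\arcsin\sqrt{0.80}$.

Candidate blends are enumerated on an exact integer lattice (default
step 0.01 percentage points, ≈ 45,000 points, well under a second): the
first two components step over their bounds, the third is the simplex
complement, and out-of-bounds points are dropped. The area of
operability is the subset satisfying every criterion simultaneously; an
empty region is a legal, flagged outcome. The optimum is the feasible
blend with maximal percent savings, ties broken deterministically
(lowest yeast, then highest corn flour), and component ranges are
reported rounded to 2 decimals. Exhaustive search was chosen over
desirability indices or gradient methods because it formalizes the
graphical overlay exactly and the lattice is small.

With the packaged surfaces, prices and criteria the region spans
yeast 5.27–6.00, corn flour 5.30–6.03, corncob 19.00–19.71, and the
optimum (5.27, 6.03, 19.00) saves 6.0% — US\$27.45/ton, US\$47,496/yr —
with the duration constraint active at the corncob floor. The published
lower-yeast and upper-corn-flour bounds (5.27, 6.03) and the corncob
ceiling (19.71) are reproduced exactly; the published yeast ceiling
(5.88) is not reproducible from the four stated criteria — the standard
vertex itself satisfies them all, so the computed region reaches 6.00.
The package reports its computed bounds and the binding constraints
rather than forcing agreement.

## The synthetic-data generator

`simulate_runs()` emulates the structure of the experiment's raw run
table: 40 runs over the 19 design blends (corners ×4, twelve further
blends ×2 by default — the exact published allocation is not in the
paper text, so the plan is configurable; any plan with 19 distinct
blends and 40 runs leaves the same 21 pure-error df), cohorts of 25
larvae, responses drawn from configurable truth surfaces defaulting to
the published coefficient sets. Pupation is binomial per cohort;
emergence is binomial with the *simulated pupal count* as denominator
(emergence is defined per pupa recovered); duration and weight are
Gaussian with sds 0.45 d and 1.6 mg — the publication prints no residual
standard deviations, so these were chosen once to put simulated $R^2$
in the 0.3–0.8 band the study reports, and are not revisited. Truth
probabilities are clamped to [0.001, 0.999] before sampling.

What passing tests on this generator do *not* show: real larval cohorts
share a dish, so binomial independence is optimistic; density effects,
metabolic heat and between-batch variation are not simulated; and the
emergence pathway has a known small-sample bias — with ~16–21 pupae,
$E[\arcsin\sqrt{\hat p}] \ne \arcsin\sqrt{p}$, substantially so near
$p = 0.99$ — so the strict unbiasedness-and-coverage calibration in the
test-suite applies to pupation, duration and pupal weight, while
emergence carries an RMSE sanity bound instead. Coverage checks use 200
seeded replicates; the Monte-Carlo error of a coverage estimate at that
size is about ±1.5 percentage points, which sets the asserted bands.

## Numerical choices and degenerate inputs

Simplex and mixture-total checks use a $10^{-9}$ tolerance; pseudo-coding
round-trips are exact to $10^{-12}$. Lattice blends are built in integer
arithmetic at $10^{-4}$ resolution so every grid blend sums to the
mixture total exactly. Leverage-1 points refuse PRESS (a saturated point
cannot be cross-validated). Pure error of zero with zero lack-of-fit SS
reports $F = 0$; with positive lack-of-fit SS it reports $F = \infty$.
Rank deficiency is an explicit "aliased" error everywhere, and a
missing response drops a run from that response's fit only.

## Known limitations

Three components only (the algebra generalizes; the lattice and
reporting do not yet). No binomial GLMs, no Type II sums of squares, no
mixed models, no desirability optimization, no uncertainty band on the
region boundary. Back-transformed *coefficients* of the emergence model
are display-only (signed $\sin^2$ magnitude); predictions are always
formed on the transformed scale because back-transformation does not
commute with the model sum.
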