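---
title: "Methods: a stationary life-table cost-benefit analysis of red deer management"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a stationary life-table cost-benefit analysis of red deer management}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(deerCBA)
```

## The demographic model and its assumptions

deerCBA models a managed red deer population as a *stationary* sex- and
age-structured life table with 25 September-age classes per sex. The
model assumes a steady-state equilibrium — births equal deaths every
year, the age structure is constant — with no emigration, immigration,
density dependence or demographic stochasticity. These assumptions are
defensible for a heavily managed Danish population held well below
carrying capacity, where essentially all mortality is human-caused, and
they make every derived quantity an exact closed form.

Mortality combines management and traffic. Each strategy states annual
*hunting* mortality rates by sex and age band; an all-class baseline of
0.02 per year covers vehicle collisions (every collision is assumed
lethal, and the collision rate stands in for all non-hunting mortality).
The two are combined with a **floor convention**:

$$q_x = \max(\text{hunting}_x,\ 0.02)$$

rather than additively or by compounding survival. The floor is the only
combination consistent with the male survivorship figures the strategies
are calibrated to (56% of trophy-hunted males reaching age 8 requires
$0.65 \times 0.98^7$, i.e. a flat 0.02 for the protected ages) and with
the verified population anchor cells. Deaths then partition exactly:
collision deaths $n_x \cdot 0.02$, harvest $n_x(q_x - 0.02)$.

**Recruitment closure.** The package does *not* close the loop through
the fecundity schedule. The stated fecundities (0.57 for yearling hinds,
0.82 for hinds 2+, sex ratio 0.5 at birth) do not place every strategy's
net reproduction at exactly 1, so a literal birth-equals-recruitment
model would have no stationary solution at the stated rates. Instead the
life table is treated as a pure stationary cohort model: per-sex
recruitment $n_0$ is a free scale fixed by the census constraint, and
fecundity enters only the September (pre-season) census,
$N_{Sept} = N_{Spring} + \sum_x n_{x,f} m_x$.

**Census convention.** The spring census counts ages 1–24 over both
sexes and is scaled to 1000 individuals; calves are reported separately
as recruits. Holding the spring census fixed across strategies makes the
analysis one of population *composition*, not size.

**Terminal age.** Survivors of age 24 are counted as deaths (harvest
plus collisions) in their final year, i.e. the accounting mortality at
the terminal age is 1. The affected mass is below $10^{-4}$ of
recruitment under every built-in strategy, and the convention buys exact
conservation: per sex, recruits equal total deaths to $10^{-9}$
(relative), which the tests assert on a thousand random schedules.

## Strategies and derived rates

Five strategies ship with the package (`builtin_strategies()`). Most
band rates are taken directly from the published strategy descriptions;
three cells are *derived* and tagged as such in the resolved schedules:

* **Strategy 1 male yearlings (0.35)** — the free-harvest text states no
  yearling rate; 0.35 (the same as the next band) reproduces the ~1%
  survivorship to age 8 and the verified male column.
* **Strategy 1 male age break** — the stated "0.35 at ages 2–3, 0.50 at
  4+" only reproduces the verified young-stag (172), near-mature (25)
  and mature-stag (4) cells when applied at September ages 1–2 / 3+.
  The default uses the shifted reading;
  `builtin_strategies(strategy1_ages = "literal")` keeps the literal
  one. The discrepancy looks like a years-of-life vs years-old labelling
  slip in the source; both readings are preserved rather than guessed
  away.
* **Strategy 4.B male yearlings (0.20)** — unstated; 0.20 (the 2–7 band
  rate) is the only value consistent with the documented 10.5%
  survivorship ($0.5 \times 0.8^7$).

Strategy 3 is a known inconsistency in the source material: the stated
0.50 rate for males 8+ is irreconcilable with the published mature-stag
population (50) and harvest (16) for that strategy (they imply a rate
near 0.34). The package implements the stated rate and reports its own
arithmetic (≈34 mature stags); the packaged reference table flags the
strategy-3 column as unverified, and no test forces a match.

A polygyny feasibility check (`check_sex_ratio()`) warns — deliberately
does not error — when mature stags fall below one per 20 females aged
1+, since conception, not valuation, is what the constraint protects.
Under the engine's arithmetic strategies 1 and 3 trip the warning at the
benchmark.

## Valuation

The annual net benefit is linear in harvest and population by class:
meat value $m w_i h_i$ and recreational value $r_i h_i$ accrue to the
harvest; browsing cost $b_i n_i$ and traffic cost $\alpha t_i n_i$
accrue to the standing population. Constant marginal values are a
deliberate simplification — they favour strategies with extreme
compositions, which is part of why maximum harvest dominates. The
benchmark parameter set (`benchmark_valuation()`) is fixed to producer
prices in 2022 DKK; `normalize_price()` (default VAT 25%, the Danish
standard rate) and `allocate_by_weight()` (damage costs scale linearly
with body size) are provided for users bringing their own raw prices.
Trophy value is not a separate term: it is embodied in the large
recreational values of the stag classes. The traffic group is varied and
interpreted as the product $\alpha t_i$ throughout, since only the
product enters NB.

Decision rules: implement the argmax strategy if its NB is positive;
ties are reported as indifference; if every NB is negative the
zero-population alternative (NB = 0) dominates, so the recommendation is
to drive the population toward extinction; an NB of exactly zero is
indifferent to extinction.

## Sensitivity analysis

All four parameter groups (meat values, recreational values, browsing
costs, traffic costs) are varied one group at a time by ±50%, all
classes simultaneously, preserving the published ranking of values
across classes. Because NB is exactly linear in each group, every bound
is $NB \pm f \cdot \text{total}_g$; `sensitivity_table()` computes this
identity and also offers a full-revaluation path
(`method = "recompute"`), and the two agree to $10^{-9}$ on random
scenarios — a genuine dual-route check, not the same code twice. Upper
and lower bounds are symmetric about the benchmark by construction.

Two published sensitivity rows (trophy hunting and maximum harvest)
deviate from the linearity identity by roughly 1,300–9,500 DKK and
cannot be reproduced from their own published benchmarks; the packaged
reference table records them as printed, and the identity-based tests
anchor only on the internally consistent rows.

## Known discrepancies in the reference tables

The packaged reference tables (`reference_tables()`) transcribe the
published results with per-cell verification flags, and three internal
inconsistencies are recorded in the `notes` attribute rather than
patched:

* the maximum-harvest value components sum to 298,684 DKK, not the
  published total of 296,684 — the package reproduces its own exact sum
  and flags the difference;
* the strategy-4.B components sum to one DKK below the published total
  (half-unit rounding);
* the published harvest cells are inconsistent with the published
  population cells under any single mortality convention. The engine's
  population-proportional cost totals match the published values *to the
  DKK* for the four verifiable strategies, while harvest-proportional
  value totals differ by 1–3% (e.g. the published adult-female harvest
  of 100 under free harvest versus the model's 96). Engine output is
  therefore its own arithmetic; published totals are used as data inputs
  where published anchors are asserted.

## The synthetic-scenario generator

`scenario_spec()` / `random_strategy()` / `random_valuation()` generate
test scenarios, not ecology: band-wise uniform hunting rates within
bounds spanning the built-in strategies, and independent multiplicative
perturbations (default dispersion 1.5, i.e. factors in [2/3, 3/2]) of
every benchmark valuation entry. Draws are deterministic given the seed
and leave the session RNG untouched. The generator exercises the
pipeline's invariants — resolvability, positive spring census,
conservation, exact partition, linearity — over the whole plausible rate
space. It does **not** emulate hunter behaviour, bag-data noise,
correlated valuation errors, density dependence or environmental
stochasticity, so green property tests certify the *arithmetic*, not the
realism, of any particular scenario.

## Numerical choices

* Conservation and the census constraint are asserted at $10^{-9}$
  (relative); the projection-vs-closed-form equivalence at $10^{-6}$ —
  with a zero initial structure the projection is exact after 25 years
  (one full generation), so the tolerance only absorbs floating-point
  noise.
* Degenerate schedules (no survival past age 0) raise an error when a
  census target is requested, since no positive spring population
  exists.
* Harvest is floored at zero so a hunting rate below the collision
  baseline can never produce negative harvest.
* Reports round populations and harvests to whole individuals and money
  to whole DKK; JSON summaries carry full precision. No rounding occurs
  inside the computation.
* Property sweeps use 200 scenario seeds in the module tests and 1000
  in the end-to-end suite, with a 50-seed sweep for the dual-route
  sensitivity check — sizes at which the closed-form engine completes in
  seconds while covering the rate space densely.

## Limitations

Beyond the generator's scope above: the model is static (no adjustment
paths, hence no discounting — rankings by annual NB transfer to present
values under stationarity); marginal values and costs are constant;
browsing damage covers agricultural crops only, not forestry; the
recreational term covers hunters only, excluding wildlife-watching and
existence values; and the cull-based estimator `N = C L \lambda / \eta`
inherits the biases of bag statistics (reporting rates, the longevity
transfer between regions). The published regional population figures
(10,527 post-season; 14,144 pre-season) differ slightly from the stated
formula's output (10,522; 14,134 with the cull added back); the
estimator reports the formula value and the difference is documented
rather than reverse-engineered.
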