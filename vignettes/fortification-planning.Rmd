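---
title: "Planning vitamin D food fortification: simulation and formula models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Planning vitamin D food fortification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fortisim)
```

## The problem

Population-wide vitamin D deficiency is usually addressed by fortifying
staple foods. The planning question is a constrained one: add enough
vitamin D that most of the population reaches the recommended intake (RI),
but never so much that any high consumer exceeds the tolerable upper intake
level (UL). fortisim implements two complementary ways of answering it:

1. **A per-individual simulation.** Given each person's daily grams of a
   set of candidate vehicles (breads, milks, yogurt, doogh, cheese,
   butter), a fortification plan assigning `L_v` micrograms per 100 g to
   vehicle `v` contributes

   `added_i = (1/100) * sum_v grams_iv * L_v`  [ug/day]

   to person `i` (the division by 100 converts grams to 100-g meals).
   Total intake adds the person's baseline dietary vitamin D and,
   optionally, a scenario-level supplement dose (40 IU = 1 ug). An
   exhaustive grid search over discrete levels (default 1-4 ug/100 g)
   discards any plan under which *one or more* individuals would exceed the
   UL, and among the safe plans returns the one minimizing the fraction of
   people outside the closed interval [RI, UL].

2. **The Flynn (ILSI) and Rasmussen (DFVR) safe-addition formulas.** These
   work on population summary statistics in IOM-RDA units (intakes divided
   by the RDA, 20 ug/day):

   `FA_Flynn = (UL - CI95) / (fortified_fraction * portions * PFF)`
   `FA_Rasmussen = (UL - (CI95 + SI)) / (EI95 * PFF)`

   where CI95 is the 95th-percentile current intake, SI the supplement
   intake (only Rasmussen subtracts it — Flynn by definition considers
   naturally occurring dietary sources only), EI95 the 95th-percentile
   energy intake in 100-kcal portions, and PFF the proportion of marketable
   foods that can be fortified. FA is the safe addition per 100-kcal food
   portion.

## Default parameters and where they come from

| parameter | default | unit | rationale |
|---|---|---|---|
| UL (IOM preset) | 100 | ug/day | IOM tolerable upper level; 5 IOM-RDA units |
| RI (IOM preset) | 10 | ug/day | lower bound of the adequate-intake range |
| RDA | 20 | ug/day | IOM reference used for unit conversion |
| UL / RI ("paper-methods" preset) | 250 / 40 | ug/day | alternative threshold set quoted for the simulation; the preset is always an explicit choice |
| CI95 | 0.05 | IOM-RDA | 1 ug/day at RDA 20 |
| portions | 42 | 100-kcal/day | 4200 kcal/day at the 95th energy percentile |
| fortified_fraction | 0.5 | — | half of daily portions assumed fortifiable |
| EI95 | 18.8 | 100-kcal/day | observed 95th-percentile energy in portions |
| PFF | 0.11 | — | 8 fortifiable foods of 70 (not 0.10: the table generator takes explicit PFF values, never derives them from column labels) |
| grid levels | 1, 2, 3, 4 | ug/100 g | the discrete range searched |
| IU per ug | 40 | — | fixed biological constant |

Note that `portions = 42` and `EI95 = 18.8` are mutually inconsistent as
statements about the same 95th energy percentile; both are carried as
independent configuration constants because each formula is defined with
its own denominator.

Worked values the package reproduces (also pinned in the test suite):

```{r formulas}
fi <- formula_inputs(ul = 5, ci95 = 0.05, pff = 0.11)
margin_of_addition(5, 0.05)        # 4.95 IOM RDAs of headroom
flynn_fa(fi)                       # 4.95 / 2.31 = 2.1428...
round_half_up(flynn_fa(fi), 2)     # 2.14
safe_addition_table(c(1, 0.5, 0.25, 0.11, 0.05))
```

## The synthetic population generator

No individual-level dietary data ship with the package, so analyses run on
a seeded synthetic population that emulates the summary structure the
method assumes: strictly positive, right-skewed intake quantities drawn
from independent log-normals — the standard family in dietary-exposure
modelling.

* **Baseline vitamin D**: log-normal solved to a target arithmetic mean
  (default 4 ug/day, the population average the analysis starts from),
  with log-scale sd 0.5.
* **Energy**: log-normal solved so that both the mean (2000 kcal/day) and
  the 95th percentile (4200 kcal/day) match their targets; the quadratic
  `s^2/2 - z*s + log(p95/mean) = 0` is solved for the log-sd, taking the
  smaller root (the larger would put the median above the mean). The pair
  must satisfy `p95/mean < exp(z95^2/2) ~ 3.87` or the constructor errors.
* **Vehicle grams**: per-vehicle log-normals parameterised by median
  grams/day. The medians (e.g. 150 g whole bread, 80 g milk, 10 g butter)
  are plausible staple amounts for the region chosen once as configuration
  defaults — no per-vehicle consumption distributions are published — with
  a common log-sd of 0.6.
* **Supplement**: a scenario constant (0, 400 or 1000 IU/day) applied to
  everyone; per-person supplement prevalence is out of scope.
* **Age and sex**: uniform 35-65 years, balanced sex, matching the adult
  cohort frame; neither currently influences intake draws.

What the generator does *not* emulate: correlations between vehicles
(independent by default; a shared "appetite" multiplier would be the
natural extension), energy-consumption coupling, seasonality, age/sex
intake gradients, or FFQ measurement error. Tests passing on this
population show the machinery is correct and calibrated, not that the
synthetic marginals match any real cohort beyond the stated summaries.

A note on one published inconsistency: a 95th-percentile current intake of
1 ug/day cannot coexist with a mean of 4 ug/day (a percentile below the
mean of a positive distribution at that rank is impossible). The generator
therefore calibrates to the mean, and the formula module takes CI95 as a
direct input so the published arithmetic reproduces regardless.

## Design choices in the optimizer

* **Interval convention.** "Outside the RI-UL range" is the complement of
  the *closed* interval; boundary values count as within.
* **Strict UL constraint.** A plan is infeasible if a single individual
  exceeds the UL — toxicity of even one person invalidates a plan. Plans
  are evaluated exhaustively (the full per-vehicle grid is 4^8 = 65,536
  plans, trivially tractable; uniform search, the default, evaluates 4).
* **Supplement handling.** The UL feasibility check applies the supplement
  scenario — safety must hold for supplement users, the worst case — while
  the coverage objective defaults to dietary intake alone
  (`coverage_scenario`), since deficiency coverage is a property of the
  diet the fortification actually changes. The two can be coupled by
  passing the same scenario to both arguments. This separation is what
  makes "supplement consumption barely affects the optimal level" a
  testable statement rather than a tautology.
* **Tie-breaking.** Equal objectives resolve to the smallest total added
  ug, then enumeration order: the cheapest equally-performing plan wins.
* **Degenerate inputs.** An empty population errors; a grid with no
  feasible plan returns a diagnostic result (`no_feasible = TRUE`)
  carrying the least-violating plan instead of raising.

## The calibrated recovery fixture

`calibrated_fixture_population()` builds the population for the
parameter-recovery experiment (n = 2000, seed 42 by default): generate
under the default calibration, then rescale everyone's vehicle grams by
one common factor `s = min_i (0.99*UL - supp - b_i) / (0.03 * G_i)` so the
heaviest consumer's intake at a uniform 3 ug/100 g plus a 1000 IU/day
supplement sits at 99% of the IOM UL. By construction level 4 then pushes
that consumer over the UL while level 3 stays safe, and because the
below-RI fraction falls strictly with the level on this population, the
optimizer must recover 3 ug/100 g — which the acceptance test verifies by
running the search:

```{r recovery, eval = FALSE}
pop <- calibrated_fixture_population(n = 2000, seed = 42)
optimize_plan(pop, grid_spec(1:4), threshold_preset("iom"),
              scenario = supplement_scenario(1000))
```

This is a reconstruction of the experiment's logic on synthetic data, not
a replication of cohort numbers (which are not deposited).

## Numerical and rounding conventions

* Table values are stored at full precision; display rounding is
  round-half-up (`round_half_up()`), since base `round()` rounds half to
  even. One published table cell (23 at 100% fortifiability) computes to
  23.57 under the stated formula; the regression tests pin the computed
  value and the discrepancy is treated as an upstream rounding artifact.
  Likewise the published Rasmussen cells at 10%/5% fortifiability (210,
  478) and the 1000 IU row (175) are not reproducible from the stated
  formula under any consistent input choice; the formulas are implemented
  as printed and those cells are not reverse-engineered.
* The basket comparison defaults to the published two-decimal
  100-kcal-portion multipliers (0.37, ..., 9), reproducing the printed
  energy-method total of 28.7 ug exactly; `use_printed_multipliers =
  FALSE` switches to full-precision energy densities (28.77 ug). The bread
  energy density of 37.5 kcal/100 g is implausibly low but is shipped
  verbatim as the reference fixture.
* The coverage partition is exact at the level of counts
  (`n_below + n_within + n_above = n`); fractions share that denominator.
* "20 IU equivalent to 800 ug/day" in the source material is treated as a
  typographic inversion of 20 ug = 800 IU; the conversion is fixed at
  40 IU/ug throughout.

## Problem sizes

The shipped analyses are desk-scale by design: populations of 2,000 for
the recovery experiment and 10,000 for calibration checks, uniform grids
of 4 plans and full grids of 65,536, all running in seconds on one CPU.
Larger populations only tighten the sampling bands; nothing in the method
scales worse than `n_individuals x n_plans`.

## Limitations

Beyond the generator simplifications above: bioavailability, cooking
losses and overage of the added vitamin are not modelled; serum 25(OH)D
response is out of scope (this is an intake model); infants and children
are absent from the population frame; and the optimizer treats vehicles'
consumption as fixed under fortification (no behavioural response).
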