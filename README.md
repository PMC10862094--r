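# fortisim

Planning tools for vitamin D food fortification, for nutrition scientists
and public-health modellers deciding **how much vitamin D to add to staple
foods**: enough that most of an adult population reaches the recommended
intake (RI), never so much that any high consumer exceeds the tolerable
upper intake level (UL).

Two complementary approaches are implemented and can be compared on the
same inputs:

* **Per-individual simulation.** A fortification plan assigns each vehicle
  `v` (breads, milks, yogurt, doogh, cheese, butter) a level `L_v` in
  μg/100 g; person `i` receives

  ```
  added_i = (1/100) · Σ_v grams_iv · L_v        [μg/day]
  total_i = baseline_i + added_i + supplement    (40 IU = 1 μg)
  ```

  An exhaustive grid search over discrete levels (default 1–4 μg/100 g)
  discards any plan under which **even one** individual would exceed the
  UL, and among the safe plans minimizes the fraction of people outside
  the closed interval [RI, UL].

* **Safe-addition formulas** (per 100-kcal food portion, intakes in
  IOM-RDA units, RDA = 20 μg/day):

  ```
  FA_Flynn     = (UL − CI95) / (0.5 · 42 · PFF)          # ILSI
  FA_Rasmussen = (UL − (CI95 + SI)) / (EI95 · PFF)       # DFVR
  ```

  with CI95 the 95th-percentile current intake, SI the supplement intake
  (Flynn ignores it by definition), EI95 the 95th-percentile energy intake
  in 100-kcal portions, and PFF the proportion of foods that can be
  fortified (0.11 for 8 vehicles out of 70 foods).

A seeded synthetic population generator (log-normal intakes solved from
target means/percentiles: mean baseline 4 μg/day, 95th-percentile energy
4200 kcal/day) stands in for cohort data, which are not deposited. See the
methods vignette (`vignettes/fortification-planning.Rmd`) for the model,
assumptions and design choices.

## Worked example

```r
library(fortisim)

# Safe addition by the ILSI formula: UL = 5 IOM RDAs (100 μg), CI95 = 0.05
# (1 μg), 42 daily 100-kcal portions, half fortifiable, PFF = 0.11
fi <- formula_inputs(ul = 5, ci95 = 0.05, pff = 0.11)
round_half_up(flynn_fa(fi), 2)
#> [1] 2.14

safe_addition_table(c(1, 0.5, 0.25, 0.11, 0.05))
#>   model si  pff fa_rda_units fa_percent_rda fa_ug_per_100kcal
#> 1 flynn  0 1.00       0.2357          23.57             4.714
#> 2 flynn  0 0.50       0.4714          47.14             9.429
#> 3 flynn  0 0.25       0.9429          94.29            18.857
#> 4 flynn  0 0.11       2.1429         214.29            42.857
#> 5 flynn  0 0.05       4.7143         471.43            94.286
```

2.14 IOM-RDA units per 100-kcal portion — about **2.1 μg per 100 kcal** —
is the most vitamin D that can be added to each fortifiable 100-kcal
portion without the highest consumers exceeding the UL when 8 of 70 foods
are fortified; the table shows how that ceiling tightens as more of the
food supply is fortified (columns: IOM-RDA units, % of RDA, μg).

The simulation route, on the calibrated synthetic population (2,000
individuals, 1000 IU/day supplement scenario guarding the UL check):

```r
pop <- calibrated_fixture_population(n = 2000, seed = 42)
optimize_plan(pop, grid_spec(1:4), threshold_preset("iom"),
              scenario = supplement_scenario(1000))
#> best plan (of 4 evaluated, 3 feasible):
#>       butter       cheese        doogh low_fat_milk  white_bread  whole_bread
#>            3            3            3            3            3            3
#>   whole_milk       yogurt
#>            3            3
#> objective (frac outside RI-UL): 0.0000
```

A uniform **3 μg/100 g** is recovered: 4 μg/100 g would push the heaviest
consumer over the UL (only 3 of the 4 uniform plans are feasible), and 3
covers the population better than 1 or 2. Fortifying a reference basket of
100 g of each vehicle then delivers 24 μg by the per-mass method versus
28.7 μg by the per-energy (2.1 μg/100 kcal) method:

```r
cmp <- compare_fortification_methods(reference_basket(), 3, 2.1)
c(cmp$total_method1_ug, cmp$total_method2_ug)
#> [1] 24.000 28.749
```

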