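test_that("added vitamin D follows the grams x level / 100 summation", {
  pop <- tibble::tibble(grams_milk = 200, grams_bread = 100)
  plan <- fortification_plan(c(milk = 3, bread = 2))
  expect_equal(added_vitamin_d(pop, plan), 8)

  # all-zero plan contributes nothing
  expect_equal(added_vitamin_d(pop, fortification_plan(c(milk = 0))), 0)

  # 100 g of each of 8 vehicles at a uniform 3 ug/100 g gives 24 ug
  pop8 <- tibble::as_tibble(as.list(setNames(
    rep(100, 8), paste0("grams_", default_vehicles()$name))))
  expect_equal(added_vitamin_d(pop8, uniform_plan(3)), 24)

  # plan vehicles missing from the record contribute 0 g
  expect_equal(added_vitamin_d(pop, fortification_plan(c(kefir = 4))), 0)
})

test_that("summation matches an independent double-loop oracle", {
  set.seed(301)
  for (rep in 1:10) {
    nveh <- sample(1:6, 1)
    veh <- paste0("v", seq_len(nveh))
    n <- sample(1:12, 1)
    pop <- tibble::as_tibble(
      setNames(replicate(nveh, runif(n, 0, 500), simplify = FALSE),
               paste0("grams_", veh)))
    levels <- setNames(runif(nveh, 0, 4), veh)
    plan <- fortification_plan(levels)
    expect_equal(added_vitamin_d(pop, plan),
                 oracle_added_vitd(pop, levels), tolerance = 1e-12)
  }
})

test_that("added vitamin D is linear in levels and grams", {
  set.seed(302)
  pop <- tibble::tibble(grams_a = runif(20, 0, 400),
                        grams_b = runif(20, 0, 400))
  plan1 <- fortification_plan(c(a = 1.5, b = 2.5))
  plan2 <- fortification_plan(c(a = 3, b = 5))
  expect_equal(2 * added_vitamin_d(pop, plan1), added_vitamin_d(pop, plan2))
  pop2 <- pop; pop2[] <- pop[] * 3
  expect_equal(added_vitamin_d(pop2, plan1), 3 * added_vitamin_d(pop, plan1))
})

test_that("total intake adds baseline and converted supplement", {
  pop <- toy_population(baselines = 4, grams = 200, vehicle = "milk")
  plan <- fortification_plan(c(milk = 4))  # adds 8 ug
  expect_equal(total_intake(pop, plan, supplement_scenario(0)), 12)
  expect_equal(total_intake(pop, fortification_plan(c(milk = 0)),
                            supplement_scenario(400)), 4 + 10)
  zero <- toy_population(baselines = 0, grams = 0)
  expect_equal(total_intake(zero, fortification_plan(c(milk = 0)),
                            supplement_scenario(0)), 0)
  # scenario flag can keep a recorded dose out of the total
  expect_equal(total_intake(pop, plan,
                            supplement_scenario(1000, FALSE)), 12)
})

test_that("coverage metrics partition the population against RI and UL", {
  thr <- thresholds(10, 250)
  cm <- coverage_metrics(c(5, 15, 300), thr)
  expect_equal(cm$frac_below_ri, 1 / 3)
  expect_equal(cm$frac_above_ul, 1 / 3)
  expect_equal(cm$frac_within, 1 / 3)

  # boundary values count as within (closed interval)
  all_ri <- coverage_metrics(rep(10, 7), thr)
  expect_equal(all_ri$frac_within, 1)
  expect_equal(coverage_metrics(c(10, 250), thr)$frac_within, 1)

  # unfortified intake at the population mean sits below the IOM RI
  expect_equal(coverage_metrics(4, thresholds(10, 100))$frac_below_ri, 1)

  expect_error(coverage_metrics(numeric(0), thr), "non-empty")
  expect_error(coverage_metrics(c(1, -2), thr), ">= 0")
})

test_that("coverage fractions always sum to exactly one", {
  thr <- thresholds(10, 100)
  set.seed(303)
  for (rep in 1:25) {
    x <- runif(sample(1:50, 1), 0, 150)
    cm <- coverage_metrics(x, thr)
    # the count partition is exact; the fractions share its denominator
    expect_identical(cm$n_below + cm$n_within + cm$n_above, cm$n)
    expect_equal(cm$frac_below_ri + cm$frac_above_ul + cm$frac_within, 1,
                 tolerance = 1e-15)
    o <- oracle_coverage(x, 10, 100)
    expect_equal(cm$frac_below_ri, unname(o["below"]))
    expect_equal(cm$frac_above_ul, unname(o["above"]))
  }
})

test_that("raising any level weakly shifts intakes and coverage upward", {
  pop <- generate_population(population_params(n_individuals = 300,
                                               seed = 17))
  thr <- threshold_preset("iom")
  lo <- uniform_plan(1); hi <- uniform_plan(2)
  ti_lo <- total_intake(pop, lo); ti_hi <- total_intake(pop, hi)
  expect_true(all(ti_hi >= ti_lo))
  cm_lo <- coverage_metrics(ti_lo, thr); cm_hi <- coverage_metrics(ti_hi, thr)
  expect_lte(cm_hi$frac_below_ri, cm_lo$frac_below_ri)
  expect_gte(cm_hi$frac_above_ul, cm_lo$frac_above_ul)
})

test_that("threshold presets and validation behave as specified", {
  pm <- threshold_preset("paper-methods")
  expect_equal(c(pm$ri_lower, pm$ul), c(40, 250))
  iom <- threshold_preset("iom")
  expect_equal(c(iom$ri_lower, iom$ul, iom$rda), c(10, 100, 20))
  expect_error(thresholds(10, 10), "ri_lower < ul")
  expect_error(fortification_plan(c(milk = -1)), ">= 0")
})
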