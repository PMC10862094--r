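test_that("plan enumeration has the right size and lexicographic order", {
  two <- toy_vehicles(c("bread", "milk"))
  g <- grid_spec(c(1, 2), uniform_only = FALSE)
  plans <- enumerate_plans(g, two)
  expect_equal(nrow(plans), 4)
  # last vehicle fastest: (1,1), (1,2), (2,1), (2,2)
  expect_equal(plans$bread, c(1, 1, 2, 2))
  expect_equal(plans$milk, c(1, 2, 1, 2))

  full <- enumerate_plans(grid_spec(1:4, uniform_only = FALSE),
                          default_vehicles())
  expect_equal(nrow(full), 4^8)
  expect_equal(nrow(unique(full)), 4^8)

  expect_equal(nrow(enumerate_plans(grid_spec(1:4), default_vehicles())), 4)
  none <- toy_vehicles("bread"); none$fortifiable <- FALSE
  expect_error(enumerate_plans(g, none), "fortifiable")
})

test_that("feasibility is the strict no-individual-above-UL criterion", {
  thr <- thresholds(10, 100)
  p1 <- toy_population(baselines = 4, grams = 100)
  expect_true(is_feasible(fortification_plan(c(milk = 4)), p1, thr))
  p2 <- toy_population(baselines = 99, grams = 100)
  expect_false(is_feasible(fortification_plan(c(milk = 2)), p2, thr))
  expect_true(is_feasible(fortification_plan(c(milk = 0)), p2, thr))
  # the supplement scenario participates in the check
  expect_false(is_feasible(fortification_plan(c(milk = 0)), p2, thr,
                           supplement_scenario(400)))
})

test_that("optimizer agrees with a brute-force recomputation on a toy case", {
  pop <- toy_population(baselines = c(2, 5, 90), grams = c(100, 200, 400))
  thr <- thresholds(10, 100)
  res <- optimize_plan(pop, grid_spec(1:4), thr, vehicles = toy_vehicles())

  # independent exhaustive oracle over the 4 uniform levels
  objs <- sapply(1:4, function(L) {
    tot <- pop$baseline_vitd_ug + pop$grams_milk * L / 100
    if (max(tot) > 100) return(NA_real_)
    o <- oracle_coverage(tot, 10, 100)
    unname(o["below"] + o["above"])
  })
  # level 3: person 3 has 90 + 12 = 102 > UL -> infeasible; so are 4
  expect_equal(which(is.na(objs)), c(3, 4))
  best_level <- which.min(objs)
  expect_equal(unname(res$best_plan[["milk"]]),
               best_level)
  expect_equal(res$objective, objs[best_level])
  expect_equal(res$feasible_count, sum(!is.na(objs)))
  expect_equal(res$evaluated_count, 4)
  expect_equal(res$best_metrics$frac_above_ul, 0)
})

test_that("all-tied objectives fall back to the cheapest plan", {
  pop <- toy_population(baselines = c(20, 30), grams = c(10, 10))
  thr <- thresholds(10, 100)
  res <- optimize_plan(pop, grid_spec(1:4), thr, vehicles = toy_vehicles())
  expect_equal(unname(res$best_plan[["milk"]]), 1)
  expect_equal(res$objective, 0)
})

test_that("objective values survive an independent re-evaluation", {
  pop <- generate_population(population_params(n_individuals = 150,
                                               seed = 23))
  thr <- threshold_preset("iom")
  res <- optimize_plan(pop, grid_spec(1:4, uniform_only = FALSE),
                       thr,
                       vehicles = default_vehicles()[1:2, ])
  recheck <- function(row) {
    lv <- unlist(row[names(res$best_plan)])
    tot <- pop$baseline_vitd_ug +
      oracle_added_vitd(pop, lv)
    o <- oracle_coverage(tot, thr$ri_lower, thr$ul)
    unname(o["below"] + o["above"])
  }
  set.seed(99)
  rows <- unique(c(1, sample(nrow(res$ranking), 10)))
  for (i in rows) {
    expect_equal(res$ranking$objective[i], recheck(res$ranking[i, ]),
                 tolerance = 1e-12)
  }
})

test_that("feasibility is monotone: shrinking a feasible plan stays feasible", {
  pop <- generate_population(population_params(n_individuals = 100,
                                               seed = 31))
  thr <- threshold_preset("iom")
  veh <- default_vehicles()
  set.seed(32)
  for (rep in 1:10) {
    lv <- setNames(sample(0:4, 8, replace = TRUE), veh$name)
    plan <- fortification_plan(lv)
    if (is_feasible(plan, pop, thr)) {
      smaller <- fortification_plan(pmax(lv - sample(0:2, 8, TRUE), 0))
      expect_true(is_feasible(smaller, pop, thr))
    }
  }
})

test_that("uniform-grid optimum is never better than the full-grid optimum", {
  pop <- generate_population(population_params(n_individuals = 120,
                                               seed = 41))
  thr <- threshold_preset("iom")
  veh <- default_vehicles()[1:3, ]
  uni <- optimize_plan(pop, grid_spec(1:4, uniform_only = TRUE), thr,
                       vehicles = veh)
  full <- optimize_plan(pop, grid_spec(1:4, uniform_only = FALSE), thr,
                        vehicles = veh)
  expect_gte(uni$objective, full$objective)
  expect_equal(full$evaluated_count, 4^3)
})

test_that("an infeasible grid yields a diagnostic, not an exception", {
  pop <- toy_population(baselines = c(150, 200), grams = c(10, 10))
  thr <- thresholds(10, 100)  # UL below every baseline
  res <- optimize_plan(pop, grid_spec(1:4), thr, vehicles = toy_vehicles())
  expect_true(res$no_feasible)
  expect_equal(res$feasible_count, 0L)
  # least-violating plan is the lowest level
  expect_equal(unname(res$best_plan[["milk"]]), 1)
})
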