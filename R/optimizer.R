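#' Discrete grid of fortification levels
#'
#' The search space for fortification plans: a set of allowed per-100 g
#' addition levels (default 1-4 ug, the range applied in the simulation),
#' searched either uniformly (one shared level for all vehicles, the default,
#' matching how a single optimal level is reported) or per vehicle (the full
#' Cartesian grid, |levels|^V plans).
#'
#' @param levels_allowed Strictly increasing vector of allowed levels,
#'   ug/100 g, all >= 0.
#' @param uniform_only If `TRUE` (default) the same level is applied to all
#'   vehicles.
#' @return A `grid_spec` list.
#' @export
grid_spec <- function(levels_allowed = 1:4, uniform_only = TRUE) {
  if (length(levels_allowed) == 0 || any(!is.finite(levels_allowed)) ||
      any(levels_allowed < 0) || is.unsorted(levels_allowed,
                                             strictly = TRUE)) {
    stop("`levels_allowed` must be non-empty, strictly increasing, all >= 0",
         call. = FALSE)
  }
  structure(list(levels_allowed = as.double(levels_allowed),
                 uniform_only = isTRUE(uniform_only)),
            class = "grid_spec")
}

#' Enumerate all fortification plans on a grid
#'
#' Returns every candidate plan over the fortifiable vehicles: one row per
#' plan, one column per vehicle (ug/100 g). Order is deterministic:
#' vehicles sorted by name, levels varied lexicographically with the last
#' vehicle fastest. Uniform grids give one plan per allowed level, full grids
#' `|levels|^V` plans.
#'
#' @param grid A [grid_spec()].
#' @param vehicles Vehicle tibble; only `fortifiable = TRUE` rows enter.
#' @return A tibble of plans; convert a row with [plan_from_row()].
#' @examples
#' nrow(enumerate_plans(grid_spec(1:4), default_vehicles())) # 4 (uniform)
#' @export
enumerate_plans <- function(grid, vehicles = default_vehicles()) {
  stopifnot(inherits(grid, "grid_spec"))
  vehicles <- validate_vehicles(vehicles)
  nm <- sort(vehicles$name[vehicles$fortifiable])
  if (length(nm) == 0) {
    stop("no fortifiable vehicles in the vehicle set", call. = FALSE)
  }
  lv <- grid$levels_allowed
  if (grid$uniform_only) {
    m <- matrix(rep(lv, each = 1), ncol = 1)[, rep(1, length(nm)),
                                             drop = FALSE]
    plans <- tibble::as_tibble(stats::setNames(as.data.frame(m), nm))
  } else {
    # expand.grid varies the first factor fastest; reverse to make the last
    # vehicle (lexicographically) the fastest-varying
    g <- expand.grid(rev(replicate(length(nm), lv, simplify = FALSE)),
                     KEEP.OUT.ATTRS = FALSE)
    g <- g[, rev(seq_along(nm)), drop = FALSE]
    names(g) <- nm
    plans <- tibble::as_tibble(g)
  }
  plans
}

#' @rdname enumerate_plans
#' @param plans A plan tibble from [enumerate_plans()].
#' @param i Row index.
#' @export
plan_from_row <- function(plans, i) {
  fortification_plan(unlist(plans[i, , drop = FALSE]))
}

#' Is a fortification plan feasible?
#'
#' A plan is feasible when no individual's total daily intake exceeds the UL
#' under the given supplement scenario — a strict reading in which a single
#' individual above the UL invalidates the plan.
#'
#' @inheritParams total_intake
#' @param thresholds A [thresholds()] object.
#' @return Logical flag.
#' @export
is_feasible <- function(plan, population, thresholds,
                        scenario = supplement_scenario(0)) {
  if (nrow(tibble::as_tibble(population)) == 0) {
    stop("population is empty", call. = FALSE)
  }
  max(total_intake(population, plan, scenario)) <= thresholds$ul
}

#' Optimize a fortification plan over the grid
#'
#' Exhaustively evaluates every plan on the grid; plans under which any
#' individual would exceed the UL (with the supplement scenario applied, the
#' worst case for toxicity) are discarded. Among feasible plans the one
#' minimizing the fraction of the population outside the closed RI-UL
#' interval is returned. Ties are broken by the smallest total added ug
#' across the plan's levels, then by enumeration (lexicographic) order —
#' i.e. the cheapest equally-performing plan wins.
#'
#' The coverage objective is evaluated under `coverage_scenario`, which
#' defaults to no supplement: deficiency coverage is assessed on dietary
#' intake alone, while the UL safety constraint guards supplement users.
#' Pass the same scenario to both arguments to couple them.
#'
#' If no plan is feasible the result carries `no_feasible = TRUE` together
#' with the least-violating plan (smallest maximum intake) for diagnostics,
#' rather than raising an error.
#'
#' @inheritParams is_feasible
#' @param grid A [grid_spec()].
#' @param vehicles Vehicle tibble.
#' @param coverage_scenario Supplement scenario for the coverage objective
#'   (default: none).
#' @return An `optimization_result` list: `best_plan`, `best_metrics`,
#'   `objective`, `feasible_count`, `evaluated_count`, `no_feasible`, and
#'   `ranking` (tibble of all feasible plans with objective values, sorted
#'   best first).
#' @examples
#' pop <- generate_population(population_params(n_individuals = 50, seed = 1))
#' optimize_plan(pop, grid_spec(1:4), threshold_preset("iom"))
#' @export
optimize_plan <- function(population, grid, thresholds,
                          scenario = supplement_scenario(0),
                          coverage_scenario = supplement_scenario(0),
                          vehicles = default_vehicles()) {
  population <- tibble::as_tibble(population)
  if (nrow(population) == 0) stop("population is empty", call. = FALSE)
  plans <- enumerate_plans(grid, vehicles)
  nm <- names(plans)
  gm <- grams_matrix(population, fortification_plan(
    stats::setNames(rep(0, length(nm)), nm)))
  supp_feas <- if (scenario$include_supplement) iu_to_ug(scenario$dose_iu)
               else 0
  supp_cov <- if (coverage_scenario$include_supplement) {
    iu_to_ug(coverage_scenario$dose_iu)
  } else 0
  baseline <- population$baseline_vitd_ug

  lvl_mat <- as.matrix(plans)
  # added intake for all plans at once: individuals x plans
  added <- gm %*% t(lvl_mat) / 100
  tot_feas <- baseline + supp_feas + added
  max_feas <- apply(tot_feas, 2, max)
  feasible <- max_feas <= thresholds$ul

  tot_cov <- baseline + supp_cov + added
  frac_below <- colMeans(tot_cov < thresholds$ri_lower)
  frac_above <- colMeans(tot_cov > thresholds$ul)
  objective <- frac_below + frac_above
  total_added_ug <- rowSums(lvl_mat)

  if (!any(feasible)) {
    least <- which.min(max_feas)
    return(structure(
      list(best_plan = plan_from_row(plans, least),
           best_metrics = coverage_metrics(tot_cov[, least], thresholds),
           objective = objective[least],
           feasible_count = 0L,
           evaluated_count = nrow(plans),
           no_feasible = TRUE,
           ranking = tibble::tibble()),
      class = "optimization_result"))
  }

  idx <- which(feasible)
  ord <- idx[order(objective[idx], total_added_ug[idx], idx)]
  best <- ord[1]
  ranking <- tibble::as_tibble(plans[ord, , drop = FALSE])
  ranking$objective <- objective[ord]
  ranking$frac_below_ri <- frac_below[ord]
  ranking$frac_above_ul <- frac_above[ord]
  ranking$total_added_ug <- total_added_ug[ord]
  structure(
    list(best_plan = plan_from_row(plans, best),
         best_metrics = coverage_metrics(tot_cov[, best], thresholds),
         objective = objective[best],
         feasible_count = length(idx),
         evaluated_count = nrow(plans),
         no_feasible = FALSE,
         ranking = ranking),
    class = "optimization_result")
}

#' @export
print.optimization_result <- function(x, ...) {
  if (x$no_feasible) {
    cat("no feasible plan; least-violating plan shown for diagnostics\n")
  } else {
    cat(sprintf("best plan (of %d evaluated, %d feasible):\n",
                x$evaluated_count, x$feasible_count))
  }
  print(stats::setNames(as.numeric(x$best_plan), names(x$best_plan)))
  cat(sprintf("objective (frac outside RI-UL): %.4f\n", x$objective))
  invisible(x)
}
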