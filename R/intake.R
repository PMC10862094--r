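#' Fortification plans
#'
#' A fortification plan assigns each fortifiable vehicle an addition level in
#' ug of vitamin D per 100 g of food. `fortification_plan()` builds a plan
#' from a named vector; `uniform_plan()` applies the same level to every
#' fortifiable vehicle in a vehicle set.
#'
#' @param levels Named non-negative numeric vector: ug added per 100 g, named
#'   by vehicle.
#' @param level Single non-negative level applied uniformly.
#' @param vehicles Vehicle tibble (see [default_vehicles()]); only rows with
#'   `fortifiable = TRUE` receive the level.
#' @return A named numeric vector of class `fortification_plan`.
#' @examples
#' fortification_plan(c(whole_milk = 3, white_bread = 2))
#' uniform_plan(3)
#' @export
fortification_plan <- function(levels) {
  if (length(levels) == 0 || is.null(names(levels)) ||
      any(!nzchar(names(levels)))) {
    stop("`levels` must be a non-empty named numeric vector", call. = FALSE)
  }
  if (anyDuplicated(names(levels))) {
    stop("plan vehicle names must be unique", call. = FALSE)
  }
  if (any(!is.finite(levels)) || any(levels < 0)) {
    stop("every fortification level must be finite and >= 0", call. = FALSE)
  }
  structure(as.double(levels), names = names(levels),
            class = "fortification_plan")
}

#' @rdname fortification_plan
#' @export
uniform_plan <- function(level, vehicles = default_vehicles()) {
  vehicles <- validate_vehicles(vehicles)
  nm <- vehicles$name[vehicles$fortifiable]
  if (length(nm) == 0) stop("no fortifiable vehicles", call. = FALSE)
  fortification_plan(stats::setNames(rep(as.double(level), length(nm)), nm))
}

#' Intake thresholds
#'
#' The coverage analysis classifies each individual's daily vitamin D intake
#' against a recommended-intake lower bound (RI) and a tolerable upper intake
#' level (UL), with the RDA carried as the reference for IOM-RDA unit
#' conversion. Two named presets ship:
#'
#' * `"paper-methods"`: RI 40, UL 250 ug/day (the thresholds quoted for the
#'   simulation methods).
#' * `"iom"`: RI 10, UL 100, RDA 20 ug/day (the IOM values used in the
#'   ILSI-formula arithmetic, where UL = 100/20 = 5 IOM RDAs).
#'
#' The preset is always an explicit choice; nothing in the package assumes
#' one implicitly.
#'
#' @param ri_lower RI lower bound, ug/day; 0 < ri_lower < ul.
#' @param ul Tolerable upper intake level, ug/day.
#' @param rda RDA reference, ug/day.
#' @param preset One of `"paper-methods"`, `"iom"`.
#' @return A `thresholds` list.
#' @export
thresholds <- function(ri_lower, ul, rda = 20) {
  if (!is.finite(ri_lower) || !is.finite(ul) || !is.finite(rda)) {
    stop("thresholds must be finite", call. = FALSE)
  }
  if (ri_lower <= 0 || ul <= ri_lower) {
    stop("need 0 < ri_lower < ul", call. = FALSE)
  }
  if (rda <= 0) stop("`rda` must be > 0", call. = FALSE)
  structure(list(ri_lower = ri_lower, ul = ul, rda = rda),
            class = "thresholds")
}

#' @rdname thresholds
#' @export
threshold_preset <- function(preset = c("paper-methods", "iom")) {
  preset <- match.arg(preset)
  switch(preset,
         "paper-methods" = thresholds(ri_lower = 40, ul = 250, rda = 20),
         "iom" = thresholds(ri_lower = 10, ul = 100, rda = 20))
}

#' Supplement scenario
#'
#' A scenario-level constant supplement dose in IU/day, applied to every
#' individual when `include_supplement` is on. 40 IU = 1 ug.
#'
#' @param dose_iu Supplement dose, IU/day; >= 0.
#' @param include_supplement Whether the dose enters total intake. Defaults
#'   to on whenever `dose_iu > 0`.
#' @return A `supplement_scenario` list.
#' @export
supplement_scenario <- function(dose_iu = 0, include_supplement = dose_iu > 0) {
  if (!is.finite(dose_iu) || dose_iu < 0) {
    stop("`dose_iu` must be finite and >= 0", call. = FALSE)
  }
  structure(list(dose_iu = dose_iu,
                 include_supplement = isTRUE(include_supplement)),
            class = "supplement_scenario")
}

# grams matrix (individuals x plan vehicles) for a population tibble; plan
# vehicles missing from the table contribute 0 g.
grams_matrix <- function(population, plan) {
  cols <- paste0("grams_", names(plan))
  m <- matrix(0, nrow = nrow(population), ncol = length(plan),
              dimnames = list(NULL, names(plan)))
  for (j in seq_along(cols)) {
    if (cols[j] %in% names(population)) m[, j] <- population[[cols[j]]]
  }
  if (any(m < 0)) stop("negative grams in population table", call. = FALSE)
  m
}

#' Vitamin D added by a fortification plan
#'
#' For each individual, the fortified foods contribute
#' `sum_v grams(v) * level(v) / 100` ug/day: grams consumed per vehicle times
#' the ug added per 100 g, the division by 100 converting grams to 100-g
#' meals. Plan vehicles absent from the population table contribute 0 g,
#' which permits heterogeneous food lists.
#'
#' @param population Population tibble (see [generate_population()]) with one
#'   `grams_<vehicle>` column per consumed vehicle.
#' @param plan A [fortification_plan()].
#' @return Numeric vector, ug/day of added vitamin D per individual.
#' @examples
#' pop <- tibble::tibble(grams_milk = 200, grams_bread = 100)
#' added_vitamin_d(pop, fortification_plan(c(milk = 3, bread = 2))) # 8
#' @export
added_vitamin_d <- function(population, plan) {
  stopifnot(inherits(plan, "fortification_plan"))
  population <- tibble::as_tibble(population)
  drop(grams_matrix(population, plan) %*% plan) / 100
}

#' Total daily vitamin D intake under a plan and supplement scenario
#'
#' Baseline dietary intake plus fortification contribution plus, when the
#' scenario includes it, the supplement dose converted at 40 IU/ug.
#'
#' @inheritParams added_vitamin_d
#' @param scenario A [supplement_scenario()].
#' @return Numeric vector, ug/day per individual.
#' @export
total_intake <- function(population, plan,
                         scenario = supplement_scenario(0)) {
  stopifnot(inherits(scenario, "supplement_scenario"))
  population <- tibble::as_tibble(population)
  if (!"baseline_vitd_ug" %in% names(population)) {
    stop("population table must have a `baseline_vitd_ug` column",
         call. = FALSE)
  }
  supp <- if (scenario$include_supplement) iu_to_ug(scenario$dose_iu) else 0
  population$baseline_vitd_ug + added_vitamin_d(population, plan) + supp
}

#' Population coverage against the RI-UL range
#'
#' Partitions intakes into below-RI (`intake < ri_lower`), within the closed
#' interval `[ri_lower, ul]`, and above-UL (`intake > ul`); boundary values
#' count as within. The three fractions sum to exactly 1.
#'
#' @param intakes Non-empty numeric vector of daily intakes, ug/day, >= 0.
#' @param thresholds A [thresholds()] object.
#' @return A `coverage_metrics` list: `frac_below_ri`, `frac_above_ul`,
#'   `frac_within`, the underlying integer counts `n_below`, `n_within`,
#'   `n_above` (which sum to `n` exactly — the partition has no gaps or
#'   overlaps), `max_intake`, `mean_intake`, `n`.
#' @examples
#' coverage_metrics(c(5, 15, 300), thresholds(10, 250))
#' @export
coverage_metrics <- function(intakes, thresholds) {
  stopifnot(inherits(thresholds, "thresholds"))
  if (length(intakes) == 0) stop("`intakes` must be non-empty", call. = FALSE)
  if (any(!is.finite(intakes)) || any(intakes < 0)) {
    stop("all intakes must be finite and >= 0", call. = FALSE)
  }
  n <- length(intakes)
  n_below <- sum(intakes < thresholds$ri_lower)
  n_above <- sum(intakes > thresholds$ul)
  n_within <- n - n_below - n_above  # exact partition by construction
  structure(
    list(frac_below_ri = n_below / n,
         frac_above_ul = n_above / n,
         frac_within = n_within / n,
         n_below = n_below, n_within = n_within, n_above = n_above,
         max_intake = max(intakes),
         mean_intake = mean(intakes),
         n = n),
    class = "coverage_metrics"
  )
}

#' @export
print.coverage_metrics <- function(x, ...) {
  cat(sprintf(
    "coverage over %d individuals: %.1f%% below RI, %.1f%% within, %.1f%% above UL\n",
    x$n, 100 * x$frac_below_ri, 100 * x$frac_within, 100 * x$frac_above_ul))
  cat(sprintf("mean intake %.2f ug/day, max %.2f ug/day\n",
              x$mean_intake, x$max_intake))
  invisible(x)
}

#' Export per-individual intake results as CSV
#'
#' Writes one row per individual with baseline, added, supplement and total
#' vitamin D in ug/day.
#'
#' @inheritParams total_intake
#' @param path Output CSV path.
#' @return The tibble written, invisibly.
#' @export
write_intake_results <- function(population, plan, scenario, path) {
  population <- tibble::as_tibble(population)
  added <- added_vitamin_d(population, plan)
  supp <- if (scenario$include_supplement) iu_to_ug(scenario$dose_iu) else 0
  out <- tibble::tibble(
    id = population$id,
    baseline_ug = population$baseline_vitd_ug,
    added_ug = added,
    supplement_ug = supp,
    total_ug = population$baseline_vitd_ug + added + supp
  )
  readr::write_csv(out, path)
  invisible(out)
}
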