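#' Default pipeline configuration
#'
#' A nested list mirroring the YAML/JSON config schema accepted by
#' [run_pipeline()] and the command-line wrapper: `population` (either
#' [population_params()] fields or a `csv` path), optional `vehicles_csv`,
#' `preset` (threshold preset name), `grid` (`levels_allowed`,
#' `uniform_only`), `scenario` / `coverage_scenario` (supplement IU),
#' `formulas` (`ul`, `ci95`, `ei95`, `pff_list`, `si_rda_units` for the
#' Rasmussen rows), and `comparison` (`level_ug_per_100g`,
#' `fa_ug_per_100kcal`).
#'
#' @return The default config list.
#' @export
default_config <- function() {
  list(
    population = list(n_individuals = 2000, seed = 42, supplement_iu = 1000),
    vehicles_csv = NULL,
    preset = "iom",
    grid = list(levels_allowed = 1:4, uniform_only = TRUE),
    scenario = list(dose_iu = 1000),
    coverage_scenario = list(dose_iu = 0),
    formulas = list(ul = 5, ci95 = 0.05, ei95 = 18.8,
                    pff_list = c(1, 0.5, 0.25, 0.11, 0.05),
                    si_rda_units = c(0.5, 1.25)),
    comparison = list(level_ug_per_100g = 3, fa_ug_per_100kcal = 2.1)
  )
}

#' Read a pipeline config from YAML or JSON
#'
#' Missing keys fall back to [default_config()] values.
#'
#' @param path `.yaml`/`.yml` or `.json` file.
#' @return Config list.
#' @export
read_config <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path)) {
    yaml::read_yaml(path)
  } else if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    stop("config must be a .yaml/.yml or .json file", call. = FALSE)
  }
  utils::modifyList(default_config(), cfg)
}

#' Run the full fortification-planning pipeline
#'
#' Executes generate -> intake -> optimize -> formulas -> comparisons and
#' writes a report directory: `population.csv`, `intake.csv`,
#' `optimization.json`, `safe_addition_table.csv`,
#' `method_comparison.json`, `country_comparison.csv`, plus `pipeline.log`.
#' Data files are deterministic for a fixed config and seed (the log carries
#' timestamps). Stage failures are logged with the stage name and re-raised.
#'
#' @param config Config list (see [default_config()]) or a path accepted by
#'   [read_config()].
#' @param out_dir Report directory (created if absent).
#' @param seed Optional seed overriding `config$population$seed`.
#' @return Invisibly, a list with the in-memory stage results.
#' @export
run_pipeline <- function(config = default_config(), out_dir, seed = NULL) {
  if (is.character(config)) config <- read_config(config)
  config <- utils::modifyList(default_config(), config)
  if (!is.null(seed)) config$population$seed <- seed
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "pipeline.log")
  log_line <- function(...) {
    cat(format(Sys.time(), "%Y-%m-%d %H:%M:%S "), sprintf(...), "\n",
        sep = "", file = log_path, append = TRUE)
  }
  stage <- function(name, expr) {
    log_line("stage %s: start", name)
    res <- tryCatch(expr, error = function(e) {
      log_line("stage %s: ERROR %s", name, conditionMessage(e))
      stop(sprintf("pipeline stage `%s` failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
    log_line("stage %s: done", name)
    res
  }

  vehicles <- stage("vehicles", {
    if (is.null(config$vehicles_csv)) default_vehicles()
    else read_vehicles(config$vehicles_csv)
  })

  pop <- stage("generate", {
    pc <- config$population
    if (!is.null(pc$csv)) {
      read_population(pc$csv)
    } else {
      pc$csv <- NULL
      pc$vehicles <- vehicles
      generate_population(do.call(population_params, pc))
    }
  })
  write_population(pop, file.path(out_dir, "population.csv"))

  thr <- threshold_preset(config$preset)
  scen <- supplement_scenario(config$scenario$dose_iu)
  cov_scen <- supplement_scenario(config$coverage_scenario$dose_iu)
  grid <- grid_spec(config$grid$levels_allowed, config$grid$uniform_only)

  opt <- stage("optimize",
               optimize_plan(pop, grid, thr, scenario = scen,
                             coverage_scenario = cov_scen,
                             vehicles = vehicles))
  stage("intake", write_intake_results(pop, opt$best_plan, scen,
                                       file.path(out_dir, "intake.csv")))
  opt_json <- list(
    no_feasible = opt$no_feasible,
    best_plan = as.list(stats::setNames(as.numeric(opt$best_plan),
                                        names(opt$best_plan))),
    objective = opt$objective,
    feasible_count = opt$feasible_count,
    evaluated_count = opt$evaluated_count,
    best_metrics = unclass(opt$best_metrics)
  )
  jsonlite::write_json(opt_json, file.path(out_dir, "optimization.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  fml <- config$formulas
  sat <- stage("formulas", {
    scen_tbl <- tibble::tibble(
      model = c("flynn", rep("rasmussen", length(fml$si_rda_units))),
      si = c(0, fml$si_rda_units))
    safe_addition_table(fml$pff_list, scen_tbl,
                        formula_inputs(ul = fml$ul, ci95 = fml$ci95,
                                       ei95 = fml$ei95))
  })
  readr::write_csv(sat, file.path(out_dir, "safe_addition_table.csv"))

  cmp <- stage("compare", compare_fortification_methods(
    reference_basket(vehicles),
    level_ug_per_100g = config$comparison$level_ug_per_100g,
    fa_ug_per_100kcal = config$comparison$fa_ug_per_100kcal))
  jsonlite::write_json(
    list(per_food = cmp$per_food,
         total_method1_ug = cmp$total_method1_ug,
         total_method2_ug = cmp$total_method2_ug,
         total_kcal = cmp$total_kcal),
    file.path(out_dir, "method_comparison.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)

  cc <- stage("countries", country_comparison())
  readr::write_csv(cc$table, file.path(out_dir, "country_comparison.csv"))

  log_line("pipeline complete")
  invisible(list(population = pop, optimization = opt,
                 safe_addition_table = sat, method_comparison = cmp,
                 country_comparison = cc))
}
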