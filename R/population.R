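#' Parameters for the synthetic dietary population
#'
#' The generator emulates the statistical structure of an adult cohort's
#' food-frequency data: strictly positive intake quantities (baseline dietary
#' vitamin D, daily energy, grams/day of each candidate vehicle) are drawn
#' from independent log-normal distributions — the standard family in dietary
#' exposure modelling for right-skewed consumption data.
#'
#' Calibration targets are stated as moments/percentiles and the log-normal
#' parameters are solved from them: baseline vitamin D matches a given
#' arithmetic mean (default 4 ug/day); energy matches both a mean (default
#' 2000 kcal/day) and a 95th percentile (default 4200 kcal/day, i.e. 42
#' portions of 100 kcal). Vehicle consumption is parameterised by per-vehicle
#' medians (grams/day) and a common log-scale sd; the default medians are
#' plausible staple-food amounts for the region, not cohort values (none are
#' published). Supplement dose is a scenario constant applied to everyone
#' (0, 400 or 1000 IU/day). Age is uniform over 35-65 years and sex balanced,
#' matching the cohort frame the analysis assumes.
#'
#' @param n_individuals Number of individuals; >= 1.
#' @param mean_baseline_vitd Target arithmetic mean of baseline dietary
#'   vitamin D, ug/day.
#' @param sd_log_baseline Log-scale sd of baseline vitamin D.
#' @param mean_energy Target mean daily energy, kcal/day.
#' @param p95_energy Target 95th-percentile daily energy, kcal/day; must
#'   exceed `mean_energy` (and their ratio must be attainable by a
#'   log-normal: p95/mean < exp(z95^2/2) ~ 3.87).
#' @param median_grams Named vector of per-vehicle median consumption,
#'   grams/day; names must match `vehicles$name`.
#' @param sd_log_grams Log-scale sd shared by the vehicle consumption
#'   distributions.
#' @param supplement_iu Scenario supplement dose, IU/day, same for everyone.
#' @param vehicles Vehicle tibble (see [default_vehicles()]).
#' @param seed Integer seed; identical params (including seed) give
#'   identical populations.
#' @return A validated `population_params` list.
#' @export
population_params <- function(n_individuals = 2000,
                              mean_baseline_vitd = 4,
                              sd_log_baseline = 0.5,
                              mean_energy = 2000,
                              p95_energy = 4200,
                              median_grams = default_median_grams(),
                              sd_log_grams = 0.6,
                              supplement_iu = 0,
                              vehicles = default_vehicles(),
                              seed = 1L) {
  chk_pos <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
      stop(sprintf("`%s` must be a single positive number", nm),
           call. = FALSE)
    }
  }
  if (!is.numeric(n_individuals) || length(n_individuals) != 1L ||
      n_individuals < 1 || n_individuals != floor(n_individuals)) {
    stop("`n_individuals` must be an integer >= 1", call. = FALSE)
  }
  chk_pos(mean_baseline_vitd, "mean_baseline_vitd")
  chk_pos(sd_log_baseline, "sd_log_baseline")
  chk_pos(mean_energy, "mean_energy")
  chk_pos(p95_energy, "p95_energy")
  chk_pos(sd_log_grams, "sd_log_grams")
  if (p95_energy <= mean_energy) {
    stop("`p95_energy` must exceed `mean_energy`", call. = FALSE)
  }
  if (!is.finite(supplement_iu) || supplement_iu < 0) {
    stop("`supplement_iu` must be >= 0", call. = FALSE)
  }
  vehicles <- validate_vehicles(vehicles)
  if (is.null(names(median_grams)) ||
      !setequal(names(median_grams), vehicles$name)) {
    stop("`median_grams` must be named for exactly the vehicle set",
         call. = FALSE)
  }
  if (any(!is.finite(median_grams)) || any(median_grams <= 0)) {
    stop("`median_grams` must be positive", call. = FALSE)
  }
  # fail early if the mean/p95 pair is outside the log-normal family
  lognormal_from_mean_p95(mean_energy, p95_energy)
  structure(
    list(n_individuals = as.integer(n_individuals),
         mean_baseline_vitd = mean_baseline_vitd,
         sd_log_baseline = sd_log_baseline,
         mean_energy = mean_energy,
         p95_energy = p95_energy,
         median_grams = median_grams[vehicles$name],
         sd_log_grams = sd_log_grams,
         supplement_iu = supplement_iu,
         vehicles = vehicles,
         seed = as.integer(seed)),
    class = "population_params"
  )
}

#' Default per-vehicle median consumption (grams/day)
#'
#' Invented but realistic staple-food amounts; the source cohort publishes no
#' per-vehicle consumption distributions, so these are configuration values.
#'
#' @return Named numeric vector, grams/day.
#' @export
default_median_grams <- function() {
  c(whole_bread = 150, white_bread = 100, whole_milk = 80, low_fat_milk = 50,
    yogurt = 80, doogh = 100, cheese = 20, butter = 10)
}

# Solve log-normal (meanlog, sdlog) so the distribution has the given
# arithmetic mean and 95th percentile:
#   mean = exp(mu + s^2/2),  p95 = exp(mu + z * s),  z = qnorm(0.95)
# eliminating mu gives s^2/2 - z*s + log(p95/mean) = 0; the smaller root is
# taken (the larger corresponds to a median above the mean).
lognormal_from_mean_p95 <- function(mean, p95) {
  z <- stats::qnorm(0.95)
  disc <- z^2 - 2 * log(p95 / mean)
  if (disc <= 0) {
    stop("`p95_energy`/`mean_energy` ratio too large for a log-normal ",
         sprintf("(must be below exp(z95^2/2) = %.3f)", exp(z^2 / 2)),
         call. = FALSE)
  }
  s <- z - sqrt(disc)
  list(meanlog = log(mean) - s^2 / 2, sdlog = s)
}

# meanlog for a log-normal with given arithmetic mean and sdlog
lognormal_from_mean_sdlog <- function(mean, sdlog) {
  list(meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
}

#' Generate a synthetic dietary population
#'
#' Draws `n_individuals` records under [population_params()]; see that help
#' page for the distributional assumptions. Generation is fully seeded and
#' leaves the caller's RNG state untouched.
#'
#' @param params A [population_params()] object.
#' @return A tibble with columns `id`, `age`, `sex`, `energy_kcal`,
#'   `baseline_vitd_ug`, `supplement_iu`, then one `grams_<vehicle>` column
#'   per vehicle.
#' @examples
#' pop <- generate_population(population_params(n_individuals = 100, seed = 7))
#' summarize_population(pop)
#' @export
generate_population <- function(params) {
  stopifnot(inherits(params, "population_params"))
  n <- params$n_individuals
  withr::with_seed(params$seed, {
    base <- lognormal_from_mean_sdlog(params$mean_baseline_vitd,
                                      params$sd_log_baseline)
    en <- lognormal_from_mean_p95(params$mean_energy, params$p95_energy)
    pop <- tibble::tibble(
      id = seq_len(n),
      age = round(stats::runif(n, 35, 65), 1),
      sex = sample(c("F", "M"), n, replace = TRUE),
      energy_kcal = stats::rlnorm(n, en$meanlog, en$sdlog),
      baseline_vitd_ug = stats::rlnorm(n, base$meanlog, base$sdlog),
      supplement_iu = rep(params$supplement_iu, n)
    )
    for (v in params$vehicles$name) {
      pop[[paste0("grams_", v)]] <-
        stats::rlnorm(n, log(params$median_grams[[v]]), params$sd_log_grams)
    }
    pop
  })
}

#' Summarize a dietary population
#'
#' @param population Population tibble from [generate_population()] or
#'   [read_population()].
#' @return A list: `n`, `mean_baseline_ug`, `p95_baseline_ug`,
#'   `mean_energy_kcal`, `p95_energy_kcal`, `ei95_portions` (95th-percentile
#'   energy divided by 100, i.e. in 100-kcal portions), and `p95_grams`
#'   (named vector of per-vehicle 95th-percentile grams/day).
#' @export
summarize_population <- function(population) {
  population <- tibble::as_tibble(population)
  if (nrow(population) == 0) stop("population is empty", call. = FALSE)
  q95 <- function(x) unname(stats::quantile(x, 0.95))
  gcols <- grep("^grams_", names(population), value = TRUE)
  p95_energy <- q95(population$energy_kcal)
  out <- list(
    n = nrow(population),
    mean_baseline_ug = mean(population$baseline_vitd_ug),
    p95_baseline_ug = q95(population$baseline_vitd_ug),
    mean_energy_kcal = mean(population$energy_kcal),
    p95_energy_kcal = p95_energy,
    ei95_portions = p95_energy / 100,
    p95_grams = vapply(population[gcols], q95, numeric(1))
  )
  names(out$p95_grams) <- sub("^grams_", "", gcols)
  stopifnot(all(vapply(out[2:6], is.finite, logical(1))))
  out
}

pop_base_cols <- c("id", "age", "sex", "energy_kcal", "baseline_vitd_ug",
                   "supplement_iu")

#' Write / read a population table (CSV)
#'
#' One header row, one row per individual; columns `id`, `age`, `sex`,
#' `energy_kcal`, `baseline_vitd_ug`, `supplement_iu`, then one
#' `grams_<vehicle>` column per vehicle. Values are serialized at full
#' precision so that `read_population(write_population(x))` reproduces `x`.
#' Malformed files (missing required columns, no vehicle columns, negative
#' values) raise a format error naming the offending column and row.
#'
#' @param population Population tibble.
#' @param path CSV path.
#' @return `write_population()` returns `path` invisibly; `read_population()`
#'   the validated tibble.
#' @export
write_population <- function(population, path) {
  population <- tibble::as_tibble(population)
  miss <- setdiff(pop_base_cols, names(population))
  if (length(miss) > 0) {
    stop("population missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  readr::write_csv(population, path)
  invisible(path)
}

#' @rdname write_population
#' @export
read_population <- function(path) {
  pop <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           sex = readr::col_character(),
                           .default = readr::col_guess()))
  miss <- setdiff(pop_base_cols, names(pop))
  if (length(miss) > 0) {
    stop("population file missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  gcols <- grep("^grams_", names(pop), value = TRUE)
  if (length(gcols) == 0) {
    stop("population file has no grams_<vehicle> columns", call. = FALSE)
  }
  for (col in c("energy_kcal", "baseline_vitd_ug", "supplement_iu", gcols)) {
    x <- pop[[col]]
    if (!is.numeric(x) || any(!is.finite(x))) {
      stop(sprintf("column `%s` must be numeric and finite", col),
           call. = FALSE)
    }
    bad <- which(if (col == "energy_kcal") x <= 0 else x < 0)
    if (length(bad) > 0) {
      stop(sprintf("invalid value in column `%s`, row %d: %g",
                   col, bad[1], x[bad[1]]), call. = FALSE)
    }
  }
  pop
}
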