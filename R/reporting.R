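#' Reference basket of fortification vehicles
#'
#' The standard comparison basket: 100 g of each of the eight vehicles
#' (800 g total). `printed_kcal_multipliers` carries the two-decimal
#' 100-kcal-portion multipliers used in the published comparison (0.37,
#' 0.37, 0.62, 0.5, 0.66, 0.5, 1.67, 9); they differ in the third decimal
#' from the full-precision `kcal_per_100g * grams / 100 / 100` values.
#'
#' @param vehicles Vehicle tibble.
#' @param grams_each Grams of each vehicle in the basket (default 100).
#' @return A tibble with columns `name`, `kcal_per_100g`, `grams`.
#' @export
reference_basket <- function(vehicles = default_vehicles(),
                             grams_each = 100) {
  vehicles <- validate_vehicles(vehicles)
  if (!is.finite(grams_each) || grams_each <= 0) {
    stop("`grams_each` must be > 0", call. = FALSE)
  }
  tibble::tibble(name = vehicles$name,
                 kcal_per_100g = vehicles$kcal_per_100g,
                 grams = grams_each)
}

printed_kcal_multipliers <- function() {
  c(whole_bread = 0.37, white_bread = 0.37, whole_milk = 0.62,
    low_fat_milk = 0.5, yogurt = 0.66, doogh = 0.5, cheese = 1.67,
    butter = 9)
}

#' Compare per-100 g and per-100 kcal fortification on a basket
#'
#' Method 1 fortifies by mass: each food contributes
#' `grams / 100 * level_ug_per_100g` ug. Method 2 fortifies by energy: each
#' food contributes `fa_ug_per_100kcal` times its number of 100-kcal
#' portions (`kcal_per_100g * grams / 100 / 100`). Totals are exact sums of
#' the per-food values.
#'
#' With `use_printed_multipliers = TRUE` (default) method 2 uses the
#' two-decimal portion multipliers of the published comparison table, which
#' reproduces its printed total exactly; switch it off for full-precision
#' energy densities.
#'
#' @param basket Basket tibble from [reference_basket()] (columns `name`,
#'   `kcal_per_100g`, `grams`).
#' @param level_ug_per_100g Method-1 uniform addition, ug/100 g; >= 0.
#' @param fa_ug_per_100kcal Method-2 safe addition, ug/100 kcal; >= 0.
#' @param use_printed_multipliers Use the two-decimal portion multipliers
#'   where available (only defined for the default vehicle names).
#' @return A `method_comparison` list: `per_food` tibble (`name`,
#'   `method1_ug`, `method2_ug`), `total_method1_ug`, `total_method2_ug`,
#'   `total_kcal`.
#' @examples
#' compare_fortification_methods(reference_basket(), 3, 2.1)
#' @export
compare_fortification_methods <- function(basket,
                                          level_ug_per_100g = 3,
                                          fa_ug_per_100kcal = 2.1,
                                          use_printed_multipliers = TRUE) {
  basket <- tibble::as_tibble(basket)
  if (nrow(basket) == 0) stop("basket is empty", call. = FALSE)
  stopifnot(all(c("name", "kcal_per_100g", "grams") %in% names(basket)))
  if (any(basket$grams <= 0)) stop("basket grams must be > 0", call. = FALSE)
  if (level_ug_per_100g < 0 || fa_ug_per_100kcal < 0) {
    stop("levels must be >= 0", call. = FALSE)
  }
  portions <- basket$kcal_per_100g * basket$grams / 100 / 100
  if (use_printed_multipliers) {
    pm <- printed_kcal_multipliers()
    hit <- basket$name %in% names(pm) & basket$grams == 100
    portions[hit] <- pm[basket$name[hit]]
  }
  per_food <- tibble::tibble(
    name = basket$name,
    method1_ug = basket$grams / 100 * level_ug_per_100g,
    method2_ug = fa_ug_per_100kcal * portions
  )
  structure(
    list(per_food = per_food,
         total_method1_ug = sum(per_food$method1_ug),
         total_method2_ug = sum(per_food$method2_ug),
         total_kcal = sum(basket$kcal_per_100g * basket$grams / 100)),
    class = "method_comparison"
  )
}

#' @export
print.method_comparison <- function(x, ...) {
  print(x$per_food)
  cat(sprintf(
    "totals: method 1 = %.1f ug, method 2 = %.1f ug over %.0f kcal\n",
    x$total_method1_ug, x$total_method2_ug, x$total_kcal))
  invisible(x)
}

#' Per-100 kcal vitamin D availability across countries
#'
#' Reference values (ug per 100 kcal, ILSI-model basis) for six European
#' countries and Iran, used to situate a national safe-addition estimate.
#'
#' @return Named numeric vector, ug/100 kcal.
#' @export
european_vitd_values <- function() {
  c(Denmark = 1.8, France = 1.3, Ireland = 1.7, Germany = 3.4,
    Holland = 1.8, UK = 2.0, Iran = 2.1)
}

#' Country comparison of per-100 kcal vitamin D values
#'
#' @param values Non-empty named numeric vector, country -> ug/100 kcal.
#' @return A list: `mean` (arithmetic mean, ug/100 kcal, full precision —
#'   round to 1 d.p. for display), `table` (tibble `country`, `ug_per_100kcal`).
#' @examples
#' eu <- european_vitd_values()
#' country_comparison(eu[names(eu) != "Iran"])$mean # 2.0
#' @export
country_comparison <- function(values = european_vitd_values()) {
  if (length(values) == 0) stop("`values` must be non-empty", call. = FALSE)
  if (is.null(names(values)) || any(!nzchar(names(values)))) {
    stop("`values` must be named by country", call. = FALSE)
  }
  list(mean = mean(values),
       table = tibble::tibble(country = names(values),
                              ug_per_100kcal = unname(values)))
}
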