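#' Default fortification vehicle set
#'
#' The eight staple foods considered as vitamin D fortification vehicles —
#' breads, milks, yogurt, doogh (a yogurt drink), cheese and butter — with
#' their energy densities in kcal per 100 g. These eight are drawn from a
#' 70-food market basket (a fortifiable proportion of about 0.11).
#'
#' The bread energy density of 37.5 kcal/100 g is carried verbatim from the
#' source basket even though it is implausibly low for bread; it is a fixture
#' value, not a nutritional reference.
#'
#' @return A tibble with columns `name`, `kcal_per_100g`, `fortifiable`.
#' @export
default_vehicles <- function() {
  tibble::tibble(
    name = c("whole_bread", "white_bread", "whole_milk", "low_fat_milk",
             "yogurt", "doogh", "cheese", "butter"),
    kcal_per_100g = c(37.5, 37.5, 62.5, 50, 66, 50, 166.6, 900),
    fortifiable = TRUE
  )
}

validate_vehicles <- function(vehicles) {
  vehicles <- tibble::as_tibble(vehicles)
  req <- c("name", "kcal_per_100g", "fortifiable")
  miss <- setdiff(req, names(vehicles))
  if (length(miss) > 0) {
    stop("vehicle table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(vehicles$name)) {
    stop("vehicle names must be unique", call. = FALSE)
  }
  if (any(!is.finite(vehicles$kcal_per_100g)) ||
      any(vehicles$kcal_per_100g <= 0)) {
    stop("`kcal_per_100g` must be positive for every vehicle", call. = FALSE)
  }
  vehicles$fortifiable <- as.logical(vehicles$fortifiable)
  vehicles
}

#' Read or write a vehicle table (CSV)
#'
#' CSV columns: `name`, `kcal_per_100g`, `fortifiable` (0/1 or logical).
#'
#' @param path File path.
#' @param vehicles Vehicle tibble as from [default_vehicles()].
#' @return `read_vehicles()` returns the validated tibble;
#'   `write_vehicles()` returns `path` invisibly.
#' @export
read_vehicles <- function(path) {
  v <- readr::read_csv(path, show_col_types = FALSE)
  validate_vehicles(v)
}

#' @rdname read_vehicles
#' @export
write_vehicles <- function(vehicles, path) {
  readr::write_csv(validate_vehicles(vehicles), path)
  invisible(path)
}
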