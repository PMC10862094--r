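#' Unit conversions for vitamin D fortification arithmetic
#'
#' Vitamin D quantities circulate in three unit systems: International Units
#' (IU), micrograms (1 ug = 40 IU), and IOM-RDA units (an intake expressed as
#' a multiple of the Institute of Medicine RDA, 20 ug/day by default).
#' `iu_to_ug()` converts IU to micrograms, `ug_to_rda_units()` converts
#' micrograms to IOM-RDA units, and `round_half_up()` provides the
#' round-half-up convention used when table values are displayed (base
#' `round()` rounds half to even, which is not how printed nutrition tables
#' are conventionally rounded).
#'
#' @param x Non-negative numeric quantity (IU for `iu_to_ug`, ug for
#'   `ug_to_rda_units`).
#' @param rda_ug RDA reference in ug/day; must be positive.
#' @param digits Number of decimal places for `round_half_up()`.
#' @return Converted numeric of the same length as `x`.
#' @examples
#' iu_to_ug(400)            # 10 ug
#' ug_to_rda_units(100, 20) # 5 IOM-RDA units
#' @export
iu_to_ug <- function(x) {
  if (any(!is.finite(x)) || any(x < 0)) {
    stop("`x` must be finite and non-negative (IU)", call. = FALSE)
  }
  x / IU_PER_UG
}

#' @rdname iu_to_ug
#' @export
ug_to_rda_units <- function(x, rda_ug = 20) {
  if (any(!is.finite(x)) || any(x < 0)) {
    stop("`x` must be finite and non-negative (ug)", call. = FALSE)
  }
  if (!is.finite(rda_ug) || rda_ug <= 0) {
    stop("`rda_ug` must be positive", call. = FALSE)
  }
  x / rda_ug
}

#' @rdname iu_to_ug
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

# 40 IU of vitamin D = 1 ug; fixed biological conversion constant.
IU_PER_UG <- 40
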