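#' Inputs for the Flynn (ILSI) and Rasmussen (DFVR) safe-addition formulas
#'
#' Both formulas estimate FA, the maximum amount of a micronutrient that can
#' safely be added to each 100-kcal food portion without pushing the highest
#' consumers over the tolerable upper intake level (UL). Intakes are expressed
#' in IOM-RDA units (multiples of the RDA, 20 ug/day for vitamin D), energy in
#' 100-kcal portions.
#'
#' The two models differ in how they treat supplements and the energy
#' denominator. Flynn ignores supplement intake and assumes a fixed number of
#' daily 100-kcal portions (42, i.e. 4200 kcal at the 95th percentile of adult
#' male energy intake) of which a fixed fraction (50%) is potentially
#' fortifiable. Rasmussen subtracts supplement intake from the headroom and
#' uses the population's observed 95th-percentile energy intake directly.
#'
#' @param ul Tolerable upper intake level, IOM-RDA units (default 5, i.e.
#'   100 ug at RDA 20 ug).
#' @param ci95 95th-percentile current intake from non-fortified food,
#'   IOM-RDA units (default 0.05, i.e. 1 ug).
#' @param si Supplement intake, IOM-RDA units (default 0). Only Rasmussen
#'   uses it.
#' @param ei95 95th-percentile energy intake, in 100-kcal portions/day
#'   (default 18.8).
#' @param pff Proportion of marketable foods that can be fortified, in (0, 1].
#' @param portions Daily 100-kcal portions assumed by Flynn (default 42).
#' @param fortified_fraction Fraction of those portions that is potentially
#'   fortified (default 0.5).
#' @param rda_ug RDA reference used to convert IOM-RDA units back to ug
#'   (default 20 ug/day).
#' @return A `formula_inputs` list.
#' @examples
#' fi <- formula_inputs(pff = 0.11)
#' flynn_fa(fi) # 2.1428... IOM-RDA units per 100-kcal portion
#' @export
formula_inputs <- function(ul = 5, ci95 = 0.05, si = 0, ei95 = 18.8,
                           pff = 0.11, portions = 42,
                           fortified_fraction = 0.5, rda_ug = 20) {
  chk_num <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
      stop(sprintf("`%s` must be a single finite number", nm), call. = FALSE)
    }
  }
  for (nm in c("ul", "ci95", "si", "ei95", "pff", "portions",
               "fortified_fraction", "rda_ug")) {
    chk_num(get(nm), nm)
  }
  if (ci95 < 0) stop("`ci95` must be >= 0", call. = FALSE)
  if (ul <= ci95) stop("`ul` must exceed `ci95` (no fortification headroom)",
                       call. = FALSE)
  if (si < 0) stop("`si` must be >= 0", call. = FALSE)
  if (ei95 <= 0) stop("`ei95` must be > 0", call. = FALSE)
  if (pff <= 0 || pff > 1) stop("`pff` must be in (0, 1]", call. = FALSE)
  if (portions <= 0) stop("`portions` must be > 0", call. = FALSE)
  if (fortified_fraction <= 0 || fortified_fraction > 1) {
    stop("`fortified_fraction` must be in (0, 1]", call. = FALSE)
  }
  if (rda_ug <= 0) stop("`rda_ug` must be > 0", call. = FALSE)
  structure(
    list(ul = ul, ci95 = ci95, si = si, ei95 = ei95, pff = pff,
         portions = portions, fortified_fraction = fortified_fraction,
         rda_ug = rda_ug),
    class = "formula_inputs"
  )
}

#' Fortification headroom (margin of addition)
#'
#' The margin of addition MA = UL - CI95: the intake room left between the
#' 95th-percentile current intake and the tolerable upper level, in IOM-RDA
#' units. With UL = 100 ug and CI95 = 1 ug at RDA 20 ug this is
#' 5 - 0.05 = 4.95 IOM RDAs.
#'
#' @param ul Tolerable upper intake level, IOM-RDA units.
#' @param ci95 95th-percentile current intake, IOM-RDA units.
#' @return MA in IOM-RDA units.
#' @export
margin_of_addition <- function(ul, ci95) {
  if (!is.finite(ul) || !is.finite(ci95) || ci95 < 0) {
    stop("`ul` and `ci95` must be finite with `ci95` >= 0", call. = FALSE)
  }
  if (ul <= ci95) {
    stop("no fortification headroom: `ul` must exceed `ci95`", call. = FALSE)
  }
  ul - ci95
}

#' Safe addition per 100-kcal portion: Flynn (ILSI) model
#'
#' FA = (UL - CI95) / (fortified_fraction * portions * PFF). Supplement
#' intake is ignored by construction: the model considers vitamin D from
#' naturally occurring dietary sources only.
#'
#' @param inputs A [formula_inputs()] object.
#' @return FA in IOM-RDA units per 100-kcal portion.
#' @examples
#' flynn_fa(formula_inputs(pff = 0.11)) # 4.95 / 2.31 = 2.1428...
#' @export
flynn_fa <- function(inputs) {
  stopifnot(inherits(inputs, "formula_inputs"))
  ma <- margin_of_addition(inputs$ul, inputs$ci95)
  ma / (inputs$fortified_fraction * inputs$portions * inputs$pff)
}

#' Safe addition per 100-kcal portion: Rasmussen (DFVR) model
#'
#' FA = (UL - (CI95 + SI)) / (EI95 * PFF). Supplement intake is subtracted
#' from the headroom; the denominator is the observed 95th-percentile energy
#' intake in 100-kcal portions times the fortifiable proportion of foods.
#'
#' @inheritParams flynn_fa
#' @return FA in IOM-RDA units per 100-kcal portion.
#' @examples
#' # 400 IU/day supplement = 10 ug = 0.5 IOM-RDA units
#' rasmussen_fa(formula_inputs(si = 0.5, ei95 = 18.8, pff = 1))
#' @export
rasmussen_fa <- function(inputs) {
  stopifnot(inherits(inputs, "formula_inputs"))
  headroom <- inputs$ul - (inputs$ci95 + inputs$si)
  if (headroom <= 0) {
    stop("no fortification headroom: `ci95` + `si` must be below `ul`",
         call. = FALSE)
  }
  headroom / (inputs$ei95 * inputs$pff)
}

#' Convert a safe-addition value from IOM-RDA units to ug per 100 kcal
#'
#' @param fa Safe addition in IOM-RDA units per 100-kcal portion; >= 0.
#' @param rda_ug RDA reference in ug (default 20).
#' @return ug of vitamin D per 100-kcal portion.
#' @export
fa_to_ug_per_100kcal <- function(fa, rda_ug = 20) {
  if (any(!is.finite(fa)) || any(fa < 0)) {
    stop("`fa` must be finite and >= 0", call. = FALSE)
  }
  if (!is.finite(rda_ug) || rda_ug <= 0) stop("`rda_ug` must be > 0",
                                              call. = FALSE)
  fa * rda_ug
}

#' Safe-addition table over fortifiable-proportion scenarios
#'
#' Builds the maximum-safe-addition table: one row per combination of
#' fortifiable proportion (PFF) and model scenario, reporting FA in IOM-RDA
#' units per 100-kcal portion, as a percentage of the RDA, and in ug per
#' 100 kcal. Row-level domain errors (e.g. supplement intake exhausting the
#' headroom) abort with the offending PFF named.
#'
#' @param pff_list Numeric vector of fortifiable proportions in (0, 1].
#' @param scenarios A data frame (or tibble) with columns `model` ("flynn" or
#'   "rasmussen") and `si` (supplement intake in IOM-RDA units; ignored by
#'   Flynn rows). Defaults to Flynn with no supplement.
#' @param inputs Base [formula_inputs()]; `pff` and `si` are overridden per
#'   row.
#' @return A tibble with columns `model`, `si`, `pff`, `fa_rda_units`,
#'   `fa_percent_rda`, `fa_ug_per_100kcal`. The identities
#'   `fa_percent_rda = 100 * fa_rda_units` and
#'   `fa_ug_per_100kcal = fa_rda_units * rda_ug` hold exactly; values are
#'   stored at full precision (round for display).
#' @examples
#' safe_addition_table(c(1, 0.5, 0.25, 0.11, 0.05))
#' @export
safe_addition_table <- function(pff_list,
                                scenarios = tibble::tibble(model = "flynn",
                                                           si = 0),
                                inputs = formula_inputs()) {
  if (length(pff_list) == 0) {
    return(tibble::tibble(model = character(), si = double(), pff = double(),
                          fa_rda_units = double(), fa_percent_rda = double(),
                          fa_ug_per_100kcal = double()))
  }
  if (any(!is.finite(pff_list)) || any(pff_list <= 0) || any(pff_list > 1)) {
    stop("all `pff_list` values must be in (0, 1]", call. = FALSE)
  }
  scenarios <- tibble::as_tibble(scenarios)
  stopifnot(all(c("model", "si") %in% names(scenarios)))
  if (!all(scenarios$model %in% c("flynn", "rasmussen"))) {
    stop('`scenarios$model` must be "flynn" or "rasmussen"', call. = FALSE)
  }
  rows <- purrr::map_dfr(seq_len(nrow(scenarios)), function(j) {
    model <- scenarios$model[j]
    si <- scenarios$si[j]
    purrr::map_dfr(pff_list, function(p) {
      fi <- formula_inputs(ul = inputs$ul, ci95 = inputs$ci95, si = si,
                           ei95 = inputs$ei95, pff = p,
                           portions = inputs$portions,
                           fortified_fraction = inputs$fortified_fraction,
                           rda_ug = inputs$rda_ug)
      fa <- tryCatch(
        if (model == "flynn") flynn_fa(fi) else rasmussen_fa(fi),
        error = function(e) {
          stop(sprintf("scenario %s (si = %g) at pff = %g: %s",
                       model, si, p, conditionMessage(e)), call. = FALSE)
        }
      )
      tibble::tibble(model = model, si = si, pff = p, fa_rda_units = fa,
                     fa_percent_rda = 100 * fa,
                     fa_ug_per_100kcal = fa * inputs$rda_ug)
    })
  })
  rows
}
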