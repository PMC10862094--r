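# Independent oracles, deliberately naive: plain double loops over records
# and vehicles, no matrix algebra shared with the implementation.

oracle_added_vitd <- function(population, levels) {
  out <- numeric(nrow(population))
  for (i in seq_len(nrow(population))) {
    acc <- 0
    for (v in names(levels)) {
      col <- paste0("grams_", v)
      g <- if (col %in% names(population)) population[[col]][i] else 0
      acc <- acc + g * levels[[v]]
    }
    out[i] <- acc / 100
  }
  out
}

oracle_coverage <- function(intakes, ri, ul) {
  below <- 0; above <- 0; within <- 0
  for (x in intakes) {
    if (x < ri) below <- below + 1
    else if (x > ul) above <- above + 1
    else within <- within + 1
  }
  c(below = below / length(intakes), within = within / length(intakes),
    above = above / length(intakes))
}

# tiny hand-built population: known grams and baselines
toy_population <- function(baselines = c(2, 5, 90),
                           grams = c(100, 200, 400),
                           vehicle = "milk") {
  pop <- tibble::tibble(
    id = seq_along(baselines),
    age = 50, sex = "F",
    energy_kcal = 2000,
    baseline_vitd_ug = baselines,
    supplement_iu = 0
  )
  pop[[paste0("grams_", vehicle)]] <- grams
  pop
}

toy_vehicles <- function(names = "milk", kcal = 60) {
  tibble::tibble(name = names, kcal_per_100g = kcal, fortifiable = TRUE)
}
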