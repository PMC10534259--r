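#' Beverage categories used throughout the model
#'
#' The nine beverage categories distinguished by the consumption survey
#' structure the model emulates: carbonated soft drinks, energy and sports
#' drinks, juice and juice drinks, sweetened teas, powdered drink mixes,
#' cereal- and grain-based beverages, coffee-based beverages, milk-based
#' beverages, and a residual "other sweetened drinks" category.
#'
#' @return Character vector of length 9.
#' @export
sb_categories <- function() {
  c("soft_drinks", "energy_sports_drinks", "juice", "sweetened_tea",
    "powdered", "cereal_grain", "coffee_based", "milk_based", "other")
}

#' Age bands at which beverage consumption is reported
#'
#' Consumption surveys of the kind the model consumes report per-capita
#' beverage intake for five age bands; every single year of age maps to
#' exactly one band.
#'
#' @return Character vector of band labels, youngest first.
#' @export
age_bands <- function() {
  c("2-5", "6-12", "13-18", "19-59", "60+")
}

#' Map single years of age to consumption age bands
#'
#' @param age Integer vector of ages in years (2-100).
#' @return Character vector of band labels, same length as `age`.
#' @export
#' @examples
#' age_band(c(2, 5, 6, 13, 19, 60, 100))
age_band <- function(age) {
  stopifnot(is.numeric(age), all(age >= 2), all(age <= 100))
  bands <- age_bands()
  idx <- findInterval(age, c(2, 6, 13, 19, 60))
  bands[idx]
}

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# RNG state. All generators route randomness through this so that a
# SynthConfig seed gives byte-identical output regardless of call order.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed), kind = "Mersenne-Twister")
  expr
}

# Annual rate -> one-year transition probability. Keeps probabilities in
# [0, 1] for any non-negative rate.
rate_to_prob <- function(rate) {
  stopifnot(all(rate >= 0))
  1 - exp(-rate)
}

# Discount factor(s) for amounts accruing t whole years after the
# reference year (t = 0 is undiscounted).
discount_factor <- function(t, rate) {
  stopifnot(rate >= 0, all(t >= 0))
  (1 + rate)^(-t)
}
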