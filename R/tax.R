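#' Define a beverage-tax scenario
#'
#' A scenario is a specific (per-litre) excise design: a tax rate per
#' category (zero for excluded categories), the fraction of the tax
#' passed through to consumer prices, and the mean retail price of a
#' litre of sweetened beverages used to convert the specific rate into a
#' percentage price change. Sensitivity switches (elasticity set,
#' healthcare-cost and implementation-cost multipliers, child utility
#' set) ride along so a scenario file fully determines a model run.
#'
#' @param name Scenario name (unique within a comparison).
#' @param rate_per_litre Either a single rate (currency per litre)
#'   applied to `included_categories`, or a named vector over all
#'   categories.
#' @param included_categories Character vector of taxed categories
#'   (ignored when `rate_per_litre` is a full named vector).
#' @param pass_through Fraction of the tax reflected in consumer prices,
#'   in \[0, 1\]. Defaults to 1 (full pass-through, the empirically
#'   supported default for producer-levied specific taxes).
#' @param mean_price Mean retail price of a litre of sweetened
#'   beverages, currency per litre; must be positive.
#' @param elasticity_set Which elasticity matrix to use ("mexico" or
#'   "chile" in the bundled synthetic inputs).
#' @param healthcare_cost_multiplier Multiplier on every per-case
#'   healthcare cost (sensitivity use).
#' @param implementation_cost_multiplier Multiplier on the policy
#'   implementation/monitoring cost (sensitivity use).
#' @param child_utility_set Which child utility-weight set to use.
#' @return An object of class `tax_scenario`.
#' @export
tax_scenario <- function(name, rate_per_litre = 0,
                         included_categories = character(),
                         pass_through = 1, mean_price = 45.05,
                         elasticity_set = "mexico",
                         healthcare_cost_multiplier = 1,
                         implementation_cost_multiplier = 1,
                         child_utility_set = "default") {
  cats <- sb_categories()
  if (!is.numeric(mean_price) || length(mean_price) != 1L || mean_price <= 0)
    stop("invalid scenario: mean_price must be a single positive price")
  if (!is.numeric(pass_through) || pass_through < 0 || pass_through > 1)
    stop("invalid scenario: pass_through must lie in [0, 1]")
  if (length(rate_per_litre) == 1L && is.null(names(rate_per_litre))) {
    rate <- stats::setNames(numeric(length(cats)), cats)
    bad <- setdiff(included_categories, cats)
    if (length(bad)) stop("invalid scenario: unknown categories ",
                          paste(bad, collapse = ", "))
    rate[included_categories] <- rate_per_litre
  } else {
    if (!all(cats %in% names(rate_per_litre)))
      stop("invalid scenario: per-category rates must name all categories")
    rate <- rate_per_litre[cats]
  }
  if (any(rate < 0)) stop("invalid scenario: negative tax rate")
  structure(list(name = name, rate_per_litre = rate,
                 pass_through = pass_through, mean_price = mean_price,
                 elasticity_set = elasticity_set,
                 healthcare_cost_multiplier = healthcare_cost_multiplier,
                 implementation_cost_multiplier = implementation_cost_multiplier,
                 child_utility_set = child_utility_set),
            class = "tax_scenario")
}

#' Effective fractional price change per category under a scenario
#'
#' For a specific tax of rate tau (currency/litre) with pass-through phi
#' on beverages with mean price P (currency/litre), the consumer price of
#' a taxed category rises by the fraction phi * tau / P. Excluded
#' categories (rate 0) change by 0.
#'
#' @param scenario A [tax_scenario()].
#' @param category Optional category name(s); default all nine.
#' @return Named vector of fractional price changes (dimensionless).
#' @export
#' @examples
#' sc <- tax_scenario("uniform10", 10, sb_categories(), mean_price = 45.05)
#' effective_price_change(sc)[["soft_drinks"]]  # ~0.222
effective_price_change <- function(scenario, category = sb_categories()) {
  stopifnot(inherits(scenario, "tax_scenario"))
  if (scenario$mean_price <= 0)
    stop("invalid scenario: mean_price must be positive")
  dp <- scenario$pass_through * scenario$rate_per_litre / scenario$mean_price
  dp[category]
}

#' Apply the price-elasticity matrix to baseline consumption
#'
#' The percentage change in the consumed quantity of category j is the
#' elasticity-weighted sum of the percentage price changes of all
#' categories: dq_j = q_j * sum_k eps_jk * dp_k. Cross terms capture
#' substitution towards untaxed categories; a category with zero baseline
#' consumption has zero change.
#'
#' @param dp Named vector of fractional price changes by category.
#' @param elasticity Square elasticity matrix (rows = responding
#'   category, columns = category whose price changed).
#' @param consumption Matrix of baseline consumption, categories x
#'   groups (any number of group columns), ml/person/day; a named vector
#'   is treated as a single group.
#' @return Matrix (or vector, matching the input shape) of consumption
#'   changes in ml/person/day.
#' @export
apply_elasticities <- function(dp, elasticity, consumption) {
  vec_in <- is.null(dim(consumption))
  vec_names <- names(consumption)
  if (vec_in) consumption <- matrix(consumption, ncol = 1)
  if (!is.matrix(elasticity) || nrow(elasticity) != ncol(elasticity))
    stop("structural error: elasticity matrix must be square")
  if (length(dp) != nrow(elasticity) || nrow(consumption) != nrow(elasticity))
    stop("structural error: dp, elasticity and consumption dimensions disagree")
  if (any(!is.finite(dp)) || any(!is.finite(elasticity)))
    stop("structural error: non-finite price changes or elasticities")
  pct <- as.vector(elasticity %*% dp)   # fractional quantity change per category
  dq <- consumption * pct
  if (vec_in) stats::setNames(dq[, 1], vec_names) else dq
}

#' Convert consumption changes to daily energy-intake changes
#'
#' dE = sum_j dq_j * e_j / 100, with dq in ml/person/day and energy
#' density e in kJ per 100 ml. Zero-calorie categories contribute
#' nothing.
#'
#' @param dq Matrix (categories x groups) or named vector of consumption
#'   changes, ml/person/day.
#' @param energy_density Named vector of energy densities, kJ/100 ml,
#'   covering every category in `dq`.
#' @return Vector of energy changes by group (kJ/person/day), or a
#'   scalar for vector input.
#' @export
energy_change <- function(dq, energy_density) {
  vec_in <- is.null(dim(dq))
  if (vec_in) dq <- cbind(dq)
  cats <- rownames(dq)
  if (is.null(cats) || !all(cats %in% names(energy_density)))
    stop("structural error: missing energy density for some categories")
  e <- energy_density[cats]
  out <- as.vector(crossprod(dq, e) / 100)
  names(out) <- colnames(dq)
  if (vec_in) unname(out)[1] else out
}

#' Population-weighted mean of a per-group quantity
#'
#' @param values Numeric vector, one value per population group.
#' @param population A [generate_population()] data frame (or any data
#'   frame with a `count` column aligned with `values`).
#' @return Scalar weighted mean, sum(N_g v_g) / sum(N_g).
#' @export
weighted_mean_by_group <- function(values, population) {
  if (is.null(population$count) || nrow(population) == 0)
    stop("empty population")
  stopifnot(length(values) == nrow(population))
  sum(population$count * values) / sum(population$count)
}

#' Expand band-level consumption to population groups
#'
#' Every single year of age receives its band's per-capita consumption
#' (assignment, not interpolation — the resolution at which consumption
#' surveys report).
#'
#' @param consumption 9 x 5 matrix, categories x age bands.
#' @param population A [generate_population()] data frame.
#' @return 9 x n_groups matrix of ml/person/day, columns aligned with
#'   population rows.
#' @export
consumption_by_group <- function(consumption, population) {
  bands <- age_band(population$age)
  q <- consumption[, bands, drop = FALSE]
  colnames(q) <- paste(population$sex, population$age, sep = "_")
  q
}

#' Per-group consumption and energy changes under a tax scenario
#'
#' Chains [effective_price_change()], [apply_elasticities()] and
#' [energy_change()] over the whole population.
#'
#' @param scenario A [tax_scenario()].
#' @param inputs A [synth_inputs()] bundle (or equivalent list).
#' @return List of class `consumption_delta`: `dq` (9 x n_groups matrix,
#'   ml/person/day), `dq_total` (per-group net volume change),
#'   `dE` (per-group kJ/person/day), `q_base` (baseline matrix), and
#'   `dp` (per-category price change).
#' @export
consumption_delta <- function(scenario, inputs) {
  E <- inputs$beverages$elasticities[[scenario$elasticity_set]]
  if (is.null(E)) stop("unknown elasticity set: ", scenario$elasticity_set)
  dp <- effective_price_change(scenario)
  q <- consumption_by_group(inputs$beverages$consumption, inputs$population)
  dq <- apply_elasticities(dp, E, q)
  structure(list(dq = dq, dq_total = colSums(dq),
                 dE = energy_change(dq, inputs$beverages$energy_density),
                 q_base = q, dp = dp),
            class = "consumption_delta")
}
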