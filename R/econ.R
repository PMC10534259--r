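#' Economic parameters
#'
#' Discounting, the cost-effectiveness threshold, and the inputs needed
#' to express the policy implementation/monitoring cost in
#' reference-year local currency. The implementation cost enters as a
#' base-year figure per 10 million population (the standardised
#' costing convention for tax-policy interventions), converted with an
#' explicit exchange rate and annual inflation series — both plain
#' config inputs, never fetched.
#'
#' @param r Annual discount rate (default 0.03).
#' @param threshold Cost-effectiveness threshold, currency per HALY
#'   (default 168236, a per-capita-GDP-style threshold).
#' @param implementation_base_cost Base-year cost per 10 million
#'   population, base currency (default 5400016 USD).
#' @param exchange_rate Base-year exchange rate, local currency per unit
#'   base currency (default 45.11 PHP/USD, 2010).
#' @param inflation Annual inflation factors from base year to reference
#'   year (local CPI); their product converts base-year to
#'   reference-year prices. Default: 2011-2018 consumer-price series of
#'   roughly 1.25 cumulative.
#' @param implementation_mode "fixed_total" (the converted base figure
#'   is the national total, the published accounting convention) or
#'   "scaled" (linear in population / 10 million).
#' @return Object of class `econ_params`.
#' @export
econ_params <- function(r = 0.03, threshold = 168236,
                        implementation_base_cost = 5400016,
                        exchange_rate = 45.11,
                        inflation = c(1.047, 1.030, 1.026, 1.036,
                                      1.007, 1.013, 1.029, 1.052),
                        implementation_mode = c("fixed_total", "scaled")) {
  stopifnot(r >= 0, threshold > 0, implementation_base_cost >= 0,
            exchange_rate > 0)
  if (is.null(inflation) || any(inflation <= 0))
    stop("config error: inflation series missing or non-positive")
  structure(list(r = r, threshold = threshold,
                 implementation_base_cost = implementation_base_cost,
                 exchange_rate = exchange_rate, inflation = inflation,
                 implementation_mode = match.arg(implementation_mode)),
            class = "econ_params")
}

#' Policy implementation and monitoring cost in reference-year currency
#'
#' base cost x exchange rate x cumulative inflation, then (in "scaled"
#' mode) x population / 10^7. The cost is a one-off lifetime figure, not
#' annuitised.
#'
#' @param params An [econ_params()].
#' @param population_size Total persons in the modelled population.
#' @param multiplier Scenario multiplier (e.g. 2 for a doubled-cost
#'   sensitivity scenario).
#' @return Cost in reference-year local currency.
#' @export
intervention_cost <- function(params, population_size, multiplier = 1) {
  stopifnot(inherits(params, "econ_params"), population_size > 0)
  base <- params$implementation_base_cost * params$exchange_rate *
    prod(params$inflation)
  scale <- if (params$implementation_mode == "scaled")
    population_size / 1e7 else 1
  base * scale * multiplier
}

#' Healthcare cost offsets from averted disease cases
#'
#' Cancers are costed on incident-case deltas (a per-case lifetime
#' treatment cost attributed to the year of diagnosis); other diseases
#' on prevalent case-year deltas (an annual cost per year lived with the
#' disease). Streams are discounted to the reference year at rate `r`.
#' Averted cases (negative deltas) yield negative offsets, i.e. savings.
#'
#' @param ledger A [halys()] ledger (carries per-disease case-delta
#'   streams).
#' @param diseases The [generate_diseases()] set (cost basis and per-case
#'   costs).
#' @param r Annual discount rate.
#' @param cost_multiplier Multiplier on every per-case cost.
#' @return Discounted offset in local currency (negative = savings).
#' @export
healthcare_offsets <- function(ledger, diseases, r = 0.03,
                               cost_multiplier = 1) {
  stopifnot(inherits(ledger, "haly_ledger"))
  t <- seq_len(nrow(ledger$incident_delta)) - 1L
  disc <- discount_factor(t, r)
  total <- 0
  for (d in names(diseases)) {
    basis <- diseases[[d]]$cost_basis
    cost <- diseases[[d]]$cost_per_case * cost_multiplier
    stream <- switch(basis,
                     incident = ledger$incident_delta[, d],
                     prevalent = ledger$prev_years_delta[, d],
                     stop("unknown cost_basis: ", basis))
    total <- total + sum(stream * disc) * cost
  }
  total
}

#' Taxation revenue under a scenario
#'
#' Annual revenue is post-tax consumption volume times the per-litre
#' rate, summed over taxed categories and population groups:
#' sum_g N_g sum_j (q + dq)_{j,g} (365/1000) tau_j. Lifetime revenue
#' accrues annually over the closed cohort, weighted by the surviving
#' fraction of the population each year and discounted at `r`. Negative
#' post-tax volumes (possible under extreme elasticities) are clamped to
#' zero with a warning.
#'
#' @param delta A [consumption_delta()] for the scenario.
#' @param scenario The [tax_scenario()].
#' @param population The population data frame.
#' @param run The intervention-arm `mslt_run` (survivorship weighting).
#' @param r Annual discount rate.
#' @return List with `annual` (reference-year revenue) and `lifetime`
#'   (discounted total over the cohort's lifetime), local currency.
#' @export
tax_revenue <- function(delta, scenario, population, run, r = 0.03) {
  post <- delta$q_base + delta$dq
  if (any(post < -1e-9)) {
    warning("negative post-tax consumption clamped to zero")
    post <- pmax(post, 0)
  }
  tau <- scenario$rate_per_litre[rownames(post)]
  # litres/person/year taxed at tau, per group
  rev_per_person <- as.vector(crossprod(post, tau)) * 365 / 1000
  annual <- sum(population$count * rev_per_person)
  # per-year survivor weighting: revenue scales with each cohort's
  # surviving headcount (per-capita consumption held at its initial
  # level); run$alive is already in persons
  rev_by_year <- as.vector(run$alive %*% rev_per_person)
  t <- seq_along(rev_by_year) - 1L
  lifetime <- sum(rev_by_year * discount_factor(t, r))
  list(annual = annual, lifetime = lifetime)
}

#' ICER and dominance classification
#'
#' Net cost is healthcare offsets plus intervention cost (taxation
#' revenue is a transfer and never enters). Negative net cost with
#' positive HALYs is DOMINANT (reported categorically, not as a ratio);
#' positive net cost with negative HALYs is DOMINATED; otherwise the
#' ratio is compared against the threshold, with equality counting as
#' cost-effective.
#'
#' @param net_cost Incremental net cost (currency).
#' @param halys Incremental HALYs.
#' @param threshold Cost-effectiveness threshold (currency/HALY).
#' @return List of class `icer_result`: `verdict` ("dominant",
#'   "dominated", "ratio", or "undefined"), `icer` (ratio or NA),
#'   `cost_effective` (logical).
#' @export
icer <- function(net_cost, halys, threshold = 168236) {
  if (halys == 0) {
    return(structure(list(verdict = if (net_cost == 0) "ratio" else "undefined",
                          icer = if (net_cost == 0) 0 else NA_real_,
                          cost_effective = net_cost <= 0),
                     class = "icer_result"))
  }
  if (net_cost < 0 && halys > 0)
    return(structure(list(verdict = "dominant", icer = NA_real_,
                          cost_effective = TRUE), class = "icer_result"))
  if (net_cost > 0 && halys < 0)
    return(structure(list(verdict = "dominated", icer = NA_real_,
                          cost_effective = FALSE), class = "icer_result"))
  ratio <- net_cost / halys
  structure(list(verdict = "ratio", icer = ratio,
                 cost_effective = ratio <= threshold),
            class = "icer_result")
}

#' Relative reduction of one scenario's result against another's
#'
#' For each metric, 100 (1 - implemented/proposed): the percentage by
#' which the weaker design falls short of the stronger one.
#'
#' @param implemented,proposed Numeric vectors (aligned, same names) of
#'   headline metrics.
#' @return Named vector of percentages (NA where the proposed-scenario
#'   value is zero).
#' @export
#' @examples
#' comparative_stats(c(intake = 51.1), c(intake = 89.7))  # 43.0
comparative_stats <- function(implemented, proposed) {
  stopifnot(length(implemented) == length(proposed))
  out <- ifelse(proposed == 0, NA_real_, 100 * (1 - implemented / proposed))
  names(out) <- names(proposed)
  out
}
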