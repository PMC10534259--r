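#' Evaluate one tax scenario end-to-end against a do-nothing baseline
#'
#' Chains the full pipeline: price change, elasticity response, energy
#' intake, weight/BMI shift, proportional multi-state life table for the
#' baseline and intervention arms, incremental HALYs, healthcare
#' offsets, intervention cost, net cost, ICER and taxation revenue.
#'
#' @param scenario A [tax_scenario()].
#' @param inputs A [synth_inputs()] bundle.
#' @param econ An [econ_params()].
#' @param energy An [energy_balance_params()].
#' @param baseline_run Optional precomputed baseline `mslt_run` (must
#'   use the same child-utility set as the scenario); recomputed when
#'   omitted.
#' @return Object of class `scenario_result` with the headline metrics
#'   (all weighted means weighted by the population age-sex
#'   distribution): per-category and net consumption changes, energy,
#'   weight and BMI changes, HALYs, costs, ICER verdict and revenue.
#' @export
run_scenario <- function(scenario, inputs, econ = econ_params(),
                         energy = energy_balance_params(),
                         baseline_run = NULL) {
  delta <- consumption_delta(scenario, inputs)
  anth <- anthropometry_delta(delta, inputs$population, energy)

  if (is.null(baseline_run))
    baseline_run <- run_life_table(inputs$population, inputs$diseases,
                                   inputs$mortality, inputs$child_utility,
                                   dbmi = 0,
                                   child_utility_set = scenario$child_utility_set)
  int_run <- run_life_table(inputs$population, inputs$diseases,
                            inputs$mortality, inputs$child_utility,
                            dbmi = anth$dbmi,
                            child_utility_set = scenario$child_utility_set)
  ledger <- halys(baseline_run, int_run, econ$r)
  offsets <- healthcare_offsets(ledger, inputs$diseases, econ$r,
                                scenario$healthcare_cost_multiplier)
  impl <- intervention_cost(econ, sum(inputs$population$count),
                            scenario$implementation_cost_multiplier)
  net <- offsets + impl
  verdict <- icer(net, ledger$halys, econ$threshold)
  rev <- tax_revenue(delta, scenario, inputs$population, int_run, econ$r)

  wm <- function(v) weighted_mean_by_group(v, inputs$population)
  dq_cat <- apply(delta$dq, 1, wm)

  structure(list(
    name = scenario$name, scenario = scenario,
    dq_by_category = dq_cat,
    dq_total = wm(delta$dq_total),
    dE = wm(delta$dE), dw = wm(anth$dw), dbmi = wm(anth$dbmi),
    halys = ledger$halys, halys_undiscounted = ledger$halys_undiscounted,
    intervention_cost = impl, healthcare_offsets = offsets, net_cost = net,
    icer = verdict, revenue_annual = rev$annual,
    revenue_lifetime = rev$lifetime,
    ledger = ledger, delta = delta, anthropometry = anth,
    baseline_run = baseline_run, intervention_run = int_run
  ), class = "scenario_result")
}

#' @noRd
#' @export
print.scenario_result <- function(x, ...) {
  cat("Tax scenario:", x$name, "\n")
  cat(sprintf("  net consumption change : %8.2f ml/person/day\n", x$dq_total))
  cat(sprintf("  energy intake change   : %8.2f kJ/person/day\n", x$dE))
  cat(sprintf("  weight change          : %8.3f kg/person\n", x$dw))
  cat(sprintf("  BMI change             : %8.3f kg/m2\n", x$dbmi))
  cat(sprintf("  incremental HALYs      : %12.0f\n", x$halys))
  cat(sprintf("  intervention cost      : %12.0f\n", x$intervention_cost))
  cat(sprintf("  healthcare offsets     : %12.0f\n", x$healthcare_offsets))
  cat(sprintf("  net cost               : %12.0f\n", x$net_cost))
  cat(sprintf("  ICER                   : %s\n",
              if (x$icer$verdict == "ratio") format(x$icer$icer)
              else x$icer$verdict))
  cat(sprintf("  revenue (annual/life)  : %12.0f / %12.0f\n",
              x$revenue_annual, x$revenue_lifetime))
  invisible(x)
}

#' Run a set of scenarios against the shared do-nothing baseline
#'
#' Every scenario is evaluated incrementally against do-nothing;
#' scenario-versus-scenario contrasts come from [comparative_stats()] on
#' the headline metrics, never from differencing life tables directly.
#'
#' @param scenarios Named list of [tax_scenario()]s (or character vector
#'   of bundled scenario names).
#' @param inputs A [synth_inputs()] bundle.
#' @param econ An [econ_params()].
#' @param energy An [energy_balance_params()].
#' @return Object of class `comparison_result`: `results` (list of
#'   `scenario_result`s), `consumption_table` and `cost_utility_table`
#'   data frames, and `comparative` (implemented-vs-proposed relative
#'   reductions, when both scenarios are present).
#' @export
run_comparison <- function(scenarios, inputs, econ = econ_params(),
                           energy = energy_balance_params()) {
  if (is.character(scenarios)) scenarios <- bundled_scenarios(scenarios)
  nm <- vapply(scenarios, `[[`, character(1), "name")
  names(scenarios) <- nm

  # one baseline life-table run per child-utility set in use
  cu_sets <- unique(vapply(scenarios, `[[`, character(1), "child_utility_set"))
  baselines <- lapply(cu_sets, function(s)
    run_life_table(inputs$population, inputs$diseases, inputs$mortality,
                   inputs$child_utility, dbmi = 0, child_utility_set = s))
  names(baselines) <- cu_sets

  results <- lapply(scenarios, function(sc)
    run_scenario(sc, inputs, econ, energy,
                 baseline_run = baselines[[sc$child_utility_set]]))

  cons <- do.call(rbind, lapply(results, function(r)
    data.frame(scenario = r$name, t(r$dq_by_category),
               total = r$dq_total, dE = r$dE, dw = r$dw, dbmi = r$dbmi,
               row.names = NULL)))
  cu <- do.call(rbind, lapply(results, function(r)
    data.frame(scenario = r$name, halys = r$halys,
               intervention_cost = r$intervention_cost,
               healthcare_offsets = r$healthcare_offsets,
               net_cost = r$net_cost,
               icer = if (r$icer$verdict == "ratio") r$icer$icer else NA,
               verdict = r$icer$verdict,
               revenue_annual = r$revenue_annual,
               revenue_lifetime = r$revenue_lifetime, row.names = NULL)))

  comparative <- NULL
  if (all(c("implemented", "proposed") %in% nm)) {
    pick <- function(r) c(intake_reduction = -r$dq_total,
                          bmi_reduction = -r$dbmi,
                          halys = r$halys,
                          healthcare_savings = -r$healthcare_offsets,
                          revenue_annual = r$revenue_annual,
                          revenue_lifetime = r$revenue_lifetime)
    comparative <- comparative_stats(pick(results[["implemented"]]),
                                     pick(results[["proposed"]]))
  }

  structure(list(results = results, consumption_table = cons,
                 cost_utility_table = cu, comparative = comparative),
            class = "comparison_result")
}

#' Run the bundled sensitivity suite
#'
#' Evaluates the proposed and implemented designs plus sensitivity
#' scenarios A-G on the same inputs.
#'
#' @inheritParams run_comparison
#' @return A `comparison_result` over the nine bundled policy scenarios.
#' @export
run_sensitivity_suite <- function(inputs, econ = econ_params(),
                                  energy = energy_balance_params()) {
  run_comparison(c("proposed", "implemented", paste0("scenario_", letters[1:7])),
                 inputs, econ, energy)
}

# Apply one PSA parameter draw to the input bundle / scenario knobs.
perturb_inputs <- function(inputs, params) {
  out <- inputs
  out$beverages$consumption <- inputs$beverages$consumption *
    (params$consumption_mult %||% 1)
  out$beverages$energy_density <- inputs$beverages$energy_density *
    (params$energy_density_mult %||% 1)
  out$beverages$elasticities <- lapply(inputs$beverages$elasticities,
                                       function(E) E * (params$elasticity_mult %||% 1))
  out$diseases <- lapply(inputs$diseases, function(d) {
    d$log_rr_per_bmi <- d$log_rr_per_bmi * (params$rr_mult %||% 1)
    d$disability_weight <- min(d$disability_weight * (params$dw_mult %||% 1),
                               0.95)
    d$cost_per_case <- d$cost_per_case * (params$cost_mult %||% 1)
    d
  })
  class(out$diseases) <- "disease_set"
  out
}

#' Probabilistic sensitivity analysis of one scenario
#'
#' Wraps [run_psa()] around the full pipeline: each repetition redraws
#' the uncertain inputs (consumption level, elasticity strength, energy
#' density, BMI relative risks, disability weights, per-case and
#' implementation costs), reruns both life-table arms, and records the
#' headline metrics. The ICER verdict is tallied per draw.
#'
#' @param scenario A [tax_scenario()].
#' @param inputs A [synth_inputs()] bundle.
#' @param econ An [econ_params()].
#' @param energy An [energy_balance_params()].
#' @param distributions List of [dist_spec()]s
#'   (default [default_distributions()]).
#' @param n_reps Monte Carlo repetitions (default 2000).
#' @param seed Master seed.
#' @return An `mc_result` over metrics `halys`, `intervention_cost`,
#'   `healthcare_offsets`, `net_cost`, `icer`, `verdict_dominant`,
#'   `revenue_annual`, `revenue_lifetime`, `intake_change`, `dbmi`.
#' @export
pipeline_psa <- function(scenario, inputs, econ = econ_params(),
                         energy = energy_balance_params(),
                         distributions = default_distributions(),
                         n_reps = 2000, seed = 1L) {
  model <- function(params) {
    pin <- perturb_inputs(inputs, params)
    impl_mult <- (params$impl_cost_mult %||% 1)
    sc <- scenario
    sc$implementation_cost_multiplier <-
      scenario$implementation_cost_multiplier * impl_mult
    r <- run_scenario(sc, pin, econ, energy)
    c(halys = r$halys,
      intervention_cost = r$intervention_cost,
      healthcare_offsets = r$healthcare_offsets,
      net_cost = r$net_cost,
      icer = r$net_cost / r$halys,
      verdict_dominant = as.numeric(r$icer$verdict == "dominant"),
      revenue_annual = r$revenue_annual,
      revenue_lifetime = r$revenue_lifetime,
      intake_change = r$dq_total,
      dbmi = r$dbmi)
  }
  run_psa(model, distributions, n_reps = n_reps, seed = seed)
}
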