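#' Potential impact fraction for a BMI distribution shift
#'
#' For a log-linear risk relation RR(BMI) = exp(beta * BMI) and a pure
#' location shift of the BMI distribution by `dbmi`, the potential impact
#' fraction — the proportional change in incidence — has the closed form
#' PIF = 1 - exp(beta * dbmi). A downward shift (dbmi < 0) with beta > 0
#' gives PIF > 0 (incidence falls). The quadrature method integrates the
#' risk function over the full (normal) BMI distribution before and after
#' the shift; for pure location shifts it agrees with the closed form and
#' serves as a numerical cross-check.
#'
#' @param dbmi BMI shift(s), kg/m^2 (vectorised for the closed form).
#' @param log_rr Log relative risk per 1 kg/m^2 (beta >= 0).
#' @param method "closed" (default) or "quadrature".
#' @param bmi_mean,bmi_sd Baseline BMI distribution parameters, required
#'   for the quadrature method.
#' @return PIF value(s) in (-Inf, 1].
#' @export
pif <- function(dbmi, log_rr, method = c("closed", "quadrature"),
                bmi_mean = NULL, bmi_sd = NULL) {
  method <- match.arg(method)
  stopifnot(all(log_rr >= 0))
  if (method == "closed") return(1 - exp(log_rr * dbmi))
  stopifnot(length(dbmi) == 1, !is.null(bmi_mean), !is.null(bmi_sd), bmi_sd > 0)
  mean_rr <- function(mu) {
    stats::integrate(function(b) exp(log_rr * b) * stats::dnorm(b, mu, bmi_sd),
                     lower = mu - 10 * bmi_sd, upper = mu + 10 * bmi_sd,
                     rel.tol = 1e-10)$value
  }
  1 - mean_rr(bmi_mean + dbmi) / mean_rr(bmi_mean)
}

#' One annual cycle of the zero-remission illness-death process
#'
#' Transition probabilities are applied to the healthy (S) and diseased
#' (C) occupancies: C' = C (1 - f) + S i, S' = S (1 - i), and C f dies of
#' the disease this cycle. Arguments are one-year transition
#' probabilities (convert rates with `1 - exp(-rate)` first).
#'
#' @param S,C Healthy and diseased occupancies (any non-negative scale;
#'   vectorised).
#' @param i Adjusted incidence probability (already scaled by 1 - PIF
#'   where applicable).
#' @param f Case-fatality probability.
#' @return List with updated `S`, `C`, and `deaths` (of disease, this
#'   cycle).
#' @export
step_disease <- function(S, C, i, f) {
  stopifnot(all(i >= 0), all(i <= 1), all(f >= 0), all(f <= 1))
  if (any(S < 0) || any(C < 0))
    stop("internal error: negative state occupancy")
  deaths <- C * f
  list(S = S * (1 - i), C = C * (1 - f) + S * i, deaths = deaths)
}

# Pack the per-disease age-sex rate tables into arrays indexed
# [age-index, sex, disease] for fast lookup inside the annual loop.
disease_arrays <- function(diseases) {
  n_age <- length(model_ages())
  nd <- length(diseases)
  arr <- function(field) {
    a <- array(0, dim = c(n_age, 2, nd),
               dimnames = list(model_ages(), c("female", "male"),
                               names(diseases)))
    for (d in seq_len(nd)) a[, , d] <- diseases[[d]][[field]]
    a
  }
  list(incidence = arr("incidence"), prevalence = arr("prevalence"),
       case_fatality = arr("case_fatality"),
       log_rr = vapply(diseases, `[[`, numeric(1), "log_rr_per_bmi"),
       dw = vapply(diseases, `[[`, numeric(1), "disability_weight"))
}

#' Run the proportional multi-state life table for one arm
#'
#' Simulates every sex-by-age cohort of the closed population forward in
#' annual cycles until age 100. Each cohort carries, per disease, a
#' zero-remission illness-death process (healthy, diseased,
#' dead-of-disease) whose incidence is scaled by 1 - PIF, where the PIF
#' derives from the cohort's (lifelong) BMI shift. Total mortality each
#' year is the other-cause background schedule plus the current modelled
#' disease mortality, so averted disease deaths extend survivorship.
#' Morbidity Y is prevalence-weighted disability over the nine diseases,
#' plus, at ages below 19, utility decrements for overweight and obesity
#' prevalence computed from the (shifted) within-group BMI distribution.
#' Health-adjusted person-years accrue as L (1 - Y) with midpoint
#' person-years L.
#'
#' The other-cause background schedule is the all-cause table net of the
#' disease mortality implied by the disease specs, so a run with a zero
#' BMI shift reproduces the all-cause envelope exactly.
#'
#' @param population A [generate_population()] data frame.
#' @param diseases A [generate_diseases()] result.
#' @param mortality All-cause mortality matrix from
#'   [generate_mortality()].
#' @param child_utility A [generate_child_utility()] result.
#' @param dbmi Per-cohort lifelong BMI shift, kg/m^2: scalar 0 for the
#'   baseline arm or a vector aligned with population rows.
#' @param child_utility_set Name of the child utility-weight set.
#' @param trace If `TRUE`, also return per-year per-cohort per-disease
#'   state occupancies and cumulative deaths (for audits and tests).
#' @return Object of class `mslt_run`: matrices `alive` (start-of-year
#'   persons, years x cohorts), `person_years`, `hapy` (health-adjusted
#'   person-years), `incident` and `prev_years` (years x diseases,
#'   persons), and bookkeeping needed by downstream costing.
#' @export
run_life_table <- function(population, diseases, mortality, child_utility,
                           dbmi = 0, child_utility_set = "default",
                           trace = FALSE) {
  stopifnot(inherits(population, "population_spec"))
  ng <- nrow(population)
  nd <- length(diseases)
  if (length(dbmi) == 1L) dbmi <- rep(dbmi, ng)
  stopifnot(length(dbmi) == ng)

  ages <- model_ages()
  n_age <- length(ages)
  arrs <- disease_arrays(diseases)
  sex_idx <- ifelse(population$sex == "male", 2L, 1L)
  a0 <- population$age

  # other-cause mortality: all-cause net of modelled disease deaths
  dis_mort <- matrix(0, n_age, 2)
  for (d in seq_len(nd))
    dis_mort <- dis_mort + arrs$prevalence[, , d] * arrs$case_fatality[, , d]
  m_other <- pmax(unclass(mortality) - dis_mort, 0)

  # anthropometry by (age, sex) for childhood BMI-distribution lookups
  bmi_mean_tab <- bmi_sd_tab <- matrix(NA_real_, n_age, 2)
  bmi_mean_tab[cbind(population$age - 1L, sex_idx)] <- population$mean_bmi
  bmi_sd_tab[cbind(population$age - 1L, sex_idx)] <- population$bmi_sd
  thr <- child_utility$thresholds
  u <- child_utility$sets[[child_utility_set]]
  if (is.null(u)) stop("unknown child utility set: ", child_utility_set)
  thr_ow <- thr_ob <- matrix(NA_real_, 17, 2)   # ages 2..18
  thr_sex <- ifelse(thr$sex == "male", 2L, 1L)
  thr_ow[cbind(thr$age - 1L, thr_sex)] <- thr$overweight_bmi
  thr_ob[cbind(thr$age - 1L, thr_sex)] <- thr$obese_bmi

  # per-cohort per-disease lifelong PIF (1 row per cohort)
  pif_mat <- 1 - exp(outer(dbmi, arrs$log_rr))

  # state: per cohort x disease healthy/diseased occupancy (per person
  # alive of the disease submodel cohort), initialised at the cohort's
  # starting-age prevalence
  C <- matrix(0, ng, nd)
  for (d in seq_len(nd))
    C[, d] <- arrs$prevalence[cbind(a0 - 1L, sex_idx, d)]
  S <- 1 - C
  cum_dd <- matrix(0, ng, nd)    # cumulative disease deaths (submodel)

  ell <- rep(1, ng)              # survivorship, fraction of cohort
  cum_death <- rep(0, ng)
  N <- population$count

  n_years <- n_age                 # a cohort starting at age 2 lives <= 99 cycles
  alive <- person_years <- hapy <- matrix(0, n_years, ng)
  incident <- prev_years <- matrix(0, n_years, nd,
                                   dimnames = list(NULL, names(diseases)))
  trace_store <- if (trace) vector("list", n_years) else NULL

  for (t in seq_len(n_years) - 1L) {
    a <- a0 + t
    act <- which(a <= 100L & ell > 0)
    if (!length(act)) break
    ai <- a[act] - 1L
    si <- sex_idx[act]

    tot <- S[act, , drop = FALSE] + C[act, , drop = FALSE]
    prev <- ifelse(tot > 0, C[act, , drop = FALSE] / tot, 0)

    # morbidity: prevalence-weighted disability + child overweight/obesity
    Y <- as.vector(prev %*% arrs$dw)
    child <- which(a[act] < 19L)
    if (length(child)) {
      ci <- act[child]
      mu <- bmi_mean_tab[cbind(a[ci] - 1L, sex_idx[ci])] + dbmi[ci]
      sd_ <- bmi_sd_tab[cbind(a[ci] - 1L, sex_idx[ci])]
      p_ob <- bmi_exceedance(mu, sd_, thr_ob[cbind(a[ci] - 1L, sex_idx[ci])])
      p_ow <- bmi_exceedance(mu, sd_, thr_ow[cbind(a[ci] - 1L, sex_idx[ci])]) - p_ob
      Y[child] <- Y[child] + u[["overweight"]] * p_ow + u[["obese"]] * p_ob
    }
    Y <- pmin(Y, 0.999)

    # transition probabilities at the current age
    p_inc <- p_cf <- matrix(0, length(act), nd)
    for (d in seq_len(nd)) {
      i_adj <- arrs$incidence[cbind(ai, si, d)] * (1 - pif_mat[act, d])
      p_inc[, d] <- rate_to_prob(pmax(i_adj, 0))
      p_cf[, d] <- rate_to_prob(arrs$case_fatality[cbind(ai, si, d)])
    }

    # mortality: other-cause background + current modelled disease deaths
    q_dis <- prev * p_cf
    q_tot <- pmin(rate_to_prob(m_other[cbind(ai, si)]) + rowSums(q_dis), 1)

    ell_new <- ell[act] * (1 - q_tot)
    L <- (ell[act] + ell_new) / 2

    alive[t + 1L, act] <- N[act] * ell[act]
    person_years[t + 1L, act] <- N[act] * L
    hapy[t + 1L, act] <- N[act] * L * (1 - Y)

    healthy_share <- ifelse(tot > 0, S[act, , drop = FALSE] / tot, 0)
    inc_persons <- (N[act] * ell[act]) * healthy_share * p_inc
    incident[t + 1L, ] <- colSums(inc_persons)
    prev_years[t + 1L, ] <- colSums((N[act] * L) * prev)

    stepped <- step_disease(S[act, , drop = FALSE], C[act, , drop = FALSE],
                            p_inc, p_cf)
    S[act, ] <- stepped$S
    C[act, ] <- stepped$C
    cum_dd[act, ] <- cum_dd[act, ] + stepped$deaths
    cum_death[act] <- cum_death[act] + ell[act] * q_tot
    ell[act] <- ell_new
    # cohorts whose final modelled age (100) was just simulated are done
    done <- act[a[act] == 100L]
    ell[done] <- 0

    if (trace) trace_store[[t + 1L]] <- list(S = S, C = C, cum_dd = cum_dd,
                                             ell = ell, cum_death = cum_death)
  }

  structure(list(alive = alive, person_years = person_years, hapy = hapy,
                 incident = incident, prev_years = prev_years,
                 final = list(S = S, C = C, cum_dd = cum_dd, ell = ell,
                              cum_death = cum_death),
                 population = population, dbmi = dbmi,
                 trace = trace_store),
            class = "mslt_run")
}

#' Incremental HALYs and case streams between two life-table arms
#'
#' Differences the intervention arm against the baseline arm year by
#' year: incremental health-adjusted person-years are discounted to the
#' reference year at rate `r` (year 0 undiscounted); incident-case
#' deltas are reported undiscounted.
#'
#' @param baseline,intervention `mslt_run` objects over the same
#'   population and horizon.
#' @param r Annual discount rate (default 0.03).
#' @return Object of class `haly_ledger`: `halys` (discounted total),
#'   `halys_undiscounted`, `by_year` data frame, `incident_delta` and
#'   `prev_years_delta` (years x diseases person matrices,
#'   intervention minus baseline), and `r`.
#' @export
halys <- function(baseline, intervention, r = 0.03) {
  stopifnot(inherits(baseline, "mslt_run"), inherits(intervention, "mslt_run"))
  if (!identical(dim(baseline$hapy), dim(intervention$hapy)))
    stop("structural error: mismatched horizons")
  d_hapy <- rowSums(intervention$hapy) - rowSums(baseline$hapy)
  t <- seq_along(d_hapy) - 1L
  disc <- discount_factor(t, r)
  structure(list(
    halys = sum(d_hapy * disc),
    halys_undiscounted = sum(d_hapy),
    by_year = data.frame(year = t, d_hapy = d_hapy,
                         d_hapy_discounted = d_hapy * disc),
    incident_delta = intervention$incident - baseline$incident,
    prev_years_delta = intervention$prev_years - baseline$prev_years,
    r = r
  ), class = "haly_ledger")
}
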