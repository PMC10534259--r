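#' Configuration for the synthetic-input generators
#'
#' All synthetic inputs are pure functions of this configuration: the same
#' seed produces byte-identical tables. `scale` multiplies population
#' counts only; per-capita quantities are unaffected.
#'
#' @param seed Integer RNG seed.
#' @param scale Positive population multiplier (1 = a population of
#'   roughly 100 million, the size of a large lower-middle-income
#'   country).
#' @param noise Named list of relative noise levels (standard deviations
#'   of multiplicative jitter) for each generated table:
#'   `population`, `consumption`, `elasticity`, `disease`.
#' @param sex_stratified_consumption Logical; if `TRUE`, beverage
#'   consumption is jittered separately by sex. Off by default: the
#'   survey convention the generator emulates reports men and women
#'   combined within each age band.
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(seed = 1L, scale = 1,
                         noise = list(population = 0.02, consumption = 0.05,
                                      elasticity = 0.03, disease = 0.05),
                         sex_stratified_consumption = FALSE) {
  if (!is.numeric(scale) || length(scale) != 1L || !is.finite(scale) || scale <= 0)
    stop("invalid config: `scale` must be a single positive number")
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("invalid config: `seed` must be a single integer")
  defaults <- list(population = 0.02, consumption = 0.05,
                   elasticity = 0.03, disease = 0.05)
  noise <- utils::modifyList(defaults, as.list(noise))
  stopifnot(all(unlist(noise) >= 0))
  structure(list(seed = as.integer(seed), scale = scale, noise = noise,
                 sex_stratified_consumption = isTRUE(sex_stratified_consumption)),
            class = "synth_config")
}

# Model age range: a closed cohort followed from ages 2 through 100.
model_ages <- function() 2:100

#' Generate a synthetic closed-cohort population with anthropometry
#'
#' Produces one row per sex and single year of age 2-100 (198 groups):
#' population count, mean height, mean weight (hence mean BMI), and the
#' spread of the BMI distribution within the group. The age pyramid,
#' growth curve and BMI-by-age pattern are shaped like those of a young,
#' lower-middle-income population: counts decay with age, children are
#' shorter and lighter than adults, mean BMI rises from mid-teens in
#' early childhood to the low twenties in adulthood.
#'
#' @param config A [synth_config()].
#' @return A data frame of class `population_spec` with columns `sex`
#'   ("female"/"male"), `age`, `count`, `mean_height` (m), `mean_weight`
#'   (kg), `mean_bmi` (kg/m^2) and `bmi_sd` (kg/m^2), plus a
#'   `reference_year` attribute.
#' @export
generate_population <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  ages <- model_ages()
  grid <- expand.grid(age = ages, sex = c("female", "male"),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid <- grid[, c("sex", "age")]

  with_seed(config$seed + 101L, {
    a <- grid$age
    male <- grid$sex == "male"

    # age pyramid: exponential decay from ~1.6M per sex-age at age 2
    base_count <- 1.6e6 * exp(-0.030 * (a - 2))
    count <- config$scale * base_count *
      exp(stats::rnorm(nrow(grid), 0, config$noise$population))

    adult_h <- ifelse(male, 1.63, 1.50)
    growth <- pmin(1, ((a - 1) / 18)^0.8)
    height <- 0.78 + (adult_h - 0.78) * growth
    height <- height * exp(stats::rnorm(nrow(grid), 0, 0.005))

    adult_bmi <- ifelse(male, 22.6, 23.2)
    bmi <- 15.8 + (adult_bmi - 15.8) * pmin(1, ((a - 2) / 28))^1.1
    bmi <- bmi * exp(stats::rnorm(nrow(grid), 0, 0.01))
    bmi_sd <- 2 + 2.2 * pmin(1, (a - 2) / 17)

    out <- data.frame(sex = grid$sex, age = a, count = count,
                      mean_height = height, mean_weight = bmi * height^2,
                      mean_bmi = bmi, bmi_sd = bmi_sd,
                      stringsAsFactors = FALSE)
    attr(out, "reference_year") <- 2018L
    class(out) <- c("population_spec", "data.frame")
    out
  })
}

# Baseline per-capita consumption (ml/person/day) for the adult (19-59)
# band, and band multipliers. Adult values are loosely sized so that the
# population-weighted per-category reductions under a ~13% price increase
# land in the single-digit-to-low-tens of ml range typical of specific SB
# taxes; coffee-based volume is modest (powdered 3-in-1 servings are
# small) and milk-based drinks skew towards young children.
synth_adult_ml <- function() {
  c(soft_drinks = 62, energy_sports_drinks = 81, juice = 77,
    sweetened_tea = 84, powdered = 41, cereal_grain = 48,
    coffee_based = 26, milk_based = 25, other = 50)
}

synth_band_mult <- function() {
  m <- matrix(rep(c(0.35, 0.60, 0.90, 1.00, 0.70), each = 9),
              nrow = 9, dimnames = list(sb_categories(), age_bands()))
  m["coffee_based", ] <- c(0.05, 0.20, 0.60, 1.00, 1.10)
  m["milk_based", ]   <- c(2.50, 1.50, 1.00, 0.60, 0.50)
  m["energy_sports_drinks", ] <- c(0.05, 0.30, 1.00, 1.00, 0.40)
  m
}

# Energy densities, kJ per 100 ml as consumed. Sugar-sweetened soft
# drinks ~174, sports/energy ~191, juices ~184, milk- and grain-based
# ~266, coffee-based ~260; teas and reconstituted powders are lighter.
synth_energy_density <- function() {
  c(soft_drinks = 174, energy_sports_drinks = 191, juice = 184,
    sweetened_tea = 120, powdered = 150, cereal_grain = 266,
    coffee_based = 260, milk_based = 266, other = 174)
}

#' Generate synthetic beverage consumption and price-elasticity inputs
#'
#' Builds (i) a beverage table: per-capita consumption (ml/person/day) of
#' the nine beverage categories for each of the five age bands, plus
#' energy densities (kJ/100 ml); and (ii) own- and cross-price elasticity
#' matrices for two elasticity sets ("mexico", the default set, and
#' "chile", an alternative with stronger own-price responses). Own-price
#' elasticities are negative (demand law); coffee- and milk-based
#' beverages carry small positive cross-price elasticities with respect
#' to the other categories, so substitution towards untaxed beverages is
#' exercised whenever those categories are excluded from a tax.
#'
#' @param config A [synth_config()].
#' @return A list of class `beverage_inputs` with elements
#'   `consumption` (9 x 5 matrix, categories x bands, ml/person/day),
#'   `energy_density` (named vector, kJ/100 ml), and `elasticities`
#'   (named list of 9 x 9 matrices; rows = responding category, columns =
#'   category whose price changes).
#' @export
generate_beverages <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  cats <- sb_categories()

  with_seed(config$seed + 202L, {
    cons <- synth_adult_ml() * synth_band_mult()
    cons <- cons * matrix(exp(stats::rnorm(length(cons), 0, config$noise$consumption)),
                          nrow = nrow(cons))
    dimnames(cons) <- list(cats, age_bands())

    own <- c(soft_drinks = -1.06, energy_sports_drinks = -1.16, juice = -1.12,
             sweetened_tea = -1.09, powdered = -1.05, cereal_grain = -1.02,
             coffee_based = -0.95, milk_based = -0.85, other = -1.08)
    E <- matrix(0, 9, 9, dimnames = list(cats, cats))
    # substitution towards coffee- and milk-based drinks when other
    # categories become dearer
    E["coffee_based", setdiff(cats, "coffee_based")] <- 0.010
    E["milk_based", setdiff(cats, "milk_based")] <- 0.003
    diag(E) <- own
    jitter <- matrix(stats::rnorm(81, 0, config$noise$elasticity), 9, 9)
    E_mex <- E + jitter * (E != 0)          # perturb only structural entries
    diag(E_mex) <- pmin(diag(E_mex), -0.1)  # own-price entries stay negative
    E_mex[E_mex != 0 & row(E_mex) != col(E_mex)] <-
      pmax(E_mex[E_mex != 0 & row(E_mex) != col(E_mex)], 0.0005)
    attr(E_mex, "label") <- "mexico"

    E_chl <- E_mex
    diag(E_chl) <- 1.35 * diag(E_mex)
    attr(E_chl, "label") <- "chile"

    structure(list(consumption = cons,
                   energy_density = synth_energy_density(),
                   elasticities = list(mexico = E_mex, chile = E_chl)),
              class = "beverage_inputs")
  })
}

# ---- diseases ----------------------------------------------------------

# Scalar attributes of the nine obesity-related model diseases:
# log relative risk of incidence per 1 kg/m^2 of BMI, disability weight,
# costing basis (cancers are costed per incident case, other diseases per
# prevalent case-year), annual cost per case (local currency), and
# whether the disease occurs in one sex only.
disease_meta <- function() {
  data.frame(
    name = c("type_2_diabetes", "hypertensive_heart_disease",
             "ischaemic_heart_disease", "stroke", "osteoarthritis",
             "kidney_cancer", "colorectal_cancer", "endometrial_cancer",
             "breast_cancer"),
    log_rr_per_bmi = c(0.18, 0.10, 0.065, 0.060, 0.050,
                       0.060, 0.030, 0.090, 0.020),
    disability_weight = c(0.07, 0.08, 0.08, 0.25, 0.12,
                          0.25, 0.20, 0.29, 0.28),
    cost_basis = c(rep("prevalent", 5), rep("incident", 4)),
    cost_per_case = c(3000, 4000, 8000, 10000, 2500,
                      120000, 100000, 110000, 90000),
    sex_limit = c(NA, NA, NA, NA, NA, NA, NA, "female", "female"),
    stringsAsFactors = FALSE
  )
}

# Smooth adult incidence / case-fatality curve: zero before age 19
# (model diseases are treated as adult-onset), exponential in age above
# the anchor, capped.
adult_curve <- function(age, at50, slope, cap) {
  v <- at50 * exp(slope * (age - 50))
  v <- pmin(v, cap)
  v[age < 19] <- 0
  v
}

# Forward illness-death cohort recursion under zero remission.
# Given annual incidence and case-fatality rates over ages 2..100,
# returns the prevalence each age implies for a cohort disease-free at
# age 2: healthy -> diseased at i, diseased -> dead-of-disease at f.
implied_prevalence <- function(incidence, case_fatality, p_init = 0) {
  n <- length(incidence)
  stopifnot(length(case_fatality) == n, p_init >= 0, p_init < 1)
  p <- numeric(n)
  s <- 1 - p_init
  c_ <- p_init
  p[1] <- p_init
  for (k in seq_len(n - 1)) {
    pi_ <- rate_to_prob(incidence[k])
    pf_ <- rate_to_prob(case_fatality[k])
    c_new <- c_ * (1 - pf_) + s * pi_
    s_new <- s * (1 - pi_)
    s <- s_new; c_ <- c_new
    p[k + 1] <- if (s + c_ > 0) c_ / (s + c_) else 0
  }
  p
}

#' Generate internally consistent synthetic disease epidemiology
#'
#' For each of the nine obesity-related model diseases, generates annual
#' incidence and case-fatality rates by sex and single year of age
#' (2-100), then *derives* prevalence by the forward illness-death cohort
#' recursion with zero remission (healthy to diseased at the incidence
#' rate, diseased to dead-of-disease at the case fatality rate). The
#' three rate sets are therefore mutually consistent by construction —
#' [check_consistency()] returns a residual at numerical zero — which is
#' the property a rate-consistency tool would otherwise have to impose on
#' independently sourced rates. Sex-specific cancers (endometrial,
#' breast) have zero rates in males.
#'
#' @param config A [synth_config()].
#' @return A list of class `disease_set`: one element per disease, each a
#'   list with `name`, `incidence`, `prevalence`, `case_fatality` (each a
#'   99 x 2 matrix, ages 2-100 by sex `female`/`male`, per person per
#'   year), `log_rr_per_bmi`, `disability_weight`, `cost_basis`
#'   ("incident" or "prevalent"), and `cost_per_case`.
#' @export
generate_diseases <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  meta <- disease_meta()
  ages <- model_ages()

  # anchor incidence at age 50 and case fatality levels per disease
  inc50 <- c(type_2_diabetes = 4.0e-3, hypertensive_heart_disease = 1.2e-3,
             ischaemic_heart_disease = 2.5e-3, stroke = 1.5e-3,
             osteoarthritis = 3.0e-3, kidney_cancer = 6e-5,
             colorectal_cancer = 2.5e-4, endometrial_cancer = 1.5e-4,
             breast_cancer = 6e-4)
  inc_slope <- c(0.030, 0.050, 0.055, 0.065, 0.040, 0.050, 0.055, 0.040, 0.020)
  cf50 <- c(type_2_diabetes = 8e-3, hypertensive_heart_disease = 2.0e-2,
            ischaemic_heart_disease = 4.0e-2, stroke = 5.0e-2,
            osteoarthritis = 1e-5, kidney_cancer = 1.2e-1,
            colorectal_cancer = 1.0e-1, endometrial_cancer = 6e-2,
            breast_cancer = 5e-2)
  cf_slope <- c(0.040, 0.045, 0.050, 0.055, 0.000, 0.020, 0.020, 0.020, 0.020)

  with_seed(config$seed + 303L, {
    out <- vector("list", nrow(meta))
    for (d in seq_len(nrow(meta))) {
      inc <- prev <- cf <- matrix(0, length(ages), 2,
                                  dimnames = list(ages, c("female", "male")))
      for (sx in c("female", "male")) {
        if (!is.na(meta$sex_limit[d]) && meta$sex_limit[d] != sx) next
        sex_mult <- if (sx == "male") exp(stats::rnorm(1, 0, 0.1)) else 1
        jit_i <- exp(stats::rnorm(1, 0, config$noise$disease))
        jit_f <- exp(stats::rnorm(1, 0, config$noise$disease))
        i_a <- adult_curve(ages, inc50[d] * sex_mult * jit_i,
                           inc_slope[d], cap = 0.05)
        f_a <- adult_curve(ages, cf50[d] * jit_f, cf_slope[d], cap = 0.5)
        inc[, sx] <- i_a
        cf[, sx] <- f_a
        prev[, sx] <- implied_prevalence(i_a, f_a)
      }
      out[[d]] <- list(name = meta$name[d], incidence = inc,
                       prevalence = prev, case_fatality = cf,
                       log_rr_per_bmi = meta$log_rr_per_bmi[d],
                       disability_weight = meta$disability_weight[d],
                       cost_basis = meta$cost_basis[d],
                       cost_per_case = meta$cost_per_case[d])
    }
    names(out) <- meta$name
    class(out) <- "disease_set"
    out
  })
}

#' Residual of the illness-death consistency condition for one disease
#'
#' Recomputes the prevalence implied by a disease's incidence and case
#' fatality under the zero-remission illness-death cohort recursion
#' (starting from the observed prevalence at the youngest age) and
#' returns the maximum absolute difference from the stored prevalence,
#' taken over ages and sexes. Internally consistent inputs — such as
#' those produced by [generate_diseases()] — have residuals at numerical
#' zero; rates assembled from independent sources generally do not.
#'
#' @param spec One element of a [generate_diseases()] result.
#' @return Maximum absolute prevalence residual (dimensionless).
#' @export
check_consistency <- function(spec) {
  if (!is.list(spec) || is.null(spec$incidence) || is.null(spec$prevalence) ||
      is.null(spec$case_fatality))
    stop("structural error: spec must carry incidence, prevalence and case_fatality")
  n_age <- length(model_ages())
  if (nrow(spec$incidence) != n_age || nrow(spec$prevalence) != n_age ||
      nrow(spec$case_fatality) != n_age)
    stop("structural error: rate tables must cover ages 2-100 without gaps")
  stopifnot(all(spec$incidence >= 0), all(spec$incidence <= 1),
            all(spec$case_fatality >= 0), all(spec$case_fatality <= 1))
  res <- 0
  for (sx in colnames(spec$incidence)) {
    imp <- implied_prevalence(spec$incidence[, sx], spec$case_fatality[, sx],
                              p_init = spec$prevalence[1, sx])
    res <- max(res, max(abs(spec$prevalence[, sx] - imp)))
  }
  res
}

#' Generate synthetic background all-cause mortality
#'
#' All-cause mortality rates by sex and single year of age, composed of a
#' Gompertz-like adult schedule, a small early-childhood excess, and the
#' mortality attributable to the nine model diseases (prevalence times
#' case fatality), so that the model diseases' deaths are contained in
#' the all-cause envelope. The life-table engine nets the modelled
#' disease deaths back out when it builds the other-cause schedule.
#'
#' @param config A [synth_config()].
#' @param diseases A [generate_diseases()] result produced under the same
#'   config (used to embed disease deaths in the envelope).
#' @return A 99 x 2 matrix (ages 2-100 by sex) of annual all-cause
#'   mortality rates, class `mortality_table`.
#' @export
generate_mortality <- function(config = synth_config(),
                               diseases = generate_diseases(config)) {
  stopifnot(inherits(config, "synth_config"), inherits(diseases, "disease_set"))
  ages <- model_ages()
  m <- matrix(0, length(ages), 2, dimnames = list(ages, c("female", "male")))
  with_seed(config$seed + 404L, {
    for (sx in c("female", "male")) {
      lvl <- if (sx == "male") 3.6e-5 else 2.6e-5
      base <- 2e-4 + lvl * exp(0.088 * ages) + 1.2e-3 * exp(-0.5 * (ages - 2))
      base <- base * exp(stats::rnorm(1, 0, config$noise$disease / 2))
      m[, sx] <- base + disease_mortality_rates(diseases, sx)
    }
  })
  class(m) <- c("mortality_table", class(m))
  m
}

# Sum over diseases of prevalence x case fatality: the annual
# disease-death rate per person alive implied by the disease tables.
disease_mortality_rates <- function(diseases, sex) {
  Reduce(`+`, lapply(diseases, function(d)
    d$prevalence[, sex] * d$case_fatality[, sex]))
}

#' Generate child overweight/obesity utility-weight inputs
#'
#' Quality-of-life decrements applied per unit prevalence of childhood
#' overweight and obesity (ages below 19), plus the BMI-for-age cut-offs
#' that define the two categories, rising monotonically with age to the
#' adult 25 and 30 kg/m^2 at age 18. Two sets are provided: `default`
#' (EQ-5D-style decrements) and `review` (smaller decrements of the size
#' systematic reviews of child utility weights report), selectable per
#' scenario.
#'
#' @param config A [synth_config()].
#' @return A list of class `child_utility` with `sets` (named list of
#'   `c(overweight=, obese=)` decrements) and `thresholds` (data frame:
#'   `age`, `sex`, `overweight_bmi`, `obese_bmi` for ages 2-18).
#' @export
generate_child_utility <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  ages <- 2:18
  thr <- do.call(rbind, lapply(c("female", "male"), function(sx) {
    off <- if (sx == "male") 0.3 else 0
    data.frame(age = ages, sex = sx,
               overweight_bmi = 17.8 + off + (25 - 17.8 - off) * (ages - 2) / 16,
               obese_bmi = 19.5 + off + (30 - 19.5 - off) * (ages - 2) / 16,
               stringsAsFactors = FALSE)
  }))
  structure(list(
    sets = list(default = c(overweight = 0.020, obese = 0.050),
                review = c(overweight = 0.008, obese = 0.022)),
    thresholds = thr
  ), class = "child_utility")
}

#' Generate the full synthetic input bundle
#'
#' Convenience wrapper running every generator under one configuration.
#'
#' @param config A [synth_config()].
#' @return A list of class `synth_inputs` with elements `population`,
#'   `beverages`, `diseases`, `mortality`, `child_utility`, and the
#'   echoed `config`.
#' @export
synth_inputs <- function(config = synth_config()) {
  diseases <- generate_diseases(config)
  structure(list(
    population = generate_population(config),
    beverages = generate_beverages(config),
    diseases = diseases,
    mortality = generate_mortality(config, diseases),
    child_utility = generate_child_utility(config),
    config = config
  ), class = "synth_inputs")
}
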