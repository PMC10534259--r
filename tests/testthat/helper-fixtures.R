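# Shared fixtures, generated once per test run.

.fixtures <- new.env()

test_inputs <- function() {
  if (is.null(.fixtures$inputs))
    .fixtures$inputs <- synth_inputs(synth_config(seed = 42))
  .fixtures$inputs
}

# Reduced fixture for Monte Carlo work: the oldest cohorts only, so the
# life-table horizon (and hence per-repetition cost) is short while the
# full pipeline still runs end to end.
elderly_inputs <- function() {
  if (is.null(.fixtures$elderly)) {
    inp <- test_inputs()
    keep <- inp$population$age >= 60
    pop <- inp$population[keep, ]
    class(pop) <- class(inp$population)
    inp$population <- pop
    .fixtures$elderly <- inp
  }
  .fixtures$elderly
}

# A population_spec for hand-built cohorts (adult ages: the child
# utility branch stays inactive unless anthropometry covers all child
# ages the cohort will pass through).
make_population <- function(sex, age, count = 1000, height = 1.6,
                            bmi = 24, bmi_sd = 4) {
  df <- data.frame(sex = sex, age = as.integer(age), count = count,
                   mean_height = height, mean_weight = bmi * height^2,
                   mean_bmi = bmi, bmi_sd = bmi_sd,
                   stringsAsFactors = FALSE)
  attr(df, "reference_year") <- 2018L
  class(df) <- c("population_spec", "data.frame")
  df
}

# A single synthetic disease with constant adult rates, prevalence made
# consistent by the zero-remission cohort recursion.
make_disease <- function(name = "d1", inc = 0.01, cf = 0.05,
                         log_rr = log(1.2), dw = 0.1,
                         cost_basis = "prevalent", cost = 1000) {
  ages <- 2:100
  mk <- function(x) {
    m <- matrix(0, length(ages), 2, dimnames = list(ages, c("female", "male")))
    m[ages >= 19, ] <- x
    m
  }
  i <- mk(inc); f <- mk(cf)
  p <- i
  for (sx in c("female", "male"))
    p[, sx] <- sbtaxsim:::implied_prevalence(i[, sx], f[, sx])
  list(name = name, incidence = i, prevalence = p, case_fatality = f,
       log_rr_per_bmi = log_rr, disability_weight = dw,
       cost_basis = cost_basis, cost_per_case = cost)
}

make_disease_set <- function(...) {
  ds <- list(...)
  names(ds) <- vapply(ds, `[[`, character(1), "name")
  class(ds) <- "disease_set"
  ds
}

# Flat background mortality table (annual all-cause rate).
make_mortality <- function(rate = 0.02) {
  m <- matrix(rate, 99, 2, dimnames = list(2:100, c("female", "male")))
  class(m) <- c("mortality_table", class(m))
  m
}

# Uniform-rate scenario over every category (for rate-scaling checks).
uniform_scenario <- function(rate, name = paste0("uniform", rate)) {
  tax_scenario(name, rate, sb_categories(), mean_price = 45.05)
}

with_seed_draws <- function(spec, n, seed = 1) {
  set.seed(seed)
  sbtaxsim:::sample_dist(spec, n)
}
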