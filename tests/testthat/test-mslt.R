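test_that("PIF closed form matches hand values and the quadrature route", {
  expect_equal(pif(0, log(1.2)), 0)
  expect_equal(pif(-0.5, log(1.2)), 1 - 1.2^(-0.5))
  expect_equal(pif(-0.5, log(1.2)), 0.08713, tolerance = 1e-4)
  expect_equal(pif(-2, 0), 0)                      # unrelated disease
  expect_lt(pif(1, 0.1), 0)                        # upward shift raises risk
  q <- pif(-0.5, log(1.2), method = "quadrature", bmi_mean = 24, bmi_sd = 4)
  expect_equal(q, pif(-0.5, log(1.2)), tolerance = 1e-6)
})

test_that("one illness-death cycle follows the difference equations", {
  s <- step_disease(1000, 0, i = 0.1, f = 0)
  expect_equal(s$S, 900)
  expect_equal(s$C, 100)
  expect_equal(s$deaths, 0)
  # no flows: states unchanged
  s0 <- step_disease(700, 300, 0, 0)
  expect_equal(s0[c("S", "C")], list(S = 700, C = 300))
  # lethal limit: everyone diseased dies; C' is new incidence only
  sl <- step_disease(500, 200, i = 0.1, f = 1)
  expect_equal(sl$deaths, 200)
  expect_equal(sl$C, 50)
  expect_error(step_disease(-1, 0, 0.1, 0.1), "internal error")
})

test_that("engine matches the brute-force oracle on small instances", {
  # 3 cohorts x 2 diseases x <=5 years, agreement to 1e-9
  pop <- make_population(c("female", "male", "female"), c(96, 97, 98),
                         count = c(1000, 800, 600), bmi = c(24, 25, 23))
  dis <- make_disease_set(
    make_disease("a", inc = 0.02, cf = 0.10, log_rr = log(1.3), dw = 0.2),
    make_disease("b", inc = 0.005, cf = 0.30, log_rr = log(1.1), dw = 0.35))
  mort <- make_mortality(0.08)
  cu <- generate_child_utility(synth_config())
  for (dbmi in list(0, -0.5, c(-0.3, -0.6, -0.9))) {
    eng <- run_life_table(pop, dis, mort, cu, dbmi = dbmi)
    ora <- oracle_life_table(pop, dis, mort, dbmi = dbmi)
    expect_equal(eng$hapy, ora$hapy, tolerance = 1e-9)
    expect_equal(eng$alive, ora$alive, tolerance = 1e-9)
    expect_equal(unname(eng$incident), unname(ora$incident), tolerance = 1e-9)
    expect_equal(unname(eng$prev_years), unname(ora$prev_years),
                 tolerance = 1e-9)
  }
})

test_that("a short horizon matches a hand-unrolled recursion", {
  # one cohort aged 99: exactly two annual cycles (ages 99, 100)
  pop <- make_population("female", 99, count = 100)
  dis <- make_disease_set(make_disease("d", inc = 0.01, cf = 0.2, dw = 0.1))
  mort <- make_mortality(0.10)
  cu <- generate_child_utility(synth_config())
  eng <- run_life_table(pop, dis, mort, cu, dbmi = 0)

  p99 <- dis$d$prevalence["99", "female"]
  p_i <- 1 - exp(-0.01); p_f <- 1 - exp(-0.2)
  m_oth <- 0.10 - dis$d$prevalence["99", "female"] * 0.2
  q1 <- (1 - exp(-m_oth)) + p99 * p_f
  ell1 <- 1 - q1
  L1 <- (1 + ell1) / 2
  hapy1 <- 100 * L1 * (1 - p99 * 0.1)
  expect_equal(eng$hapy[1, 1], hapy1, tolerance = 1e-12)

  C1 <- p99 * (1 - p_f) + (1 - p99) * p_i
  S1 <- (1 - p99) * (1 - p_i)
  prev1 <- C1 / (S1 + C1)
  m_oth2 <- 0.10 - dis$d$prevalence["100", "female"] * 0.2
  q2 <- (1 - exp(-m_oth2)) + prev1 * p_f
  ell2 <- ell1 * (1 - q2)
  hapy2 <- 100 * (ell1 + ell2) / 2 * (1 - prev1 * 0.1)
  expect_equal(eng$hapy[2, 1], hapy2, tolerance = 1e-12)
  expect_equal(sum(eng$hapy[, 1] > 0), 2)   # extinction after age 100
})

test_that("cohort mass is conserved across the full horizon", {
  inp <- test_inputs()
  run <- run_life_table(inp$population, inp$diseases, inp$mortality,
                        inp$child_utility, dbmi = -0.4)
  # per disease submodel: healthy + diseased + cumulative disease deaths
  # reproduce the initial unit cohort
  total <- run$final$S + run$final$C + run$final$cum_dd
  expect_true(all(abs(total - 1) < 1e-9))
})

test_that("a null intervention leaves every stream untouched", {
  inp <- elderly_inputs()
  base <- run_life_table(inp$population, inp$diseases, inp$mortality,
                         inp$child_utility, dbmi = 0)
  int <- run_life_table(inp$population, inp$diseases, inp$mortality,
                        inp$child_utility, dbmi = 0)
  led <- halys(base, int, r = 0.03)
  expect_identical(led$halys, 0)
  expect_true(all(led$incident_delta == 0))
  expect_equal(healthcare_offsets(led, inp$diseases), 0)
})

test_that("survivorship extends and HALYs accrue when risk falls", {
  inp <- elderly_inputs()
  base <- run_life_table(inp$population, inp$diseases, inp$mortality,
                         inp$child_utility, dbmi = 0)
  int <- run_life_table(inp$population, inp$diseases, inp$mortality,
                        inp$child_utility, dbmi = -0.5)
  expect_gte(sum(int$person_years), sum(base$person_years))
  led <- halys(base, int)
  expect_gt(led$halys, 0)
  expect_gt(led$halys_undiscounted, led$halys)  # discounting shrinks a positive stream
})

test_that("doubling one disease's BMI risk increases its averted cases and HALYs", {
  inp <- elderly_inputs()
  run_with <- function(mult) {
    dis <- inp$diseases
    dis$type_2_diabetes$log_rr_per_bmi <-
      dis$type_2_diabetes$log_rr_per_bmi * mult
    class(dis) <- "disease_set"
    base <- run_life_table(inp$population, dis, inp$mortality,
                           inp$child_utility, dbmi = 0)
    int <- run_life_table(inp$population, dis, inp$mortality,
                          inp$child_utility, dbmi = -0.5)
    halys(base, int)
  }
  l1 <- run_with(1)
  l2 <- run_with(2)
  averted <- function(l) -sum(l$incident_delta[, "type_2_diabetes"])
  expect_gt(averted(l2), averted(l1))
  expect_gt(l2$halys, l1$halys)
})

test_that("HALY gain is monotone non-decreasing in the size of the BMI shift", {
  inp <- elderly_inputs()
  base <- run_life_table(inp$population, inp$diseases, inp$mortality,
                         inp$child_utility, dbmi = 0)
  gains <- vapply(seq(0, 2, by = 0.25), function(s) {
    int <- run_life_table(inp$population, inp$diseases, inp$mortality,
                          inp$child_utility, dbmi = -s)
    halys(base, int)$halys
  }, numeric(1))
  expect_equal(gains[1], 0)
  expect_true(all(diff(gains) >= 0))
})

test_that("discounting follows (1+r)^-t with year zero undiscounted", {
  pop <- make_population("male", 99)
  dis <- make_disease_set(make_disease("d"))
  mort <- make_mortality(0.05)
  cu <- generate_child_utility(synth_config())
  base <- run_life_table(pop, dis, mort, cu, dbmi = 0)
  int <- run_life_table(pop, dis, mort, cu, dbmi = -1)
  led3 <- halys(base, int, r = 0.03)
  led0 <- halys(base, int, r = 0)
  expect_equal(led0$halys, led0$halys_undiscounted)
  d <- led3$by_year$d_hapy
  expect_equal(led3$halys, d[1] + d[2] / 1.03, tolerance = 1e-12)
  # mismatched horizons are structural errors
  short <- base; short$hapy <- short$hapy[1:10, , drop = FALSE]
  expect_error(halys(short, int), "structural error")
})
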