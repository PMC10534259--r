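test_that("implementation cost converts, inflates and scales as documented", {
  id <- econ_params(implementation_base_cost = 5400016, exchange_rate = 1,
                    inflation = 1, implementation_mode = "scaled")
  expect_equal(intervention_cost(id, 1e7), 5400016)
  expect_equal(intervention_cost(id, 2e7), 10800032)
  conv <- econ_params(implementation_base_cost = 5400016, exchange_rate = 45,
                      inflation = 1.25, implementation_mode = "scaled")
  expect_equal(intervention_cost(conv, 1e7), 303750900)
  # fixed-total mode ignores the population size
  fx <- econ_params(implementation_base_cost = 5400016, exchange_rate = 45,
                    inflation = 1.25, implementation_mode = "fixed_total")
  expect_equal(intervention_cost(fx, 1e7), intervention_cost(fx, 1.06e8))
  expect_equal(intervention_cost(fx, 1e7, multiplier = 2),
               2 * intervention_cost(fx, 1e7))
  expect_error(econ_params(inflation = NULL), "config error")
})

test_that("healthcare offsets discount case streams by basis and scale linearly", {
  # a hand-built ledger: one averted prevalent case-year at t = 1,
  # one averted incident (cancer) case at t = 2
  nd <- matrix(0, 5, 2, dimnames = list(NULL, c("chronic", "cancer")))
  ledger <- structure(list(incident_delta = nd, prev_years_delta = nd,
                           r = 0.03), class = "haly_ledger")
  ledger$prev_years_delta[2, "chronic"] <- -1
  ledger$incident_delta[3, "cancer"] <- -1
  dis <- list(chronic = list(cost_basis = "prevalent", cost_per_case = 1000),
              cancer = list(cost_basis = "incident", cost_per_case = 5000))
  off <- healthcare_offsets(ledger, dis, r = 0.03)
  expect_equal(off, -1000 / 1.03 - 5000 / 1.03^2)
  expect_equal(healthcare_offsets(ledger, dis, r = 0.03, cost_multiplier = 0.5),
               off / 2)
  zero <- ledger; zero$prev_years_delta[] <- 0; zero$incident_delta[] <- 0
  expect_equal(healthcare_offsets(zero, dis), 0)
  bad <- dis; bad$chronic$cost_basis <- "weekly"
  expect_error(healthcare_offsets(ledger, bad), "unknown cost_basis")
})

test_that("revenue is post-tax volume times rate, with survivorship-weighted lifetime", {
  # 1000 people, one taxed category at 100 ml/day post-tax, 6/litre:
  # annual revenue = 0.1 * 365 * 1000 * 6 = 219,000
  pop <- make_population("female", 99, count = 1000)
  sc <- tax_scenario("one", 6, "soft_drinks")
  q <- matrix(0, 9, 1, dimnames = list(sb_categories(), NULL))
  q["soft_drinks", 1] <- 100
  delta <- structure(list(q_base = q, dq = q * 0,
                          dq_total = 0, dE = 0, dp = rep(0, 9)),
                     class = "consumption_delta")
  # constant survivorship over 2 years, r = 0: lifetime = annual * 2
  fake_run <- structure(list(alive = matrix(c(1000, 1000), 2, 1)),
                        class = "mslt_run")
  rev <- tax_revenue(delta, sc, pop, fake_run, r = 0)
  expect_equal(rev$annual, 219000)
  expect_equal(rev$lifetime, 438000)
  # discounting and mortality shrink the lifetime stream
  fake_run2 <- structure(list(alive = matrix(c(1000, 500), 2, 1)),
                         class = "mslt_run")
  rev2 <- tax_revenue(delta, sc, pop, fake_run2, r = 0.03)
  expect_equal(rev2$lifetime, 219000 + 219000 * 0.5 / 1.03)
  # zero tax: zero revenue
  sc0 <- tax_scenario("none", 0)
  expect_equal(tax_revenue(delta, sc0, pop, fake_run)$annual, 0)
  # negative post-tax consumption clamps with a warning
  deltaneg <- delta; deltaneg$dq["soft_drinks", 1] <- -150
  expect_warning(r3 <- tax_revenue(deltaneg, sc, pop, fake_run, r = 0),
                 "clamped")
  expect_equal(r3$annual, 0)
})

test_that("ICER classifies dominance and applies the threshold inclusively", {
  expect_equal(icer(-1e9, 1e6)$verdict, "dominant")
  expect_true(icer(-1e9, 1e6)$cost_effective)
  expect_equal(icer(100, -2)$verdict, "dominated")
  r <- icer(100, 2)
  expect_equal(r$icer, 50)
  expect_true(r$cost_effective)
  # equality with the threshold counts as cost-effective
  eq <- icer(168236 * 2, 2, threshold = 168236)
  expect_equal(eq$icer, 168236)
  expect_true(eq$cost_effective)
  expect_false(icer(168237 * 2, 2, threshold = 168236)$cost_effective)
  expect_equal(icer(100, 0)$verdict, "undefined")
  expect_equal(icer(0, 0)$verdict, "ratio")
  # dominance is invariant to currency rescaling
  expect_equal(icer(-1e9 * 55, 1e6)$verdict, icer(-1e9, 1e6)$verdict)
})

test_that("comparative statistics reproduce published-style relative reductions", {
  expect_equal(unname(comparative_stats(51.1, 89.7)), 43.0, tolerance = 5e-3)
  expect_equal(unname(comparative_stats(2503118, 4149030)), 39.7,
               tolerance = 5e-3)
  expect_equal(unname(comparative_stats(12.7, 17.6)), 27.8, tolerance = 5e-3)
  expect_equal(unname(comparative_stats(426.3, 589.4)), 27.7, tolerance = 5e-3)
  expect_equal(unname(comparative_stats(5, 5)), 0)
  expect_true(is.na(comparative_stats(1, 0)))
})

test_that("revenue is a transfer: it never enters net cost or the ICER", {
  inp <- elderly_inputs()
  r1 <- run_scenario(tax_scenario("t6", 6, sb_categories()), inp)
  # net cost is exactly offsets + implementation cost: no revenue term
  expect_equal(r1$net_cost, r1$healthcare_offsets + r1$intervention_cost)
  # perturbing the rate with consumption held fixed moves revenue
  # linearly but cannot move the ICER inputs
  rev_doubled <- tax_revenue(r1$delta,
                             tax_scenario("t12", 12, sb_categories()),
                             inp$population, r1$intervention_run)
  expect_equal(rev_doubled$annual, 2 * r1$revenue_annual, tolerance = 1e-9)
  expect_equal(icer(r1$net_cost, r1$halys)$verdict, r1$icer$verdict)
})
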