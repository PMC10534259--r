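test_that("a specific tax converts to the expected fractional price change", {
  sc10 <- uniform_scenario(10)
  sc6 <- uniform_scenario(6)
  expect_equal(unname(effective_price_change(sc10)[1]), 0.222, tolerance = 5e-4)
  expect_equal(unname(effective_price_change(sc6)[1]), 0.1332, tolerance = 5e-4)
  # excluded categories see no price change
  imp <- bundled_scenarios("implemented")[[1]]
  dp <- effective_price_change(imp)
  expect_equal(unname(dp[c("coffee_based", "milk_based")]), c(0, 0))
  # pass-through scales the price change
  half <- tax_scenario("half", 10, sb_categories(), pass_through = 0.5,
                       mean_price = 45.05)
  expect_equal(effective_price_change(half), effective_price_change(sc10) / 2)
  expect_error(tax_scenario("bad", 10, "soft_drinks", mean_price = 0),
               "invalid scenario")
  expect_error(tax_scenario("bad", -1, "soft_drinks"), "invalid scenario")
})

test_that("elasticity application matches hand-computed cases", {
  # no price change, no quantity change
  E <- matrix(c(-1.2, 0.3, 0, -0.8), 2, 2, byrow = TRUE)
  q <- c(100, 50)
  expect_equal(apply_elasticities(c(0, 0), E, q), c(0, 0))
  # unit elasticity: -1.0 * 10% * 100 ml = -10 ml
  expect_equal(apply_elasticities(0.10, matrix(-1), 100), -10)
  # two categories with substitution: dq = (q1*e11*dp1, q2*e21*dp1)
  E2 <- matrix(c(-1.2, 0, 0.3, 0), 2, 2, byrow = TRUE)
  expect_equal(apply_elasticities(c(0.10, 0), E2, c(100, 50)), c(-12, 1.5))
  # zero baseline consumption stays zero
  expect_equal(apply_elasticities(c(0.10, 0), E2, c(0, 50)), c(0, 1.5))
  # dimension mismatches are structural errors
  expect_error(apply_elasticities(c(0.1, 0, 0), E2, c(100, 50)),
               "structural error")
  expect_error(apply_elasticities(c(0.1, 0), E2, c(100, 50, 10)),
               "structural error")
})

test_that("matrix path agrees with an elementwise-loop oracle to 1e-12", {
  set.seed(101)
  for (rep in 1:20) {
    E <- matrix(rnorm(81, 0, 0.5), 9, 9)
    diag(E) <- -abs(rnorm(9, 1, 0.3))
    q <- matrix(runif(9 * 4, 0, 200), 9, 4)
    rownames(q) <- rownames(E) <- colnames(E) <- sb_categories()
    dp <- runif(9, 0, 0.3)
    expect_equal(apply_elasticities(dp, E, q),
                 naive_elasticity_loop(dp, E, q), tolerance = 1e-12)
  }
})

test_that("consumption response is linear in the tax rate", {
  inp <- test_inputs()
  d6 <- consumption_delta(uniform_scenario(6), inp)
  d10 <- consumption_delta(uniform_scenario(10), inp)
  d20 <- consumption_delta(uniform_scenario(20), inp)
  expect_equal(d6$dq, 0.6 * d10$dq, tolerance = 1e-12)
  expect_equal(d20$dq, 2 * d10$dq, tolerance = 1e-12)
  expect_equal(d6$dE, 0.6 * d10$dE, tolerance = 1e-12)
  # the do-nothing scenario yields the all-zero delta
  d0 <- consumption_delta(bundled_scenarios("do_nothing")[[1]], inp)
  expect_true(all(d0$dq == 0))
  expect_true(all(d0$dE == 0))
})

test_that("energy change follows densities, with zero-calorie categories inert", {
  dens <- c(soft_drinks = 174, diet = 0)
  dq <- c(soft_drinks = -7, diet = -3)
  expect_equal(energy_change(dq, dens), -12.18)
  expect_equal(energy_change(c(soft_drinks = 0, diet = 0), dens), 0)
  expect_equal(energy_change(c(soft_drinks = 0, diet = -50), dens), 0)
  expect_error(energy_change(c(unknown = -5), dens), "structural error")
  # the delta invariant: dE = sum_j dq_j e_j / 100 exactly, per group
  inp <- test_inputs()
  d <- consumption_delta(uniform_scenario(10), inp)
  manual <- colSums(d$dq * inp$beverages$energy_density[rownames(d$dq)] / 100)
  expect_equal(d$dE, manual, tolerance = 1e-12)
})

test_that("population-weighted means behave like weighted averages", {
  pop <- make_population(c("female", "female"), c(30, 40), count = c(1, 3))
  expect_equal(weighted_mean_by_group(c(0, 4), pop), 3)
  expect_equal(weighted_mean_by_group(c(7, 7), pop), 7)
  perm <- pop[2:1, ]
  expect_equal(weighted_mean_by_group(c(4, 0), perm),
               weighted_mean_by_group(c(0, 4), pop))
  expect_error(weighted_mean_by_group(numeric(0), pop[0, ]), "empty")
})

test_that("band consumption maps to single ages by assignment", {
  inp <- test_inputs()
  q <- consumption_by_group(inp$beverages$consumption, inp$population)
  expect_equal(dim(q), c(9, 198))
  # every age in a band gets the band's value
  i5 <- which(inp$population$age == 5 & inp$population$sex == "female")
  i3 <- which(inp$population$age == 3 & inp$population$sex == "female")
  expect_equal(q[, i5], q[, i3])
  i25 <- which(inp$population$age == 25 & inp$population$sex == "male")
  expect_equal(unname(q[, i25]),
               unname(inp$beverages$consumption[, "19-59"]))
})
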