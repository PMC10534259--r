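test_that("generators are deterministic in the seed and sensitive to it", {
  a <- synth_inputs(synth_config(seed = 1))
  b <- synth_inputs(synth_config(seed = 1))
  expect_identical(a, b)

  c_ <- generate_population(synth_config(seed = 2))
  expect_true(any(a$population$count != c_$count))
})

test_that("population covers ages 2-100 for both sexes with plausible anthropometry", {
  pop <- test_inputs()$population
  expect_equal(nrow(pop), 198)
  expect_setequal(pop$age[pop$sex == "female"], 2:100)
  expect_setequal(pop$age[pop$sex == "male"], 2:100)
  expect_true(all(pop$count >= 0))
  expect_true(all(pop$mean_height > 0.5 & pop$mean_height < 2.5))
  expect_true(all(pop$bmi_sd > 0))
  # children shorter and lighter than adults, within sex
  for (sx in c("female", "male")) {
    kids <- pop$age < 13 & pop$sex == sx
    adults <- pop$age %in% 25:60 & pop$sex == sx
    expect_lt(max(pop$mean_height[kids]), min(pop$mean_height[adults]))
    expect_lt(max(pop$mean_weight[kids]), min(pop$mean_weight[adults]))
  }
})

test_that("invalid generator configuration is rejected", {
  expect_error(synth_config(scale = 0), "invalid config")
  expect_error(synth_config(scale = -2), "invalid config")
  expect_error(synth_config(seed = NA), "invalid config")
})

test_that("population scale multiplies counts but not per-capita quantities", {
  p1 <- generate_population(synth_config(seed = 5, scale = 1))
  p2 <- generate_population(synth_config(seed = 5, scale = 2))
  expect_equal(p2$count, 2 * p1$count)
  expect_equal(p2$mean_height, p1$mean_height)
})

test_that("beverage table has nine categories, demand-law elasticities and substitution channels", {
  bev <- test_inputs()$beverages
  expect_setequal(rownames(bev$consumption), sb_categories())
  expect_equal(colnames(bev$consumption), age_bands())
  expect_true(all(bev$consumption >= 0))
  expect_true(all(bev$energy_density >= 0))
  for (E in bev$elasticities) {
    expect_true(all(diag(E) < 0))
    expect_true(any(E[row(E) != col(E)] > 0))
  }
  # coffee- and milk-based drinks are untaxed under the implemented design
  imp <- bundled_scenarios("implemented")[[1]]
  expect_equal(unname(imp$rate_per_litre[c("coffee_based", "milk_based")]),
               c(0, 0))
  expect_true(all(imp$rate_per_litre[setdiff(sb_categories(),
                                             c("coffee_based", "milk_based"))] > 0))
})

test_that("generated disease rates satisfy the illness-death consistency condition", {
  dis <- test_inputs()$diseases
  expect_length(dis, 9)
  for (d in dis) {
    expect_true(all(d$incidence >= 0 & d$incidence <= 1))
    expect_true(all(d$prevalence >= 0 & d$prevalence < 1))
    expect_true(d$disability_weight >= 0 && d$disability_weight < 1)
    expect_lt(check_consistency(d), 1e-9)
  }
  # cancers costed per incident case, others per prevalent case
  cancers <- grep("cancer", names(dis), value = TRUE)
  expect_true(all(vapply(dis[cancers], `[[`, character(1), "cost_basis") ==
                    "incident"))
  expect_true(all(vapply(dis[setdiff(names(dis), cancers)], `[[`,
                         character(1), "cost_basis") == "prevalent"))
})

test_that("consistency residual detects a perturbed prevalence", {
  d <- test_inputs()$diseases[["type_2_diabetes"]]
  d$prevalence[40, "female"] <- d$prevalence[40, "female"] + 0.01
  expect_gte(check_consistency(d), 0.01 - 1e-12)
})

test_that("zero flows leave the implied prevalence unchanged", {
  # no incidence ever: implied prevalence stays zero
  p <- sbtaxsim:::implied_prevalence(rep(0, 99), rep(0, 99))
  expect_equal(p, rep(0, 99))
  # flows that stop after age 60 freeze prevalence at its prior value
  i <- c(rep(0.01, 50), rep(0, 49))
  f <- c(rep(0.02, 50), rep(0, 49))
  p <- sbtaxsim:::implied_prevalence(i, f)
  expect_true(all(diff(p[52:99]) == 0))
})

test_that("check_consistency rejects structurally broken specs", {
  d <- test_inputs()$diseases[[1]]
  d$incidence <- d$incidence[1:50, ]
  expect_error(check_consistency(d), "structural error")
  expect_error(check_consistency(list(incidence = 1)), "structural error")
})

test_that("all-cause mortality dominates modelled disease mortality at every age", {
  inp <- test_inputs()
  for (sx in c("female", "male")) {
    dis_mort <- sbtaxsim:::disease_mortality_rates(inp$diseases, sx)
    expect_true(all(unclass(inp$mortality)[, sx] >= dis_mort))
  }
})

test_that("child BMI thresholds are monotone in age and utility sets are valid", {
  cu <- test_inputs()$child_utility
  for (sx in c("female", "male")) {
    thr <- cu$thresholds[cu$thresholds$sex == sx, ]
    thr <- thr[order(thr$age), ]
    expect_true(all(diff(thr$overweight_bmi) > 0))
    expect_true(all(diff(thr$obese_bmi) > 0))
    expect_true(all(thr$obese_bmi > thr$overweight_bmi))
  }
  for (u in cu$sets) expect_true(all(u >= 0 & u < 1))
})
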