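test_that("null generating model yields prevalence near one half", {
  geo <- small_geo(seed = 1, n_states = 4)
  tm <- true_model(geo, coef_table(), sigma2_state = 0, sigma2_county = 0,
                   seed = 2)
  rec <- simulate_survey(geo, tm, n_per_state = 5000, seed = 3)
  p <- mean(rec$obese)
  se <- sqrt(0.25 / nrow(rec))
  expect_lt(abs(p - 0.5), 4 * se)
})

test_that("intercept-only model calibrates to its inverse-logit", {
  # pooled prevalence converges to invlogit(beta0) with all other
  # effects zero; binomial interval check at n = 200,000
  geo <- small_geo(seed = 4, n_states = 8)
  b0 <- -3.4529
  tm <- true_model(geo, coef_table(intercept = b0), sigma2_state = 0,
                   sigma2_county = 0, seed = 5)
  rec <- simulate_survey(geo, tm, n_per_state = 25000, seed = 6)
  truth <- invlogit(b0)
  se <- sqrt(truth * (1 - truth) / nrow(rec))
  expect_equal(nrow(rec), 200000)
  expect_lt(abs(mean(rec$obese) - truth), 4 * se)
})

test_that("survey size and weights follow the sampling design", {
  geo <- generate_geography(51, 2, 2, 2, seed = 7)
  tm <- true_model(geo, seed = 8)
  rec <- simulate_survey(geo, tm, n_per_state = 865, seed = 9)
  expect_equal(nrow(rec), 51 * 865)
  expect_true(all(rec$obese %in% c(0, 1)))
  expect_true(all(rec$weight > 0))
  # weight = state child population / state sample size
  w1 <- rec$weight[rec$state == geo$states$state[1]][1]
  expect_equal(w1, geo$states$child_population[1] / 865)
})

test_that("every record's area chain is consistent with the geography", {
  geo <- small_geo(seed = 10)
  tm <- true_model(geo, seed = 11)
  rec <- simulate_survey(geo, tm, n_per_state = 200, seed = 12)
  zi <- match(rec$zip, geo$zips$zip)
  expect_false(anyNA(zi))
  expect_identical(geo$zips$county[zi], rec$county)
  ci <- match(rec$county, geo$counties$county)
  expect_identical(geo$counties$state[ci], rec$state)
})

test_that("survey simulation is deterministic given the seed", {
  geo <- small_geo(seed = 13)
  tm <- true_model(geo, seed = 14)
  expect_identical(simulate_survey(geo, tm, 100, seed = 15),
                   simulate_survey(geo, tm, 100, seed = 15))
})

test_that("a coefficient table inconsistent with the categories is rejected", {
  geo <- small_geo(seed = 16)
  bad <- risk_coefficients()
  bad <- bad[!(bad$term == "zip_lifestyle" & bad$level == "Metropolis"), ]
  expect_error(true_model(geo, bad, seed = 1), "levels")
  bad2 <- risk_coefficients()
  bad2$estimate[bad2$term == "sex" & bad2$level == "Female"] <- 0.2
  expect_error(true_model(geo, bad2, seed = 1), "reference")
})

test_that("population cells reject a non-positive mean", {
  geo <- small_geo(seed = 17)
  expect_error(generate_population_cells(geo, 0), "positive")
  expect_error(generate_population_cells(geo, -3), "positive")
})

test_that("uniform marginals give near-equal cells at large mean", {
  geo <- generate_geography(1, 1, 1, 1, seed = 18)
  cells <- generate_population_cells(geo, 1e5, seed = 19)
  expect_equal(nrow(cells), 32)  # 2 sex x 2 age x 8 race
  expect_lt(max(abs(cells$count - mean(cells$count))) / mean(cells$count),
            0.05)
})

test_that("cell totals are conserved", {
  geo <- small_geo(seed = 20)
  cells <- generate_population_cells(geo, 40, seed = 21)
  expect_true(all(cells$count >= 0))
  expect_equal(population_total(cells), sum(cells$count))
  key <- paste(cells$bg, cells$sex, cells$age_group, cells$race)
  expect_equal(anyDuplicated(key), 0L)
  expect_identical(cells, generate_population_cells(geo, 40, seed = 21))
})
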