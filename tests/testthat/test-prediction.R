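test_that("cell risk is the inverse-logit of the summed coefficients", {
  m <- predictive_model(coefficients = risk_coefficients())
  expect_equal(cell_risk(m, "Female", "15-17", "White", 8, "Solo Acts"),
               invlogit(-3.4529), tolerance = 1e-12)
  expect_equal(
    cell_risk(m, "Male", "10-14", "Black", 1, "Global Roots"),
    invlogit(-3.4529 + 0.5753 + 0.4117 + 0.6804 + 0.8478 + 0.4404),
    tolerance = 1e-12)
  # null model: all coefficients zero
  m0 <- predictive_model(coefficients = coef_table())
  expect_equal(cell_risk(m0, "Male", "10-14", "Asian", 3, "Metropolis"),
               0.5)
  # state effect enters additively
  m2 <- predictive_model(coefficients = coef_table(),
                         state_effects = c(S1 = 0.7))
  expect_equal(cell_risk(m2, "Male", "10-14", "Asian", 3, "Metropolis",
                         state = "S1"), invlogit(0.7))
  # unknown state falls back to the population average (effect 0)
  expect_equal(cell_risk(m2, "Male", "10-14", "Asian", 3, "Metropolis",
                         state = "S9"), 0.5)
})

test_that("cell risk is monotone in any active coefficient", {
  tab <- coef_table(intercept = -1, sex = c(Male = 0.2))
  m_lo <- predictive_model(coefficients = tab)
  tab$estimate[tab$term == "sex" & tab$level == "Male"] <- 0.8
  m_hi <- predictive_model(coefficients = tab)
  expect_gt(cell_risk(m_hi, "Male", "15-17", "White", 8, "Solo Acts"),
            cell_risk(m_lo, "Male", "15-17", "White", 8, "Solo Acts"))
  # inactive (reference) design value: no change
  expect_equal(cell_risk(m_hi, "Female", "15-17", "White", 8, "Solo Acts"),
               cell_risk(m_lo, "Female", "15-17", "White", 8, "Solo Acts"))
})

# model whose only nonzero terms are intercept (logit 0.1) and Male
# (logit 0.3 - logit 0.1): Female cells risk 0.1, Male cells risk 0.3
two_risk_model <- function() {
  predictive_model(coefficients = coef_table(
    intercept = logit(0.1), sex = c(Male = logit(0.3) - logit(0.1))))
}

one_bg_cells <- function(geo, counts) {
  # one Female and one Male cell in the first block group
  data.frame(bg = geo$block_groups$bg[1], sex = c("Female", "Male"),
             age_group = "15-17", race = "White", count = counts)
}

test_that("block-group prevalence is the population-weighted cell average", {
  geo <- generate_geography(1, 1, 1, 1, seed = 1)
  m <- two_risk_model()
  res <- block_group_prevalence(m, one_bg_cells(geo, c(10, 30)), geo)
  expect_equal(res$estimate, (10 * 0.1 + 30 * 0.3) / 40, tolerance = 1e-12)
  expect_equal(res$n_children, 40)
  # single cell: the average is the cell risk itself
  res1 <- block_group_prevalence(m, one_bg_cells(geo, c(10, 0))[1, ], geo)
  expect_equal(res1$estimate, 0.1, tolerance = 1e-12)
  # constant risk: counts are irrelevant
  mc <- predictive_model(coefficients = coef_table(intercept = logit(0.2)))
  resc <- block_group_prevalence(mc, one_bg_cells(geo, c(3, 97)), geo)
  expect_equal(resc$estimate, 0.2, tolerance = 1e-12)
  # all-zero counts are suppressed
  expect_equal(nrow(block_group_prevalence(m, one_bg_cells(geo, c(0, 0)),
                                           geo)), 0)
})

test_that("zero coefficient uncertainty collapses the MC interval", {
  geo <- generate_geography(1, 1, 1, 1, seed = 2)
  m <- two_risk_model()   # all SEs are 0
  res <- mc_intervals(m, one_bg_cells(geo, c(10, 30)), geo, n_draws = 50,
                      seed = 3)
  expect_equal(res$ci_width, 0, tolerance = 1e-12)
  expect_equal(res$cv, 0, tolerance = 1e-12)
  expect_equal(res$ci_low, res$estimate, tolerance = 1e-12)
})

test_that("an intercept-only draw reproduces the normal-quantile interval", {
  geo <- generate_geography(1, 1, 1, 1, seed = 4)
  m <- predictive_model(coefficients = coef_table(ses = list(intercept = 1)))
  cells <- one_bg_cells(geo, c(20, 0))
  res <- mc_intervals(m, cells, geo, n_draws = 1e5, seed = 5)
  expect_lt(abs(res$ci_low - invlogit(-1.96)), 0.005)
  expect_lt(abs(res$ci_high - invlogit(1.96)), 0.005)
})

test_that("MC intervals are reproducible and respect probability bounds", {
  geo <- small_geo(seed = 6, n_states = 3)
  m <- predictive_model(
    coefficients = coef_table(intercept = -1.7, sex = c(Male = 0.5),
                              ses = list(intercept = 0.15,
                                         sex = c(Male = 0.05))),
    state_effects = stats::setNames(rep(0, 3), geo$states$state))
  cells <- generate_population_cells(geo, 40, seed = 7)
  r1 <- mc_intervals(m, cells, geo, n_draws = 200, seed = 8)
  r2 <- mc_intervals(m, cells, geo, n_draws = 200, seed = 8)
  expect_identical(r1, r2)
  expect_true(all(r1$ci_low >= 0 & r1$ci_high <= 1))
  expect_true(all(r1$estimate >= r1$ci_low - 0.005 &
                    r1$estimate <= r1$ci_high + 0.005))
  expect_true(all(r1$cv >= 0))
  # chunking must not change the draws
  r3 <- mc_intervals(m, cells, geo, n_draws = 200, seed = 8, chunk = 37)
  expect_equal(r1$ci_low, r3$ci_low, tolerance = 1e-12)
})

test_that("aggregation is a draw-wise population-weighted average", {
  geo <- generate_geography(1, 1, 1, 2, seed = 9)
  m <- two_risk_model()
  cells <- rbind(
    data.frame(bg = geo$block_groups$bg[1], sex = "Female",
               age_group = "15-17", race = "White", count = 100),
    data.frame(bg = geo$block_groups$bg[2], sex = "Male",
               age_group = "15-17", race = "White", count = 300))
  bg <- mc_intervals(m, cells, geo, n_draws = 50, seed = 10)
  cty <- aggregate_sae(bg, geo, "county")
  expect_equal(cty$estimate, (100 * 0.1 + 300 * 0.3) / 400,
               tolerance = 1e-12)
  expect_equal(cty$n_children, 400)
  # single block group per county: county equals the block group
  one <- aggregate_sae(bg[bg$geo_id == geo$block_groups$bg[1], ], geo,
                       "county")
  expect_equal(one$estimate, bg$estimate[1], tolerance = 1e-12)
  expect_equal(one$ci_width, bg$ci_width[1], tolerance = 1e-12)
})

test_that("national aggregates agree from block-group and state routes", {
  geo <- small_geo(seed = 11, n_states = 4)
  m <- predictive_model(
    coefficients = coef_table(intercept = -1.2, sex = c(Male = 0.4),
                              ses = list(intercept = 0.1)),
    state_effects = stats::setNames(stats::rnorm(4, 0, 0.2),
                                    geo$states$state))
  cells <- generate_population_cells(geo, 30, seed = 12)
  bg <- mc_intervals(m, cells, geo, n_draws = 100, seed = 13)
  nat_direct <- aggregate_sae(bg, geo, "national")
  st <- aggregate_sae(bg, geo, "state")
  nat_via_state <- sum(st$estimate * st$n_children) / sum(st$n_children)
  expect_equal(nat_direct$estimate, nat_via_state, tolerance = 1e-12)
  # orphan block group is named in the aggregation error
  bg2 <- bg
  bg2$geo_id[1] <- "B9999999"
  expect_error(aggregate_sae(bg2, geo, "state"), "B9999999")
})

test_that("summary statistics use the conventional quartile definition", {
  res <- data.frame(geo_id = letters[1:5], level = "block_group",
                    n_children = 10, estimate = 0.2,
                    ci_width = c(1, 2, 3, 4, 5) / 100,
                    cv = c(0.1, 0.1, 0.2, 0.3, 0.5))
  class(res) <- c("sae_results", "data.frame")
  s <- summarize_sae(res)
  ciw <- s[s$statistic == "ci_width_pp", ]
  expect_equal(ciw$median, 3)
  expect_equal(ciw$iqr, 2)
  expect_equal(ciw$min, 1)
  expect_equal(ciw$max, 5)
  expect_equal(ciw$mean, 3)
  # single result: all order statistics collapse, IQR 0
  s1 <- summarize_sae(res[3, ])
  expect_true(all(s1$min == s1$max))
  expect_equal(s1$iqr, c(0, 0))
})

test_that("missing standard errors block interval simulation", {
  geo <- generate_geography(1, 1, 1, 1, seed = 14)
  tab <- coef_table(intercept = -1)
  m <- predictive_model(coefficients = tab[, c("term", "level", "estimate",
                                               "reference")])
  expect_error(mc_intervals(m, one_bg_cells(geo, c(5, 5)), geo,
                            n_draws = 10, seed = 1), "standard errors")
  expect_error(mc_intervals(two_risk_model(), one_bg_cells(geo, c(5, 5)),
                            geo, n_draws = 1, seed = 1), "n_draws")
})
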