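rec_df <- function(y, w = rep(1, length(y)), county = "C1") {
  data.frame(obese = y, weight = w, county = county, state = "S1")
}

test_that("direct estimates reduce to binomial proportions under equal weights", {
  d <- direct_estimates(rec_df(c(rep(1, 3), rep(0, 7))), "county")
  expect_equal(d$estimate, 0.3)
  expect_equal(d$se, sqrt(0.3 * 0.7 / 10), tolerance = 1e-12)
  expect_equal(d$n, 10L)
  d1 <- direct_estimates(rec_df(rep(1, 5)), "county")
  expect_equal(d1$estimate, 1)
})

test_that("direct estimates are invariant to weight rescaling", {
  y <- c(1, 0, 0, 1, 0, 1, 0, 0)
  w <- c(2, 1, 3, 1, 2, 5, 1, 1)
  a <- direct_estimates(rec_df(y, w), "county")
  b <- direct_estimates(rec_df(y, 2 * w), "county")
  expect_equal(a$estimate, b$estimate, tolerance = 1e-12)
  expect_equal(a$se, b$se, tolerance = 1e-12)
  # weighted proportion
  expect_equal(a$estimate, sum(w * y) / sum(w), tolerance = 1e-12)
})

test_that("the reliability filter applies both rules with strict RSE", {
  est <- data.frame(geo_id = c("a", "b", "c", "d"), level = "county",
                    estimate = c(0.2, 0.2, 0.2, 0),
                    se = c(0.29 * 0.2, 0.02, 0.06001, 0),
                    n = c(30, 29, 30, 50))
  kept <- apply_reliability_filter(est)
  expect_identical(kept$geo_id, "a")      # b fails n, c fails rse, d zero
  expect_true(all(kept$reliable))
  # raising min_n never increases the retained count
  n_kept <- vapply(c(1, 10, 30, 100),
                   function(m) nrow(apply_reliability_filter(est, min_n = m)),
                   numeric(1))
  expect_true(all(diff(n_kept) <= 0))
})

test_that("only a small fraction of counties is reliable at survey scale", {
  # many counties per state so county samples are mostly below the
  # reliability threshold, as with real sub-state survey coverage
  geo <- generate_geography(51, 40, 1, 1, seed = 31)
  tm <- true_model(geo, seed = 32)
  rec <- simulate_survey(geo, tm, n_per_state = 865, seed = 33)
  direct <- direct_estimates(rec, "county")
  reliable <- apply_reliability_filter(direct)
  expect_gt(nrow(reliable), 0)
  expect_lt(nrow(reliable) / nrow(direct), 0.10)
})

test_that("paired comparison flags degenerate difference vectors", {
  model <- data.frame(geo_id = letters[1:10], estimate = seq(0.1, 0.19, 0.01))
  direct <- data.frame(geo_id = letters[1:10],
                       estimate = seq(0.1, 0.19, 0.01),
                       se = 0.02, n = 50)
  cmp <- compare_paired(model, direct)
  expect_true(cmp$degenerate)
  expect_true(all(cmp$differences_pp == 0))
  # constant shift: differences have zero variance
  model2 <- model
  model2$estimate <- model$estimate + 0.01
  cmp2 <- compare_paired(model2, direct)
  expect_true(cmp2$degenerate)
  expect_equal(unname(cmp2$quartiles_pp["median"]), 1)
  expect_error(compare_paired(model[1, , drop = FALSE],
                              direct[1, , drop = FALSE]), "fewer than 2")
})

test_that("interval non-overlap counts significant discrepancies", {
  model <- data.frame(geo_id = c("a", "b"), estimate = c(0.30, 0.20),
                      ci_low = c(0.28, 0.18), ci_high = c(0.32, 0.22))
  direct <- data.frame(geo_id = c("a", "b"), estimate = c(0.10, 0.19),
                       se = c(0.01, 0.05), n = c(40, 40))
  cmp <- compare_paired(model, direct)
  expect_equal(cmp$n_significant, 1L)
})

test_that("the correlation curve matches a direct computation at threshold 0", {
  set.seed(41)
  n <- 30
  direct <- data.frame(geo_id = paste0("C", 1:n),
                       estimate = runif(n, 0.1, 0.3),
                       se = 0.03, n = rpois(n, 60))
  model <- data.frame(geo_id = paste0("C", 1:n),
                      estimate = runif(n, 0.1, 0.3))
  cc <- correlation_curve(model, direct, thresholds = c(0, 50))
  expect_equal(cc$r[1], stats::cor(model$estimate, direct$estimate),
               tolerance = 1e-12)
  expect_equal(cc$n_geos[1], n)
  # exact agreement gives r = 1 everywhere defined
  cc2 <- correlation_curve(direct, direct, thresholds = c(0, 50, 70))
  expect_true(all(abs(cc2$r[!is.na(cc2$r)] - 1) < 1e-12))
  # a threshold above every county size is undefined
  cc3 <- correlation_curve(model, direct, thresholds = max(direct$n) + 1)
  expect_true(is.na(cc3$r))
  expect_error(correlation_curve(model, direct, thresholds = c(50, 15)),
               "unsorted|sorted|increasing")
})

test_that("the weighted direct estimator is unbiased for the true prevalence", {
  geo <- small_geo(seed = 51, n_states = 4)
  truth <- invlogit(-1.8)
  ests <- vapply(1:10, function(r) {
    tm <- true_model(geo, coef_table(intercept = -1.8), sigma2_state = 0,
                     seed = 60 + r)
    rec <- simulate_survey(geo, tm, 500, seed = 80 + r)
    direct_estimates(rec, "national")$estimate
  }, numeric(1))
  mcse <- stats::sd(ests) / sqrt(length(ests))
  expect_lt(abs(mean(ests) - truth), 2 * mcse + 1e-12)
})
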