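test_that("intercept-only fixed-effect fit recovers the closed-form MLE", {
  y <- c(rep(1, 7), rep(0, 13))
  d <- make_design(y, cbind(`(Intercept)` = rep(1, 20)))
  f <- fit_laplace(d)
  expect_true(f$converged)
  expect_equal(unname(f$beta[1]), logit(7 / 20), tolerance = 1e-8)
  expect_equal(f$aic, -2 * f$loglik + 2 * f$npar)
})

test_that("fixed-effect-only fit matches iteratively reweighted least squares", {
  geo <- small_geo(seed = 1)
  tm <- true_model(geo, sigma2_state = 0, seed = 2)
  rec <- simulate_survey(geo, tm, 150, seed = 3)
  d <- build_design(rec, geo, model_spec(c("age", "sex", "race"), "none"))
  f <- fit_laplace(d)
  g <- stats::glm.fit(d$X, d$y, family = stats::binomial())
  expect_true(f$converged)
  expect_lt(max(abs(f$beta - g$coefficients)), 1e-6)
  expect_equal(f$loglik,
               sum(stats::dbinom(d$y, 1, g$fitted.values, log = TRUE)),
               tolerance = 1e-8)
})

test_that("Laplace fit agrees with the quadrature oracle on small data", {
  for (seed in c(101, 202)) {
    inst <- tiny_instance(seed)
    d <- make_design(inst$y, inst$X, inst$area)
    f <- fit_laplace(d)
    o <- fit_agq(inst$y, inst$X, inst$area)
    expect_true(o$converged)
    expect_lt(abs(f$loglik - o$loglik), 0.05)
    expect_lt(max(abs(f$beta - o$beta)), 0.02)
  }
})

test_that("Laplace fit matches lme4's Laplace objective on moderate data", {
  skip_if_not_installed("lme4")
  geo <- small_geo(seed = 4, n_states = 10)
  tm <- true_model(geo, sigma2_state = 0.3, seed = 5)
  rec <- simulate_survey(geo, tm, 250, seed = 6)
  d <- build_design(rec, geo, model_spec(c("age", "sex"), "state"))
  f <- fit_laplace(d)
  df <- data.frame(y = d$y, age = d$X[, 2], sex = d$X[, 3],
                   state = rec$state)
  g <- lme4::glmer(y ~ age + sex + (1 | state), data = df,
                   family = stats::binomial(), nAGQ = 1)
  expect_lt(abs(f$loglik - as.numeric(stats::logLik(g))), 0.01)
  expect_lt(max(abs(f$beta - lme4::fixef(g))), 0.005)
  expect_lt(abs(f$sigma2[["state"]] -
                  as.numeric(lme4::VarCorr(g)$state)), 0.01)
  expect_lt(max(abs(f$se_beta - sqrt(diag(as.matrix(stats::vcov(g)))))),
            0.01)
})

test_that("estimates are invariant to record order", {
  geo <- small_geo(seed = 7)
  tm <- true_model(geo, sigma2_state = 0.2, seed = 8)
  rec <- simulate_survey(geo, tm, 120, seed = 9)
  spec <- model_spec(c("age", "sex", "zip_income"), "state")
  f1 <- fit_laplace(build_design(rec, geo, spec))
  set.seed(10)
  f2 <- fit_laplace(build_design(rec[sample(nrow(rec)), ], geo, spec))
  expect_lt(max(abs(f1$beta - f2$beta)), 1e-8)
  expect_lt(abs(f1$sigma2 - f2$sigma2), 1e-8)
  expect_lt(abs(f1$loglik - f2$loglik), 1e-8)
})

test_that("identical area proportions drive the variance to the boundary", {
  # every area has exactly 15/50 successes: the between-area variance
  # estimate is 0 and must be reported as a boundary fit
  y <- rep(rep(c(1, 0), times = c(15, 35)), 8)
  area <- rep(1:8, each = 50)
  d <- make_design(y, cbind(`(Intercept)` = rep(1, length(y))), area)
  f <- fit_laplace(d)
  expect_identical(unname(f$sigma2[["state"]]), 0)
  expect_true(any(f$boundary))
  expect_true(is.na(f$sigma2_se[["state"]]))
  # the boundary fit coincides with plain logistic regression
  expect_equal(unname(f$beta[1]), logit(0.3), tolerance = 1e-5)
})

test_that("nested state and county intercepts are both recovered", {
  geo <- generate_geography(12, 4, 2, 2, seed = 12)
  tm <- true_model(geo, coef_table(intercept = -1.5),
                   sigma2_state = 0.4, sigma2_county = 0.25, seed = 13)
  rec <- simulate_survey(geo, tm, 600, seed = 14)
  d <- build_design(rec, geo, model_spec(character(0),
                                         c("state", "county")))
  f <- fit_laplace(d)
  expect_true(f$converged)
  expect_named(f$sigma2, c("state", "county"))
  expect_true(all(f$sigma2 >= 0))
  expect_gt(f$sigma2[["county"]], 0.05)
  expect_length(f$re_modes$state, 12)
  expect_length(f$re_modes$county, 48)
})

test_that("variance explained reproduces published arithmetic", {
  expect_equal(round(variance_explained(0.1950, 0.0134), 1), 93.1)
  expect_equal(round(variance_explained(0.0530, 0.0213), 1), 59.8)
  expect_equal(round(variance_explained(0.0928, 0.0160), 1), 82.8)
  expect_equal(variance_explained(0.5, 0.5), 0)
  expect_error(variance_explained(0, 0.1), "undefined")
})

test_that("the adequacy rule is an inclusive 40% threshold", {
  expect_true(is_adequate(93.1))
  expect_true(is_adequate(40))
  expect_false(is_adequate(39.999))
  expect_false(is_adequate(c(93.1, 20)))
  expect_error(is_adequate(NaN), "finite")
})

test_that("model selection minimizes AIC with deterministic tie-breaks", {
  f1 <- structure(list(aic = 100, npar = 5, converged = TRUE),
                  class = "sae_fit")
  f2 <- structure(list(aic = 90, npar = 8, converged = TRUE),
                  class = "sae_fit")
  f3 <- structure(list(aic = 90, npar = 6, converged = TRUE),
                  class = "sae_fit")
  f4 <- structure(list(aic = 50, npar = 2, converged = FALSE),
                  class = "sae_fit")
  expect_identical(select_model(list(f1)), f1)
  expect_identical(select_model(list(f1, f2)), f2)
  expect_identical(select_model(list(f1, f2, f3)), f3)  # fewer params
  expect_identical(select_model(list(f4, f1)), f1)      # unconverged skipped
  expect_error(select_model(list(f4)), "converged")
})
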