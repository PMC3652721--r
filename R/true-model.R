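#' Define the true generating model for synthetic surveys
#'
#' A true model couples a fixed-effect coefficient table (log-odds
#' scale, dummy-coded with zero-coefficient reference levels) with
#' state- and county-level random-intercept variances and one realized
#' mean-zero normal intercept per state and per county. A child's true
#' obesity risk is `invlogit` of the fixed-effect linear predictor (zip
#' and county covariates of the child's areas) plus the state and county
#' intercepts.
#'
#' Defaults are the study conditions the generator emulates: the
#' published coefficient table ([risk_coefficients()]), a state
#' random-intercept variance of 0.0530 (the state-level between-area
#' variance of the null model) and no county variance.
#'
#' @param geo An `sae_geography`; effects are realized for its areas.
#' @param coefficients Coefficient table as from [risk_coefficients()].
#'   Terms absent from `terms` are ignored.
#' @param sigma2_state,sigma2_county Random-intercept variances (>= 0).
#' @param terms Fixed-effect terms that enter the linear predictor.
#' @param seed RNG seed for the realized random intercepts.
#' @return An object of class `sae_true_model`.
#' @export
true_model <- function(geo, coefficients = risk_coefficients(),
                       sigma2_state = 0.0530, sigma2_county = 0,
                       terms = full_fixed_terms(), seed = 1L) {
  stopifnot(inherits(geo, "sae_geography"),
            sigma2_state >= 0, sigma2_county >= 0)
  check_coefficient_table(coefficients, terms)
  with_seed(seed, {
    state_effects <- stats::rnorm(nrow(geo$states), 0, sqrt(sigma2_state))
    names(state_effects) <- geo$states$state
    county_effects <- stats::rnorm(nrow(geo$counties), 0,
                                   sqrt(sigma2_county))
    names(county_effects) <- geo$counties$county
    structure(list(coefficients = coefficients, terms = terms,
                   sigma2_state = sigma2_state,
                   sigma2_county = sigma2_county,
                   state_effects = state_effects,
                   county_effects = county_effects),
              class = "sae_true_model")
  })
}

#' @export
print.sae_true_model <- function(x, ...) {
  cat(sprintf(
    "sae_true_model: %d fixed terms, sigma2_state=%.4f, sigma2_county=%.4f\n",
    length(x$terms), x$sigma2_state, x$sigma2_county))
  invisible(x)
}

# Per-area fixed-effect contributions under a coefficient table: returns
# a numeric vector indexed like `area_df` rows, summing the coefficients
# of the area's covariate levels for the given area-level terms.
area_coefficient_sum <- function(coefficients, area_df, terms) {
  reg <- sae_term_registry()
  total <- numeric(nrow(area_df))
  for (term in terms) {
    def <- reg[[term]]
    sub <- coefficients[coefficients$term == term, , drop = FALSE]
    total <- total + sub$estimate[match(area_df[[def$column]], sub$level)]
  }
  total
}
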