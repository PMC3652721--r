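#' Simulate a state-stratified survey of children
#'
#' Draws `n_per_state` children per state. Each child's county is
#' sampled within the state proportionally to county size weights, the
#' zip code uniformly within the county, and demographics (sex, age
#' group, race/ethnicity) from configurable marginals (uniform by
#' default). The obesity indicator is Bernoulli with probability
#' `invlogit(eta)`, where `eta` is the true model's fixed-effect linear
#' predictor (zip- and county-level covariates of the child's areas)
#' plus the realized state and county intercepts. Survey weights are
#' inverse sampling fractions: state child population divided by the
#' state sample size.
#'
#' @param geo An `sae_geography`.
#' @param true An `sae_true_model` realized on `geo`.
#' @param n_per_state Children sampled per state (>= 1).
#' @param seed RNG seed.
#' @param demographic_marginals Optional list with named probability
#'   vectors `sex`, `age`, `race` over the declared category labels.
#' @return A `data.frame` with one row per child: `child_id`, `sex`,
#'   `age_group`, `race`, `obese`, `weight`, `state`, `county`, `zip`.
#' @export
simulate_survey <- function(geo, true, n_per_state = 865, seed = 1L,
                            demographic_marginals = NULL) {
  stopifnot(inherits(geo, "sae_geography"), inherits(true, "sae_true_model"))
  n_per_state <- check_count(n_per_state, "n_per_state")
  check_coefficient_table(true$coefficients, true$terms)
  if (!all(geo$states$state %in% names(true$state_effects)) ||
      !all(geo$counties$county %in% names(true$county_effects))) {
    stop("true model effects do not cover the geography", call. = FALSE)
  }
  m <- normalize_marginals(demographic_marginals)
  reg <- sae_term_registry()
  zip_terms <- intersect(true$terms, c("zip_income", "zip_lifestyle",
                                       "zip_urbanization"))
  county_terms <- intersect(true$terms, c("county_income",
                                          "county_urban_rural"))
  zip_fx <- area_coefficient_sum(true$coefficients, geo$zips, zip_terms)
  county_fx <- area_coefficient_sum(true$coefficients, geo$counties,
                                    county_terms)
  intercept <- true$coefficients$estimate[
    true$coefficients$term == "intercept"][1]
  coef_of <- function(term, values) {
    sub <- true$coefficients[true$coefficients$term == term, , drop = FALSE]
    sub$estimate[match(values, sub$level)]
  }

  with_seed(seed, {
    per_state <- lapply(seq_len(nrow(geo$states)), function(s) {
      st <- geo$states$state[s]
      cidx <- which(geo$counties$state == st)
      pick_c <- if (length(cidx) == 1L) rep(cidx, n_per_state) else
        sample(cidx, n_per_state, replace = TRUE,
               prob = geo$counties$size_weight[cidx])
      zip <- vapply(pick_c, function(ci) {
        zi <- which(geo$zips$county == geo$counties$county[ci])
        geo$zips$zip[if (length(zi) == 1L) zi else sample(zi, 1L)]
      }, character(1))
      data.frame(
        state = st,
        county = geo$counties$county[pick_c],
        zip = zip,
        sex = sample(names(m$sex), n_per_state, TRUE, m$sex),
        age_group = sample(names(m$age), n_per_state, TRUE, m$age),
        race = sample(names(m$race), n_per_state, TRUE, m$race),
        weight = geo$states$child_population[s] / n_per_state
      )
    })
    records <- do.call(rbind, per_state)
    records$child_id <- sprintf("K%07d", seq_len(nrow(records)))
    eta <- intercept +
      (if ("sex" %in% true$terms) coef_of("sex", records$sex) else 0) +
      (if ("age" %in% true$terms) coef_of("age", records$age_group) else 0) +
      (if ("race" %in% true$terms) coef_of("race", records$race) else 0) +
      zip_fx[match(records$zip, geo$zips$zip)] +
      county_fx[match(records$county, geo$counties$county)] +
      true$state_effects[records$state] +
      true$county_effects[records$county]
    records$obese <- stats::rbinom(nrow(records), 1L, stats::plogis(eta))
    rownames(records) <- NULL
    records[, c("child_id", "sex", "age_group", "race", "obese", "weight",
                "state", "county", "zip")]
  })
}

#' Generate block-group demographic population cells
#'
#' One post-stratification cell per block group x sex x age group x
#' race/ethnicity (2 x 2 x 8 = 32 cells per block group). Counts are
#' Poisson with mean `mean_children_per_bg` times the demographic cell
#' probability, scaled by the block group's county size weight
#' (normalized to mean 1 across counties) so that larger counties hold
#' more children.
#'
#' @param geo An `sae_geography`.
#' @param mean_children_per_bg Expected children per block group (> 0).
#' @param seed RNG seed.
#' @param demographic_marginals As in [simulate_survey()].
#' @param scale_by_county_weight Scale cell means by county size weight.
#' @return A `data.frame` with columns `bg`, `sex`, `age_group`, `race`,
#'   `count`.
#' @export
generate_population_cells <- function(geo, mean_children_per_bg = 50,
                                      seed = 1L,
                                      demographic_marginals = NULL,
                                      scale_by_county_weight = TRUE) {
  stopifnot(inherits(geo, "sae_geography"))
  if (!is.numeric(mean_children_per_bg) || length(mean_children_per_bg) != 1L ||
      !is.finite(mean_children_per_bg) || mean_children_per_bg <= 0) {
    stop("`mean_children_per_bg` must be a single positive number",
         call. = FALSE)
  }
  m <- normalize_marginals(demographic_marginals)
  cells <- expand.grid(bg = geo$block_groups$bg, sex = names(m$sex),
                       age_group = names(m$age), race = names(m$race),
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  p_cell <- m$sex[cells$sex] * m$age[cells$age_group] * m$race[cells$race]
  scale <- 1
  if (scale_by_county_weight) {
    w <- geo$counties$size_weight / mean(geo$counties$size_weight)
    bg_county <- geo$block_groups$county[
      match(cells$bg, geo$block_groups$bg)]
    scale <- w[match(bg_county, geo$counties$county)]
  }
  with_seed(seed, {
    cells$count <- stats::rpois(nrow(cells),
                                mean_children_per_bg * p_cell * scale)
  })
  cells <- cells[order(cells$bg, cells$sex, cells$age_group, cells$race), ]
  rownames(cells) <- NULL
  cells
}

#' Total child population of a set of cells
#'
#' @param cells Population-cell `data.frame` with a `count` column.
#' @return Total count (integer-valued numeric).
#' @export
population_total <- function(cells) {
  stopifnot("count" %in% names(cells))
  sum(cells$count)
}

normalize_marginals <- function(marginals) {
  default <- list(
    sex = stats::setNames(rep(1 / 2, 2), c("Male", "Female")),
    age = stats::setNames(rep(1 / 2, 2), c("10-14", "15-17")),
    race = stats::setNames(rep(1 / 8, 8), race_levels())
  )
  if (is.null(marginals)) return(default)
  for (nm in names(marginals)) {
    if (!nm %in% names(default)) {
      stop(sprintf("unknown demographic marginal '%s'", nm), call. = FALSE)
    }
    p <- marginals[[nm]]
    if (!setequal(names(p), names(default[[nm]])) || any(p < 0) ||
        sum(p) <= 0) {
      stop(sprintf("invalid marginal for '%s'", nm), call. = FALSE)
    }
    default[[nm]] <- p[names(default[[nm]])] / sum(p)
  }
  default
}
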