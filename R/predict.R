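#' Build the predictive (reduced) risk model
#'
#' The predictive model carries the fixed-effect coefficients and
#' standard errors of the reduced term set — intercept, sex, age group,
#' race/ethnicity, neighborhood income octile and lifestyle class — plus
#' one random-intercept value per state (empirical-Bayes modes from the
#' fit). Neighborhood coefficients estimated at the zip-code level are
#' applied unchanged to block-group covariates (coefficient transfer).
#'
#' Either pass a fitted reduced model (`fit`), or a coefficient table
#' plus state effects directly (for worked examples with published
#' coefficients).
#'
#' @param fit An `sae_fit` of the reduced term set with a state random
#'   term.
#' @param coefficients Coefficient table (as [risk_coefficients()]);
#'   used when `fit` is `NULL`.
#' @param state_effects Named numeric vector of per-state intercepts;
#'   states missing at prediction time get effect 0
#'   (population-average).
#' @param terms Fixed terms of the predictive model.
#' @return An object of class `sae_predictive_model` with `beta`, `se`
#'   (named vectors in design order) and `state_effects`.
#' @export
predictive_model <- function(fit = NULL, coefficients = NULL,
                             state_effects = NULL,
                             terms = reduced_fixed_terms()) {
  if (!is.null(fit)) {
    stopifnot(inherits(fit, "sae_fit"))
    if (!setequal(fit$spec$fixed, terms)) {
      stop("fit does not use the predictive term set", call. = FALSE)
    }
    beta <- fit$beta
    se <- fit$se_beta
    if (is.null(state_effects)) {
      if (!"state" %in% names(fit$re_modes)) {
        stop("fit carries no state random effects", call. = FALSE)
      }
      state_effects <- fit$re_modes$state
    }
  } else {
    stopifnot(!is.null(coefficients))
    check_coefficient_table(coefficients, terms)
    beta <- coefficient_vector(coefficients, terms, "estimate")
    se <- if ("se" %in% names(coefficients)) {
      coefficient_vector(coefficients, terms, "se")
    } else stats::setNames(rep(NA_real_, length(beta)), names(beta))
    if (is.null(state_effects)) state_effects <- numeric(0)
  }
  # individual level coefficients may be NA (inestimable levels); the
  # intercept must exist
  if (!is.finite(beta[["(Intercept)"]])) {
    stop("non-finite intercept", call. = FALSE)
  }
  structure(list(beta = beta, se = se, terms = terms,
                 state_effects = state_effects),
            class = "sae_predictive_model")
}

#' @export
print.sae_predictive_model <- function(x, ...) {
  cat(sprintf("sae_predictive_model: %d coefficients, %d state effects\n",
              length(x$beta), length(x$state_effects)))
  invisible(x)
}

state_effect_of <- function(model, state) {
  e <- model$state_effects[state]
  e[is.na(e)] <- 0
  unname(e)
}

#' Predicted obesity risk for a demographic cell
#'
#' Inverse-logit of the predictive linear predictor for a child of the
#' given sex, age group and race/ethnicity living in a neighborhood with
#' the given income octile and lifestyle class, in the given state.
#' All arguments are vectorized.
#'
#' @param model An `sae_predictive_model`.
#' @param sex,age_group,race Individual demographic labels.
#' @param income_octile Neighborhood income octile label (`"octile 1"`
#'   ... `"octile 8"`) or integer 1-8.
#' @param lifestyle_class Neighborhood lifestyle class label.
#' @param state Optional state id; its random intercept is added
#'   (0 for states without an effect value).
#' @return Probabilities in `[0, 1]`.
#' @examples
#' m <- predictive_model(coefficients = risk_coefficients())
#' cell_risk(m, "Female", "15-17", "White", 8, "Solo Acts")
#' @export
cell_risk <- function(model, sex, age_group, race, income_octile,
                      lifestyle_class, state = NULL) {
  stopifnot(inherits(model, "sae_predictive_model"))
  if (is.numeric(income_octile)) {
    income_octile <- paste0("octile ", income_octile)
  }
  cells <- data.frame(sex = sex, age_group = age_group, race = race,
                      income_octile = income_octile,
                      lifestyle_class = lifestyle_class)
  C <- cell_design(model, cells)
  usable <- is.finite(model$beta)
  eta <- drop(C[, usable, drop = FALSE] %*% model$beta[usable])
  if (!is.null(state)) eta <- eta + state_effect_of(model, state)
  risk <- stats::plogis(eta)
  # cells touching an inestimable coefficient cannot be predicted
  risk[rowSums(abs(C[, !usable, drop = FALSE])) > 0] <- NA_real_
  risk
}

# Dummy-coded design matrix for cell rows carrying columns sex,
# age_group, race, income_octile, lifestyle_class. Errors name any
# unseen level.
cell_design <- function(model, cells) {
  reg <- sae_term_registry()
  col_of <- c(age = "age_group", sex = "sex", race = "race",
              zip_income = "income_octile", zip_lifestyle = "lifestyle_class")
  C <- matrix(0, nrow(cells), length(model$beta),
              dimnames = list(NULL, names(model$beta)))
  C[, "(Intercept)"] <- 1
  for (term in model$terms) {
    def <- reg[[term]]
    values <- cells[[col_of[[term]]]]
    bad <- setdiff(unique(values), def$levels)
    if (length(bad)) {
      stop(sprintf("unseen level '%s' for term '%s'", bad[1], term),
           call. = FALSE)
    }
    for (lv in setdiff(def$levels, def$reference)) {
      C[, paste(term, lv, sep = ":")] <- as.numeric(values == lv)
    }
  }
  C
}

# Join population cells with block-group covariates; cells whose block
# group lacks a covariate are dropped with a message (collected in the
# "skipped" attribute).
prepare_cells <- function(cells, geo) {
  stopifnot(inherits(geo, "sae_geography"))
  i <- match(cells$bg, geo$block_groups$bg)
  if (anyNA(i)) stop("cell block group not found in geography",
                     call. = FALSE)
  cells$income_octile <- geo$block_groups$income_octile[i]
  cells$lifestyle_class <- geo$block_groups$lifestyle_class[i]
  cells$state <- geo$block_groups$state[i]
  bad <- is.na(cells$income_octile) | is.na(cells$lifestyle_class)
  skipped <- cells$bg[bad]
  cells <- cells[!bad, , drop = FALSE]
  attr(cells, "skipped") <- unique(skipped)
  cells
}

#' Block-group prevalence point estimates by post-stratification
#'
#' The model-based prevalence of a block group is the population-
#' weighted average of its demographic-cell risks:
#' `sum(count * risk) / sum(count)`. Block groups whose cells all have
#' zero counts are suppressed from the output.
#'
#' @param model An `sae_predictive_model`.
#' @param cells Population cells (from [generate_population_cells()]).
#' @param geo Geography supplying block-group covariates.
#' @return A `data.frame` (class `sae_results`) with columns `geo_id`,
#'   `level`, `n_children`, `estimate`.
#' @export
block_group_prevalence <- function(model, cells, geo) {
  pp <- prediction_frame(model, cells, geo)
  out <- pp$point
  rownames(out) <- NULL
  class(out) <- c("sae_results", "data.frame")
  out
}

# Shared preparation for point and MC prediction: join block-group
# covariates, drop unpredictable cells (missing covariates or levels
# with inestimable coefficients) and zero-population block groups, and
# assemble the cell design matrix over the estimable coefficients.
prediction_frame <- function(model, cells, geo) {
  cells <- prepare_cells(cells, geo)
  risk <- cell_risk(model, cells$sex, cells$age_group, cells$race,
                    cells$income_octile, cells$lifestyle_class,
                    cells$state)
  dropped <- sum(is.na(risk))
  cells <- cells[!is.na(risk), , drop = FALSE]
  risk <- risk[!is.na(risk)]
  den_all <- rowsum(cells$count, cells$bg)
  keep_bg <- rownames(den_all)[den_all[, 1] > 0]
  sel <- cells$bg %in% keep_bg
  cells <- cells[sel, , drop = FALSE]
  risk <- risk[sel]
  bg <- factor(cells$bg, levels = keep_bg)
  den <- as.numeric(rowsum(cells$count, bg))
  num <- as.numeric(rowsum(cells$count * risk, bg))
  point <- data.frame(geo_id = keep_bg,
                      level = rep("block_group", length(keep_bg)),
                      n_children = den, estimate = num / den)
  usable <- is.finite(model$beta)
  C <- cell_design(model, cells)[, usable, drop = FALSE]
  list(point = point, cells = cells, bg = bg, den = den, C = C,
       usable = usable, n_dropped_cells = dropped,
       st_eff = state_effect_of(model, cells$state))
}

#' Monte-Carlo confidence intervals for block-group SAEs
#'
#' Draws each fixed-effect coefficient independently from
#' `Normal(beta, se)` for each of `n_draws` draws (state random
#' intercepts are held at their fitted values), recomputes every block
#' group's population-weighted prevalence per draw, and reports the
#' 2.5th/97.5th percentile interval, its width, and the coefficient of
#' variation (MC standard deviation over the point estimate).
#'
#' @param model An `sae_predictive_model` with finite `se`.
#' @param cells Population cells.
#' @param geo Geography.
#' @param n_draws Number of MC draws (>= 2), default 1000.
#' @param seed RNG seed; results are reproducible given the seed.
#' @param chunk Draws processed per block (memory control).
#' @return An `sae_results` data.frame with `geo_id`, `level`,
#'   `n_children`, `estimate`, `ci_low`, `ci_high`, `ci_width`, `cv`,
#'   `n_draws`, `seed`; the per-draw block-group prevalences are kept in
#'   the `"draws"` attribute for draw-wise aggregation.
#' @export
mc_intervals <- function(model, cells, geo, n_draws = 1000L, seed = 1L,
                         chunk = 250L) {
  stopifnot(inherits(model, "sae_predictive_model"))
  n_draws <- check_count(n_draws, "n_draws", min = 2L)
  pp <- prediction_frame(model, cells, geo)
  point <- pp$point
  beta <- model$beta[pp$usable]
  se <- model$se[pp$usable]
  if (any(!is.finite(se))) {
    stop("coefficient standard errors are missing; cannot simulate intervals",
         call. = FALSE)
  }
  p <- length(beta)
  # all coefficient draws are generated up front so results do not
  # depend on the chunk size
  B <- with_seed(seed, {
    matrix(stats::rnorm(n_draws * p, rep(beta, each = n_draws),
                        rep(se, each = n_draws)), n_draws, p)
  })
  draws <- matrix(NA_real_, nrow(point), n_draws,
                  dimnames = list(point$geo_id, NULL))
  done <- 0L
  while (done < n_draws) {
    k <- min(chunk, n_draws - done)
    eta <- tcrossprod(pp$C, B[done + seq_len(k), , drop = FALSE]) +
      pp$st_eff
    num <- rowsum(stats::plogis(eta) * pp$cells$count, pp$bg)
    draws[, done + seq_len(k)] <- num / pp$den
    done <- done + k
  }
  finalize_results(point, draws, n_draws, seed)
}

finalize_results <- function(point, draws, n_draws, seed) {
  qs <- apply(draws, 1, quantile7, probs = c(0.025, 0.975))
  point$ci_low <- qs[1, ]
  point$ci_high <- qs[2, ]
  point$ci_width <- point$ci_high - point$ci_low
  sd_d <- apply(draws, 1, stats::sd)
  point$cv <- ifelse(point$estimate > 0, sd_d / point$estimate, NA_real_)
  point$n_draws <- n_draws
  point$seed <- seed
  attr(point, "draws") <- draws
  class(point) <- c("sae_results", "data.frame")
  point
}

#' Aggregate block-group SAEs to county, state, or national level
#'
#' Point estimates aggregate as child-population-weighted means of the
#' block-group estimates. Intervals are re-derived draw-wise: each MC
#' draw's block-group prevalences are averaged with the same population
#' weights, and the percentiles are taken over the aggregated draws
#' (never by averaging interval bounds).
#'
#' @param results Block-group `sae_results` (with draws attribute for
#'   interval aggregation).
#' @param geo Geography for the block-group-to-parent mapping.
#' @param level `"county"`, `"state"`, or `"national"`.
#' @return An `sae_results` data.frame at the requested level.
#' @export
aggregate_sae <- function(results, geo,
                          level = c("county", "state", "national")) {
  level <- match.arg(level)
  stopifnot(inherits(results, "sae_results"))
  i <- match(results$geo_id, geo$block_groups$bg)
  if (anyNA(i)) {
    stop(sprintf("block group '%s' not found in geography",
                 results$geo_id[which(is.na(i))[1]]), call. = FALSE)
  }
  parent <- switch(level,
                   county = geo$block_groups$county[i],
                   state = geo$block_groups$state[i],
                   national = rep("national", length(i)))
  w <- results$n_children
  g <- factor(parent, levels = unique(parent))
  den <- as.numeric(rowsum(w, g))
  est <- as.numeric(rowsum(w * results$estimate, g)) / den
  out <- data.frame(geo_id = levels(g), level = level, n_children = den,
                    estimate = est)
  draws <- attr(results, "draws")
  if (!is.null(draws)) {
    # align with `results` even if it was subset after simulation
    draws <- draws[results$geo_id, , drop = FALSE]
    agg <- rowsum(draws * w, g) / den
    out <- finalize_results(out, agg, results$n_draws[1], results$seed[1])
  } else {
    class(out) <- c("sae_results", "data.frame")
  }
  out
}

#' Summary statistics of interval widths and CVs at one level
#'
#' Mirrors the usual reporting layout: N, minimum, first quartile,
#' median, third quartile, maximum, mean and interquartile range of the
#' 95% CI widths and of the coefficients of variation (CI widths on the
#' percentage-point scale).
#'
#' @param results An `sae_results` with `ci_width` and `cv`.
#' @return A `data.frame` with one row per statistic family.
#' @export
summarize_sae <- function(results) {
  stopifnot(inherits(results, "sae_results"),
            all(c("ci_width", "cv") %in% names(results)))
  one <- function(x, what, scale = 1) {
    x <- x[is.finite(x)] * scale
    q <- quantile7(x, c(0.25, 0.5, 0.75))
    data.frame(statistic = what, n = length(x), min = min(x), q1 = q[1],
               median = q[2], q3 = q[3], max = max(x), mean = mean(x),
               iqr = q[3] - q[1])
  }
  rbind(one(results$ci_width, "ci_width_pp", scale = 100),
        one(results$cv, "cv"))
}
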