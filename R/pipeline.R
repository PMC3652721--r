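#' Default run configuration
#'
#' A complete configuration for an end-to-end synthetic run: geography
#' sizes, true-model variances, per-state sample size, the model roster,
#' Monte-Carlo draw count and reliability thresholds. Defaults are the
#' study conditions the generator emulates (51 states, mean state sample
#' of 865 children, state-level variance 0.0530, 1000 MC draws,
#' reliability rule n >= 30 and relative SE < 0.3).
#'
#' @return A nested list of class `sae_run_config`.
#' @export
default_run_config <- function() {
  structure(list(
    seed = 1L,
    geography = list(n_states = 51L, counties_per_state = 4L,
                     zips_per_county = 5L, bgs_per_county = 8L,
                     bg_covariate_cor = 0),
    population = list(mean_children_per_bg = 50),
    model = list(sigma2_state = 0.0530, sigma2_county = 0,
                 terms = full_fixed_terms()),
    survey = list(n_per_state = 865L),
    fit = list(fixed_terms = full_fixed_terms(),
               structures = c("state", "county", "state+county", "zip")),
    predict = list(n_draws = 1000L),
    evaluate = list(min_n = 30L, max_rse = 0.3,
                    thresholds = c(15, 30, 50, 100, 150, 200))
  ), class = "sae_run_config")
}

#' Load and validate a run configuration
#'
#' Reads a YAML configuration, fills unspecified fields from
#' [default_run_config()], rejects unknown keys, and validates every
#' field against the preconditions of the operation that consumes it.
#'
#' @param path Path to a YAML file, or a named list.
#' @param seed Optional seed overriding the configured one.
#' @return A validated `sae_run_config`.
#' @export
load_run_config <- function(path, seed = NULL) {
  raw <- if (is.character(path)) yaml::read_yaml(path) else path
  if (is.null(raw)) raw <- list()
  stopifnot(is.list(raw))
  config <- default_run_config()
  unknown <- setdiff(names(raw), names(config))
  if (length(unknown)) {
    stop(sprintf("unknown config key(s): %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  for (section in names(raw)) {
    if (section == "seed") { config$seed <- raw$seed; next }
    bad <- setdiff(names(raw[[section]]), names(config[[section]]))
    if (length(bad)) {
      stop(sprintf("unknown config key(s) in '%s': %s", section,
                   paste(bad, collapse = ", ")), call. = FALSE)
    }
    config[[section]][names(raw[[section]])] <- raw[[section]]
  }
  if (!is.null(seed)) config$seed <- seed
  validate_run_config(config)
}

validate_run_config <- function(config) {
  check_seed(config$seed)
  g <- config$geography
  check_count(g$n_states, "geography.n_states")
  check_count(g$counties_per_state, "geography.counties_per_state")
  check_count(g$zips_per_county, "geography.zips_per_county")
  check_count(g$bgs_per_county, "geography.bgs_per_county")
  stopifnot(g$bg_covariate_cor >= 0, g$bg_covariate_cor <= 1)
  if (config$population$mean_children_per_bg <= 0) {
    stop("population.mean_children_per_bg must be positive", call. = FALSE)
  }
  stopifnot(config$model$sigma2_state >= 0, config$model$sigma2_county >= 0,
            all(config$model$terms %in% full_fixed_terms()))
  check_count(config$survey$n_per_state, "survey.n_per_state")
  stopifnot(all(config$fit$fixed_terms %in% full_fixed_terms()))
  known <- c("state", "county", "state+county", "zip")
  if (!all(config$fit$structures %in% known)) {
    stop("fit.structures must be among state, county, state+county, zip",
         call. = FALSE)
  }
  check_count(config$predict$n_draws, "predict.n_draws", min = 2L)
  check_count(config$evaluate$min_n, "evaluate.min_n", min = 1L)
  stopifnot(config$evaluate$max_rse > 0,
            !is.unsorted(config$evaluate$thresholds))
  config
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(unclass(config), tmp, auto_unbox = TRUE,
                       digits = NA, pretty = FALSE)
  unname(tools::md5sum(tmp))
}

write_provenance <- function(dir, config, files) {
  info <- list(
    config_hash = config_hash(config),
    seed = config$seed,
    package = "saeprev",
    package_version = as.character(utils::packageVersion("saeprev")),
    files = as.list(unname(tools::md5sum(file.path(dir, files))))
  )
  names(info$files) <- files
  jsonlite::write_json(info, file.path(dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

write_csv <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
}

#' Simulate a full synthetic data set to disk
#'
#' Builds the geography, the true model, the survey sample and the
#' population cells under the configured seed and writes them as plain
#' CSV (one file per table) plus a provenance sidecar with the config
#' hash and per-file checksums. Sub-seeds for the four generators are
#' derived deterministically from the configured seed.
#'
#' @param config An `sae_run_config` (or path to one).
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the in-memory `geo`, `true`,
#'   `records`, `cells`.
#' @export
run_simulate <- function(config, out_dir) {
  config <- as_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  g <- config$geography
  seed <- as.integer(config$seed) %% 2000000000L
  geo <- generate_geography(g$n_states, g$counties_per_state,
                            g$zips_per_county, g$bgs_per_county,
                            seed = seed, bg_covariate_cor = g$bg_covariate_cor)
  true <- true_model(geo, sigma2_state = config$model$sigma2_state,
                     sigma2_county = config$model$sigma2_county,
                     terms = config$model$terms, seed = seed + 1L)
  records <- simulate_survey(geo, true, config$survey$n_per_state,
                             seed = seed + 2L)
  cells <- generate_population_cells(
    geo, config$population$mean_children_per_bg, seed = seed + 3L)

  write_csv(records, file.path(out_dir, "survey.csv"))
  write_csv(cells, file.path(out_dir, "population_cells.csv"))
  write_csv(geo$states, file.path(out_dir, "states.csv"))
  write_csv(geo$counties, file.path(out_dir, "covariates_county.csv"))
  write_csv(geo$zips, file.path(out_dir, "covariates_zip.csv"))
  write_csv(geo$block_groups,
            file.path(out_dir, "covariates_block_group.csv"))
  true_df <- data.frame(kind = c(rep("state_effect",
                                     length(true$state_effects)),
                                 rep("county_effect",
                                     length(true$county_effects))),
                        id = c(names(true$state_effects),
                               names(true$county_effects)),
                        value = c(unname(true$state_effects),
                                  unname(true$county_effects)))
  write_csv(true_df, file.path(out_dir, "true_effects.csv"))
  write_provenance(out_dir, config,
                   c("survey.csv", "population_cells.csv", "states.csv",
                     "covariates_county.csv", "covariates_zip.csv",
                     "covariates_block_group.csv", "true_effects.csv"))
  invisible(list(geo = geo, true = true, records = records, cells = cells))
}

#' Read a simulated data directory back into memory
#'
#' @param data_dir Directory written by [run_simulate()].
#' @return A list with `geo`, `records`, `cells`.
#' @export
read_data_dir <- function(data_dir) {
  rd <- function(f) utils::read.csv(file.path(data_dir, f),
                                    stringsAsFactors = FALSE)
  geo <- structure(list(states = rd("states.csv"),
                        counties = rd("covariates_county.csv"),
                        zips = rd("covariates_zip.csv"),
                        block_groups = rd("covariates_block_group.csv")),
                   class = "sae_geography")
  validate_geography(geo)
  list(geo = geo, records = rd("survey.csv"),
       cells = rd("population_cells.csv"))
}

parse_structure <- function(s) {
  if (s == "state+county") c("state", "county") else s
}

#' Fit the configured model roster and the predictive model
#'
#' Fits null and full models for every configured random structure,
#' writes the adequacy table (between-area variances and percent
#' explained), the coefficient table of the AIC-selected full model,
#' and a fit-metadata JSON. Then refits the reduced predictive term set
#' with a state random intercept and writes the predictive model
#' (coefficients, SEs, state effects) for the prediction stage.
#'
#' @param data_dir Directory from [run_simulate()].
#' @param config An `sae_run_config`.
#' @param out_dir Output directory.
#' @return Invisibly, the roster list plus `predictive`.
#' @export
run_fit <- function(data_dir, config, out_dir) {
  config <- as_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  dat <- read_data_dir(data_dir)
  structures <- lapply(config$fit$structures, parse_structure)
  roster <- fit_model_roster(dat$records, dat$geo,
                             fixed = config$fit$fixed_terms,
                             structures = structures)
  write_csv(roster$adequacy, file.path(out_dir, "adequacy.csv"))
  selected_fit <- roster$fits[[roster$selected]]$full
  write_csv(fit_summary_table(selected_fit),
            file.path(out_dir, "coefficients.csv"))

  meta <- list(
    selected_model = roster$selected,
    structures = config$fit$structures,
    models = lapply(roster$fits, function(f) {
      list(random = names(f$full$sigma2),
           sigma2_null = as.list(f$null$sigma2),
           sigma2_full = as.list(f$full$sigma2),
           loglik = f$full$loglik, aic = f$full$aic,
           converged = f$full$converged)
    })
  )
  jsonlite::write_json(meta, file.path(out_dir, "model_fit.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  reduced <- fit_laplace(build_design(dat$records, dat$geo,
                                      model_spec(reduced_fixed_terms(),
                                                 "state")))
  if (!reduced$converged) {
    stop("predictive-model refit did not converge", call. = FALSE)
  }
  pm <- predictive_model(reduced)
  jsonlite::write_json(
    list(terms = pm$terms, coefficient_name = names(pm$beta),
         coefficient = unname(pm$beta), se = unname(pm$se),
         state = names(pm$state_effects),
         state_effect = unname(pm$state_effects),
         sigma2_state = unname(reduced$sigma2["state"])),
    file.path(out_dir, "predictive_model.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write_provenance(out_dir, config,
                   c("adequacy.csv", "coefficients.csv", "model_fit.json",
                     "predictive_model.json"))
  invisible(c(roster, list(predictive = pm)))
}

read_predictive_model <- function(fit_dir) {
  j <- jsonlite::read_json(file.path(fit_dir, "predictive_model.json"),
                           simplifyVector = TRUE)
  structure(list(beta = stats::setNames(as.numeric(j$coefficient),
                                        j$coefficient_name),
                 se = stats::setNames(as.numeric(j$se),
                                      j$coefficient_name),
                 terms = j$terms,
                 state_effects = stats::setNames(as.numeric(j$state_effect),
                                                 j$state)),
            class = "sae_predictive_model")
}

#' Produce SAE files at all geography levels
#'
#' Computes block-group SAEs with Monte-Carlo intervals from the stored
#' predictive model and population cells, aggregates draw-wise to
#' county, state and national levels, and writes one CSV per level plus
#' the interval-width / CV summary table.
#'
#' @param data_dir Directory from [run_simulate()].
#' @param fit_dir Directory from [run_fit()].
#' @param config An `sae_run_config`.
#' @param out_dir Output directory.
#' @return Invisibly, a list of `sae_results` per level.
#' @export
run_predict <- function(data_dir, fit_dir, config, out_dir) {
  config <- as_config(config)
  if (!file.exists(file.path(fit_dir, "predictive_model.json"))) {
    stop("fit artifacts not found; run the fit stage first", call. = FALSE)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  dat <- read_data_dir(data_dir)
  pm <- read_predictive_model(fit_dir)
  seed <- (as.integer(config$seed) + 4L) %% 2000000000L
  bg <- mc_intervals(pm, dat$cells, dat$geo,
                     n_draws = config$predict$n_draws, seed = seed)
  levels <- list(block_group = bg,
                 county = aggregate_sae(bg, dat$geo, "county"),
                 state = aggregate_sae(bg, dat$geo, "state"),
                 national = aggregate_sae(bg, dat$geo, "national"))
  for (nm in names(levels)) {
    write_csv(as.data.frame(levels[[nm]]),
              file.path(out_dir, paste0("sae_", nm, ".csv")))
  }
  summary_df <- do.call(rbind, lapply(names(levels), function(nm) {
    cbind(level = nm, summarize_sae(levels[[nm]]))
  }))
  write_csv(summary_df, file.path(out_dir, "sae_summary.csv"))
  write_provenance(out_dir, config,
                   c("sae_block_group.csv", "sae_county.csv",
                     "sae_state.csv", "sae_national.csv",
                     "sae_summary.csv"))
  invisible(levels)
}

#' Validate model-based SAEs against direct survey estimates
#'
#' Computes weighted county-level direct estimates from the survey,
#' applies the reliability filter, runs the paired comparison against
#' the county SAE file, and writes the comparison CSV/JSON and the
#' correlation-versus-minimum-sample-size curve.
#'
#' @param data_dir Directory from [run_simulate()].
#' @param sae_dir Directory from [run_predict()].
#' @param config An `sae_run_config`.
#' @param out_dir Output directory.
#' @return Invisibly, a list with `comparison`, `curve`,
#'   `n_reliable`, `n_total`.
#' @export
run_evaluate <- function(data_dir, sae_dir, config, out_dir) {
  config <- as_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  dat <- read_data_dir(data_dir)
  model_county <- utils::read.csv(file.path(sae_dir, "sae_county.csv"),
                                  stringsAsFactors = FALSE)
  direct <- direct_estimates(dat$records, "county")
  reliable <- apply_reliability_filter(direct,
                                       min_n = config$evaluate$min_n,
                                       max_rse = config$evaluate$max_rse)
  curve <- correlation_curve(model_county, direct,
                             thresholds = config$evaluate$thresholds)
  write_csv(curve, file.path(out_dir, "correlation_curve.csv"))
  files <- c("correlation_curve.csv", "comparison.json")
  if (nrow(reliable) >= 2L) {
    cmp <- compare_paired(model_county, reliable)
    write_csv(data.frame(geo_id = cmp$geo_id,
                         difference_pp = cmp$differences_pp),
              file.path(out_dir, "comparison.csv"))
    files <- c(files, "comparison.csv")
    summary <- list(n_counties_total = nrow(direct),
                    n_counties_reliable = nrow(reliable),
                    t_statistic = cmp$t_statistic, p_value = cmp$p_value,
                    quartiles_pp = as.list(cmp$quartiles_pp),
                    n_significant = cmp$n_significant)
  } else {
    cmp <- NULL
    summary <- list(n_counties_total = nrow(direct),
                    n_counties_reliable = nrow(reliable),
                    note = "zero or one reliable county; no paired comparison")
  }
  jsonlite::write_json(summary, file.path(out_dir, "comparison.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write_provenance(out_dir, config, files)
  invisible(list(comparison = cmp, curve = curve,
                 n_reliable = nrow(reliable), n_total = nrow(direct)))
}

#' Run the whole pipeline under one configuration
#'
#' Simulate, fit, predict and evaluate, writing each stage under its
#' own subdirectory of `out_dir`. A fixed seed reproduces every output
#' byte-identically.
#'
#' @param config An `sae_run_config`, a path to a YAML config, or
#'   `NULL` for the defaults.
#' @param out_dir Output root directory.
#' @return Invisibly, a list with the per-stage return values.
#' @export
run_pipeline <- function(config = NULL, out_dir) {
  config <- as_config(config)
  data_dir <- file.path(out_dir, "data")
  fit_dir <- file.path(out_dir, "fit")
  sae_dir <- file.path(out_dir, "sae")
  eval_dir <- file.path(out_dir, "eval")
  sim <- run_simulate(config, data_dir)
  fit <- run_fit(data_dir, config, fit_dir)
  sae <- run_predict(data_dir, fit_dir, config, sae_dir)
  ev <- run_evaluate(data_dir, sae_dir, config, eval_dir)
  invisible(list(simulate = sim, fit = fit, predict = sae, evaluate = ev))
}

as_config <- function(config) {
  if (is.null(config)) return(default_run_config())
  if (is.character(config)) return(load_run_config(config))
  if (inherits(config, "sae_run_config")) return(validate_run_config(config))
  load_run_config(config)
}
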