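#' Specify a multilevel obesity model
#'
#' Declares the categorical fixed-effect terms (in model order, each
#' with its registry reference level) and the random-intercept
#' structure. The four structures of interest are a single state,
#' county, or zip-code random intercept, or nested state + county
#' (county identifiers are globally unique, so the nesting is purely
#' structural).
#'
#' @param fixed Character vector of fixed-term names from
#'   [full_fixed_terms()].
#' @param random `NULL`/"none", `"state"`, `"county"`, `"zip"`, or
#'   `c("state", "county")`.
#' @return An object of class `sae_model_spec`.
#' @export
model_spec <- function(fixed = full_fixed_terms(), random = "state") {
  reg <- sae_term_registry()
  if (!all(fixed %in% names(reg))) {
    stop(sprintf("unknown fixed term(s): %s",
                 paste(setdiff(fixed, names(reg)), collapse = ", ")),
         call. = FALSE)
  }
  if (is.null(random) || identical(random, "none")) random <- character(0)
  allowed <- list(character(0), "state", "county", "zip",
                  c("state", "county"))
  if (!any(vapply(allowed, identical, logical(1), y = random))) {
    stop("`random` must be none, 'state', 'county', 'zip', or c('state','county')",
         call. = FALSE)
  }
  structure(list(fixed = fixed, random = random), class = "sae_model_spec")
}

#' Build the model design bundle from survey records
#'
#' Dummy-codes the declared fixed terms (one column per non-reference
#' level, in declared level order) against the survey records and the
#' area covariates of each record's zip code and county, and builds
#' sparse indicator matrices for the random-intercept terms.
#'
#' @param records Survey record `data.frame` as from [simulate_survey()].
#' @param geo An `sae_geography` covering the records' areas.
#' @param spec An `sae_model_spec`.
#' @return A list (class `sae_design`) with `y`, dense matrix `X`
#'   (first column the intercept), list `Z` of sparse indicator
#'   matrices, `groups` (area id levels per random term), and a
#'   `term_map` data.frame mapping design columns back to (term, level).
#' @export
build_design <- function(records, geo, spec = model_spec()) {
  stopifnot(inherits(spec, "sae_model_spec"), inherits(geo, "sae_geography"))
  reg <- sae_term_registry()
  need <- c("obese", "state", "county", "zip")
  if (!all(need %in% names(records))) {
    stop("records lack required columns", call. = FALSE)
  }
  zi <- match(records$zip, geo$zips$zip)
  ci <- match(records$county, geo$counties$county)
  if (anyNA(zi) || anyNA(ci) ||
      !all(records$state %in% geo$states$state)) {
    stop("record areas not found in geography", call. = FALSE)
  }

  n <- nrow(records)
  cols <- list(`(Intercept)` = rep(1, n))
  term_map <- data.frame(column = "(Intercept)", term = "intercept",
                         level = "(Intercept)")
  for (term in spec$fixed) {
    def <- reg[[term]]
    values <- switch(def$source,
                     record = records[[def$column]],
                     zip = geo$zips[[def$column]][zi],
                     county = geo$counties[[def$column]][ci])
    bad <- setdiff(unique(values), def$levels)
    if (length(bad)) {
      stop(sprintf("unseen level '%s' for term '%s'", bad[1], term),
           call. = FALSE)
    }
    for (lv in setdiff(def$levels, def$reference)) {
      nm <- paste(term, lv, sep = ":")
      cols[[nm]] <- as.numeric(values == lv)
      term_map <- rbind(term_map,
                        data.frame(column = nm, term = term, level = lv))
    }
  }
  X <- do.call(cbind, cols)
  colnames(X) <- names(cols)

  Z <- list()
  groups <- list()
  for (rt in spec$random) {
    ids <- switch(rt, state = records$state, county = records$county,
                  zip = records$zip)
    univ <- switch(rt, state = geo$states$state,
                   county = geo$counties$county, zip = geo$zips$zip)
    lev <- univ[univ %in% unique(ids)]
    f <- factor(ids, levels = lev)
    Z[[rt]] <- Matrix::sparseMatrix(i = seq_len(n), j = as.integer(f),
                                    x = 1, dims = c(n, length(lev)),
                                    dimnames = list(NULL, lev))
    groups[[rt]] <- lev
  }

  structure(list(y = as.numeric(records$obese), X = X, Z = Z,
                 groups = groups, term_map = term_map, spec = spec),
            class = "sae_design")
}
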