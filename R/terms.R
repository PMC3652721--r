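#' @title Model term registry
#' @description
#' The obesity-risk model uses categorical terms at three levels:
#' individual (age group, sex, race/ethnicity), neighborhood (median
#' household income octile, lifestyle segmentation class, urbanization
#' class — measured at the zip-code level for model fitting and carried
#' over to block groups for prediction), and county (income octile,
#' urban-rural class). Every term is dummy-coded against a declared
#' reference level; reference levels carry coefficient 0.
#' @name term-registry
NULL

#' Category labels for area covariates
#'
#' Label sets for the categorical area covariates: 12 lifestyle
#' segmentation classes, 11 urbanization classes, and the 6-level
#' county urban-rural classification.
#'
#' @return Character vector of level labels.
#' @export
lifestyle_levels <- function() {
  c("High Society", "Upscale Avenues", "Metropolis", "Solo Acts",
    "Senior Styles", "Scholars and Patriots", "High Hopes", "Global Roots",
    "Family Portrait", "Traditional Living", "Factories and Farms",
    "American Quilt")
}

#' @rdname lifestyle_levels
#' @export
urbanization_levels <- function() {
  c("Principal Urban Centers I", "Principal Urban Centers II",
    "Metro Cities I", "Metro Cities II", "Urban Outskirts I",
    "Urban Outskirts II", "Suburban Periphery I", "Suburban Periphery II",
    "Small Towns", "Rural I", "Rural II")
}

#' @rdname lifestyle_levels
#' @export
urban_rural_levels <- function() {
  c("Central metro", "Fringe metro", "Medium metro", "Small metro",
    "Micropolitan", "Noncore rural")
}

#' @rdname lifestyle_levels
#' @export
race_levels <- function() {
  c("White", "Black", "Hispanic", "Asian",
    "American Indian/Alaska Native", "Native Hawaiian/Pacific Islander",
    "Multiracial", "Other")
}

income_octile_levels <- function() paste0("octile ", 1:8)

# Registry of categorical fixed-effect terms. `source` says where the
# value lives: on the survey record, on the zip-code row, or on the
# county row. For prediction the zip-level terms are read from the
# block-group row instead (coefficient transfer).
sae_term_registry <- function() {
  list(
    age = list(source = "record", column = "age_group",
               levels = c("10-14", "15-17"), reference = "15-17"),
    sex = list(source = "record", column = "sex",
               levels = c("Male", "Female"), reference = "Female"),
    race = list(source = "record", column = "race",
                levels = race_levels(), reference = "White"),
    zip_income = list(source = "zip", column = "income_octile",
                      levels = income_octile_levels(),
                      reference = "octile 8"),
    zip_lifestyle = list(source = "zip", column = "lifestyle_class",
                         levels = lifestyle_levels(),
                         reference = "Solo Acts"),
    zip_urbanization = list(source = "zip", column = "urbanization_class",
                            levels = urbanization_levels(),
                            reference = "Principal Urban Centers I"),
    county_income = list(source = "county", column = "income_octile",
                         levels = income_octile_levels(),
                         reference = "octile 8"),
    county_urban_rural = list(source = "county", column = "urban_rural_class",
                              levels = urban_rural_levels(),
                              reference = "Central metro")
  )
}

#' All fixed-effect term names of the full risk model
#'
#' @return Character vector of term names in model order.
#' @export
full_fixed_terms <- function() names(sae_term_registry())

#' Fixed-effect terms of the reduced (predictive) risk model
#'
#' County-level covariates and the urbanization classes are dropped from
#' the predictive model (their coefficients are not significant once
#' individual demographics, neighborhood income and lifestyle are
#' controlled for), leaving age, sex, race, neighborhood income octile
#' and lifestyle class.
#'
#' @return Character vector of term names.
#' @export
reduced_fixed_terms <- function() {
  c("age", "sex", "race", "zip_income", "zip_lifestyle")
}

#' Reference coefficient table for the childhood obesity risk model
#'
#' Published fixed-effect estimates (log-odds scale) and standard errors
#' for the full multilevel childhood obesity model estimated from a
#' state-stratified national children's health survey. Reference levels
#' carry coefficient 0 and are flagged. This table is the package default
#' for the synthetic-data generator's true model and for worked-example
#' predictions.
#'
#' @return A `data.frame` with columns `term`, `level`, `estimate`, `se`,
#'   `reference`.
#' @export
risk_coefficients <- function() {
  reg <- sae_term_registry()
  rows <- list(data.frame(term = "intercept", level = "(Intercept)",
                          estimate = -3.4529, se = 0.15,
                          reference = FALSE))
  est <- list(
    age = c("10-14" = 0.4117),
    sex = c("Male" = 0.5753),
    race = c("Black" = 0.6804, "Hispanic" = 0.5697, "Asian" = -0.1188,
             "American Indian/Alaska Native" = 0.7070,
             "Native Hawaiian/Pacific Islander" = 0.7325,
             "Multiracial" = 0.1655, "Other" = 0.0220),
    zip_income = c("octile 1" = 0.8478, "octile 2" = 0.7535,
                   "octile 3" = 0.6750, "octile 4" = 0.7204,
                   "octile 5" = 0.5944, "octile 6" = 0.4319,
                   "octile 7" = 0.3410),
    zip_lifestyle = c("High Society" = 0.3810, "Upscale Avenues" = 0.3063,
                      "Metropolis" = 0.3515, "Senior Styles" = 0.2716,
                      "Scholars and Patriots" = -0.1758,
                      "High Hopes" = 0.3312, "Global Roots" = 0.4404,
                      "Family Portrait" = 0.4092,
                      "Traditional Living" = 0.3541,
                      "Factories and Farms" = 0.4768,
                      "American Quilt" = 0.3711),
    zip_urbanization = c("Principal Urban Centers II" = 0.0574,
                         "Metro Cities I" = -0.0739,
                         "Metro Cities II" = 0.1325,
                         "Urban Outskirts I" = 0.0561,
                         "Urban Outskirts II" = 0.1739,
                         "Suburban Periphery I" = -0.0788,
                         "Suburban Periphery II" = 0.0746,
                         "Small Towns" = 0.1453,
                         "Rural I" = 0.0458, "Rural II" = 0.2242),
    county_income = c("octile 1" = -0.1670, "octile 2" = -0.1919,
                      "octile 3" = -0.1783, "octile 4" = -0.1616,
                      "octile 5" = -0.0259, "octile 6" = -0.0455,
                      "octile 7" = 0.0031),
    county_urban_rural = c("Fringe metro" = 0.0027, "Medium metro" = 0.0118,
                           "Small metro" = -0.0168, "Micropolitan" = -0.0136,
                           "Noncore rural" = -0.0526)
  )
  ses <- list(
    age = c("10-14" = 0.03),
    sex = c("Male" = 0.03),
    race = c("Black" = 0.05478, "Hispanic" = 0.05, "Asian" = 0.1714,
             "American Indian/Alaska Native" = 0.14,
             "Native Hawaiian/Pacific Islander" = 0.25,
             "Multiracial" = 0.12, "Other" = 0.12),
    zip_income = c(0.11, 0.11, 0.10, 0.10, 0.10, 0.08, 0.08),
    zip_lifestyle = c(0.12, 0.12, 0.12, 0.13, 0.17, 0.11, 0.11, 0.12,
                      0.11, 0.13, 0.13),
    zip_urbanization = c(0.12, 0.11, 0.11, 0.11, 0.13, 0.11, 0.12, 0.14,
                         0.13, 0.14),
    county_income = c(0.12, 0.11, 0.10, 0.10, 0.10, 0.10, 0.09),
    county_urban_rural = c(0.07, 0.06, 0.07, 0.07, 0.08)
  )
  for (term in names(reg)) {
    def <- reg[[term]]
    e <- est[[term]]
    s <- unname(ses[[term]])
    lv <- def$levels
    estimate <- ifelse(lv %in% names(e), e[lv], 0)
    se <- rep(0, length(lv))
    se[lv %in% names(e)] <- s
    rows[[term]] <- data.frame(term = term, level = lv,
                               estimate = unname(estimate), se = se,
                               reference = lv == def$reference)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Validate a coefficient table against the registry: every term present
# with exactly its registry levels and a zero-coefficient reference row.
check_coefficient_table <- function(coefficients,
                                    terms = full_fixed_terms()) {
  stopifnot(is.data.frame(coefficients),
            all(c("term", "level", "estimate") %in% names(coefficients)))
  reg <- sae_term_registry()
  if (!any(coefficients$term == "intercept")) {
    stop("coefficient table lacks an intercept row", call. = FALSE)
  }
  for (term in terms) {
    def <- reg[[term]]
    sub <- coefficients[coefficients$term == term, , drop = FALSE]
    if (!setequal(sub$level, def$levels)) {
      stop(sprintf("coefficient table term '%s' does not match the %d declared levels",
                   term, length(def$levels)), call. = FALSE)
    }
    ref <- sub$estimate[sub$level == def$reference]
    if (length(ref) != 1L || ref != 0) {
      stop(sprintf("reference level '%s' of term '%s' must carry coefficient 0",
                   def$reference, term), call. = FALSE)
    }
  }
  invisible(coefficients)
}

# Named coefficient vector in design-matrix column order for `terms`.
coefficient_vector <- function(coefficients, terms, what = "estimate") {
  reg <- sae_term_registry()
  out <- c("(Intercept)" =
             coefficients[[what]][coefficients$term == "intercept"][1])
  for (term in terms) {
    def <- reg[[term]]
    keep <- setdiff(def$levels, def$reference)
    sub <- coefficients[coefficients$term == term, , drop = FALSE]
    v <- sub[[what]][match(keep, sub$level)]
    names(v) <- paste(term, keep, sep = ":")
    out <- c(out, v)
  }
  out
}
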