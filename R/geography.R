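#' Generate a nested synthetic geography with area covariates
#'
#' Builds a state / county / zip-code / block-group hierarchy emulating
#' the geography underlying a state-stratified national children's
#' health survey: zip codes and block groups are parallel sub-county
#' units, and every non-state area has exactly one parent. Each zip code
#' and block group receives a median-household-income octile (1-8), one
#' of 12 lifestyle segmentation classes and one of 11 urbanization
#' classes; each county receives an income octile and one of 6
#' urban-rural classes. Counties additionally carry a positive size
#' weight (log-normal) that drives how survey children are allocated to
#' counties and how large block-group child populations are; states
#' carry a nominal child population used for survey weights.
#'
#' @param n_states Number of states.
#' @param counties_per_state Counties in each state.
#' @param zips_per_county Zip codes in each county.
#' @param bgs_per_county Block groups in each county.
#' @param seed RNG seed; the same seed reproduces the frame exactly.
#' @param bg_covariate_cor Probability that a block group copies its
#'   covariates from a randomly chosen zip code of its county instead of
#'   drawing them independently. Default 0 (independent), because the
#'   zip-to-block-group coefficient transfer is exactly the assumption
#'   the pipeline exercises.
#' @return An object of class `sae_geography`: a list with data frames
#'   `states`, `counties`, `zips`, `block_groups`.
#' @examples
#' geo <- generate_geography(2, 2, 2, 2, seed = 1)
#' nrow(geo$block_groups)  # 2 states x 2 counties x 2 block groups = 8
#' @export
generate_geography <- function(n_states, counties_per_state, zips_per_county,
                               bgs_per_county, seed = 1L,
                               bg_covariate_cor = 0) {
  n_states <- check_count(n_states, "n_states")
  counties_per_state <- check_count(counties_per_state, "counties_per_state")
  zips_per_county <- check_count(zips_per_county, "zips_per_county")
  bgs_per_county <- check_count(bgs_per_county, "bgs_per_county")
  stopifnot(bg_covariate_cor >= 0, bg_covariate_cor <= 1)

  with_seed(seed, {
    states <- data.frame(
      state = sprintf("S%03d", seq_len(n_states)),
      child_population = round(stats::rlnorm(n_states, log(1e5), 0.4))
    )
    n_counties <- n_states * counties_per_state
    counties <- data.frame(
      county = sprintf("C%05d", seq_len(n_counties)),
      state = rep(states$state, each = counties_per_state),
      income_octile = sample(income_octile_levels(), n_counties,
                             replace = TRUE),
      urban_rural_class = sample(urban_rural_levels(), n_counties,
                                 replace = TRUE),
      size_weight = stats::rlnorm(n_counties, 0, 0.8)
    )
    n_zips <- n_counties * zips_per_county
    zips <- data.frame(
      zip = sprintf("Z%06d", seq_len(n_zips)),
      county = rep(counties$county, each = zips_per_county),
      state = rep(counties$state, each = zips_per_county),
      income_octile = sample(income_octile_levels(), n_zips, replace = TRUE),
      lifestyle_class = sample(lifestyle_levels(), n_zips, replace = TRUE),
      urbanization_class = sample(urbanization_levels(), n_zips,
                                  replace = TRUE)
    )
    n_bgs <- n_counties * bgs_per_county
    block_groups <- data.frame(
      bg = sprintf("B%07d", seq_len(n_bgs)),
      county = rep(counties$county, each = bgs_per_county),
      state = rep(counties$state, each = bgs_per_county),
      income_octile = sample(income_octile_levels(), n_bgs, replace = TRUE),
      lifestyle_class = sample(lifestyle_levels(), n_bgs, replace = TRUE),
      urbanization_class = sample(urbanization_levels(), n_bgs,
                                  replace = TRUE)
    )
    if (bg_covariate_cor > 0) {
      copy <- stats::runif(n_bgs) < bg_covariate_cor
      if (any(copy)) {
        for (i in which(copy)) {
          zsub <- zips[zips$county == block_groups$county[i], , drop = FALSE]
          j <- sample.int(nrow(zsub), 1L)
          block_groups$income_octile[i] <- zsub$income_octile[j]
          block_groups$lifestyle_class[i] <- zsub$lifestyle_class[j]
          block_groups$urbanization_class[i] <- zsub$urbanization_class[j]
        }
      }
    }
    geo <- structure(list(states = states, counties = counties, zips = zips,
                          block_groups = block_groups),
                     class = "sae_geography")
    validate_geography(geo)
    geo
  })
}

#' Validate the structural invariants of a geography frame
#'
#' Checks that every non-state area has exactly one existing parent and
#' that all covariate codes lie in their declared category sets.
#'
#' @param geo An `sae_geography`.
#' @return `geo`, invisibly; errors on violation.
#' @export
validate_geography <- function(geo) {
  stopifnot(inherits(geo, "sae_geography"))
  if (anyDuplicated(geo$states$state) || anyDuplicated(geo$counties$county) ||
      anyDuplicated(geo$zips$zip) || anyDuplicated(geo$block_groups$bg)) {
    stop("area identifiers must be unique", call. = FALSE)
  }
  if (!all(geo$counties$state %in% geo$states$state)) {
    stop("county with unknown parent state", call. = FALSE)
  }
  if (!all(geo$zips$county %in% geo$counties$county)) {
    stop("zip code with unknown parent county", call. = FALSE)
  }
  if (!all(geo$block_groups$county %in% geo$counties$county)) {
    stop("block group with unknown parent county", call. = FALSE)
  }
  cs <- geo$counties$state[match(geo$zips$county, geo$counties$county)]
  if (!identical(cs, geo$zips$state)) {
    stop("zip state labels inconsistent with county parentage", call. = FALSE)
  }
  bs <- geo$counties$state[match(geo$block_groups$county, geo$counties$county)]
  if (!identical(bs, geo$block_groups$state)) {
    stop("block-group state labels inconsistent with county parentage",
         call. = FALSE)
  }
  ok <- all(geo$zips$income_octile %in% income_octile_levels()) &&
    all(geo$zips$lifestyle_class %in% lifestyle_levels()) &&
    all(geo$zips$urbanization_class %in% urbanization_levels()) &&
    all(geo$block_groups$income_octile %in% income_octile_levels()) &&
    all(geo$block_groups$lifestyle_class %in% lifestyle_levels()) &&
    all(geo$block_groups$urbanization_class %in% urbanization_levels()) &&
    all(geo$counties$income_octile %in% income_octile_levels()) &&
    all(geo$counties$urban_rural_class %in% urban_rural_levels())
  if (!ok) stop("area covariate outside its category set", call. = FALSE)
  invisible(geo)
}

#' @export
print.sae_geography <- function(x, ...) {
  cat(sprintf(
    "sae_geography: %d states, %d counties, %d zip codes, %d block groups\n",
    nrow(x$states), nrow(x$counties), nrow(x$zips), nrow(x$block_groups)))
  invisible(x)
}
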