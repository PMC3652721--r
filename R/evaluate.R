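#' Weighted direct survey estimates of prevalence by geography
#'
#' Computes the design-weighted prevalence `sum(w*y)/sum(w)` for each
#' geography, with a linearized (weighted-ratio) standard error
#' `sqrt(sum(w^2 (y - p)^2)) / sum(w)`, which reduces to
#' `sqrt(p(1-p)/n)` under equal weights. Weights are treated as fixed;
#' no finite-population correction or stratum/PSU structure is applied.
#'
#' @param records Survey records with `obese` and `weight`.
#' @param level Grouping column: `"county"`, `"state"`, or
#'   `"national"`.
#' @param use_weights If `FALSE`, all weights are set to 1.
#' @return A `data.frame` with `geo_id`, `level`, `estimate`, `se`,
#'   `n` (unweighted sample size).
#' @export
direct_estimates <- function(records, level = c("county", "state",
                                                "national"),
                             use_weights = TRUE) {
  level <- match.arg(level)
  stopifnot(nrow(records) >= 1L, all(records$weight > 0))
  g <- switch(level, county = records$county, state = records$state,
              national = rep("national", nrow(records)))
  w <- if (use_weights) records$weight else rep(1, nrow(records))
  y <- records$obese
  f <- factor(g, levels = unique(g))
  sw <- as.numeric(rowsum(w, f))
  p <- as.numeric(rowsum(w * y, f)) / sw
  resid2 <- (y - p[as.integer(f)])^2
  se <- sqrt(as.numeric(rowsum(w^2 * resid2, f))) / sw
  out <- data.frame(geo_id = levels(f), level = level, estimate = p,
                    se = se, n = as.integer(table(f)[levels(f)]))
  rownames(out) <- NULL
  out
}

#' Reliability filter for direct survey estimates
#'
#' Keeps estimates based on at least `min_n` children and with relative
#' standard error (SE over mean) strictly below `max_rse` — the
#' conventional suppression rule for survey estimates. Zero estimates
#' are excluded because their relative SE is undefined.
#'
#' @param estimates Output of [direct_estimates()].
#' @param min_n Minimum unweighted sample size (default 30).
#' @param max_rse Maximum relative standard error (default 0.3).
#' @return The reliable subset, with a `reliable` column set to `TRUE`.
#' @export
apply_reliability_filter <- function(estimates, min_n = 30, max_rse = 0.3) {
  keep <- estimates$n >= min_n & estimates$estimate > 0 &
    estimates$se / estimates$estimate < max_rse
  out <- estimates[keep, , drop = FALSE]
  out$reliable <- rep(TRUE, nrow(out))
  rownames(out) <- NULL
  out
}

#' Paired comparison of model-based and direct estimates
#'
#' Matches geographies present in both sets, computes model-minus-direct
#' differences in percentage points with their quartiles, a two-sided
#' paired t-test, and the count of geographies whose model MC 95%
#' interval and direct normal interval (`estimate +/- 1.96 SE`) do not
#' overlap (significant discrepancies).
#'
#' @param model_estimates `sae_results` with `estimate` (and optionally
#'   `ci_low`/`ci_high`).
#' @param direct_estimates Output of [direct_estimates()] (optionally
#'   filtered).
#' @return A list with `n`, `differences_pp`, `quartiles_pp`,
#'   `t_statistic`, `p_value`, `n_significant`, `degenerate`.
#' @export
compare_paired <- function(model_estimates, direct_estimates) {
  m <- match(direct_estimates$geo_id, model_estimates$geo_id)
  ok <- !is.na(m)
  if (sum(ok) < 2L) {
    stop("fewer than 2 matched geographies to compare", call. = FALSE)
  }
  direct <- direct_estimates[ok, , drop = FALSE]
  model <- model_estimates[m[ok], , drop = FALSE]
  diff_pp <- 100 * (model$estimate - direct$estimate)
  degenerate <- stats::sd(diff_pp) < 1e-12
  if (degenerate) {
    tt <- list(statistic = NaN, p.value = NaN)
  } else {
    tt <- stats::t.test(model$estimate, direct$estimate, paired = TRUE)
  }
  n_sig <- NA_integer_
  if (all(c("ci_low", "ci_high") %in% names(model))) {
    dlo <- direct$estimate - 1.96 * direct$se
    dhi <- direct$estimate + 1.96 * direct$se
    n_sig <- sum(model$ci_low > dhi | model$ci_high < dlo)
  }
  list(n = sum(ok),
       geo_id = direct$geo_id,
       differences_pp = diff_pp,
       quartiles_pp = stats::setNames(
         quantile7(diff_pp, c(0.25, 0.5, 0.75)), c("q1", "median", "q3")),
       t_statistic = unname(tt$statistic),
       p_value = unname(tt$p.value),
       n_significant = n_sig,
       degenerate = degenerate)
}

#' Correlation of model and direct estimates versus minimum sample size
#'
#' For each minimum county sample size `m`, computes the Pearson
#' correlation between model-based and direct estimates over the
#' counties with at least `m` sampled children. Entries with fewer than
#' 3 such counties are reported as `NA`.
#'
#' @param model_estimates,direct_estimates As in [compare_paired()];
#'   `direct_estimates` must carry `n`.
#' @param thresholds Increasing vector of minimum sample sizes; the
#'   default grid covers the sizes conventionally examined.
#' @return A `data.frame` with `min_n`, `r`, `n_geos`.
#' @export
correlation_curve <- function(model_estimates, direct_estimates,
                              thresholds = c(15, 30, 50, 100, 150, 200)) {
  stopifnot(length(thresholds) >= 1L, !is.unsorted(thresholds))
  m <- match(direct_estimates$geo_id, model_estimates$geo_id)
  ok <- !is.na(m)
  direct <- direct_estimates[ok, , drop = FALSE]
  model <- model_estimates[m[ok], , drop = FALSE]
  rows <- lapply(thresholds, function(th) {
    sel <- direct$n >= th
    r <- if (sum(sel) >= 3L) {
      stats::cor(model$estimate[sel], direct$estimate[sel])
    } else NA_real_
    data.frame(min_n = th, r = r, n_geos = sum(sel))
  })
  do.call(rbind, rows)
}
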