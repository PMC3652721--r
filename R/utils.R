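#' Inverse-logit transform
#'
#' Maps a linear predictor on the log-odds scale to a probability.
#'
#' @param x Numeric vector of log-odds.
#' @return Probabilities in `[0, 1]`.
#' @export
invlogit <- function(x) stats::plogis(x)

#' Logit transform
#'
#' @param p Probabilities in `(0, 1)`.
#' @return Log-odds.
#' @export
logit <- function(p) stats::qlogis(p)

# Run `code` under `set.seed(seed)` and restore the caller's RNG state,
# so seeded generators do not perturb the global random stream.
with_seed <- function(seed, code) {
  check_seed(seed)
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

check_seed <- function(seed) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed) ||
      seed < 0 || seed != trunc(seed)) {
    stop("`seed` must be a single non-negative integer", call. = FALSE)
  }
  invisible(as.integer(seed))
}

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) ||
      x < min || x != trunc(x)) {
    stop(sprintf("`%s` must be a single integer >= %d", name, min),
         call. = FALSE)
  }
  invisible(as.integer(x))
}

# Quartile convention used throughout the package (see methods vignette).
quantile7 <- function(x, probs) {
  unname(stats::quantile(x, probs = probs, type = 7, names = FALSE))
}
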