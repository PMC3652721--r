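# Shared fixture builders. Everything is generated in code; no files.

small_geo <- function(seed = 1, n_states = 6, counties = 2, zips = 2,
                      bgs = 2, ...) {
  generate_geography(n_states, counties, zips, bgs, seed = seed, ...)
}

# Coefficient table with every estimate 0 except those supplied, e.g.
# coef_table(intercept = -1, sex = c(Male = 0.5)). SEs default to 0.
coef_table <- function(..., ses = NULL) {
  tab <- risk_coefficients()
  tab$estimate <- 0
  tab$se <- 0
  mods <- list(...)
  for (term in names(mods)) {
    if (term == "intercept") {
      tab$estimate[tab$term == "intercept"] <- mods[[term]]
    } else {
      v <- mods[[term]]
      i <- match(names(v), tab$level[tab$term == term])
      rows <- which(tab$term == term)[i]
      tab$estimate[rows] <- unname(v)
    }
  }
  if (!is.null(ses)) {
    for (term in names(ses)) {
      if (term == "intercept") {
        tab$se[tab$term == "intercept"] <- ses[[term]]
      } else {
        v <- ses[[term]]
        i <- match(names(v), tab$level[tab$term == term])
        rows <- which(tab$term == term)[i]
        tab$se[rows] <- unname(v)
      }
    }
  }
  tab
}

# Hand-built design bundle for engine tests that do not need a
# geography: intercept + optional covariate columns, one grouping term.
make_design <- function(y, X, area = NULL) {
  if (is.null(colnames(X))) {
    colnames(X) <- c("(Intercept)",
                     paste0("x", seq_len(ncol(X) - 1)))[seq_len(ncol(X))]
  }
  Z <- list()
  groups <- list()
  if (!is.null(area)) {
    f <- factor(area)
    Z <- list(state = Matrix::sparseMatrix(i = seq_along(y),
                                           j = as.integer(f), x = 1,
                                           dims = c(length(y),
                                                    nlevels(f)),
                                           dimnames = list(NULL,
                                                           levels(f))))
    groups <- list(state = levels(f))
  }
  structure(list(y = as.numeric(y), X = X, Z = Z, groups = groups,
                 term_map = data.frame(column = colnames(X),
                                       term = colnames(X),
                                       level = colnames(X)),
                 spec = model_spec(character(0),
                                   if (length(Z)) "state" else "none")),
            class = "sae_design")
}

# Random small binomial mixed-model instance with one random intercept,
# sized like the engine's oracle-comparison contract (<= 8 areas,
# <= 40 observations) and with variances on the scale seen in
# area-level prevalence models.
tiny_instance <- function(seed) {
  # Redraw (deterministically) until the instance is a valid probe of
  # engine correctness:
  # * the fixed effects must be identifiable — with a separated
  #   covariate the MLE is infinite and neither the engine nor the
  #   quadrature oracle has a finite target;
  # * the realized between-area spread must be consistent with the
  #   drawn variance range (method-of-moments logit variance below
  #   0.35, the upper end of the truth support) — tiny samples
  #   occasionally realize extreme spread whose inflated variance
  #   estimate makes the Laplace approximation itself (not its
  #   implementation) diverge from exact quadrature.
  for (offset in seq(0, 3e5, by = 1e4)) {
    set.seed(seed + offset)
    n_areas <- sample(4:8, 1)
    n <- min(40L, n_areas * sample(4:6, 1))
    area <- rep_len(seq_len(n_areas), n)
    x <- stats::rbinom(n, 1, 0.5)
    sigma2 <- stats::runif(1, 0.05, 0.3)
    b0 <- stats::runif(1, -1.5, -0.5)
    b1 <- stats::runif(1, -0.6, 0.6)
    u <- stats::rnorm(n_areas, 0, sqrt(sigma2))
    y <- stats::rbinom(n, 1, stats::plogis(b0 + b1 * x + u[area]))
    g <- suppressWarnings(
      stats::glm.fit(cbind(1, x), y, family = stats::binomial()))
    k <- tapply(y, area, sum)
    nj <- tapply(y, area, length)
    pbar <- mean(y)
    mom <- max(stats::var(stats::qlogis((k + 0.5) / (nj + 1))) -
                 mean(1 / (nj * pbar * (1 - pbar))), 0)
    if (all(is.finite(g$coefficients)) &&
        max(abs(g$coefficients)) < 4 && mom < 0.35) break
  }
  list(y = y, X = cbind(`(Intercept)` = 1, x = x), area = area,
       sigma2 = sigma2, beta = c(b0, b1))
}
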