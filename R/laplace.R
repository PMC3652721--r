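#' Control parameters for the Laplace fitter
#'
#' @param tol_obj Relative objective-change tolerance of the inner
#'   Newton iterations.
#' @param tol_grad Infinity-norm gradient tolerance.
#' @param max_inner Inner Newton iteration cap.
#' @param max_outer Outer optimization iteration cap.
#' @param sigma2_min,sigma2_max Search bounds for each variance
#'   component; an optimum at `sigma2_min` is reported as a boundary fit
#'   with variance 0.
#' @return A list of class `laplace_control`.
#' @export
laplace_control <- function(tol_obj = 1e-8, tol_grad = 1e-5,
                            max_inner = 200L, max_outer = 200L,
                            sigma2_min = 1e-8, sigma2_max = 25) {
  structure(list(tol_obj = tol_obj, tol_grad = tol_grad,
                 max_inner = max_inner, max_outer = max_outer,
                 sigma2_min = sigma2_min, sigma2_max = sigma2_max),
            class = "laplace_control")
}

# Numerically stable log(1 + exp(x)).
log1pexp <- function(x) pmax(x, 0) + log1p(exp(-abs(x)))

# Block positions of the random-effect vector, one block per term.
u_positions <- function(p, q) {
  if (!length(q)) return(list())
  split(p + seq_len(sum(q)), rep(seq_along(q), q))
}

# Dense joint negative Hessian of the penalized log-likelihood at
# (beta, u) with IRLS weights w.
joint_hessian <- function(X, Z, w, sigma2) {
  p <- ncol(X)
  q <- vapply(Z, ncol, integer(1))
  upos <- u_positions(p, q)
  H <- matrix(0, p + sum(q), p + sum(q))
  H[seq_len(p), seq_len(p)] <- crossprod(X, X * w)
  for (t in seq_along(Z)) {
    XtWZ <- as.matrix(Matrix::crossprod(X * w, Z[[t]]))
    H[seq_len(p), upos[[t]]] <- XtWZ
    H[upos[[t]], seq_len(p)] <- t(XtWZ)
    for (s in seq_along(Z)) {
      H[upos[[t]], upos[[s]]] <-
        as.matrix(Matrix::crossprod(Z[[t]], Z[[s]] * w))
    }
    i <- upos[[t]]
    H[cbind(i, i)] <- H[cbind(i, i)] + 1 / sigma2[t]
  }
  H
}

# Joint Newton maximization of the penalized binomial log-likelihood
# over (beta, u) for fixed variance components (used to initialize the
# marginal optimization and for fixed-effect-only fits).
penalized_newton <- function(y, X, Z, sigma2, beta, u, control) {
  p <- ncol(X)
  nt <- length(Z)
  q <- vapply(Z, ncol, integer(1))
  upos <- u_positions(p, q)
  theta <- c(beta, unlist(u, use.names = FALSE))

  eta_of <- function(th) {
    eta <- drop(X %*% th[seq_len(p)])
    for (t in seq_len(nt)) eta <- eta + as.numeric(Z[[t]] %*% th[upos[[t]]])
    eta
  }
  pen_obj <- function(th, eta) {
    val <- sum(y * eta - log1pexp(eta))
    for (t in seq_len(nt)) {
      val <- val - sum(th[upos[[t]]]^2) / (2 * sigma2[t])
    }
    val
  }
  gradient <- function(th, mu) {
    g <- c(crossprod(X, y - mu))
    for (t in seq_len(nt)) {
      g <- c(g, as.numeric(Matrix::crossprod(Z[[t]], y - mu)) -
               th[upos[[t]]] / sigma2[t])
    }
    g
  }

  eta <- eta_of(theta)
  obj <- pen_obj(theta, eta)
  if (!is.finite(obj)) stop("non-finite penalized likelihood at start",
                            call. = FALSE)
  converged <- FALSE
  for (it in seq_len(control$max_inner)) {
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-12)
    g <- gradient(theta, mu)
    if (max(abs(g)) < control$tol_grad) { converged <- TRUE; break }
    H <- joint_hessian(X, Z, w, sigma2)
    ch <- tryCatch(chol(H), error = function(e) chol(H + diag(1e-8, nrow(H))))
    step <- backsolve(ch, forwardsolve(t(ch), g))
    lambda <- 1
    repeat {
      cand <- theta + lambda * step
      eta_c <- eta_of(cand)
      obj_c <- pen_obj(cand, eta_c)
      if (is.finite(obj_c) && obj_c >= obj - 1e-12) break
      lambda <- lambda / 2
      if (lambda < 1e-10) {
        stop("penalized likelihood is not increasing; data may be separated (consider penalization)",
             call. = FALSE)
      }
    }
    rel <- abs(obj_c - obj) / (abs(obj) + 1)
    theta <- cand; eta <- eta_c; obj <- obj_c
    if (rel < control$tol_obj &&
        max(abs(gradient(theta, stats::plogis(eta)))) < control$tol_grad) {
      converged <- TRUE
      break
    }
  }
  mu <- stats::plogis(eta)
  w <- pmax(mu * (1 - mu), 1e-12)
  list(beta = theta[seq_len(p)],
       u = lapply(seq_len(nt), function(t) theta[upos[[t]]]),
       eta = eta, w = w, obj = obj,
       H = joint_hessian(X, Z, w, sigma2),
       converged = converged)
}

# Newton solve of the random-intercept modes for fixed (beta, sigma2).
# `gi` holds the per-term area index of each observation.
solve_modes <- function(y, xb, Z, gi, sigma2, u, control) {
  nt <- length(Z)
  q <- vapply(Z, ncol, integer(1))
  pos <- u_positions(0L, q)
  converged <- FALSE
  for (it in seq_len(control$max_inner)) {
    eta <- xb
    for (t in seq_len(nt)) eta <- eta + u[[t]][gi[[t]]]
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-12)
    g <- unlist(lapply(seq_len(nt), function(t) {
      as.numeric(Matrix::crossprod(Z[[t]], y - mu)) - u[[t]] / sigma2[t]
    }))
    Huu <- matrix(0, sum(q), sum(q))
    for (t in seq_len(nt)) {
      for (s in seq_len(nt)) {
        Huu[pos[[t]], pos[[s]]] <-
          as.matrix(Matrix::crossprod(Z[[t]], Z[[s]] * w))
      }
      i <- pos[[t]]
      Huu[cbind(i, i)] <- Huu[cbind(i, i)] + 1 / sigma2[t]
    }
    if (max(abs(g)) < control$tol_grad * 0.1) { converged <- TRUE; break }
    du <- solve(Huu, g)
    uf <- unlist(u) + du
    u <- lapply(seq_len(nt), function(t) uf[pos[[t]]])
  }
  list(u = u, eta = eta, mu = mu, w = w, Huu = Huu, pos = pos,
       converged = converged)
}

# Laplace marginal log-likelihood and its analytic gradient with
# respect to (beta, log sigma2), with the random-intercept modes
# profiled out. The gradient combines the envelope theorem for the
# penalized part with the derivative of log det(Z'WZ + D^-1) through
# the IRLS weights (dw/deta = w(1-2mu)) and the implicit dependence of
# the modes on the parameters.
laplace_objgrad <- function(par, y, X, Z, gi, control, cache) {
  p <- ncol(X)
  nt <- length(Z)
  beta <- par[seq_len(p)]
  sigma2 <- pmax(exp(par[p + seq_len(nt)]), control$sigma2_min)
  xb <- drop(X %*% beta)
  m <- solve_modes(y, xb, Z, gi, sigma2, cache$u, control)
  cache$u <- m$u
  ch <- tryCatch(chol(m$Huu), error = function(e) NULL)
  if (is.null(ch)) return(list(obj = -Inf, grad = rep(NA_real_, length(par))))
  obj <- sum(y * m$eta - log1pexp(m$eta))
  for (t in seq_len(nt)) {
    obj <- obj - sum(m$u[[t]]^2) / (2 * sigma2[t]) -
      length(m$u[[t]]) / 2 * log(sigma2[t])
  }
  obj <- obj - sum(log(diag(ch)))

  Hinv <- chol2inv(ch)
  wp <- m$w * (1 - 2 * m$mu)
  si <- numeric(length(y))
  for (t in seq_len(nt)) {
    for (s in seq_len(nt)) {
      si <- si + Hinv[cbind(m$pos[[t]][gi[[t]]], m$pos[[s]][gi[[s]]])]
    }
  }
  v <- si * wp
  Ztv <- unlist(lapply(seq_len(nt), function(t) {
    as.numeric(Matrix::crossprod(Z[[t]], v))
  }))
  ZtWX <- do.call(rbind, lapply(seq_len(nt), function(t) {
    as.matrix(Matrix::crossprod(Z[[t]], m$w * X))
  }))
  HinvZtv <- Hinv %*% Ztv
  gbeta <- as.numeric(crossprod(X, y - m$mu)) -
    0.5 * as.numeric(crossprod(X, v)) +
    0.5 * as.numeric(crossprod(ZtWX, HinvZtv))
  gls <- numeric(nt)
  for (t in seq_len(nt)) {
    i <- m$pos[[t]]
    e <- numeric(sum(vapply(Z, ncol, integer(1))))
    e[i] <- m$u[[t]] / sigma2[t]^2
    gls[t] <- sigma2[t] * (sum(m$u[[t]]^2) / (2 * sigma2[t]^2) -
                             length(i) / (2 * sigma2[t]) +
                             sum(diag(Hinv)[i]) / (2 * sigma2[t]^2) -
                             0.5 * sum((Hinv %*% e) * Ztv))
  }
  list(obj = obj, grad = c(gbeta, gls), modes = m)
}

#' Fit a binomial multilevel logistic model by Laplace-approximated ML
#'
#' Maximizes the Laplace approximation to the marginal likelihood of a
#' logistic model with zero, one, or two nested area random intercepts.
#' The fit proceeds in two phases: a joint penalized Newton iteration
#' over (fixed effects, random-intercept modes) with the variance
#' component(s) profiled on the log scale provides a starting point;
#' a quasi-Newton (L-BFGS-B) pass over (fixed effects, log-variances)
#' with the analytic gradient of the Laplace objective then finds the
#' exact Laplace maximum-likelihood estimates. Optimizing variances on
#' the log scale enforces positivity; an optimum at the lower search
#' bound is reported as a boundary fit with variance 0. With no random
#' terms the fit is ordinary logistic regression by Newton-Raphson.
#'
#' Fixed-effect standard errors come from the inverse of the joint
#' observed information at the optimum; variance-component standard
#' errors from the numerically differentiated profile information on
#' the log scale, delta-transformed back to the variance scale.
#'
#' @param design An `sae_design` from [build_design()].
#' @param control A [laplace_control()].
#' @return An object of class `sae_fit` with elements `beta`, `se_beta`,
#'   `sigma2`, `sigma2_se`, `re_modes`, `loglik`, `npar`, `aic`,
#'   `converged`, `boundary`.
#' @export
fit_laplace <- function(design, control = laplace_control()) {
  stopifnot(inherits(design, "sae_design"))
  y <- design$y
  if (!all(y %in% c(0, 1))) stop("response must be 0/1", call. = FALSE)
  X <- design$X
  Z <- design$Z
  nt <- length(Z)
  if (nt && any(vapply(Z, ncol, integer(1)) < 2L)) {
    stop("each random term needs at least 2 areas", call. = FALSE)
  }
  p <- ncol(X)
  # levels never observed (zero columns) or aliased with other columns
  # are inestimable: fit without them, report NA for them
  qrx <- qr(X)
  estimable <- rep(FALSE, p)
  estimable[qrx$pivot[seq_len(qrx$rank)]] <- TRUE
  X <- X[, estimable, drop = FALSE]
  pe <- ncol(X)
  expand <- function(v) {
    out <- rep(NA_real_, p)
    out[estimable] <- v
    out
  }
  gi <- lapply(Z, function(z) as.integer(z %*% seq_len(ncol(z))))
  state <- new.env(parent = emptyenv())
  state$beta <- c(stats::qlogis(max(min(mean(y), 1 - 1e-6), 1e-6)),
                  rep(0, pe - 1))
  state$u <- lapply(Z, function(z) rep(0, ncol(z)))

  if (nt == 0L) {
    fit <- penalized_newton(y, X, Z, numeric(0), state$beta, state$u,
                            control)
    ll <- sum(y * fit$eta - log1pexp(fit$eta))
    se <- se_from_information(fit$H, pe)
    return(new_sae_fit(design, beta = expand(fit$beta),
                       se_beta = expand(se),
                       sigma2 = numeric(0), sigma2_se = numeric(0),
                       re_modes = list(), loglik = ll, npar = pe,
                       converged = fit$converged, boundary = logical(0)))
  }

  # Phase 1: profile the variance(s) with (beta, u) at the joint mode.
  inner <- function(sigma2) {
    fit <- penalized_newton(y, X, Z, sigma2, state$beta, state$u, control)
    state$beta <- fit$beta
    state$u <- fit$u
    fit
  }
  prof_negll <- function(ls) {
    s2 <- pmax(exp(ls), control$sigma2_min)
    fit <- inner(s2)
    ui <- pe + seq_len(nrow(fit$H) - pe)
    ch <- tryCatch(chol(fit$H[ui, ui, drop = FALSE]),
                   error = function(e) NULL)
    if (is.null(ch)) return(Inf)
    ll <- sum(y * fit$eta - log1pexp(fit$eta)) - sum(log(diag(ch)))
    for (t in seq_len(nt)) {
      ll <- ll - sum(fit$u[[t]]^2) / (2 * s2[t]) -
        length(fit$u[[t]]) / 2 * log(s2[t])
    }
    -ll
  }
  lo <- log(control$sigma2_min)
  hi <- log(control$sigma2_max)
  if (nt == 1L) {
    ls0 <- stats::optimize(prof_negll, c(lo, hi), tol = 1e-4)$minimum
  } else {
    opt0 <- stats::optim(rep(log(0.05), nt), prof_negll,
                         method = "L-BFGS-B", lower = lo, upper = hi,
                         control = list(maxit = control$max_outer,
                                        factr = 1e10))
    ls0 <- opt0$par
  }

  # Phase 2: quasi-Newton on the Laplace objective over
  # (beta, log sigma2) with the analytic gradient.
  cache <- new.env(parent = emptyenv())
  cache$u <- state$u
  cache$par <- NULL
  evalpt <- function(par) {
    if (!identical(par, cache$par)) {
      cache$val <- laplace_objgrad(par, y, X, Z, gi, control, cache)
      cache$par <- par
    }
    cache$val
  }
  opt <- stats::optim(c(state$beta, ls0),
                      fn = function(par) -evalpt(par)$obj,
                      gr = function(par) -evalpt(par)$grad,
                      method = "L-BFGS-B",
                      lower = c(rep(-Inf, pe), rep(lo, nt)),
                      upper = c(rep(Inf, pe), rep(hi, nt)),
                      control = list(maxit = control$max_outer,
                                     factr = 1e7))
  beta_hat <- opt$par[seq_len(pe)]
  ls_hat <- opt$par[pe + seq_len(nt)]
  boundary <- ls_hat < lo + 0.5
  sigma2 <- exp(ls_hat)
  sigma2[boundary] <- 0
  s2_eff <- pmax(exp(ls_hat), control$sigma2_min)

  final <- evalpt(opt$par)
  ll <- final$obj
  modes <- final$modes
  H <- joint_hessian(X, Z, modes$w, s2_eff)
  se <- se_from_information(H, pe)

  sigma2_se <- rep(NA_real_, nt)
  if (!any(boundary)) {
    state$beta <- beta_hat
    state$u <- modes$u
    hess <- tryCatch(numeric_hessian(prof_negll, ls_hat),
                     error = function(e) NULL)
    if (!is.null(hess)) {
      inv <- tryCatch(solve(hess), error = function(e) NULL)
      if (!is.null(inv) && all(diag(inv) > 0)) {
        sigma2_se <- sigma2 * sqrt(diag(inv))
      }
    }
  }

  re_modes <- lapply(seq_len(nt), function(t) {
    stats::setNames(modes$u[[t]], design$groups[[t]])
  })
  names(re_modes) <- names(Z)
  names(sigma2) <- names(Z)
  names(sigma2_se) <- names(Z)

  new_sae_fit(design, beta = expand(beta_hat), se_beta = expand(se),
              sigma2 = sigma2,
              sigma2_se = sigma2_se, re_modes = re_modes, loglik = ll,
              npar = pe + nt,
              converged = opt$convergence == 0L && modes$converged,
              boundary = boundary)
}

numeric_hessian <- function(f, x, h = 1e-3) {
  n <- length(x)
  H <- matrix(NA_real_, n, n)
  f0 <- f(x)
  for (i in seq_len(n)) {
    for (j in i:n) {
      if (i == j) {
        H[i, i] <- (f(replace(x, i, x[i] + h)) - 2 * f0 +
                      f(replace(x, i, x[i] - h))) / h^2
      } else {
        pp <- f(x + h * (seq_len(n) %in% c(i, j)))
        pm <- f(x + h * (seq_len(n) == i) - h * (seq_len(n) == j))
        mp <- f(x - h * (seq_len(n) == i) + h * (seq_len(n) == j))
        mm <- f(x - h * (seq_len(n) %in% c(i, j)))
        H[i, j] <- H[j, i] <- (pp - pm - mp + mm) / (4 * h^2)
      }
    }
  }
  H
}

# SEs of the fixed effects from the joint observed information.
# Columns of X that never vary (e.g. category levels unobserved in the
# sample) make the information singular; their coefficients are
# inestimable and get NA, and the remaining block is inverted alone.
se_from_information <- function(H, p, estimable = rep(TRUE, p)) {
  keep <- c(which(estimable), seq(p + 1, length.out = nrow(H) - p))
  se <- rep(NA_real_, p)
  inv <- tryCatch(chol2inv(chol(H[keep, keep, drop = FALSE])),
                  error = function(e) NULL)
  if (is.null(inv)) return(se)
  d <- diag(inv)[seq_len(sum(estimable))]
  se[estimable] <- ifelse(d > 0, sqrt(d), NA_real_)
  se
}

new_sae_fit <- function(design, beta, se_beta, sigma2, sigma2_se, re_modes,
                        loglik, npar, converged, boundary) {
  names(beta) <- colnames(design$X)
  names(se_beta) <- colnames(design$X)
  structure(list(beta = beta, se_beta = se_beta, sigma2 = sigma2,
                 sigma2_se = sigma2_se, re_modes = re_modes,
                 loglik = loglik, npar = npar,
                 aic = -2 * loglik + 2 * npar, converged = converged,
                 boundary = boundary, term_map = design$term_map,
                 spec = design$spec, n_obs = length(design$y)),
            class = "sae_fit")
}

#' @export
print.sae_fit <- function(x, ...) {
  cat(sprintf("sae_fit: %d obs, %d fixed effects, random = {%s}\n",
              x$n_obs, length(x$beta),
              paste(names(x$sigma2), collapse = ", ")))
  cat(sprintf("  logLik %.3f  AIC %.3f  converged %s\n",
              x$loglik, x$aic, x$converged))
  if (length(x$sigma2)) {
    for (t in names(x$sigma2)) {
      cat(sprintf("  sigma2[%s] = %.4f (SE %.4f)%s\n", t, x$sigma2[t],
                  x$sigma2_se[t],
                  if (isTRUE(x$boundary[which(names(x$sigma2) == t)]))
                    " [boundary]" else ""))
    }
  }
  invisible(x)
}

#' Coefficient summary of a fitted model
#'
#' One row per fixed-effect coefficient with Wald z test, mirroring the
#' usual published layout (term, level, coefficient, SE, p).
#'
#' @param fit An `sae_fit`.
#' @return A `data.frame` with columns `term`, `level`, `coefficient`,
#'   `se`, `z`, `p`.
#' @export
fit_summary_table <- function(fit) {
  stopifnot(inherits(fit, "sae_fit"))
  tm <- fit$term_map
  z <- fit$beta / fit$se_beta
  data.frame(term = tm$term, level = tm$level,
             coefficient = unname(fit$beta), se = unname(fit$se_beta),
             z = unname(z), p = unname(2 * stats::pnorm(-abs(z))))
}

#' Percentage of between-area variance explained by fixed effects
#'
#' Compares the random-intercept variance of a null model (random
#' effects only) with the same variance in the covariate-adjusted full
#' model: `100 * (s2_null - s2_full) / s2_null`. Values are computed
#' from unrounded variances and rounded only for display.
#'
#' @param null,full `sae_fit` objects sharing the random structure, or
#'   bare numeric variances.
#' @param term Random term to compare (default the first).
#' @return Percentage explained.
#' @export
variance_explained <- function(null, full, term = NULL) {
  s0 <- extract_sigma2(null, term)
  s1 <- extract_sigma2(full, term)
  if (s0 == 0) {
    stop("null-model variance is 0; percentage explained undefined",
         call. = FALSE)
  }
  100 * (s0 - s1) / s0
}

extract_sigma2 <- function(x, term) {
  if (inherits(x, "sae_fit")) {
    if (is.null(term)) return(unname(x$sigma2[1]))
    if (!term %in% names(x$sigma2)) {
      stop(sprintf("random term '%s' not in fit", term), call. = FALSE)
    }
    return(unname(x$sigma2[term]))
  }
  stopifnot(is.numeric(x), length(x) == 1L)
  x
}

#' Model-adequacy rule for small-area estimation
#'
#' A multilevel model is considered adequate for small-area estimation
#' when its fixed effects explain at least 40% of the between-area
#' variance for every random term.
#'
#' @param pct_explained Numeric vector of percentages (one per random
#'   term).
#' @return `TRUE` iff all values are >= 40.
#' @export
is_adequate <- function(pct_explained) {
  if (!length(pct_explained) || any(!is.finite(pct_explained))) {
    stop("percentages must be finite", call. = FALSE)
  }
  all(pct_explained >= 40)
}

#' Select the final model by AIC
#'
#' Returns the converged candidate with the smallest AIC; ties are
#' broken by fewer parameters, then by declaration order.
#'
#' @param candidates List of `sae_fit` objects.
#' @return The selected `sae_fit`.
#' @export
select_model <- function(candidates) {
  stopifnot(length(candidates) >= 1L,
            all(vapply(candidates, inherits, logical(1), "sae_fit")))
  ok <- which(vapply(candidates, function(f) isTRUE(f$converged),
                     logical(1)))
  if (!length(ok)) stop("no converged candidate model", call. = FALSE)
  aic <- vapply(candidates[ok], `[[`, numeric(1), "aic")
  npar <- vapply(candidates[ok], `[[`, numeric(1), "npar")
  candidates[[ok[order(aic, npar, seq_along(ok))[1]]]]
}

#' Fit the null/full model roster over candidate random structures
#'
#' For each random structure, fits the null model (intercept + random
#' effects only) and the full covariate model, computes the percentage
#' of between-area variance explained per random term, and selects the
#' full model with smallest AIC.
#'
#' @param records Survey records.
#' @param geo Geography.
#' @param fixed Fixed terms of the full models.
#' @param structures List of random structures.
#' @param control A [laplace_control()].
#' @return A list with `fits` (per structure: `null`, `full`),
#'   `adequacy` (one row per structure x random term), and `selected`
#'   (index of the AIC-best full model).
#' @export
fit_model_roster <- function(records, geo, fixed = full_fixed_terms(),
                             structures = list("state", "county",
                                               c("state", "county"), "zip"),
                             control = laplace_control()) {
  fits <- list()
  rows <- list()
  for (k in seq_along(structures)) {
    rt <- structures[[k]]
    null_fit <- fit_laplace(build_design(records, geo,
                                         model_spec(character(0), rt)),
                            control)
    full_fit <- fit_laplace(build_design(records, geo,
                                         model_spec(fixed, rt)), control)
    fits[[k]] <- list(null = null_fit, full = full_fit)
    for (t in rt) {
      pct <- if (null_fit$sigma2[t] > 0) {
        variance_explained(null_fit, full_fit, t)
      } else NA_real_
      rows[[length(rows) + 1L]] <- data.frame(
        model = as.character(as.roman(k)), random_term = t,
        null_variance = unname(null_fit$sigma2[t]),
        null_se = unname(null_fit$sigma2_se[t]),
        full_variance = unname(full_fit$sigma2[t]),
        full_se = unname(full_fit$sigma2_se[t]),
        pct_explained = pct)
    }
  }
  adequacy <- do.call(rbind, rows)
  fulls <- lapply(fits, `[[`, "full")
  sel <- select_model(fulls)
  selected <- which(vapply(fulls, identical, logical(1), sel))[1]
  list(fits = fits, adequacy = adequacy, selected = selected)
}
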