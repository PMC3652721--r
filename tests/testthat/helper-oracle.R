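# Independent adaptive Gauss-Hermite quadrature oracle for binomial
# logistic models with one random intercept. Written without reference
# to the package's Laplace engine: the marginal likelihood of each
# cluster is integrated numerically around its conditional mode.

gh_rule <- function(n) {
  # Golub-Welsch: eigen-decomposition of the Jacobi matrix for the
  # Hermite weight exp(-x^2).
  J <- matrix(0, n, n)
  off <- sqrt(seq_len(n - 1) / 2)
  J[cbind(seq_len(n - 1), 2:n)] <- off
  J[cbind(2:n, seq_len(n - 1))] <- off
  e <- eigen(J, symmetric = TRUE)
  list(nodes = e$values, weights = sqrt(pi) * e$vectors[1, ]^2)
}

log1pexp_oracle <- function(x) pmax(x, 0) + log1p(exp(-abs(x)))

agq_loglik <- function(beta, sigma2, y, X, area, n_nodes = 25) {
  rule <- gh_rule(n_nodes)
  xb <- drop(X %*% beta)
  total <- 0
  for (j in unique(area)) {
    idx <- which(area == j)
    h <- function(u) {
      eta <- xb[idx] + u
      sum(y[idx] * eta - log1pexp_oracle(eta)) - u^2 / (2 * sigma2) -
        0.5 * log(2 * pi * sigma2)
    }
    # 1-D Newton for the conditional mode
    u <- 0
    for (it in 1:100) {
      eta <- xb[idx] + u
      mu <- stats::plogis(eta)
      g <- sum(y[idx] - mu) - u / sigma2
      hpp <- -sum(mu * (1 - mu)) - 1 / sigma2
      step <- -g / hpp
      u <- u + step
      if (abs(g) < 1e-12) break
    }
    tau <- 1 / sqrt(-hpp)
    z <- u + sqrt(2) * tau * rule$nodes
    lv <- vapply(z, h, numeric(1)) + rule$nodes^2 + log(rule$weights)
    mx <- max(lv)
    total <- total + log(sqrt(2) * tau) + mx + log(sum(exp(lv - mx)))
  }
  total
}

# Maximum-likelihood fit under the quadrature objective.
fit_agq <- function(y, X, area, n_nodes = 25) {
  glm0 <- stats::glm.fit(X, y, family = stats::binomial())
  start <- c(glm0$coefficients, log(0.2))
  nll <- function(par) {
    s2 <- exp(par[length(par)])
    -agq_loglik(par[-length(par)], s2, y, X, area, n_nodes)
  }
  opt <- stats::optim(start, nll, method = "L-BFGS-B",
                      lower = c(rep(-Inf, ncol(X)), log(1e-8)),
                      upper = c(rep(Inf, ncol(X)), log(25)),
                      control = list(maxit = 500, factr = 1e7))
  list(beta = opt$par[seq_len(ncol(X))],
       sigma2 = exp(opt$par[ncol(X) + 1]),
       loglik = -opt$value, converged = opt$convergence == 0)
}
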