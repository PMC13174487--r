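## Zero-inflated negative binomial regression by EM.
##
## Model: y_i ~ pi * delta_0 + (1 - pi) * NB(mu_i, theta) with
## mu_i = exp(x_i' beta) (log link) and NB2 variance mu + mu^2/theta.
## The zero-inflation probability pi is a shared scalar. The E-step
## computes the posterior probability that each observed zero is
## structural; the M-step updates pi in closed form and (beta, log theta)
## by warm-started quasi-Newton maximization of the weighted NB
## log-likelihood, so the observed-data log-likelihood is non-decreasing
## across iterations.

nb_logpmf <- function(y, mu, theta) {
  stats::dnbinom(y, size = theta, mu = mu, log = TRUE)
}

zinb_loglik <- function(y, mu, theta, pi) {
  f <- stats::dnbinom(y, size = theta, mu = mu)
  ll <- ifelse(y == 0, log(pi + (1 - pi) * f + 1e-300),
               log1p(-pi) + nb_logpmf(y, mu, theta))
  sum(ll)
}

#' Fit a zero-inflated negative binomial model by EM
#'
#' @param counts Nonnegative integer response vector.
#' @param design Covariate matrix (n x p) WITHOUT an intercept column; an
#'   intercept is always added. `NULL` fits the intercept-only model.
#' @param max_iter Maximum EM iterations (default 500).
#' @param tol Convergence threshold on the change in log-likelihood
#'   (default 1e-6).
#' @return A `zinb_fit` list: `pi`, `beta` (named, `(Intercept)` first),
#'   `theta`, `mu` fitted means, `loglik`, `loglik_trace`, `converged`,
#'   `iterations`, `n`.
#' @export
fit_zinb <- function(counts, design = NULL, max_iter = 500L, tol = 1e-6) {
  y <- counts
  if (any(y < 0) || any(y != round(y))) {
    stop("counts must be nonnegative integers", call. = FALSE)
  }
  if (all(y == 0)) stop("all counts are zero; model is unidentifiable", call. = FALSE)
  n <- length(y)
  x <- cbind(`(Intercept)` = rep(1, n))
  if (!is.null(design)) {
    design <- as.matrix(design)
    if (nrow(design) != n) stop("design rows must match counts", call. = FALSE)
    if (is.null(colnames(design))) {
      colnames(design) <- paste0("x", seq_len(ncol(design)))
    }
    x <- cbind(x, design)
  }
  p <- ncol(x)
  if (n < 10 * (p + 2)) {
    warning("fewer than 10 observations per parameter; fit may be unstable")
  }

  # initial values: Poisson GLM for beta, moments for theta, half the
  # excess zeros for pi
  beta <- tryCatch(
    stats::glm.fit(x, y, family = stats::poisson())$coefficients,
    error = function(e) c(log(mean(y) + 0.1), rep(0, p - 1))
  )
  beta[!is.finite(beta)] <- 0
  mu <- as.numeric(exp(x %*% beta))
  vy <- stats::var(y); my <- mean(y)
  theta <- if (vy > my) min(100, max(0.1, my^2 / (vy - my))) else 10
  pi_hat <- min(0.9, max(0.01, 0.5 * mean(y == 0)))

  neg_q <- function(par, w) {
    b <- par[seq_len(p)]; th <- exp(par[p + 1])
    mu_ <- as.numeric(exp(x %*% b))
    -sum(w * nb_logpmf(y, mu_, th))
  }
  grad_q <- function(par, w) {
    b <- par[seq_len(p)]; th <- exp(par[p + 1])
    mu_ <- as.numeric(exp(x %*% b))
    dmu <- w * (y - mu_) * th / (th + mu_)
    gb <- -as.numeric(crossprod(x, dmu))
    dth <- sum(w * (digamma(y + th) - digamma(th) + log(th) + 1 -
                      log(th + mu_) - (y + th) / (th + mu_)))
    c(gb, -dth * th)
  }

  ll <- zinb_loglik(y, mu, theta, pi_hat)
  trace <- ll
  converged <- FALSE
  it <- 0L
  for (it in seq_len(max_iter)) {
    # E-step: posterior probability a zero is structural
    f0 <- stats::dnbinom(0, size = theta, mu = mu)
    z <- ifelse(y == 0, pi_hat / (pi_hat + (1 - pi_hat) * f0 + 1e-300), 0)
    # M-step
    pi_hat <- min(1 - 1e-10, max(1e-10, mean(z)))
    w <- 1 - z
    par <- c(beta, log(theta))
    opt <- stats::optim(par, neg_q, grad_q, w = w, method = "BFGS",
                        control = list(maxit = 100))
    if (opt$value <= neg_q(par, w)) { # only accept improvements of Q
      beta <- unname(opt$par[seq_len(p)])
      theta <- unname(exp(opt$par[p + 1]))
    }
    mu <- as.numeric(exp(x %*% beta))
    ll_new <- zinb_loglik(y, mu, theta, pi_hat)
    trace <- c(trace, ll_new)
    if (is.finite(ll) && abs(ll_new - ll) < tol) {
      converged <- TRUE
      ll <- ll_new
      break
    }
    ll <- ll_new
  }
  structure(list(pi = pi_hat, beta = stats::setNames(beta, colnames(x)),
                 theta = theta, mu = mu, loglik = ll, loglik_trace = trace,
                 converged = converged, iterations = it, n = n),
            class = "zinb_fit")
}

#' Likelihood-ratio test of ZINB covariate association
#'
#' Fits the full model with `design` and the intercept-only null, and
#' compares them with a chi-squared LRT on `ncol(design)` degrees of
#' freedom.
#'
#' @param counts Nonnegative integer response.
#' @param design Covariate matrix (n x p), no intercept column.
#' @param ... Passed to [fit_zinb()].
#' @return List: `fit_full`, `fit_null`, `lrt`, `df`, `p_value`.
#' @export
zinb_lrt <- function(counts, design, ...) {
  design <- as.matrix(design)
  fit1 <- fit_zinb(counts, design, ...)
  fit0 <- fit_zinb(counts, NULL, ...)
  lrt <- max(0, 2 * (fit1$loglik - fit0$loglik))
  df <- ncol(design)
  list(fit_full = fit1, fit_null = fit0, lrt = lrt, df = df,
       p_value = stats::pchisq(lrt, df = df, lower.tail = FALSE))
}

#' Simulate zero-inflated negative binomial counts
#'
#' Generator used for parameter-recovery and calibration checks.
#'
#' @param n Number of observations.
#' @param mu Mean vector (recycled) of the NB component.
#' @param theta NB dispersion.
#' @param pi Zero-inflation probability.
#' @param seed RNG seed.
#' @return Integer vector of counts.
#' @export
simulate_zinb <- function(n, mu, theta, pi, seed = 1L) {
  with_seed(seed, {
    y <- stats::rnbinom(n, size = theta, mu = rep_len(mu, n))
    y[stats::runif(n) < pi] <- 0L
    y
  })
}
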