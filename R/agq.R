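## Adaptive Gauss-Hermite quadrature oracle for single-level
## random-intercept binomial logit models. Deliberately implemented without
## any shared machinery with the Laplace fitter (per-group one-dimensional
## Newton search for the mode, Golub-Welsch quadrature nodes) so that the
## two routes are independent checks on one another.

#' Gauss-Hermite nodes and weights
#'
#' Nodes/weights for \eqn{\int e^{-x^2} f(x) dx} via the Golub-Welsch
#' eigen decomposition of the Jacobi matrix.
#'
#' @param k Number of nodes.
#' @return List with `nodes` and `weights` (increasing node order).
#' @export
gauss_hermite <- function(k) {
  if (k == 1) return(list(nodes = 0, weights = sqrt(pi)))
  i <- seq_len(k - 1)
  off <- sqrt(i / 2)
  J <- matrix(0, k, k)
  J[cbind(i, i + 1)] <- off
  J[cbind(i + 1, i)] <- off
  e <- eigen(J, symmetric = TRUE)
  ord <- order(e$values)
  list(nodes = e$values[ord], weights = (sqrt(pi) * e$vectors[1, ]^2)[ord])
}

#' Marginal log-likelihood by adaptive Gauss-Hermite quadrature
#'
#' Exact (to quadrature accuracy) marginal log-likelihood of a single-level
#' random-intercept binomial logit model at fixed parameters. Each group's
#' integral is centred at its conditional mode and scaled by the local
#' curvature before applying the quadrature rule, so 50 nodes are ample
#' for the group sizes used here.
#'
#' @param y Successes.
#' @param X Design matrix.
#' @param group Single grouping factor.
#' @param beta Fixed-effect coefficients.
#' @param sd Random-intercept standard deviation.
#' @param size Binomial denominators (default 1).
#' @param nodes Number of quadrature nodes (default 50).
#' @return Marginal log-likelihood (scalar).
#' @export
agq_loglik <- function(y, X, group, beta, sd, size = 1, nodes = 50L) {
  X <- as.matrix(X)
  n <- nrow(X)
  size <- rep_len(size, n)
  group <- factor(group)
  eta0 <- drop(X %*% beta)
  gh <- gauss_hermite(nodes)
  total <- 0
  for (g in levels(group)) {
    idx <- which(group == g)
    logf <- function(u) {
      sum(stats::dbinom(y[idx], size[idx], inv_logit(eta0[idx] + u),
                        log = TRUE)) + stats::dnorm(u, 0, sd, log = TRUE)
    }
    # 1-D Newton for the mode of the integrand
    u <- 0
    for (it in 1:50) {
      mu <- inv_logit(eta0[idx] + u)
      g1 <- sum(y[idx] - size[idx] * mu) - u / sd^2
      g2 <- -sum(size[idx] * mu * (1 - mu)) - 1 / sd^2
      step <- g1 / g2
      u <- u - step
      if (abs(step) < 1e-12) break
    }
    mu <- inv_logit(eta0[idx] + u)
    h <- sum(size[idx] * mu * (1 - mu)) + 1 / sd^2
    s <- 1 / sqrt(h)
    z <- u + sqrt(2) * s * gh$nodes
    lf <- vapply(z, logf, 0)
    m <- max(lf)
    total <- total + m +
      log(sqrt(2) * s * sum(gh$weights * exp(gh$nodes^2) * exp(lf - m)))
  }
  total
}
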