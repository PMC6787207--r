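#' Maximum-likelihood logistic regression by IRLS
#'
#' Plain fixed-effects binomial logit fit via iteratively reweighted least
#' squares, written out explicitly so it can serve as the zero-variance
#' reference for the mixed-effects fitter. Converges when the relative
#' deviance change falls below `tol` (default 1e-10) or after `max_iter`
#' iterations; diverging coefficients are flagged as (quasi-)separation.
#'
#' @param y 0/1 response (or successes when `size > 1`).
#' @param X Design matrix (including intercept column).
#' @param size Binomial denominators (scalar or vector, default 1).
#' @param tol,max_iter Convergence controls.
#' @return A list with `coefficients`, `std_errors`, `z_values`, `p_values`,
#'   `loglik`, `deviance`, `n`, `k`, `converged`, `separation`.
#' @examples
#' # intercept-only: MLE is logit of the raw proportion
#' fit <- fit_logistic_glm(c(rep(1, 136), rep(0, 24)),
#'                         matrix(1, 160, 1, dimnames = list(NULL, "(Intercept)")))
#' fit$coefficients  # logit(0.85) = 1.7346
#' @export
fit_logistic_glm <- function(y, X, size = 1, tol = 1e-10, max_iter = 100L) {
  X <- as.matrix(X)
  n <- nrow(X)
  size <- rep_len(size, n)
  if (qr(X)$rank < ncol(X)) stop("design matrix not full rank", call. = FALSE)
  beta <- numeric(ncol(X))
  dev_old <- Inf
  converged <- FALSE
  separation <- FALSE
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- inv_logit(eta)
    w <- pmax(size * mu * (1 - mu), 1e-12)
    z <- eta + (y - size * mu) / w
    WX <- X * w
    beta_new <- solve(crossprod(X, WX), crossprod(WX, z))
    beta <- drop(beta_new)
    if (max(abs(beta)) > 30) { separation <- TRUE; break }
    mu <- inv_logit(drop(X %*% beta))
    dev <- -2 * sum(stats::dbinom(y, size, mu, log = TRUE))
    if (is.finite(dev_old) && abs(dev - dev_old) / (abs(dev) + 0.1) < tol) {
      converged <- TRUE
      dev_old <- dev
      break
    }
    dev_old <- dev
  }
  eta <- drop(X %*% beta)
  mu <- inv_logit(eta)
  w <- pmax(size * mu * (1 - mu), 1e-12)
  V <- solve(crossprod(X, X * w))
  se <- sqrt(diag(V))
  zv <- beta / se
  nm <- colnames(X) %||% paste0("b", seq_along(beta))
  names(beta) <- names(se) <- names(zv) <- nm
  list(coefficients = beta, std_errors = se, z_values = zv,
       p_values = 2 * stats::pnorm(-abs(zv)),
       loglik = sum(stats::dbinom(y, size, mu, log = TRUE)),
       deviance = dev_old, n = n, k = ncol(X),
       converged = converged && !separation, separation = separation)
}
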