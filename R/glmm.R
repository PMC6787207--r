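## Binomial logit mixed-effects model with site-nested-in-week random
## intercepts, fitted by Laplace approximation.
##
## Parameterisation: spherical random effects b ~ N(0, I); the linear
## predictor is eta = X beta + sum_l sd_l * Z_l b_l. For a candidate theta
## (vector of random-intercept sds) a penalized IRLS finds the joint
## conditional mode of (beta, b); the Laplace criterion
##   -2 logLik = deviance + |b|^2 + log det(Lambda' Z' W Z Lambda + I)
## is minimised over theta by a box-constrained quasi-Newton search
## (variances may hit the zero boundary, which is flagged, and reduces the
## model to plain logistic regression).

#' Specification of a binomial consumption model
#'
#' @param target Consumer modelled as the success class
#'   (`"alligator"` or `"turkey_vulture"`).
#' @param covariates Fixed-effect covariates, in declared order. Continuous
#'   columns are z-scored when `scale_continuous` is `TRUE`. The
#'   categorical covariates `colony_type` (coded `Ardea = 0`,
#'   `Egretta = 1`), `island_type` (`inactive` indicator), `placement`
#'   (`water` indicator) and `veg_complexity` (treatment-coded, `low`
#'   reference) are recognised by name.
#' @param scale_continuous Z-score continuous covariates (default `TRUE`).
#' @return A `model_spec` object. The random structure is always intercepts
#'   for week-of-season and for island-within-week.
#' @export
model_spec <- function(target = c("alligator", "turkey_vulture"),
                       covariates = c("dist_water_m", "colony_type",
                                      "local_density", "avg_temp_F"),
                       scale_continuous = TRUE) {
  target <- match.arg(target)
  structure(list(target = target, covariates = covariates,
                 scale_continuous = scale_continuous),
            class = "model_spec")
}

CATEGORICAL_CODINGS <- list(
  colony_type = list(colony_type_egretta = function(r) r$colony_type == "Egretta"),
  island_type = list(island_type_inactive = function(r) r$island_type == "inactive"),
  placement = list(placement_water = function(r) r$placement == "water"),
  veg_complexity = list(
    veg_complexity_medium = function(r) r$veg_complexity == "medium",
    veg_complexity_high = function(r) r$veg_complexity == "high")
)

#' @noRd
build_design <- function(records, covariates, scale_continuous = TRUE,
                         scaling = NULL) {
  n <- nrow(records)
  cols <- list(`(Intercept)` = rep(1, n))
  col_of <- c(`(Intercept)` = NA_character_)
  cont <- character()
  for (cv in covariates) {
    if (cv %in% names(CATEGORICAL_CODINGS)) {
      for (nm in names(CATEGORICAL_CODINGS[[cv]])) {
        cols[[nm]] <- as.numeric(CATEGORICAL_CODINGS[[cv]][[nm]](records))
        col_of[nm] <- cv
      }
    } else {
      if (is.null(records[[cv]])) stop("unknown covariate: ", cv, call. = FALSE)
      cont <- c(cont, cv)
    }
  }
  if (length(cont) && scale_continuous) {
    if (is.null(scaling)) {
      sc <- scale_covariates(records, cont)
      records <- sc$records
      scaling <- sc$scaling
    } else {
      records <- apply_scaling(records, scaling)
    }
  }
  for (cv in cont) {
    cols[[cv]] <- records[[cv]]
    col_of[cv] <- cv
  }
  X <- do.call(cbind, cols)
  colnames(X) <- names(cols)
  list(X = X, scaling = scaling, term_covariate = col_of)
}

#' @noRd
sparse_indicator <- function(f) {
  Matrix::sparseMatrix(i = seq_along(f), j = as.integer(f), x = 1,
                       dims = c(length(f), nlevels(f)))
}

#' Laplace fit of a random-intercept binomial logit model (matrix interface)
#'
#' Low-level fitter over an explicit response, design matrix and list of
#' grouping factors (one Gaussian intercept per level of each factor).
#' [fit_binomial_glmm()] is the bait-record front end.
#'
#' @param y Successes (0/1 for Bernoulli data).
#' @param X Fixed-effects design matrix including the intercept column.
#' @param groups List of factors, one random-intercept term each.
#' @param size Binomial denominators (default 1).
#' @param theta_start Starting sds for the variance components.
#' @param control List: `outer_rel_tol` (default 1e-8), `outer_max_iter`
#'   (200), `pirls_tol` (1e-10), `pirls_max_iter` (60), `polish` (default
#'   `TRUE`: one guarded Newton step of the fixed effects on the Laplace
#'   criterion with the random-effect mode profiled, refining the joint
#'   penalized-IRLS estimate), `se_method` (`"full"`, the default, takes
#'   Wald standard errors from the observed information of the Laplace
#'   objective over fixed effects and non-boundary variance parameters
#'   jointly; `"conditional"` conditions on the fitted variance
#'   components).
#' @return A list with `coefficients`, `std_errors`, `z_values`, `p_values`,
#'   `theta` (fitted sds), `loglik`, `n`, `k`, `aicc`, `converged`,
#'   `boundary`, `ranef` (conditional modes, spherical scale).
#' @export
glmm_laplace_fit <- function(y, X, groups, size = 1,
                             theta_start = NULL, control = list()) {
  ctrl <- utils::modifyList(list(outer_rel_tol = 1e-8, outer_max_iter = 200L,
                                 pirls_tol = 1e-10, pirls_max_iter = 60L,
                                 polish = TRUE, se_method = "full"),
                            control)
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  size <- rep_len(size, n)
  groups <- lapply(groups, function(f) factor(f))
  for (f in groups) {
    if (nlevels(f) < 2) stop("each random level needs >= 2 groups", call. = FALSE)
  }
  if (qr(X)$rank < p) stop("design matrix not full rank", call. = FALSE)
  qs <- vapply(groups, nlevels, 1L)
  q <- sum(qs)
  blk <- rep(seq_along(qs), qs)           # which variance component
  sparse <- (q + p) > 400
  Z0s <- if (sparse) do.call(cbind, lapply(groups, sparse_indicator)) else
    NULL
  A0 <- if (sparse) NULL else {
    cbind(do.call(cbind, lapply(groups, function(f) {
      Zi <- matrix(0, n, nlevels(f)); Zi[cbind(seq_len(n), as.integer(f))] <- 1
      Zi
    })), X)
  }
  pen <- c(rep(1, q), rep(0, p))
  qi <- seq_len(q)
  fi <- q + seq_len(p)
  Iq <- if (sparse) Matrix::Diagonal(q) else NULL
  v_warm <- numeric(q + p)
  # One penalized IRLS pass at fixed theta, jointly over (b, beta). The
  # sparse path exploits the bordered ("arrow") structure: CHOLMOD on the
  # random-effect block plus a dense p x p Schur complement for beta.
  pirls <- function(theta, keep = FALSE) {
    theta <- abs(theta)
    D <- c(theta[blk], rep(1, p))
    Dq <- theta[blk]
    if (sparse) Zs <- Z0s %*% Matrix::Diagonal(x = Dq)
    v <- v_warm
    eta_of <- function(vv) {
      if (sparse) {
        as.vector(Zs %*% vv[qi]) + drop(X %*% vv[fi])
      } else {
        as.vector(A0 %*% (D * vv))
      }
    }
    eta <- eta_of(v)
    mu <- inv_logit(eta)
    pdev <- -2 * sum(stats::dbinom(y, size, mu, log = TRUE)) +
      sum((v * pen)^2)
    M <- NULL; ch <- NULL; S <- NULL
    ok <- FALSE
    for (it in seq_len(ctrl$pirls_max_iter)) {
      w <- pmax(size * mu * (1 - mu), 1e-12)
      z <- eta + (y - size * mu) / w
      if (sparse) {
        sw <- sqrt(w)
        Zsw <- Zs * sw
        Xw <- X * sw
        Mqq <- Matrix::crossprod(Zsw) + Iq
        Mqp <- as.matrix(Matrix::crossprod(Zsw, Xw))
        Mpp <- crossprod(Xw)
        ch <- Matrix::Cholesky(Mqq, LDL = FALSE, perm = TRUE)
        wz <- w * z
        rq <- as.vector(Matrix::crossprod(Zs, wz))
        rp <- as.vector(crossprod(X, wz))
        iqp <- as.matrix(Matrix::solve(ch, Mqp, system = "A"))
        S <- Mpp - crossprod(Mqp, iqp)
        beta_new <- solve(S, rp - drop(crossprod(iqp, rq)))
        b_new <- as.vector(Matrix::solve(ch, rq - Mqp %*% beta_new,
                                         system = "A"))
        v_new <- c(b_new, beta_new)
      } else {
        C <- crossprod(A0 * sqrt(w))
        M <- C * tcrossprod(D) + diag(pen, q + p)
        rhs <- D * as.vector(crossprod(A0, w * z))
        v_new <- as.vector(solve(M, rhs))
      }
      step <- 1
      repeat {
        v_try <- v + step * (v_new - v)
        eta_try <- eta_of(v_try)
        mu_try <- inv_logit(eta_try)
        pdev_try <- -2 * sum(stats::dbinom(y, size, mu_try, log = TRUE)) +
          sum((v_try * pen)^2)
        if (is.finite(pdev_try) && (pdev_try <= pdev + 1e-10 || step < 1e-4)) break
        step <- step / 2
      }
      done <- abs(pdev - pdev_try) / (abs(pdev_try) + 0.1) < ctrl$pirls_tol
      v <- v_try; eta <- eta_try; mu <- mu_try; pdev <- pdev_try
      if (done) { ok <- TRUE; break }
    }
    v_warm <<- v
    ld <- if (sparse) {
      2 * as.numeric(Matrix::determinant(ch, sqrt = TRUE)$modulus)
    } else {
      2 * sum(log(diag(chol(M[qi, qi, drop = FALSE]))))
    }
    m2ll <- pdev + ld
    if (!keep) return(m2ll)
    list(m2ll = m2ll, v = v, M = M, S = S, mu = mu, pirls_converged = ok)
  }
  theta0 <- theta_start %||% rep(0.5, length(qs))
  if (!is.null(ctrl$theta_fixed)) {
    # variance components held at user-supplied values (e.g. 0, reducing
    # the model to plain logistic regression): no outer search, joint-mode
    # estimates with conditional Wald covariance
    ctrl$polish <- FALSE
    ctrl$se_method <- "conditional"
    opt <- list(par = ctrl$theta_fixed,
                value = pirls(ctrl$theta_fixed),
                convergence = 0L, message = "theta fixed")
  } else {
  # derivative-free outer search; |theta| folding makes 0 an interior point.
  # Nelder-Mead simplexes can collapse early, so restart until the restart
  # no longer improves the criterion.
  opt <- stats::optim(theta0, pirls, method = "Nelder-Mead",
                      control = list(reltol = ctrl$outer_rel_tol,
                                     maxit = ctrl$outer_max_iter * 5L))
  for (restart in 1:2) {
    opt2 <- stats::optim(opt$par, pirls, method = "Nelder-Mead",
                         control = list(reltol = ctrl$outer_rel_tol,
                                        maxit = ctrl$outer_max_iter * 5L))
    improved <- opt$value - opt2$value
    if (opt2$value <= opt$value) opt <- opt2
    if (improved < 1e-5) break
  }
  }
  theta_hat <- abs(opt$par)
  fin <- pirls(theta_hat, keep = TRUE)
  beta <- fin$v[fi]
  m2ll <- fin$m2ll

  # Laplace criterion with only the random-effect mode profiled (fixed
  # effects held as an offset); used for the Newton polish of beta and for
  # the full observed-information standard errors.
  Z0 <- if (sparse) Z0s else A0[, qi, drop = FALSE]
  b_warm <- fin$v[qi]
  pirls_u <- function(beta_u, theta_u, keep = FALSE) {
    theta_u <- abs(theta_u)
    Db <- theta_u[blk]
    if (sparse) Zs <- Z0s %*% Matrix::Diagonal(x = Db)
    off <- drop(X %*% beta_u)
    b <- b_warm
    eta_of <- function(bb) {
      off + if (sparse) as.vector(Zs %*% bb) else
        as.vector(Z0 %*% (Db * bb))
    }
    eta <- eta_of(b)
    mu <- inv_logit(eta)
    pdev <- -2 * sum(stats::dbinom(y, size, mu, log = TRUE)) + sum(b^2)
    Mb <- NULL; ch <- NULL
    for (it in seq_len(ctrl$pirls_max_iter)) {
      w <- pmax(size * mu * (1 - mu), 1e-12)
      zr <- (eta - off) + (y - size * mu) / w
      if (sparse) {
        Zsw <- Zs * sqrt(w)
        Mqq <- Matrix::crossprod(Zsw) + Iq
        ch <- Matrix::Cholesky(Mqq, LDL = FALSE, perm = TRUE)
        b_new <- as.vector(Matrix::solve(
          ch, as.vector(Matrix::crossprod(Zs, w * zr)), system = "A"))
      } else {
        Mb <- crossprod(Z0 * sqrt(w)) * tcrossprod(Db) + diag(q)
        b_new <- as.vector(solve(Mb, Db * as.vector(crossprod(Z0, w * zr))))
      }
      step <- 1
      repeat {
        b_try <- b + step * (b_new - b)
        eta_try <- eta_of(b_try)
        mu_try <- inv_logit(eta_try)
        pdev_try <- -2 * sum(stats::dbinom(y, size, mu_try, log = TRUE)) +
          sum(b_try^2)
        if (is.finite(pdev_try) && (pdev_try <= pdev + 1e-10 || step < 1e-4)) break
        step <- step / 2
      }
      done <- abs(pdev - pdev_try) / (abs(pdev_try) + 0.1) < ctrl$pirls_tol
      b <- b_try; eta <- eta_try; mu <- mu_try; pdev <- pdev_try
      if (done) break
    }
    b_warm <<- b
    ld <- if (sparse) {
      2 * as.numeric(Matrix::determinant(ch, sqrt = TRUE)$modulus)
    } else {
      2 * sum(log(diag(chol(Mb))))
    }
    if (!keep) pdev + ld else list(m2ll = pdev + ld, b = b)
  }

  se <- NULL
  need_hessian <- isTRUE(ctrl$polish) || identical(ctrl$se_method, "full")
  if (need_hessian) {
    # parameters for differentiation: beta and log(sd) of the non-boundary
    # variance components (the criterion is smooth in log-sd; boundary
    # components stay fixed at their estimate)
    free_th <- which(theta_hat >= 1e-3)
    par0 <- c(beta, log(theta_hat[free_th]))
    d <- length(par0)
    ctrl$pirls_tol <- min(ctrl$pirls_tol, 1e-12)
    f0 <- pirls_u(beta, theta_hat)
    b_center <- b_warm
    fpar <- function(par) {
      th <- theta_hat
      if (length(free_th)) th[free_th] <- exp(par[p + seq_along(free_th)])
      # start every probe from the central mode so finite differences are
      # free of warm-start hysteresis
      b_warm <<- b_center
      pirls_u(par[seq_len(p)], th)
    }
    h <- c(rep(2e-2, p), rep(5e-2, d - p))
    g <- numeric(d)
    H <- matrix(0, d, d)
    fp <- fm <- numeric(d)
    for (i in seq_len(d)) {
      ei <- replace(numeric(d), i, h[i])
      fp[i] <- fpar(par0 + ei); fm[i] <- fpar(par0 - ei)
      g[i] <- (fp[i] - fm[i]) / (2 * h[i])
      H[i, i] <- (fp[i] - 2 * f0 + fm[i]) / h[i]^2
    }
    if (d > 1) {
      for (i in seq_len(d - 1)) for (j in (i + 1):d) {
        ei <- replace(numeric(d), i, h[i])
        ej <- replace(numeric(d), j, h[j])
        H[i, j] <- H[j, i] <-
          (fpar(par0 + ei + ej) - fpar(par0 + ei - ej) -
             fpar(par0 - ei + ej) + fpar(par0 - ei - ej)) /
          (4 * h[i] * h[j])
      }
    }
    Hok <- !inherits(tryCatch(chol(H), error = identity), "error")
    par_hat <- par0
    if (isTRUE(ctrl$polish) && Hok) {
      # damped Newton refinement on the u-profiled criterion; the second
      # step reuses the Hessian with a refreshed gradient
      fcur <- f0
      for (newton in 1:2) {
        delta <- -solve(H, g)
        step <- 1
        moved <- FALSE
        for (half in 1:6) {
          cand <- par_hat + step * delta
          ftry <- fpar(cand)
          if (ftry < fcur) {
            par_hat <- cand; fcur <- ftry; moved <- TRUE; break
          }
          step <- step / 2
        }
        if (!moved || newton == 2) break
        for (i in seq_len(d)) {
          ei <- replace(numeric(d), i, h[i])
          g[i] <- (fpar(par_hat + ei) - fpar(par_hat - ei)) / (2 * h[i])
        }
        if (sqrt(sum(g^2)) < 1e-3) break
      }
      m2ll <- fcur
      beta <- par_hat[seq_len(p)]
      if (length(free_th)) {
        theta_hat[free_th] <- exp(par_hat[p + seq_along(free_th)])
      }
    }
    if (identical(ctrl$se_method, "full") && Hok) {
      Vfull <- tryCatch(2 * solve(H), error = function(e) NULL)
      if (!is.null(Vfull) && all(diag(Vfull)[seq_len(p)] > 0)) {
        se <- sqrt(diag(Vfull)[seq_len(p)])
      }
    }
    fin_u <- pirls_u(beta, theta_hat, keep = TRUE)
    m2ll <- fin_u$m2ll
    ranef_b <- fin_u$b
  } else {
    ranef_b <- fin$v[qi]
  }
  if (is.null(se)) {
    # conditional-on-theta Wald covariance: Schur complement of the
    # random-effect block in the joint penalized-IRLS information
    Vb <- if (sparse) {
      solve(fin$S)
    } else {
      E <- matrix(0, q + p, p); E[cbind(fi, seq_len(p))] <- 1
      solve(fin$M, E)[fi, , drop = FALSE]
    }
    se <- sqrt(pmax(diag(Vb), 0))
  }
  nm <- colnames(X) %||% paste0("b", seq_len(p))
  names(beta) <- names(se) <- nm
  zv <- beta / se
  k <- p + length(qs)
  ll <- -0.5 * m2ll
  list(coefficients = beta, std_errors = se, z_values = zv,
       p_values = 2 * stats::pnorm(-abs(zv)),
       theta = theta_hat, loglik = ll, n = n, k = k,
       aicc = aicc_value(ll, k, n),
       converged = opt$convergence == 0 && fin$pirls_converged,
       optimizer_message = opt$message,
       boundary = theta_hat < 1e-3,
       ranef = split(ranef_b, blk))
}

#' Laplace log-likelihood at fixed parameters
#'
#' Evaluates the Laplace-approximate marginal log-likelihood of a
#' random-intercept binomial logit model at supplied `beta` and `theta`
#' (no estimation): the random-effect conditional mode is found by
#' penalized IRLS with the fixed effects held as an offset.
#'
#' @inheritParams glmm_laplace_fit
#' @param beta Fixed-effect coefficients.
#' @param theta Random-intercept sds, one per grouping factor.
#' @return The Laplace log-likelihood (scalar).
#' @seealso [agq_loglik()] for the quadrature oracle this is validated
#'   against on single-level instances.
#' @export
laplace_loglik <- function(y, X, groups, beta, theta, size = 1) {
  X <- as.matrix(X)
  n <- nrow(X)
  size <- rep_len(size, n)
  groups <- lapply(groups, factor)
  qs <- vapply(groups, nlevels, 1L)
  q <- sum(qs)
  blk <- rep(seq_along(qs), qs)
  Z <- do.call(cbind, lapply(groups, sparse_indicator))
  off <- drop(X %*% beta)
  D <- theta[blk]
  b <- numeric(q)
  eta <- off
  mu <- inv_logit(eta)
  pdev <- -2 * sum(stats::dbinom(y, size, mu, log = TRUE)) + sum(b^2)
  M <- Matrix::Diagonal(q)
  for (it in 1:60) {
    w <- pmax(size * mu * (1 - mu), 1e-12)
    zr <- eta - off + (y - size * mu) / w
    Zw <- Z * sqrt(w)
    Dm <- Matrix::Diagonal(x = D)
    M <- Dm %*% Matrix::crossprod(Zw) %*% Dm + Matrix::Diagonal(q)
    rhs <- D * as.vector(Matrix::crossprod(Z, w * zr))
    b_new <- as.vector(Matrix::solve(M, rhs))
    step <- 1
    repeat {
      b_try <- b + step * (b_new - b)
      eta_try <- off + as.vector(Z %*% (D * b_try))
      mu_try <- inv_logit(eta_try)
      pdev_try <- -2 * sum(stats::dbinom(y, size, mu_try, log = TRUE)) +
        sum(b_try^2)
      if (is.finite(pdev_try) && (pdev_try <= pdev + 1e-10 || step < 1e-4)) break
      step <- step / 2
    }
    done <- abs(pdev - pdev_try) / (abs(pdev_try) + 0.1) < 1e-12
    b <- b_try; eta <- eta_try; mu <- mu_try; pdev <- pdev_try
    if (done) break
  }
  ld <- as.numeric(Matrix::determinant(M, logarithm = TRUE)$modulus)
  -0.5 * (pdev + ld)
}

#' Fit the binomial consumption GLMM to bait records
#'
#' Front end over [glmm_laplace_fit()]: builds the response
#' (consumed-by-target vs not), the fixed-effects design (z-scored
#' continuous covariates, recognised categorical codings) and the
#' site-nested-in-week random structure (intercepts for week and for each
#' island-within-week), then fits by Laplace approximation. Wald standard
#' errors come from the observed information of the Laplace objective at
#' the optimum, z = beta/SE, and p-values use the normal reference.
#'
#' @param records Known-fate bait records.
#' @param spec A [model_spec()].
#' @param control Passed to [glmm_laplace_fit()].
#' @return A `baitfate_glmm` object: coefficient table, `var_week`,
#'   `var_site_in_week`, `loglik`, `n`, `k`, `aicc`, `scaling`,
#'   `converged`, `boundary`.
#' @examples
#' \donttest{
#' sites <- generate_sites(10, 4, 4, seed = 1)
#' baits <- generate_deployments(sites, seed = 2)
#' baits <- simulate_fates(baits, seed = 3)
#' fit <- fit_binomial_glmm(filter_known_fates(baits),
#'                          model_spec("alligator"))
#' print(fit)
#' }
#' @export
fit_binomial_glmm <- function(records, spec = model_spec(),
                              control = list()) {
  assert_known_fate(records)
  y <- as.integer(records$consumer == spec$target)
  des <- build_design(records, spec$covariates, spec$scale_continuous)
  wk <- factor(records$week)
  ws <- factor(paste(records$week, records$site_id, sep = ":"))
  fit <- glmm_laplace_fit(y, des$X, list(week = wk, site_in_week = ws),
                          control = control)
  out <- c(fit, list(var_week = fit$theta[1]^2,
                     var_site_in_week = fit$theta[2]^2,
                     scaling = des$scaling,
                     term_covariate = des$term_covariate,
                     spec = spec))
  class(out) <- "baitfate_glmm"
  out
}

#' @export
print.baitfate_glmm <- function(x, ...) {
  cat("Binomial logit mixed model (Laplace), target =", x$spec$target, "\n")
  cat(sprintf("n = %d, logLik = %.3f, AICc = %.3f%s\n", x$n, x$loglik,
              x$aicc, if (x$converged) "" else "  [NOT CONVERGED]"))
  cat(sprintf("Random intercept sds: week = %.4f, site-in-week = %.4f\n",
              x$theta[1], x$theta[2]))
  tab <- data.frame(Estimate = x$coefficients,
                    `Std. Error` = x$std_errors,
                    `z value` = x$z_values,
                    `Pr(>|z|)` = x$p_values,
                    check.names = FALSE)
  print(round(tab, 4))
  invisible(x)
}

#' @noRd
aicc_value <- function(loglik, k, n) {
  if (n <= k + 1) stop("AICc undefined: n must exceed k + 1", call. = FALSE)
  -2 * loglik + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Corrected Akaike information criterion of a fit
#'
#' `-2 logLik + 2k + 2k(k+1)/(n - k - 1)`, with `k` counting fixed effects
#' (including the intercept) plus the variance components.
#'
#' @param fit A fit with `loglik`, `k` and `n` components
#'   ([fit_binomial_glmm()], [glmm_laplace_fit()], [fit_logistic_glm()]),
#'   or a numeric log-likelihood together with `k` and `n`.
#' @param k,n Parameter count and sample size (when `fit` is numeric).
#' @return The AICc value.
#' @export
aicc <- function(fit, k = NULL, n = NULL) {
  if (is.numeric(fit)) return(aicc_value(fit, k, n))
  aicc_value(fit$loglik, fit$k, fit$n)
}

#' Predicted consumption probability on the original covariate scale
#'
#' Applies the scaling stored in the fit, rebuilds the fixed-effects row(s)
#' and returns the inverse-logit linear predictor with random effects at
#' zero (population-level curves, as used for covariate-response figures).
#'
#' @param fit A `baitfate_glmm` (or any fit carrying `coefficients`,
#'   `scaling`, `spec`).
#' @param newdata Data frame of covariate values on the original scale.
#' @return Numeric vector of probabilities.
#' @export
predict_probability <- function(fit, newdata) {
  des <- build_design(newdata, fit$spec$covariates,
                      fit$spec$scale_continuous, scaling = fit$scaling)
  X <- des$X[, names(fit$coefficients), drop = FALSE]
  inv_logit(drop(X %*% fit$coefficients))
}
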