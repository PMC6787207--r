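# Mixed-model machinery: covariate scaling, collinearity screen, Laplace
# fitter, quadrature oracle, prediction.

test_that("z-scoring is exact and invertible", {
  recs <- data.frame(a = c(0, 10, 20), b = c(5, 6, 10))
  sc <- scale_covariates(recs, c("a", "b"))
  expect_equal(sc$records$a, c(-1, 0, 1))
  expect_equal(mean(sc$records$b), 0, tolerance = 1e-12)
  expect_equal(sd(sc$records$b), 1, tolerance = 1e-12)
  back <- unscale_covariates(sc$records, sc$scaling)
  expect_equal(back$a, recs$a, tolerance = 1e-12)
  expect_equal(back$b, recs$b, tolerance = 1e-12)
  recs$c <- 7
  expect_error(scale_covariates(recs, "c"), "zero-variance.*c")
})

test_that("collinearity screen removes rank-correlated covariates", {
  set.seed(8)
  x <- runif(300, 1, 5)
  recs <- data.frame(x = x, xsq = x^2, z = runif(300))
  out <- collinearity_screen(recs, c("x", "xsq", "z"), threshold = 0.5)
  # x and x^2 have rank correlation 1: exactly one of them survives
  expect_equal(length(intersect(out$retained, c("x", "xsq"))), 1)
  expect_true("z" %in% out$retained)
  expect_equal(nrow(out$dropped), 1)
  # three mutually rank-identical covariates: exactly one retained
  recs3 <- data.frame(a = x, b = exp(x), c = x^3)
  out3 <- collinearity_screen(recs3, c("a", "b", "c"))
  expect_equal(length(out3$retained), 1)
  # independent uniforms at n = 500: null r_s is ~N(0, 1/sqrt(499)), so
  # exceeding 0.5 has vanishing probability and everything is retained
  set.seed(9)
  ind <- as.data.frame(matrix(runif(500 * 5), 500, 5))
  outi <- collinearity_screen(ind, names(ind))
  expect_equal(sort(outi$retained), sort(names(ind)))
  expect_error(collinearity_screen(ind, "V1"), "at least 2")
})

test_that("AICc follows the small-sample formula", {
  expect_equal(aicc(-10, k = 3, n = 20), 20 + 6 + 24 / 16)
  expect_equal(aicc(-10, k = 0, n = 20), 20)
  # the correction vanishes as n grows
  expect_lt(abs(aicc(-10, k = 3, n = 1e7) - (20 + 6)), 1e-5)
  expect_error(aicc(-10, k = 5, n = 6), "n must exceed")
})

test_that("zero-variance mixed model reduces to plain logistic regression", {
  recs <- make_minimal_records(400, n_sites = 12, seed = 21)
  sim <- simulate_binomial_fates(
    recs, c(`(Intercept)` = -0.5, dist_water_m = -1, local_density = 0.4),
    sd_week = 0.4, sd_site_in_week = 0.4, seed = 22)
  y <- as.integer(sim$consumer == "alligator")
  des <- baitfate:::build_design(sim, c("dist_water_m", "local_density"),
                                 TRUE)
  wk <- factor(sim$week)
  ws <- factor(paste(sim$week, sim$site_id, sep = ":"))
  red <- glmm_laplace_fit(y, des$X, list(wk, ws),
                          control = list(theta_fixed = c(0, 0)))
  ref <- fit_logistic_glm(y, des$X)
  expect_equal(unname(red$coefficients), unname(ref$coefficients),
               tolerance = 1e-6)
  expect_equal(unname(red$std_errors), unname(ref$std_errors),
               tolerance = 1e-6)
  expect_equal(red$loglik, ref$loglik, tolerance = 1e-6)
})

test_that("Laplace loglik at fixed parameters matches the quadrature oracle", {
  # information-rich binomial groups: the Laplace error itself is far below
  # the comparison tolerance, so implementation defects are detectable
  set.seed(23)
  for (r in 1:10) {
    ng <- sample(3:4, 1)
    m <- sample(10:15, 1)
    g <- factor(rep(seq_len(ng), each = m))
    n <- length(g)
    X <- cbind(1, rnorm(n))
    beta <- rnorm(2, 0, 0.8)
    sdv <- runif(1, 0.05, 0.25)
    size <- rep(100L, n)
    y <- rbinom(n, size, plogis(drop(X %*% beta) + rnorm(ng, 0, sdv)[g]))
    lap <- laplace_loglik(y, X, list(g), beta, sdv, size = size)
    agq <- agq_loglik(y, X, g, beta, sdv, size = size, nodes = 50)
    expect_lt(abs(lap - agq), 1e-3)
  }
  # Bernoulli data: the approximation (not the implementation) differs at
  # the 1e-2 scale; assert that sanity band
  for (r in 1:5) {
    g <- factor(rep(1:3, each = 10))
    X <- cbind(1, rnorm(30))
    beta <- rnorm(2, 0, 0.8)
    sdv <- runif(1, 0.2, 0.8)
    y <- rbinom(30, 1, plogis(drop(X %*% beta) + rnorm(3, 0, sdv)[g]))
    expect_lt(abs(laplace_loglik(y, X, list(g), beta, sdv) -
                    agq_loglik(y, X, g, beta, sdv)), 0.05)
  }
})

test_that("quadrature oracle is internally consistent", {
  # node count convergence: 20 vs 50 nodes agree once adapted
  set.seed(24)
  g <- factor(rep(1:4, each = 8))
  X <- cbind(1, rnorm(32))
  y <- rbinom(32, 1, 0.4)
  a20 <- agq_loglik(y, X, g, c(-0.3, 0.5), 0.6, nodes = 20)
  a50 <- agq_loglik(y, X, g, c(-0.3, 0.5), 0.6, nodes = 50)
  expect_lt(abs(a20 - a50), 1e-8)
  # sd -> 0 limit equals the plain Bernoulli loglik
  eta <- drop(X %*% c(-0.3, 0.5))
  ll0 <- sum(dbinom(y, 1, plogis(eta), log = TRUE))
  expect_equal(agq_loglik(y, X, g, c(-0.3, 0.5), 1e-6), ll0,
               tolerance = 1e-4)
})

test_that("the fitter agrees with an independent mixed-model implementation", {
  skip_if_not_installed("lme4")
  recs <- make_minimal_records(600, n_sites = 30, seed = 25)
  sim <- simulate_binomial_fates(
    recs, c(`(Intercept)` = -1, dist_water_m = -1.2, local_density = 0.5),
    sd_week = 0.5, sd_site_in_week = 0.5, seed = 26)
  y <- as.integer(sim$consumer == "alligator")
  des <- baitfate:::build_design(sim, c("dist_water_m", "local_density"),
                                 TRUE)
  wk <- factor(sim$week)
  ws <- factor(paste(sim$week, sim$site_id, sep = ":"))
  mine <- glmm_laplace_fit(y, des$X, list(wk, ws))
  d <- data.frame(y = y, des$X[, -1], wk = wk, ws = ws, check.names = FALSE)
  ref <- lme4::glmer(y ~ dist_water_m + local_density + (1 | wk) + (1 | ws),
                     data = d, family = binomial)
  # same Laplace criterion: the optima must essentially coincide
  expect_lt(-2 * mine$loglik, -2 * as.numeric(stats::logLik(ref)) + 0.05)
  expect_lt(max(abs(mine$coefficients -
                      lme4::fixef(ref)[names(mine$coefficients)])), 0.02)
})

test_that("structural preconditions are enforced", {
  recs <- make_minimal_records(30, n_sites = 5, seed = 27)
  y <- rbinom(30, 1, 0.5)
  X <- cbind(1, rnorm(30))
  expect_error(glmm_laplace_fit(y, X, list(factor(rep("a", 30)))),
               ">= 2 groups")
  expect_error(glmm_laplace_fit(y, cbind(X, X[, 2]),
                                list(factor(rep(1:5, 6)))), "full rank")
  recs$fate_known <- FALSE
  expect_error(fit_binomial_glmm(recs, model_spec("alligator")),
               "unknown-fate")
})

test_that("predicted probabilities respect the fitted link", {
  # constructed fit: published-style coefficients, identity scaling
  fit <- structure(list(
    coefficients = c(`(Intercept)` = -1.72, colony_type_egretta = 1.61,
                     dist_water_m = -1.43, local_density = 0.56,
                     avg_temp_F = 0.52),
    scaling = data.frame(covariate = c("dist_water_m", "local_density",
                                       "avg_temp_F"),
                         mean = c(5, 3, 72), sd = c(4, 2, 5)),
    spec = model_spec("alligator",
                      c("dist_water_m", "colony_type", "local_density",
                        "avg_temp_F"))),
    class = "baitfate_glmm")
  base <- data.frame(dist_water_m = 5, local_density = 3, avg_temp_F = 72,
                     colony_type = "Ardea")
  # all scaled covariates at zero on an Ardea island: inverse-logit of the
  # intercept alone
  expect_equal(predict_probability(fit, base), plogis(-1.72),
               tolerance = 1e-12)
  expect_equal(round(predict_probability(fit, base), 3), 0.152)
  # monotone decreasing in distance to water (negative coefficient)
  grid <- base[rep(1, 50), ]
  grid$dist_water_m <- seq(0, 30, length.out = 50)
  p <- predict_probability(fit, grid)
  expect_true(all(diff(p) < 0))
  expect_true(all(p >= 0 & p <= 1))
  # all-zero coefficients: probability one half everywhere
  fit0 <- fit
  fit0$coefficients[] <- 0
  expect_true(all(predict_probability(fit0, grid) == 0.5))
  expect_error(predict_probability(fit, data.frame(dist_water_m = 1)),
               "unknown covariate")
})

test_that("AICc ranking is invariant to affine covariate rescaling", {
  recs <- make_minimal_records(300, n_sites = 10, seed = 28)
  sim <- simulate_binomial_fates(
    recs, c(`(Intercept)` = -0.8, dist_water_m = -1, local_density = 0.3),
    sd_week = 0.3, sd_site_in_week = 0.3, seed = 29)
  spec1 <- model_spec("alligator", c("dist_water_m", "local_density"))
  spec2 <- model_spec("alligator", "dist_water_m")
  a1 <- fit_binomial_glmm(sim, spec1)$aicc
  a2 <- fit_binomial_glmm(sim, spec2)$aicc
  resc <- sim
  resc$dist_water_m <- resc$dist_water_m * 1000 + 7
  resc$local_density <- resc$local_density / 50 - 2
  b1 <- fit_binomial_glmm(resc, spec1)$aicc
  b2 <- fit_binomial_glmm(resc, spec2)$aicc
  # z-scoring makes the fits identical, so the ranking (and the values)
  # carry over under affine maps
  expect_equal(a1, b1, tolerance = 1e-4)
  expect_equal(a2, b2, tolerance = 1e-4)
  expect_identical(a1 < a2, b1 < b2)
})
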