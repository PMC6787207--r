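# Synthetic bait-deployment generator: site profiles, deployments, fates.

test_that("generate_sites respects class structure and invariants", {
  sites <- generate_sites(20, 6, 6, seed = 1)
  expect_equal(nrow(sites), 32)
  expect_equal(sum(sites$colony_type == "Ardea"), 20)
  expect_equal(sum(sites$colony_type == "Egretta"), 6)
  # inactive <=> colony none <=> zero nests
  inact <- sites$island_type == "inactive"
  expect_true(all(sites$colony_type[inact] == "none"))
  expect_true(all(sites$colony_size_nests[inact] == 0))
  expect_true(all(sites$colony_type[!inact] != "none"))
  expect_true(all(sites$colony_size_nests[!inact] > 0))
  cfg <- default_generator_config()
  eg <- sites[sites$colony_type == "Egretta", ]
  expect_true(all(eg$area_m2 >= cfg$site$Egretta$area_m2[["min"]]))
  expect_true(all(eg$area_m2 <= cfg$site$Egretta$area_m2[["max"]]))
})

test_that("site attributes follow the configured truncated distributions", {
  # large sample: Egretta mean area must sit near the configured centre,
  # inside the truncation-shifted plausible band
  sites <- generate_sites(0, 4000, 0, seed = 7)
  m <- mean(sites$area_m2)
  expect_gt(m, 982.11)
  expect_lt(m, 5903.98)
  # truncation [982.11, 5903.98] of N(1554.79, 2697.77) pulls the mean up;
  # check against the analytic truncated-normal mean within Monte Carlo error
  a <- (982.11 - 1554.79) / 2697.77
  b <- (5903.98 - 1554.79) / 2697.77
  tn_mean <- 1554.79 + 2697.77 * (dnorm(a) - dnorm(b)) / (pnorm(b) - pnorm(a))
  expect_lt(abs(m - tn_mean) / tn_mean, 0.05)
})

test_that("generation is deterministic given the seed", {
  expect_identical(generate_sites(5, 2, 2, seed = 42),
                   generate_sites(5, 2, 2, seed = 42))
  s <- generate_sites(5, 2, 2, seed = 42)
  expect_identical(generate_deployments(s, seed = 9),
                   generate_deployments(s, seed = 9))
  b <- generate_deployments(s, seed = 9)
  expect_identical(simulate_fates(b, seed = 11), simulate_fates(b, seed = 11))
  expect_false(identical(simulate_fates(b, seed = 11),
                         simulate_fates(b, seed = 12)))
})

test_that("invalid generator configuration is rejected", {
  cfg <- default_generator_config()
  cfg$site$Ardea$area_m2[["min"]] <- 1e6  # min > max
  expect_error(generate_sites(2, 0, 0, config = cfg, seed = 1),
               "invalid range")
  expect_error(generate_deployments(generate_sites(2, 1, 1, seed = 1),
                                    baits_per_site_visit = 6),
               "between 1 and 5")
  expect_error(generate_deployments(generate_sites(2, 1, 1, seed = 1),
                                    visits = 4),
               "between 1 and 3")
})

test_that("deployments respect protocol constraints", {
  sites <- generate_sites(20, 6, 6, seed = 3)
  baits <- generate_deployments(sites, seed = 4)
  # at most 5 baits x 3 visits x 32 sites; at least one bait per site
  expect_lte(nrow(baits), 480)
  expect_gte(nrow(baits), nrow(sites))
  expect_setequal(unique(baits$site_id), sites$site_id)
  # successive visits to a site are >= 2 weeks apart
  for (s in unique(baits$site_id)) {
    wk <- sort(unique(baits$week[baits$site_id == s]))
    if (length(wk) > 1) expect_true(all(diff(wk) >= 2))
  }
  # per-visit cap
  pervisit <- table(paste(baits$site_id, baits$week))
  expect_lte(max(pervisit), 5)
  # inactive islands have zero local nesting density
  expect_true(all(baits$local_density[baits$island_type == "inactive"] == 0))
  # water placements are at zero distance to water
  expect_true(all(baits$dist_water_m[baits$placement == "water"] == 0))
  # ground-placed Egretta baits stay in the configured distance range
  eg <- baits[baits$colony_type == "Egretta" & baits$placement == "ground", ]
  expect_true(all(eg$dist_water_m >= 0.61 & eg$dist_water_m <= 5.91))
})

test_that("simulated fates are exclusive and complete", {
  baits <- default_design(21)
  done <- simulate_fates(baits, seed = 5)
  known <- filter_known_fates(done)
  # exactly one consumer category per bait
  expect_true(all(known$consumer %in% c("turkey_vulture", "alligator",
                                        "amphiuma", "black_vulture",
                                        "other", "none")))
  # alligator <=> informative size class
  is_all <- known$consumer == "alligator"
  expect_true(all(known$alligator_size[is_all] %in%
                    c("small", "medium", "large")))
  expect_true(all(known$alligator_size[!is_all] == "not_applicable"))
  # unconsumed baits carry no latency; consumed ones do
  expect_true(all(is.na(known$latency_h[known$consumer == "none"])))
  expect_true(all(!is.na(known$latency_h[known$consumer != "none"])))
  # censored records are unusable by construction
  cens <- done[!done$fate_known, ]
  expect_true(all(is.na(cens$consumer)))
})

test_that("censoring boundary and rate behave as configured", {
  baits <- default_design(31)
  all_known <- simulate_fates(baits, true_model_params(censor_rate = 0),
                              seed = 6)
  expect_true(all(all_known$fate_known))
  # observed censoring within 3 binomial SEs of the configured rate
  n_tot <- 0; n_cens <- 0
  for (s in 1:10) {
    d <- simulate_fates(baits, seed = 100 + s)
    n_tot <- n_tot + nrow(d)
    n_cens <- n_cens + sum(!d$fate_known)
  }
  se <- sqrt(0.2 * 0.8 / n_tot)
  expect_lt(abs(n_cens / n_tot - 0.2), 3 * se)
})

test_that("intercept-only fates match the closed-form softmax", {
  # all slopes zero, random-effect sds zero: category frequencies must
  # equal the analytic four-way softmax within binomial error at n = 50,000
  n <- 50000
  recs <- make_minimal_records(n, n_sites = 50, seed = 13)
  params <- true_model_params(
    alligator_coefs = c(`(Intercept)` = -1.72),
    vulture_coefs = c(`(Intercept)` = 1.01),
    sd_week = 0, sd_site_in_week = 0, censor_rate = 0)
  done <- simulate_fates(recs, params, seed = 14)
  lin <- c(none = params$none_logit, alligator = -1.72,
           turkey_vulture = 1.01, other = params$other_logit)
  pr <- exp(lin) / sum(exp(lin))
  obs <- c(none = mean(done$consumer == "none"),
           alligator = mean(done$consumer == "alligator"),
           turkey_vulture = mean(done$consumer == "turkey_vulture"),
           other = mean(done$consumer %in% c("amphiuma", "black_vulture",
                                             "other")))
  for (k in names(pr)) {
    se <- sqrt(pr[k] * (1 - pr[k]) / n)
    expect_lt(abs(obs[k] - pr[k]), 4 * se)
  }
})

test_that("alligator consumption declines across distance-to-water quartiles", {
  n <- 12000
  recs <- make_minimal_records(n, n_sites = 60, seed = 15)
  params <- true_model_params(censor_rate = 0)
  done <- simulate_fates(recs, params, seed = 16)
  qs <- cut(done$dist_water_m,
            breaks = quantile(done$dist_water_m, 0:4 / 4),
            include.lowest = TRUE)
  rate <- tapply(done$consumer == "alligator", qs, mean)
  expect_true(all(diff(rate) < 0))
})

test_that("marginal consumption is calibrated to the observed overall rate", {
  cons <- vapply(1:20, function(s) {
    done <- simulate_fates(default_design(400 + s), seed = 600 + s)
    known <- filter_known_fates(done)
    mean(known$consumer != "none")
  }, 0)
  expect_lt(abs(mean(cons) - 0.85), 0.05)
})

test_that("consumption latency follows the truncated exponential law", {
  recs <- make_minimal_records(3000, n_sites = 80, seed = 17)
  done <- simulate_fates(recs, true_model_params(censor_rate = 0), seed = 18)
  eaten <- done$consumer != "none"
  lat <- done$latency_h[eaten]
  expect_gt(length(lat), 1000)
  # analytic mean of an exponential(48 h) censored at each bait's exposure
  # window: E[min(X, T)] = 48 (1 - exp(-T/48))
  Th <- done$exposure_min[eaten] / 60
  expected <- mean(48 * (1 - exp(-Th / 48)))
  se <- sd(lat) / sqrt(length(lat))
  expect_lt(abs(mean(lat) - expected), 3 * se)
  expect_true(all(lat <= Th + 1e-12))
})

test_that("unknown covariates in the true model are rejected", {
  recs <- make_minimal_records(50, seed = 19)
  bad <- true_model_params(
    alligator_coefs = c(`(Intercept)` = -1, nonexistent_cov = 2))
  expect_error(simulate_fates(recs, bad, seed = 1), "unknown covariate")
})
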