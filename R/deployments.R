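#' Generate synthetic bait deployments (covariates only)
#'
#' Expands a site table into one row per deployed bait, mirroring the field
#' protocol: each island is visited on one to three occasions, successive
#' visits to the same island are at least two weeks apart, and no more than
#' five baits are deployed per island visit. Covariates are drawn from the
#' per-class distributions in `config`; baits placed in water have
#' `dist_water_m = 0`, and baits on inactive islands have
#' `local_density = 0`.
#'
#' Fate fields (`fate_known`, `consumer`, `alligator_size`, `latency_h`)
#' are initialised as unset; see [simulate_fates()].
#'
#' @param sites Site table from [generate_sites()].
#' @param baits_per_site_visit Maximum baits per island visit (1--5).
#' @param visits Maximum visits per island (1--3).
#' @param config Generator settings ([default_generator_config()]).
#' @param seed Integer seed.
#' @return A data frame, one row per bait, carrying site attributes
#'   (`site_id`, `island_type`, `colony_type`, `area_m2`,
#'   `colony_size_nests`, `stem_density`) and bait covariates (`week`,
#'   `dist_water_m`, `dist_canal_m`, `dist_gatorhole_m`, `local_density`,
#'   `avg_temp_F`, `exposure_min`, `veg_complexity`, `placement`), plus
#'   unset fate columns.
#' @examples
#' sites <- generate_sites(4, 2, 2, seed = 1)
#' baits <- generate_deployments(sites, seed = 2)
#' table(baits$colony_type)
#' @export
generate_deployments <- function(sites, baits_per_site_visit = 5L,
                                 visits = 3L,
                                 config = default_generator_config(),
                                 seed = 1L) {
  if (baits_per_site_visit < 1 || baits_per_site_visit > 5) {
    stop("baits_per_site_visit must be between 1 and 5", call. = FALSE)
  }
  if (visits < 1 || visits > 3) {
    stop("visits must be between 1 and 3", call. = FALSE)
  }
  for (cl in c("Ardea", "Egretta", "inactive")) {
    validate_tn(config$bait[[cl]]$dist_water_m, paste(cl, "dist_water_m"))
    validate_tn(config$bait[[cl]]$local_density, paste(cl, "local_density"))
  }
  with_seed(seed, {
    # visit schedule: small per-site loop for the protocol draws, then one
    # vectorized pass for all bait covariates
    site_row <- integer(0)
    week <- integer(0)
    for (i in seq_len(nrow(sites))) {
      nv <- sample.int(visits, 1L)
      # first visit early in the season; later visits >= 2 weeks apart
      wk0 <- sample.int(max(1L, config$season_weeks - 2L * (nv - 1L) - 1L),
                        1L)
      weeks <- wk0 + cumsum(c(0L, sample(2:3, nv - 1L, replace = TRUE)))
      nb <- sample(seq_len(baits_per_site_visit), nv, replace = TRUE,
                   prob = seq_len(baits_per_site_visit))
      site_row <- c(site_row, rep(i, sum(nb)))
      week <- c(week, rep(weeks, nb))
    }
    n <- length(site_row)
    cls <- ifelse(sites$island_type[site_row] == "inactive", "inactive",
                  sites$colony_type[site_row])
    placement <- ifelse(stats::runif(n) < config$placement_water_prob,
                        "water", "ground")
    dw <- ld <- numeric(n)
    vc <- character(n)
    for (cl in unique(cls)) {
      idx <- which(cls == cl)
      dw_spec <- config$bait[[cl]]$dist_water_m
      ld_spec <- config$bait[[cl]]$local_density
      dw[idx] <- rtruncnorm(length(idx), dw_spec[["mean"]], dw_spec[["sd"]],
                            dw_spec[["min"]], dw_spec[["max"]])
      ld[idx] <- rtruncnorm(length(idx), ld_spec[["mean"]], ld_spec[["sd"]],
                            ld_spec[["min"]], ld_spec[["max"]])
      vc_probs <- config$veg_complexity_probs[[cl]]
      vc[idx] <- sample(names(vc_probs), length(idx), replace = TRUE,
                        prob = vc_probs)
    }
    dw[placement == "water"] <- 0
    ld[cls == "inactive"] <- 0
    dc <- config$bait$dist_canal_m
    dg <- config$bait$dist_gatorhole_m
    ex <- config$bait$exposure_min
    out <- data.frame(
      bait_id = sprintf("B%03d", seq_len(n)),
      site_id = sites$site_id[site_row],
      island_type = sites$island_type[site_row],
      colony_type = sites$colony_type[site_row],
      area_m2 = sites$area_m2[site_row],
      colony_size_nests = sites$colony_size_nests[site_row],
      stem_density = sites$vegetation_density_stems[site_row],
      week = week,
      dist_water_m = dw,
      dist_canal_m = rtruncnorm(n, dc[["mean"]], dc[["sd"]], dc[["min"]],
                                dc[["max"]]),
      dist_gatorhole_m = rtruncnorm(n, dg[["mean"]], dg[["sd"]],
                                    dg[["min"]], dg[["max"]]),
      local_density = ld,
      avg_temp_F = config$temp$base + config$temp$slope_per_week * week +
        stats::rnorm(n, 0, config$temp$sd),
      exposure_min = rtruncnorm(n, ex[["mean"]], ex[["sd"]], ex[["min"]],
                                ex[["max"]]),
      veg_complexity = vc,
      placement = placement,
      fate_known = NA,
      consumer = NA_character_,
      alligator_size = NA_character_,
      latency_h = NA_real_,
      stringsAsFactors = FALSE
    )
    rownames(out) <- NULL
    out
  })
}
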