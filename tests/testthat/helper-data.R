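# Shared test helpers: small deterministic datasets and a minimal record
# builder for forward-model checks where covariates are irrelevant.

make_minimal_records <- function(n, n_sites = 20, weeks = 1:8, seed = 1) {
  baitfate:::with_seed(seed, {
    site <- sample(sprintf("S%02d", seq_len(n_sites)), n, replace = TRUE)
    data.frame(
      bait_id = sprintf("B%05d", seq_len(n)),
      site_id = site,
      island_type = "active",
      colony_type = "Ardea",
      week = sample(weeks, n, replace = TRUE),
      dist_water_m = stats::runif(n, 0, 25),
      dist_canal_m = stats::runif(n, 0, 2000),
      dist_gatorhole_m = stats::runif(n, 0, 60),
      local_density = stats::runif(n, 0, 6),
      avg_temp_F = stats::rnorm(n, 72, 4),
      exposure_min = stats::runif(n, 600, 10080),
      veg_complexity = sample(c("low", "medium", "high"), n, replace = TRUE),
      stem_density = stats::runif(n, 0.4, 6),
      placement = "ground",
      fate_known = TRUE,
      consumer = "none",
      alligator_size = "not_applicable",
      latency_h = NA_real_,
      stringsAsFactors = FALSE
    )
  })
}

fixture_known <- function() {
  filter_known_fates(
    read_bait_records(baitfate_example("consumer_table_fixture.csv")))
}

# default design at roughly the published deployment scale
default_design <- function(seed) {
  sites <- generate_sites(20, 6, 6, seed = seed)
  generate_deployments(sites, seed = seed + 1L)
}
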