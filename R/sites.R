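#' Generate synthetic island (site) profiles
#'
#' Draws a set of tree-island profiles of the three classes used in the
#' bait-monitoring design: active *Ardea*-heron colonies, active
#' *Egretta*-heron colonies, and inactive (non-colony) islands. Attributes
#' are drawn from truncated normal distributions whose mean, sd and range
#' default to the published per-class field summaries
#' (see [default_generator_config()]).
#'
#' Inactive islands always have `colony_type = "none"` and
#' `colony_size_nests = 0`.
#'
#' @param n_ardea,n_egretta,n_inactive Number of sites of each class.
#' @param config Generator settings, as from [default_generator_config()].
#' @param seed Integer seed; the same seed yields an identical site table.
#' @return A data frame with one row per site: `site_id`, `island_type`
#'   (`active`/`inactive`), `colony_type` (`Ardea`/`Egretta`/`none`),
#'   `area_m2`, `colony_size_nests`, `vegetation_density_stems`.
#' @examples
#' sites <- generate_sites(20, 6, 6, seed = 1)
#' table(sites$colony_type)
#' @export
generate_sites <- function(n_ardea, n_egretta, n_inactive,
                           config = default_generator_config(), seed = 1L) {
  for (n in c(n_ardea, n_egretta, n_inactive)) {
    if (!is.numeric(n) || length(n) != 1L || is.na(n) || n < 0) {
      stop("site counts must be non-negative integers", call. = FALSE)
    }
  }
  classes <- rep(c("Ardea", "Egretta", "inactive"),
                 times = c(n_ardea, n_egretta, n_inactive))
  n <- length(classes)
  with_seed(seed, {
    draw <- function(class, field) {
      spec <- validate_tn(config$site[[class]][[field]],
                          paste(class, field, sep = "/"))
      idx <- classes == class
      out <- numeric(n)
      out[idx] <- rtruncnorm(sum(idx), spec[["mean"]], spec[["sd"]],
                             spec[["min"]], spec[["max"]])
      out
    }
    area <- stems <- csize <- numeric(n)
    for (cl in unique(classes)) {
      idx <- classes == cl
      area[idx] <- draw(cl, "area_m2")[idx]
      stems[idx] <- draw(cl, "stem_density")[idx]
      csize[idx] <- draw(cl, "colony_size_nests")[idx]
    }
    data.frame(
      site_id = sprintf("S%02d", seq_len(n)),
      island_type = ifelse(classes == "inactive", "inactive", "active"),
      colony_type = ifelse(classes == "inactive", "none", classes),
      area_m2 = area,
      colony_size_nests = as.integer(round(csize)),
      vegetation_density_stems = stems,
      stringsAsFactors = FALSE
    )
  })
}
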