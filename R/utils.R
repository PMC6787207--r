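## Internal helpers shared across modules.

#' Run code under a fixed RNG seed, restoring the caller's RNG state
#' @noRd
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Truncated normal draws by inverse-CDF, deterministic given the RNG state.
#'
#' Degenerate cases (sd = 0 or lo = hi) return the clamped mean. The printed
#' field summaries give mean, sd and observed range only, so a clipped normal
#' is the assumed shape throughout the generator.
#' @noRd
rtruncnorm <- function(n, mean, sd, lo = -Inf, hi = Inf) {
  if (lo > hi) stop("invalid range: min > max", call. = FALSE)
  if (sd <= 0 || lo == hi) return(rep(min(max(mean, lo), hi), n))
  plo <- stats::pnorm(lo, mean, sd)
  phi <- stats::pnorm(hi, mean, sd)
  u <- stats::runif(n, plo, phi)
  q <- stats::qnorm(u, mean, sd)
  pmin(pmax(q, lo), hi)
}

#' @noRd
logit <- function(p) log(p / (1 - p))

#' @noRd
inv_logit <- function(x) stats::plogis(x)

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
assert_known_fate <- function(records) {
  if (!all(records$fate_known)) {
    stop("records contain unknown-fate baits; apply filter_known_fates() first",
         call. = FALSE)
  }
  invisible(records)
}
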