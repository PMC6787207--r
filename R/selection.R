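#' Backward stepwise covariate selection by AICc
#'
#' Starting from the full model, repeatedly removes the single fixed
#' covariate whose removal most reduces AICc, refitting at each step, and
#' stops when no removal reduces AICc. The random structure (week and
#' island-within-week intercepts) is never removed. When two removals give
#' AICc equal within `tie_tol`, the covariate with the larger Wald p-value
#' is removed. Candidate fits that fail to converge are skipped and logged
#' in the trace.
#'
#' A covariate can lower AICc and be retained even when its Wald test is
#' marginally non-significant; selection is by information criterion, not
#' by p-value.
#'
#' @param records Known-fate bait records.
#' @param spec Full-model [model_spec()].
#' @param control Passed to [fit_binomial_glmm()].
#' @param tie_tol AICc tie tolerance (default 1e-6).
#' @return A list with `fit` (best `baitfate_glmm`), `spec` (its
#'   specification) and `trace`, a data frame with one row per candidate
#'   model evaluated: `step`, `dropped` (candidate covariate, `<none>` for
#'   the incumbent), `aicc`, `delta_aicc` (vs the step's incumbent),
#'   `converged`, `selected`.
#' @export
backward_stepwise <- function(records, spec = model_spec(),
                              control = list(), tie_tol = 1e-6) {
  current_spec <- spec
  current <- fit_binomial_glmm(records, current_spec, control)
  trace <- data.frame(step = 1L, dropped = "<none>", aicc = current$aicc,
                      delta_aicc = 0, converged = current$converged,
                      selected = FALSE, stringsAsFactors = FALSE)
  step <- 1L
  repeat {
    cands <- current_spec$covariates
    if (length(cands) == 0) break
    fits <- vector("list", length(cands))
    for (i in seq_along(cands)) {
      cand_spec <- current_spec
      cand_spec$covariates <- setdiff(cands, cands[i])
      fit <- tryCatch(fit_binomial_glmm(records, cand_spec, control),
                      error = function(e) NULL)
      ok <- !is.null(fit) && isTRUE(fit$converged)
      trace <- rbind(trace, data.frame(
        step = step, dropped = cands[i],
        aicc = if (ok) fit$aicc else NA_real_,
        delta_aicc = if (ok) fit$aicc - current$aicc else NA_real_,
        converged = ok, selected = FALSE, stringsAsFactors = FALSE))
      if (ok) fits[[i]] <- fit
    }
    aiccs <- vapply(fits, function(f) if (is.null(f)) NA_real_ else f$aicc,
                    0)
    if (all(is.na(aiccs)) || min(aiccs, na.rm = TRUE) >= current$aicc) break
    best <- min(aiccs, na.rm = TRUE)
    tied <- which(!is.na(aiccs) & aiccs <= best + tie_tol)
    pick <- if (length(tied) > 1) {
      # larger Wald p of the candidate's own terms in the incumbent model
      pvals <- vapply(tied, function(i) {
        terms <- names(current$term_covariate)[
          current$term_covariate == cands[i] & !is.na(current$term_covariate)]
        max(current$p_values[terms], na.rm = TRUE)
      }, 0)
      tied[which.max(pvals)]
    } else {
      tied
    }
    current <- fits[[pick]]
    current_spec$covariates <- setdiff(cands, cands[pick])
    trace$selected[nrow(trace) - length(cands) + pick] <- TRUE
    step <- step + 1L
    trace <- rbind(trace, data.frame(
      step = step, dropped = "<none>", aicc = current$aicc, delta_aicc = 0,
      converged = current$converged, selected = FALSE,
      stringsAsFactors = FALSE))
  }
  list(fit = current, spec = current_spec, trace = trace)
}
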