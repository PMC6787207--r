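## Auxiliary classical tests: Pearson chi-square of equal proportions,
## ANOVA for consumption latency, Spearman rank correlation. Thin,
## validated wrappers over the standard stats routines, returning a
## uniform result structure.

#' @noRd
test_result <- function(statistic, df, p_value, n, method) {
  structure(list(statistic = statistic, df = df, p_value = p_value,
                 n = n, method = method),
            class = "baitfate_test")
}

#' @export
print.baitfate_test <- function(x, ...) {
  dfs <- paste(x$df, collapse = ", ")
  cat(sprintf("%s: statistic = %.4g, df = (%s), N = %d, p = %.4g\n",
              x$method, x$statistic, dfs, x$n, x$p_value))
  invisible(x)
}

#' Pearson chi-square test of equal proportions
#'
#' Two-tailed Pearson chi-square test on a contingency matrix of counts,
#' with expected counts from the row/column margins,
#' df = (rows-1)(cols-1), and the upper chi-square tail. Yates continuity
#' correction is off by default and only applies to 2x2 tables.
#'
#' @param counts Non-negative contingency matrix, at least 2x2.
#' @param continuity_correction Apply the Yates correction (2x2 only).
#' @return A `baitfate_test` with `statistic` (X^2), `df`, `p_value`, `n`.
#' @examples
#' pearson_chi_square(matrix(c(10, 5, 10, 15), 2))
#' @export
pearson_chi_square <- function(counts, continuity_correction = FALSE) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  if (nrow(counts) < 2 || ncol(counts) < 2) {
    stop("contingency table must be at least 2x2", call. = FALSE)
  }
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0)) {
    stop("zero row or column margin: expected counts undefined",
         call. = FALSE)
  }
  ht <- suppressWarnings(
    stats::chisq.test(counts, correct = continuity_correction))
  test_result(unname(ht$statistic), unname(ht$parameter),
              unname(ht$p.value), sum(counts),
              "Pearson chi-square test of equal proportions")
}

#' One- or two-way analysis of variance
#'
#' Classical fixed-effects ANOVA via the standard sequential
#' sums-of-squares decomposition, returning one test per factor. With a
#' single two-level factor the F statistic equals the squared two-sample
#' t statistic.
#'
#' @param values Numeric response (e.g. latency to consumption in hours).
#' @param ... One or two categorical gradings (factors or coercible).
#' @return A list of `baitfate_test` objects, one per factor, each with
#'   `df = c(factor df, residual df)`.
#' @examples
#' anova_test(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3))
#' @export
anova_test <- function(values, ...) {
  factors <- lapply(list(...), as.factor)  # declared-but-empty levels kept
  if (length(factors) < 1 || length(factors) > 2) {
    stop("supply one or two factors", call. = FALSE)
  }
  names(factors) <- paste0("f", seq_along(factors))
  for (f in factors) {
    if (nlevels(f) < 2) stop("each factor needs >= 2 levels", call. = FALSE)
    if (any(table(f) == 0)) stop("factor level with no observations",
                                 call. = FALSE)
  }
  dat <- data.frame(y = values, factors)
  fml <- stats::as.formula(paste("y ~", paste(names(factors), collapse = " + ")))
  at <- stats::anova(stats::lm(fml, data = dat))
  resid_df <- at[nrow(at), "Df"]
  if (resid_df < 1) stop("residual df must be >= 1", call. = FALSE)
  out <- lapply(seq_along(factors), function(i) {
    test_result(at[i, "F value"], c(at[i, "Df"], resid_df),
                at[i, "Pr(>F)"], length(values),
                sprintf("ANOVA (factor %d of %d)", i, length(factors)))
  })
  names(out) <- names(factors)
  out
}

#' Spearman rank correlation
#'
#' Pearson correlation of mid-ranks (average ranks for ties).
#'
#' @param x,y Equal-length numeric vectors, length >= 3.
#' @return The rank correlation in `[-1, 1]`.
#' @examples
#' spearman_rho(1:4, c(1, 3, 2, 4))  # 0.8
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length",
                                   call. = FALSE)
  if (length(x) < 3) stop("need at least 3 observations", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("rank correlation undefined for constant input", call. = FALSE)
  }
  stats::cor(x, y, method = "spearman")
}
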