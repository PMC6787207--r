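#' Z-score continuous covariates
#'
#' Centres and scales the named covariates to mean 0, sample sd 1, recording
#' the transform so fitted models can score new data on the original scale.
#'
#' @param records Bait-record data frame.
#' @param covariates Character vector of continuous covariate columns.
#' @return A list with `records` (transformed copy) and `scaling`, a data
#'   frame of per-covariate `mean` and `sd`.
#' @export
scale_covariates <- function(records, covariates) {
  mu <- s <- numeric(length(covariates))
  names(mu) <- names(s) <- covariates
  for (v in covariates) {
    x <- records[[v]]
    if (is.null(x)) stop("unknown covariate: ", v, call. = FALSE)
    s[v] <- stats::sd(x)
    if (is.na(s[v]) || s[v] == 0) {
      stop("zero-variance covariate cannot be scaled: ", v, call. = FALSE)
    }
    mu[v] <- mean(x)
    records[[v]] <- (x - mu[v]) / s[v]
  }
  list(records = records,
       scaling = data.frame(covariate = covariates, mean = mu, sd = s,
                            row.names = NULL))
}

#' Invert the z-scoring recorded by [scale_covariates()]
#' @param records Scaled records.
#' @param scaling The `scaling` data frame from [scale_covariates()].
#' @return Records on the original scale.
#' @export
unscale_covariates <- function(records, scaling) {
  for (i in seq_len(nrow(scaling))) {
    v <- scaling$covariate[i]
    records[[v]] <- records[[v]] * scaling$sd[i] + scaling$mean[i]
  }
  records
}

#' @noRd
apply_scaling <- function(records, scaling) {
  for (i in seq_len(nrow(scaling))) {
    v <- scaling$covariate[i]
    if (is.null(records[[v]])) stop("unknown covariate: ", v, call. = FALSE)
    records[[v]] <- (records[[v]] - scaling$mean[i]) / scaling$sd[i]
  }
  records
}

#' Screen continuous covariates for rank collinearity
#'
#' Iteratively removes covariates until no retained pair has an absolute
#' Spearman rank correlation above `threshold`. When a pair exceeds the
#' threshold, the member with the larger mean absolute rank correlation
#' against all other covariates is dropped; ties drop the covariate that
#' appears later in the declared order.
#'
#' @param records Bait-record data frame.
#' @param covariates Character vector (length >= 2) of continuous columns,
#'   in declared order.
#' @param threshold Absolute rank-correlation cutoff (default 0.5).
#' @return A list with `retained` (character vector) and `dropped` (data
#'   frame of `dropped`, `correlate`, `r_s`).
#' @export
collinearity_screen <- function(records, covariates, threshold = 0.5) {
  if (length(covariates) < 2) stop("need at least 2 covariates", call. = FALSE)
  keep <- covariates
  dropped <- data.frame(dropped = character(), correlate = character(),
                        r_s = numeric(), stringsAsFactors = FALSE)
  repeat {
    if (length(keep) < 2) break
    cm <- stats::cor(records[keep], method = "spearman")
    diag(cm) <- 0
    worst <- which(abs(cm) == max(abs(cm)), arr.ind = TRUE)[1, ]
    if (abs(cm[worst[1], worst[2]]) <= threshold) break
    pair <- keep[worst]
    score <- rowMeans(abs(cm))[match(pair, keep)]
    victim <- if (score[1] > score[2]) pair[1]
      else if (score[2] > score[1]) pair[2]
      else pair[which.max(match(pair, covariates))]
    dropped <- rbind(dropped, data.frame(
      dropped = victim, correlate = setdiff(pair, victim)[1],
      r_s = cm[worst[1], worst[2]], stringsAsFactors = FALSE))
    keep <- setdiff(keep, victim)
  }
  list(retained = keep, dropped = dropped)
}
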