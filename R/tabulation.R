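## Consumer and alligator size-class tabulations, stratum proportions,
## relative risks, and latency summaries for known-fate bait records.

CONSUMER_LEVELS <- c("turkey_vulture", "alligator", "amphiuma",
                     "black_vulture", "none", "other")
SIZE_LEVELS <- c("large", "medium", "small", "not_alligator", "not_eaten")

#' Keep only records whose fate could be identified
#'
#' Records whose outcome could not be determined from camera imagery are
#' excluded from every analysis; this drops them, preserving order.
#'
#' @param records Bait-record data frame.
#' @return The known-fate subset of `records`.
#' @export
filter_known_fates <- function(records) {
  records[which(records$fate_known %in% TRUE), , drop = FALSE]
}

#' @noRd
stratum_factor <- function(records, strata = c("island_type", "colony_type")) {
  strata <- match.arg(strata)
  if (strata == "island_type") {
    factor(records$island_type, levels = c("active", "inactive"))
  } else {
    factor(records$colony_type, levels = c("Ardea", "Egretta"))
  }
}

#' @noRd
new_crosstab <- function(counts) {
  totals <- colSums(counts)
  pct <- sweep(counts, 2, pmax(totals, 1), "/") * 100
  structure(list(row_labels = rownames(counts),
                 col_labels = colnames(counts),
                 counts = counts,
                 col_pct = round(pct, 2),
                 col_totals = totals),
            class = "baitfate_crosstab")
}

#' @export
print.baitfate_crosstab <- function(x, ...) {
  cat("Cross-tabulation of", sum(x$counts), "known-fate baits\n")
  m <- matrix("", nrow(x$counts), 2 * ncol(x$counts),
              dimnames = list(x$row_labels,
                              paste(rep(x$col_labels, each = 2),
                                    c("%", "N"))))
  for (j in seq_along(x$col_labels)) {
    m[, 2 * j - 1] <- sprintf("%.2f", x$col_pct[, j])
    m[, 2 * j] <- x$counts[, j]
  }
  print(m, quote = FALSE)
  invisible(x)
}

#' Consumer cross-tabulation by island or colony type
#'
#' Tallies the primary consumer of each known-fate bait within strata and
#' reports raw counts with column percentages (percent of the stratum
#' total). Rows are the six consumer categories (Turkey Vulture, alligator,
#' amphiuma, Black Vulture, not eaten, pooled other); columns are either
#' island types (active/inactive) or colony types (*Ardea*/*Egretta*).
#'
#' @param records Known-fate bait records ([filter_known_fates()]).
#' @param strata `"island_type"` or `"colony_type"`.
#' @return A `baitfate_crosstab` with `counts`, `col_pct` and totals.
#' @export
consumer_crosstab <- function(records,
                              strata = c("island_type", "colony_type")) {
  if (nrow(records) == 0) stop("no analyzable records", call. = FALSE)
  assert_known_fate(records)
  f <- stratum_factor(records, strata)
  cons <- factor(records$consumer, levels = CONSUMER_LEVELS)
  counts <- table(cons, f, dnn = NULL)
  counts <- counts[, !is.na(colnames(counts)), drop = FALSE]
  new_crosstab(unclass(counts))
}

#' Alligator size-class cross-tabulation
#'
#' As [consumer_crosstab()], but rows classify each bait by the size class
#' of the consuming alligator (large/medium/small), `not_alligator` for
#' baits eaten by any other consumer, or `not_eaten`.
#'
#' @inheritParams consumer_crosstab
#' @return A `baitfate_crosstab`.
#' @export
size_class_crosstab <- function(records,
                                strata = c("island_type", "colony_type")) {
  if (nrow(records) == 0) stop("no analyzable records", call. = FALSE)
  assert_known_fate(records)
  f <- stratum_factor(records, strata)
  cls <- ifelse(records$consumer == "none", "not_eaten",
                ifelse(records$consumer == "alligator",
                       records$alligator_size, "not_alligator"))
  cls <- factor(cls, levels = SIZE_LEVELS)
  counts <- table(cls, f, dnn = NULL)
  counts <- counts[, !is.na(colnames(counts)), drop = FALSE]
  new_crosstab(unclass(counts))
}

#' Proportion of baits with a given fate within a stratum
#'
#' @param records Known-fate bait records.
#' @param consumer A consumer category (e.g. `"alligator"`), or a predicate
#'   function on the records returning the event indicator.
#' @param stratum Optional predicate function on the records selecting the
#'   stratum (default: all records).
#' @return A list with `numerator`, `denominator`, `proportion`, and
#'   `percent` (nearest integer, the convention used in reporting).
#' @examples
#' recs <- read_bait_records(baitfate_example("consumer_table_fixture.csv"))
#' recs <- filter_known_fates(recs)
#' stratum_proportion(recs, "alligator",
#'                    function(r) r$island_type == "inactive")
#' @export
stratum_proportion <- function(records, consumer, stratum = NULL) {
  assert_known_fate(records)
  keep <- if (is.null(stratum)) rep(TRUE, nrow(records)) else stratum(records)
  den <- sum(keep)
  if (den == 0) stop("empty stratum: proportion undefined", call. = FALSE)
  event <- if (is.function(consumer)) consumer(records) else
    records$consumer == consumer
  num <- sum(event & keep)
  list(numerator = num, denominator = den, proportion = num / den,
       percent = round(100 * num / den))
}

#' Relative risk of a fate between two strata
#'
#' Ratio of the stratum-A proportion to the stratum-B proportion of baits
#' with the given fate.
#'
#' @inheritParams stratum_proportion
#' @param stratum_a,stratum_b Predicate functions selecting the two strata.
#' @return The relative risk (non-negative real).
#' @export
relative_risk <- function(records, consumer, stratum_a, stratum_b) {
  pa <- stratum_proportion(records, consumer, stratum_a)
  pb <- stratum_proportion(records, consumer, stratum_b)
  if (pb$proportion == 0) {
    stop("reference stratum proportion is zero: relative risk undefined",
         call. = FALSE)
  }
  pa$proportion / pb$proportion
}

#' Latency-to-consumption summary
#'
#' Mean, sd and count of hours from bait placement to consumption, over
#' consumed known-fate baits, optionally grouped (e.g. by island and day).
#'
#' @param records Known-fate bait records.
#' @param group_by Optional character vector of grouping columns.
#' @return A data frame with `mean_h`, `sd_h`, `n` (one row per group, or a
#'   single row when ungrouped). `sd_h` is `NA` for single-observation
#'   groups.
#' @export
latency_summary <- function(records, group_by = NULL) {
  assert_known_fate(records)
  eaten <- records[records$consumer != "none" & !is.na(records$latency_h), ,
                   drop = FALSE]
  if (nrow(eaten) == 0) stop("no consumed baits with latency", call. = FALSE)
  if (is.null(group_by)) {
    data.frame(mean_h = mean(eaten$latency_h),
               sd_h = if (nrow(eaten) > 1) stats::sd(eaten$latency_h) else NA_real_,
               n = nrow(eaten))
  } else {
    key <- interaction(eaten[group_by], drop = TRUE)
    out <- do.call(rbind, lapply(split(eaten$latency_h, key), function(x) {
      data.frame(mean_h = mean(x),
                 sd_h = if (length(x) > 1) stats::sd(x) else NA_real_,
                 n = length(x))
    }))
    out <- cbind(group = rownames(out), out)
    rownames(out) <- NULL
    out
  }
}

#' Read / write bait-record CSV files
#'
#' One row per deployed bait with the documented column set; missing
#' latency is encoded as an empty field.
#'
#' @param path File path.
#' @param records Bait-record data frame (for writing).
#' @return `read_bait_records()` returns the records data frame.
#' @export
read_bait_records <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  out$fate_known <- as.logical(out$fate_known)
  for (col in c("consumer", "alligator_size")) {
    if (!is.null(out[[col]])) out[[col]][out[[col]] == ""] <- NA_character_
  }
  out
}

#' @rdname read_bait_records
#' @export
write_bait_records <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE, na = "")
  invisible(path)
}
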