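# Consumer and size-class tabulations on the packaged record fixture and
# on constructed edge cases.

test_that("packaged fixture file matches its deterministic builder", {
  from_file <- read_bait_records(baitfate_example("consumer_table_fixture.csv"))
  built <- consumer_table_records()
  expect_equal(nrow(from_file), 202)
  expect_equal(from_file$consumer, built$consumer)
  expect_equal(from_file$fate_known, built$fate_known)
  expect_equal(from_file$dist_water_m, built$dist_water_m, tolerance = 1e-8)
})

test_that("known-fate filtering drops exactly the censored records", {
  recs <- read_bait_records(baitfate_example("consumer_table_fixture.csv"))
  known <- filter_known_fates(recs)
  expect_equal(nrow(recs), 202)
  expect_equal(nrow(known), 160)
  expect_true(all(known$fate_known))
  # identity on fully known input, empty on fully censored input
  expect_identical(filter_known_fates(known), known)
  cens <- recs; cens$fate_known <- FALSE
  expect_equal(nrow(filter_known_fates(cens)), 0)
})

test_that("consumer crosstab reproduces the published counts exactly", {
  known <- fixture_known()
  ct <- consumer_crosstab(known, "island_type")
  expect_equal(unname(ct$counts[, "active"]), c(61, 43, 5, 1, 23, 4))
  expect_equal(unname(ct$counts[, "inactive"]), c(14, 3, 0, 4, 1, 1))
  expect_equal(unname(ct$col_pct["turkey_vulture", "active"]), 44.53)
  cc <- consumer_crosstab(known, "colony_type")
  expect_equal(unname(cc$counts[, "Ardea"]), c(59, 26, 5, 1, 21, 4))
  expect_equal(unname(cc$counts[, "Egretta"]), c(2, 17, 0, 0, 2, 0))
  expect_equal(unname(cc$col_pct["alligator", "Egretta"]), 80.95)
  # column percentages sum to 100 within rounding
  for (tab in list(ct, cc)) {
    expect_true(all(abs(colSums(tab$col_pct) - 100) < 0.1))
  }
  # conservation: all counts account for every known-fate record
  expect_equal(sum(ct$counts), nrow(known))
  # stratum additivity: Ardea + Egretta = active for every consumer row
  expect_equal(unname(cc$counts[, "Ardea"] + cc$counts[, "Egretta"]),
               unname(ct$counts[, "active"]))
})

test_that("size-class crosstab reports the jointly consistent marginals", {
  known <- fixture_known()
  sz <- size_class_crosstab(known, "island_type")
  expect_equal(unname(sz$counts["large", "active"]), 28)
  expect_equal(unname(sz$col_pct["large", "active"]), 20.44)
  expect_equal(unname(sz$counts[, "inactive"]), c(2, 0, 1, 19, 1))
  szc <- size_class_crosstab(known, "colony_type")
  expect_equal(unname(szc$counts["large", "Egretta"]), 13)
  expect_equal(unname(szc$col_pct["large", "Egretta"]), 61.90)
  expect_equal(sum(sz$counts), nrow(known))
})

test_that("single-record and no-alligator tallies are degenerate but exact", {
  one <- make_minimal_records(1, seed = 2)
  ct <- consumer_crosstab(one, "island_type")
  expect_equal(unname(ct$counts[, "active"]), c(0, 0, 0, 0, 1, 0))
  expect_equal(unname(ct$col_pct["none", "active"]), 100)
  recs <- make_minimal_records(40, seed = 3)
  recs$consumer <- rep(c("turkey_vulture", "none"), 20)
  recs$island_type <- rep(c("active", "inactive"), each = 20)
  sz <- size_class_crosstab(recs, "island_type")
  expect_true(all(sz$counts[c("large", "medium", "small"), ] == 0))
  expect_error(consumer_crosstab(recs[0, ], "island_type"), "no analyzable")
})

test_that("stratum proportions carry exact numerator and denominator", {
  known <- fixture_known()
  p <- stratum_proportion(known, "alligator",
                          function(r) r$island_type == "inactive")
  expect_equal(p$numerator, 3)
  expect_equal(p$denominator, 23)
  expect_equal(p$proportion, 3 / 23)
  expect_equal(p$percent, 13)
  # certainty boundary
  sub <- known[known$consumer == "alligator", ]
  expect_equal(stratum_proportion(sub, "alligator")$proportion, 1.0)
  expect_error(stratum_proportion(known, "alligator",
                                  function(r) rep(FALSE, nrow(r))),
               "empty stratum")
})

test_that("relative risk behaves as a ratio of proportions", {
  known <- fixture_known()
  rr <- relative_risk(known, "alligator",
                      function(r) r$colony_type == "Egretta",
                      function(r) r$colony_type == "Ardea")
  expect_equal(rr, (17 / 21) / (26 / 116))
  expect_equal(round(rr, 1), 3.6)
  rr_inv <- relative_risk(known, "alligator",
                          function(r) r$colony_type == "Ardea",
                          function(r) r$colony_type == "Egretta")
  expect_equal(rr * rr_inv, 1.0)
  # identical strata give exactly 1; zero numerator gives 0
  expect_equal(relative_risk(known, "alligator",
                             function(r) r$island_type == "active",
                             function(r) r$island_type == "active"), 1.0)
  expect_equal(relative_risk(known, "amphiuma",
                             function(r) r$island_type == "inactive",
                             function(r) r$island_type == "active"), 0.0)
  expect_error(relative_risk(known, "amphiuma",
                             function(r) r$island_type == "active",
                             function(r) r$island_type == "inactive"),
               "undefined")
})

test_that("latency summaries are exact means with grouping support", {
  recs <- make_minimal_records(2, seed = 4)
  recs$consumer <- "turkey_vulture"
  recs$latency_h <- c(10, 40)
  s <- latency_summary(recs)
  expect_equal(s$mean_h, 25)
  expect_equal(s$n, 2)
  one <- recs[1, ]
  s1 <- latency_summary(one)
  expect_equal(s1$mean_h, 10)
  expect_true(is.na(s1$sd_h))
  none <- recs; none$consumer <- "none"; none$latency_h <- NA_real_
  expect_error(latency_summary(none), "no consumed")
  # grouped path
  recs4 <- make_minimal_records(4, seed = 5)
  recs4$consumer <- "alligator"
  recs4$alligator_size <- "large"
  recs4$latency_h <- c(1, 3, 10, 30)
  recs4$site_id <- c("A", "A", "B", "B")
  g <- latency_summary(recs4, group_by = "site_id")
  expect_equal(sort(g$mean_h), c(2, 20))
})

test_that("bait-record CSV round-trips preserve analysis content", {
  recs <- consumer_table_records()
  tmp <- tempfile(fileext = ".csv")
  write_bait_records(recs, tmp)
  back <- read_bait_records(tmp)
  expect_equal(back$consumer, recs$consumer)
  expect_equal(back$latency_h, recs$latency_h, tolerance = 1e-8)
  expect_identical(back$fate_known, recs$fate_known)
})

test_that("the verbatim printed size-class table is preserved as printed", {
  t2 <- size_class_table_printed()
  expect_equal(t2$count[t2$stratum == "Ardea" & t2$size_class == "Large"], 17)
  expect_equal(t2$pct[t2$stratum == "Egretta" & t2$size_class == "Large"],
               61.90)
  # its printed internal inconsistency is preserved, not repaired: the
  # Ardea column sums to more baits than the consumer table allots
  expect_equal(sum(t2$count[t2$stratum == "Ardea"]), 139)
})
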