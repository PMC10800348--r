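# Record ingestion, annual indicators and derived ratios.

test_that("ingest collapses duplicates and filters by region", {
  res <- ingest_records(ingest_fixture())
  expect_equal(nrow(res$records), 7)
  expect_equal(res$report$duplicates, 2)
  expect_equal(res$report$out_of_region, 1)
  expect_equal(res$report$bad_date, 0)
})

test_that("ingest of an empty table yields empty output and zero counters", {
  res <- ingest_records(ingest_fixture()[0, ])
  expect_equal(nrow(res$records), 0)
  expect_true(all(unlist(res$report) == 0))
})

test_that("non-flora notices are dropped but embargoes kept regardless of theme", {
  raw <- ingest_fixture()[1:8, ]
  raw$theme[1] <- "fauna"      # an infraction notice
  raw$theme[6] <- "fauna"      # an embargo
  res <- ingest_records(raw, filter_config(flora_only = TRUE))
  expect_false("R01" %in% res$records$record_id)
  expect_true("R06" %in% res$records$record_id)
  expect_equal(res$report$wrong_theme, 1)
  # with flora_only = FALSE the notice survives too
  res2 <- ingest_records(raw, filter_config(flora_only = FALSE))
  expect_true("R01" %in% res2$records$record_id)
})

test_that("ingest rejects unparseable dates and names missing columns", {
  raw <- ingest_fixture()[1:4, ]
  raw$date[2] <- "not-a-date"
  res <- ingest_records(raw)
  expect_equal(res$report$bad_date, 1)
  expect_equal(nrow(res$records), 3)
  expect_error(ingest_records(raw[, -3]), "date")
})

test_that("ingest is idempotent", {
  first <- ingest_records(ingest_fixture())
  second <- ingest_records(first$records)
  expect_equal(second$records[, names(first$records)], first$records)
  expect_equal(second$report$duplicates, 0)
  expect_equal(second$report$out_of_region, 0)
})

test_that("annual indicators count sanctions and ratios by year", {
  raw <- data.frame(
    record_id = sprintf("R%02d", 1:5),
    process_id = sprintf("P%02d", 1:5),
    date = c("2010-03-01", "2010-05-10", "2010-07-09", "2010-08-01",
             "2010-09-30"),
    state = "PA", theme = "flora",
    sanction_type = c(rep("infraction_notice", 3), "embargo", "embargo"),
    fine_value_brl = c(100, 300, 200, 0, 0),
    x = c(5, NA, NA, NA, NA), y = c(5, NA, NA, NA, NA),
    stringsAsFactors = FALSE)
  ind <- annual_indicators(ingest_records(raw)$records, window = c(2009, 2011))
  r10 <- ind[ind$year == 2010, ]
  expect_equal(r10$notices_count, 3)
  expect_equal(r10$embargoes_count, 2)
  expect_equal(r10$confiscations_count, 0)
  expect_equal(r10$fines_total_brl, 600)
  expect_equal(r10$fines_mean_brl, 200)
  expect_equal(r10$geolocated_share, 1 / 3)
  # empty year: zero counts, missing share
  r09 <- ind[ind$year == 2009, ]
  expect_equal(r09$notices_count, 0)
  expect_true(is.na(r09$geolocated_share))
  # invariant: total = mean x notices with nonzero fines
  expect_equal(r10$fines_total_brl, r10$fines_mean_brl * 3)
})

test_that("a 1-in-20 geolocated share is reported as 0.05", {
  raw <- data.frame(
    record_id = sprintf("R%02d", 1:20), process_id = sprintf("P%02d", 1:20),
    date = "2004-06-15", state = "AM", theme = "flora",
    sanction_type = "infraction_notice", fine_value_brl = 10,
    x = c(1, rep(NA, 19)), y = c(1, rep(NA, 19)), stringsAsFactors = FALSE)
  ind <- annual_indicators(ingest_records(raw)$records)
  expect_equal(ind$geolocated_share[1], 0.05)
})

test_that("percent change reproduces reported reductions and identities", {
  expect_equal(percent_change(27.8, 11.7), -57.91367, tolerance = 1e-6)
  expect_equal(report_percent(abs(percent_change(27.8, 11.7))), 58)
  expect_equal(percent_change(5, 5), 0)
  expect_equal(percent_change(4.6, 2.6), -43.47826, tolerance = 1e-6)
  expect_error(percent_change(0, 3), "zero")
  # antisymmetry identity: pc(a,b) = -pc(b,a) * b/a
  for (ab in list(c(2, 5), c(10, 3), c(1.5, 1.5), c(7, 0.2))) {
    expect_equal(percent_change(ab[1], ab[2]),
                 -percent_change(ab[2], ab[1]) * ab[2] / ab[1])
  }
})

test_that("period aggregation sums, means, and respects partitions", {
  ind <- annual_indicators(
    ingest_records(ingest_fixture())$records, window = c(2009, 2012))
  whole <- period_aggregate(ind, c(2009, 2012), "sum")
  part1 <- period_aggregate(ind, c(2009, 2010), "sum")
  part2 <- period_aggregate(ind, c(2011, 2012), "sum")
  for (col in c("notices_count", "embargoes_count", "fines_total_brl")) {
    expect_equal(whole[[col]], part1[[col]] + part2[[col]])
  }
  # single-year, either mode = that year unchanged
  one_sum <- period_aggregate(ind, 2010, "sum")
  one_mean <- period_aggregate(ind, 2010, "mean")
  expect_equal(one_sum$notices_count, one_mean$notices_count)
  expect_equal(one_sum$notices_count, ind$notices_count[ind$year == 2010])
  # mean of {2, 4, 6}
  toy <- data.frame(year = 1:3, notices_count = c(2, 4, 6))
  expect_equal(period_aggregate(toy, c(1, 3), "mean")$notices_count, 4)
  expect_error(period_aggregate(ind, c(2050, 2060)), "empty")
})

test_that("paid-fine ratio counts terminal paid stages per filing cohort", {
  pros <- data.frame(
    process_id = sprintf("P%03d", 1:100),
    filed_date = "2010-06-01",
    stage = c(rep("paid", 17), rep("filed", 60), rep("judged_first", 23)),
    stage_date = "2012-06-01", amount_paid_brl = 0,
    stringsAsFactors = FALSE)
  expect_equal(paid_fine_ratio(pros, c(2010, 2010)), 0.17)
  pros$stage[pros$stage == "paid"] <- "judged_first"
  expect_equal(paid_fine_ratio(pros, c(2010, 2010)), 0)
  expect_error(paid_fine_ratio(pros, c(1990, 1991)), "undefined")
})

test_that("embargo cross-referencing measures flora-notice overlap", {
  notices <- data.frame(
    record_id = sprintf("N%02d", 1:10), process_id = sprintf("P%02d", 1:10),
    sanction_type = "infraction_notice",
    theme = c(rep("flora", 8), "other", "other"), stringsAsFactors = FALSE)
  embargoes <- data.frame(
    record_id = sprintf("E%02d", 1:10), process_id = sprintf("P%02d", 1:10),
    sanction_type = "embargo", theme = "flora", stringsAsFactors = FALSE)
  expect_equal(cross_reference_embargoes(embargoes, notices), 0.8)
  embargoes$process_id <- sprintf("Q%02d", 1:10)
  expect_equal(cross_reference_embargoes(embargoes, notices), 0)
  notices2 <- notices; notices2$theme <- "flora"
  embargoes2 <- embargoes; embargoes2$process_id <- notices2$process_id
  expect_equal(cross_reference_embargoes(embargoes2, notices2), 1)
  expect_error(cross_reference_embargoes(embargoes[0, ], notices),
               "undefined")
})
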