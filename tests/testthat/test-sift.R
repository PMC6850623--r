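# helpers building a parsed 10-record table with two records failing each
# of relevance, validity and acceptability
mini_table <- function() {
  recs <- dplyr::bind_rows(
    lapply(1:4, function(i) template_record(
      record_id = sprintf("K%02d", i), effect_value = i)),
    template_record(record_id = "REL1", latin_name = "Lemna minor"),
    template_record(record_id = "REL2", latin_name = "Chironomidae"),
    template_record(record_id = "VAL1", statistic = "<LC50"),
    template_record(record_id = "VAL2", source = NA),
    template_record(record_id = "ACC1", duration = "12 h"),
    template_record(record_id = "ACC2", effect = "biomarker")
  )
  parse_records(as_record_table(recs))
}

test_that("filter_relevance keeps the four trophic levels at species/genus", {
  tax <- fixture_taxonomy()
  recs <- parse_records(as_record_table(dplyr::bind_rows(
    template_record(record_id = "A", latin_name = "Danio rerio"),
    template_record(record_id = "B", latin_name = "Lemna minor"),
    template_record(record_id = "C", latin_name = "Chironomidae"),
    template_record(record_id = "D", latin_name = "Chironomus sp."),
    template_record(record_id = "E", latin_name = "Nemo unknownii"),
    template_record(record_id = "F", latin_name = "Mixed plankton community")
  )))
  p <- filter_relevance(recs, tax)
  expect_setequal(p$kept$record_id, c("A", "D"))
  reasons <- setNames(p$removed$reason_code, p$removed$record_id)
  expect_equal(reasons[["B"]], "trophic_not_relevant")
  expect_equal(reasons[["C"]], "above_genus")
  expect_equal(reasons[["E"]], "unresolved_taxon")
  expect_equal(reasons[["F"]], "mixed_community")
  expect_equal(p$kept$trophic_level, c("fish", "invertebrate"))
})

test_that("filter_validity removes qualifiers and missing fields", {
  recs <- parse_records(as_record_table(dplyr::bind_rows(
    template_record(record_id = "OK"),
    template_record(record_id = "Q", statistic = "<LC50"),
    template_record(record_id = "SRC", source = NA),
    template_record(record_id = "CAS", cas = NA),
    template_record(record_id = "UNIT", unit = "furlongs"),
    template_record(record_id = "DUR", duration = "overnight"),
    template_record(record_id = "STAT", statistic = "TLm")
  )))
  p <- filter_validity(recs)
  expect_equal(p$kept$record_id, "OK")
  reasons <- setNames(p$removed$reason_code, p$removed$record_id)
  expect_equal(reasons[["Q"]], "qualifier")
  expect_equal(reasons[["SRC"]], "missing_field")
  expect_equal(reasons[["CAS"]], "missing_cas")
  expect_equal(reasons[["UNIT"]], "unit_conversion")
  expect_equal(reasons[["DUR"]], "duration_conversion")
  expect_equal(reasons[["STAT"]], "statistic_unparsed")
})

test_that("filter_acceptability applies inclusive boundaries", {
  recs <- parse_records(as_record_table(dplyr::bind_rows(
    template_record(record_id = "IN", duration = "96 h"),
    template_record(record_id = "D24", duration = "24 h",
                    statistic = "EC5", effect = "growth"),
    template_record(record_id = "D23", duration = "23.5 h",
                    statistic = "EC5", effect = "growth"),
    template_record(record_id = "E70", statistic = "EC70",
                    effect = "growth"),
    template_record(record_id = "E71", statistic = "EC71",
                    effect = "growth"),
    template_record(record_id = "WL", effect = "biomarker")
  )))
  p <- filter_acceptability(recs)
  expect_setequal(p$kept$record_id, c("IN", "D24", "E70"))
  reasons <- setNames(p$removed$reason_code, p$removed$record_id)
  expect_equal(reasons[["D23"]], "duration")
  expect_equal(reasons[["E71"]], "statistic_window")
  expect_equal(reasons[["WL"]], "effect_not_whitelisted")
})

test_that("each filter partitions its input and is idempotent", {
  tax <- fixture_taxonomy()
  recs <- mini_table()
  filters <- list(
    relevance = function(x) filter_relevance(x, tax),
    validity = filter_validity,
    acceptability = filter_acceptability
  )
  for (nm in names(filters)) {
    p <- filters[[nm]](recs)
    expect_equal(nrow(p$kept) + nrow(p$removed), nrow(recs), label = nm)
    expect_length(intersect(p$kept$record_id, p$removed$record_id), 0)
    # idempotence: re-filtering the kept set removes nothing
    p2 <- filters[[nm]](p$kept)
    expect_equal(p2$kept$record_id, p$kept$record_id, label = nm)
    expect_equal(nrow(p2$removed), 0, label = nm)
  }
})

test_that("per-record decisions are order-independent", {
  tax <- fixture_taxonomy()
  recs <- mini_table()
  base <- run_sift(recs, tax)
  for (s in 1:5) {
    set.seed(s)
    perm <- recs[sample.int(nrow(recs)), , drop = FALSE]
    res <- run_sift(perm, tax)
    expect_setequal(res$curated$record_id, base$curated$record_id)
    expect_equal(
      dplyr::arrange(res$report$removals, record_id),
      dplyr::arrange(base$report$removals, record_id))
  }
})

test_that("run_sift chains steps with consistent counts", {
  tax <- fixture_taxonomy()
  recs <- mini_table()
  res <- run_sift(recs, tax)
  expect_equal(res$report$step_counts$n_in, c(10, 8, 6))
  expect_equal(res$report$step_counts$n_kept, c(8, 6, 4))
  expect_setequal(res$curated$record_id, sprintf("K%02d", 1:4))

  # monotonicity: adding a record never evicts a previously kept one
  bigger <- dplyr::bind_rows(recs, parse_records(as_record_table(
    template_record(record_id = "NEW"))))
  res2 <- run_sift(bigger, tax)
  expect_true(all(res$curated$record_id %in% res2$curated$record_id))

  # empty input
  res0 <- run_sift(recs[0, ], tax)
  expect_equal(nrow(res0$curated), 0)
  expect_equal(res0$report$step_counts$n_in, c(0, 0, 0))
})
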