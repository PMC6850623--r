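test_that("read_records reads canonical columns and preserves raw fields", {
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(tibble::tibble(
    cas = c("108952", "108883", "91203"),
    chemical_name = c("phenol", "toluene", "naphthalene"),
    smiles = NA_character_,
    latin_name = "Danio rerio",
    effect_value = c("1.2", "3.4", "5.6"),
    unit = "mg/L", duration = "96 h", test_type = "static",
    statistic = "LC50", effect = "mortality", source = "S1"
  ), path)
  rec <- read_records(path)
  expect_equal(nrow(rec), 3)
  expect_equal(rec$effect_value_raw, c(1.2, 3.4, 5.6))
  expect_equal(rec$unit_raw, rep("mg/L", 3))
  expect_true(all(is.na(rec$smiles)))
  expect_equal(anyDuplicated(rec$record_id), 0)
  expect_equal(nrow(attr(rec, "row_errors")), 0)
})

test_that("read_records enforces mandatory columns and collects row errors", {
  path <- withr::local_tempfile(fileext = ".csv")
  df <- tibble::tibble(
    cas = "1", chemical_name = "x", effect_value = "1", unit = "mg/L",
    duration = "96 h", test_type = "static", statistic = "LC50",
    effect = "mortality", source = "S1")
  readr::write_csv(df, path)  # no latin_name column
  expect_error(read_records(path), class = "toxsift_schema_error",
               regexp = "latin_name")

  df$latin_name <- "Danio rerio"
  df <- df[, c(1:2, 10, 3:9)]
  df3 <- dplyr::bind_rows(df, df, df)
  df3$effect_value[2] <- "abc"
  readr::write_csv(df3, path)
  rec <- read_records(path)
  expect_equal(nrow(rec), 2)
  errs <- attr(rec, "row_errors")
  expect_equal(nrow(errs), 1)
  expect_match(errs$message, "abc")
})

test_that("read_records maps file columns through a dialect", {
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(tibble::tibble(
    CASNumber = "108952", Name = "phenol", Species = "Danio rerio",
    Value = "2", Units = "mg/L", Dur = "4 d", TType = "static",
    Stat = "LC50", Endpoint = "mortality", Ref = "S1"), path)
  rec <- read_records(path, dialect = list(
    cas = "CASNumber", chemical_name = "Name", latin_name = "Species",
    effect_value = "Value", unit = "Units", duration = "Dur",
    test_type = "TType", statistic = "Stat", effect = "Endpoint",
    source = "Ref"))
  expect_equal(rec$cas, "108952")
  expect_equal(rec$duration_raw, "4 d")
})

test_that("parse_statistic normalizes kind, percent and qualifier", {
  expect_equal(parse_statistic("LC50"),
               tibble::tibble(kind = "LC", percent = 50L, qualifier = "none"))
  noec <- parse_statistic("NOEC")
  expect_equal(noec$kind, "NOEC")
  expect_true(is.na(noec$percent))
  gt <- parse_statistic(">EC50")
  expect_equal(gt$kind, "EC")
  expect_equal(gt$percent, 50L)
  expect_equal(gt$qualifier, "greater_than")
  # case-insensitive, whitespace-tolerant
  expect_equal(parse_statistic(" ic10 ")$kind, "IC")
  expect_equal(parse_statistic("<loec")$qualifier, "less_than")
})

test_that("parse_statistic rejects malformed tokens", {
  expect_error(parse_statistic("XY50"), class = "toxsift_parse_error")
  # percent required for EC/IC/LC and forbidden for NOEC/LOEC/MATC
  expect_error(parse_statistic("EC"), class = "toxsift_parse_error")
  expect_error(parse_statistic("NOEC10"), class = "toxsift_parse_error")
  lenient <- parse_statistic(c("LC50", "garbage"), strict = FALSE)
  expect_equal(lenient$kind, c("LC", NA))
})

test_that("harmonize_units rescales mass and molar units to mg/L", {
  expect_equal(harmonize_units(100, "µg/L"), 0.1)
  expect_equal(harmonize_units(1, "mmol/L", molecular_weight = 100), 100)
  expect_equal(harmonize_units(1, "ppm"), 1)
  expect_equal(harmonize_units(2.5, "g/L"), 2500)
  expect_error(harmonize_units(2, "furlongs"),
               class = "toxsift_conversion_error")
  expect_error(harmonize_units(1, "mol/L"),
               class = "toxsift_conversion_error")
  expect_error(harmonize_units(-1, "mg/L"), class = "toxsift_domain_error")
})

test_that("harmonize_units is multiplicative in the value", {
  units <- c("mg/L", "ug/L", "ng/L", "ppm", "mmol/L", "g/L")
  for (u in units) {
    for (k in c(0.5, 2, 1000)) {
      expect_equal(harmonize_units(k * 3, u, molecular_weight = 78),
                   k * harmonize_units(3, u, molecular_weight = 78))
    }
  }
})

test_that("parse_duration handles hours, days, minutes and weeks", {
  expect_equal(parse_duration("96 h"), 96)
  expect_equal(parse_duration("4 d"), 96)
  expect_equal(parse_duration("30 min"), 0.5)
  expect_equal(parse_duration("2 wk"), 336)
  for (n in c(1, 2.5, 7, 21)) {
    expect_equal(parse_duration(paste(n, "d")),
                 24 * parse_duration(paste(n, "h")))
  }
  expect_error(parse_duration("96"), class = "toxsift_parse_error")
  expect_error(parse_duration("fortnight"), class = "toxsift_parse_error")
  expect_true(is.na(parse_duration("96", strict = FALSE)))
})

test_that("write_curated emits byte-stable, round-trippable output", {
  tax <- fixture_taxonomy()
  recs <- dplyr::bind_rows(lapply(1:7, function(i) {
    template_record(record_id = sprintf("R%05d", i),
                    effect_value = i * 1.1,
                    source = if (i <= 2) "dropme" else "S1")
  }))
  parsed <- parse_records(as_record_table(recs))
  parsed$effect <- ifelse(parsed$record_id %in% c("R00001", "R00002"),
                          "biomarker", parsed$effect)
  sift <- run_sift(parsed, tax)
  expect_equal(nrow(sift$curated), 5)
  expect_equal(nrow(sift$report$removals), 2)

  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_curated(sift$curated, sift$report, d1, config = list(a = 1))
  write_curated(sift$curated, sift$report, d2, config = list(a = 1))
  for (f in c("curated.csv", "removals.csv", "summary.json")) {
    expect_identical(readBin(file.path(d1, f), "raw", 1e6),
                     readBin(file.path(d2, f), "raw", 1e6), label = f)
  }
  removals <- readr::read_csv(file.path(d1, "removals.csv"),
                              show_col_types = FALSE)
  expect_equal(nrow(removals), 2)
  expect_true(all(c("record_id", "step_name", "reason_code", "cas",
                    "source") %in% names(removals)))

  # round trip: reading the curated file reproduces the raw fields
  back <- read_records(file.path(d1, "curated.csv"), dialect = list(
    effect_value = "effect_value_raw", unit = "unit_raw",
    duration = "duration_raw", statistic = "statistic_raw"))
  ord <- order(sift$curated$record_id)
  expect_equal(back$cas, sift$curated$cas[ord])
  expect_equal(back$effect_value_raw, sift$curated$effect_value_raw[ord])
  expect_equal(back$latin_name, sift$curated$latin_name[ord])
})

test_that("write_curated handles an empty table", {
  empty <- parse_records(as_record_table(template_record()[0, ]))
  d <- withr::local_tempdir()
  write_curated(empty, filter_report(), d)
  out <- readr::read_csv(file.path(d, "curated.csv"), show_col_types = FALSE)
  expect_equal(nrow(out), 0)
})
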