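test_that("shipped default tables load with rules for both designations", {
  rules <- default_rule_table()
  fish <- rules[rules$trophic_level == "fish", ]
  expect_gte(sum(fish$designation == "acute"), 2)
  expect_gte(sum(fish$designation == "chronic"), 2)
  for (tl in c("invertebrate", "algae", "amphibian")) {
    expect_true(any(rules$trophic_level == tl), label = tl)
  }
})

test_that("load_rules validates rows and tolerates an empty file", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines("trophic_level,statistic_kinds,designation", path)
  empty <- load_rules(path)
  expect_equal(nrow(empty), 0)

  readr::write_csv(tibble::tibble(
    trophic_level = "fish", statistic_kinds = "LC",
    designation = "semi-chronic"), path)
  expect_error(load_rules(path), class = "toxsift_config_error",
               regexp = "semi-chronic")

  readr::write_csv(tibble::tibble(
    trophic_level = "fish", statistic_kinds = "LC", designation = "acute",
    duration_min_hours = 96, duration_max_hours = 24), path)
  expect_error(load_rules(path), class = "toxsift_config_error")
})

make_rec <- function(kind, percent, effect, hours,
                     latin = "Danio rerio") {
  tibble::tibble(latin_name = latin, stat_kind = kind,
                 stat_percent = percent, effect = effect,
                 duration_hours = hours)
}

test_that("classify_test follows the fish decision table", {
  fish <- tibble::tibble(trophic_level = "fish")
  expect_equal(classify_test(make_rec("LC", 50L, "mortality", 96), fish),
               "acute")
  # 96 h is the inclusive acute boundary; just beyond it no acute rule fires
  expect_equal(classify_test(make_rec("LC", 50L, "mortality", 96.5), fish),
               "unassignable")
  expect_equal(classify_test(make_rec("NOEC", NA_integer_, "growth", 21 * 24),
                             fish), "chronic")
  expect_equal(classify_test(make_rec("EC", 10L, "reproduction", 21 * 24),
                             fish), "chronic")
  # chronic ECx window closes at 20
  expect_equal(classify_test(make_rec("EC", 50L, "reproduction", 21 * 24),
                             fish), "unassignable")
})

test_that("a long Daphnia biomarker NOEC never becomes chronic", {
  inv <- tibble::tibble(trophic_level = "invertebrate")
  rec <- make_rec("NOEC", NA_integer_, "biomarker", 17 * 24,
                  latin = "Daphnia magna")
  expect_equal(classify_test(rec, inv), "unassignable")
})

test_that("classification is total, deterministic and matches row-by-row evaluation", {
  rules <- default_rule_table()
  combos <- expand.grid(
    kind = c("LC", "EC", "NOEC", "MATC"),
    percent = c(10L, 50L, NA_integer_),
    effect = c("mortality", "growth", "reproduction", "biomarker"),
    hours = c(24, 96, 168, 504),
    trophic = c("fish", "invertebrate", "algae", "amphibian"),
    stringsAsFactors = FALSE)
  combos <- combos[!(combos$kind %in% c("NOEC", "MATC") & !is.na(combos$percent)) &
                     !(combos$kind %in% c("LC", "EC") & is.na(combos$percent)), ]
  # independent oracle: literal first-match scan of the rule rows
  oracle <- function(row) {
    for (i in seq_len(nrow(rules))) {
      r <- rules[i, ]
      if (r$trophic_level != row$trophic) next
      if (!row$kind %in% strsplit(r$statistic_kinds, "|", fixed = TRUE)[[1]]) next
      if (!is.na(r$percent_min) && (is.na(row$percent) || row$percent < r$percent_min)) next
      if (!is.na(r$percent_max) && (is.na(row$percent) || row$percent > r$percent_max)) next
      if (r$effect_tokens != "any" &&
          !row$effect %in% strsplit(r$effect_tokens, "|", fixed = TRUE)[[1]]) next
      if (!is.na(r$duration_min_hours) && row$hours < r$duration_min_hours) next
      if (!is.na(r$duration_max_hours) && row$hours > r$duration_max_hours) next
      return(r$designation)
    }
    "unassignable"
  }
  for (i in seq_len(nrow(combos))) {
    row <- combos[i, ]
    got <- classify_test(
      make_rec(row$kind, row$percent, row$effect, row$hours),
      tibble::tibble(trophic_level = row$trophic), rules)
    expect_equal(got, oracle(row),
                 label = paste(row$trophic, row$kind, row$percent,
                               row$effect, row$hours))
  }
})

test_that("assign_designations leaves no record unset", {
  fx <- generate_dataset(fixture_config(n_baseline = 50, n_duplicates = 0,
                                        n_rule_a = 0, n_rule_b = 0,
                                        n_rule_c = 0, n_sub24h = 0,
                                        n_qualifier = 0, n_whitelist = 0,
                                        n_salts = 0, n_dummy_metal = 0,
                                        n_solubility = 0), seed = 7)
  res <- curate(fx$records, fx$chemicals, fx$taxonomy, fx$synonyms)
  expect_false(any(res$curated$designation == "unset"))
  expect_true(all(res$curated$designation %in%
                    c("acute", "chronic", "unassignable")))
})
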