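# Acute/chronic designation via per-trophic-group decision tables.
# The logic is data, not code: each trophic level ships an ordered CSV rule
# table (statistic kinds, percent window, effect tokens, duration window,
# designation); the first matching row wins and anything unmatched is
# "unassignable". The shipped defaults encode standard regulatory
# conventions (e.g. fish acute: lethal/effective concentrations on
# mortality at <= 96 h; fish chronic: NOEC/LOEC/MATC or ECx with x <= 20 on
# growth/reproduction/hatchability at >= 7 d) and are meant to be replaced
# wholesale by tables transcribed from an authority's decision trees.

#' Load a decision-rule table
#'
#' Rule CSVs have columns `trophic_level`, `species_group` (regular
#' expression on the Latin name, or `any`), `statistic_kinds` (pipe-
#' separated), `percent_min`/`percent_max` (optional window on ECx/ICx/LCx),
#' `effect_tokens` (pipe-separated or `any`), `duration_min_hours`/
#' `duration_max_hours` (blank = unbounded) and `designation`
#' (acute/chronic). Row order is the evaluation order.
#'
#' @param path CSV file of rules.
#' @return Tibble of class `rule_table`, declared order preserved.
#' @export
load_rules <- function(path) {
  rules <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                           progress = FALSE)
  validate_rules(rules)
}

#' Validate a rule table
#' @param rules A data frame of decision rules.
#' @return The validated `rule_table` tibble.
#' @export
validate_rules <- function(rules) {
  rules <- as_tibble(rules)
  if (nrow(rules) == 0) {
    rules <- tibble(trophic_level = character(), species_group = character(),
                    statistic_kinds = character(), percent_min = numeric(),
                    percent_max = numeric(), effect_tokens = character(),
                    duration_min_hours = numeric(),
                    duration_max_hours = numeric(), designation = character())
    class(rules) <- c("rule_table", class(rules))
    return(rules)
  }
  need <- c("trophic_level", "statistic_kinds", "designation")
  miss <- setdiff(need, names(rules))
  if (length(miss) > 0) {
    abort(paste0("rule table missing column(s): ",
                 paste(miss, collapse = ", ")),
          class = "toxsift_config_error")
  }
  for (nm in c("species_group", "effect_tokens")) {
    if (!nm %in% names(rules)) rules[[nm]] <- "any"
    rules[[nm]][is.na(rules[[nm]])] <- "any"
  }
  for (nm in c("percent_min", "percent_max", "duration_min_hours",
               "duration_max_hours")) {
    if (!nm %in% names(rules)) rules[[nm]] <- NA_real_
    rules[[nm]] <- suppressWarnings(as.numeric(rules[[nm]]))
  }
  bad <- !rules$designation %in% c("acute", "chronic")
  if (any(bad)) {
    abort(paste0("rule row ", which(bad)[1], ": designation must be ",
                 "'acute' or 'chronic', got '", rules$designation[bad][1], "'"),
          class = "toxsift_config_error")
  }
  swapped <- !is.na(rules$duration_min_hours) &
    !is.na(rules$duration_max_hours) &
    rules$duration_min_hours > rules$duration_max_hours
  if (any(swapped)) {
    abort(paste0("rule row ", which(swapped)[1],
                 ": duration window bounds out of order"),
          class = "toxsift_config_error")
  }
  class(rules) <- unique(c("rule_table", class(rules)))
  rules
}

#' Load the shipped default rule tables for all trophic levels
#' @return A `rule_table` tibble covering fish, invertebrate, algae and
#'   amphibian groups.
#' @export
default_rule_table <- function() {
  dir <- system.file("extdata", "rules", package = "toxsift")
  files <- list.files(dir, pattern = "\\.csv$", full.names = TRUE)
  validate_rules(bind_rows(lapply(sort(files), function(f) {
    readr::read_csv(f, col_types = readr::cols(.default = "c"),
                    progress = FALSE)
  })))
}

# Does rule row i match the record? All conditions are conjunctive.
.rule_matches <- function(rule, trophic, latin_name, kind, percent, effect,
                          duration_hours) {
  if (rule$trophic_level != "any" && rule$trophic_level != trophic) {
    return(FALSE)
  }
  if (rule$species_group != "any" &&
      !grepl(rule$species_group, latin_name, ignore.case = TRUE)) {
    return(FALSE)
  }
  kinds <- strsplit(rule$statistic_kinds, "|", fixed = TRUE)[[1]]
  if (!kind %in% kinds) return(FALSE)
  if (!is.na(rule$percent_min) &&
      (is.na(percent) || percent < rule$percent_min)) return(FALSE)
  if (!is.na(rule$percent_max) &&
      (is.na(percent) || percent > rule$percent_max)) return(FALSE)
  if (rule$effect_tokens != "any") {
    tokens <- strsplit(rule$effect_tokens, "|", fixed = TRUE)[[1]]
    if (!effect %in% tokens) return(FALSE)
  }
  if (!is.na(rule$duration_min_hours) &&
      duration_hours < rule$duration_min_hours) return(FALSE)
  if (!is.na(rule$duration_max_hours) &&
      duration_hours > rule$duration_max_hours) return(FALSE)
  TRUE
}

#' Classify one test record as acute, chronic or unassignable
#'
#' Evaluates the rule table in declared order for the record's trophic
#' level; the first matching rule's designation wins and `"unassignable"`
#' is returned when nothing matches. Classification is total and
#' deterministic.
#'
#' @param record One-row record tibble with parsed statistic and duration.
#' @param taxon One-row taxon entry (supplies the trophic level).
#' @param rules A `rule_table` (default: shipped tables).
#' @return `"acute"`, `"chronic"` or `"unassignable"`.
#' @export
classify_test <- function(record, taxon, rules = default_rule_table()) {
  trophic <- taxon$trophic_level[1]
  for (i in seq_len(nrow(rules))) {
    if (.rule_matches(rules[i, ], trophic, record$latin_name[1],
                      record$stat_kind[1], record$stat_percent[1],
                      record$effect[1], record$duration_hours[1])) {
      return(rules$designation[i])
    }
  }
  "unassignable"
}

#' Designate every record in a curated table
#'
#' @param records Curated records tibble carrying `trophic_level`.
#' @param rules A `rule_table`.
#' @return The records with the `designation` column filled (never left
#'   `"unset"`).
#' @export
assign_designations <- function(records, rules = default_rule_table()) {
  records <- as_tibble(records)
  n <- nrow(records)
  if (n == 0) return(records)
  out <- character(n)
  for (i in seq_len(n)) {
    out[i] <- classify_test(records[i, ],
                            tibble(trophic_level = records$trophic_level[i]),
                            rules)
  }
  records$designation <- out
  records
}
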