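# SIFT Steps 1-3: relevance (trophic level + taxonomic resolution),
# validity (required fields, qualifiers, parseability) and acceptability
# (duration >= 24 h, statistic window, effect whitelist). Each filter
# partitions its input into kept and removed-with-reason; the first failing
# check determines the reason code and removed records are not re-examined
# by later steps.

# The effect tokens of regulatory significance used by the acceptability
# filter (abundance ... teratogenesis).
.default_effect_whitelist <- c(
  "abundance", "biomass", "cells", "chlorophyll", "emergence",
  "filtration rate", "gross primary productivity", "growth", "hatchability",
  "intoxication", "mortality", "nitrogen fixation", "population growth",
  "population reduction", "population change", "primary production",
  "regeneration", "reproduction", "shell deposition", "teratogenesis"
)

#' SIFT filter configuration
#'
#' All thresholds of the relevance/validity/acceptability filters, with the
#' standard defaults: four relevant trophic levels, a 24-h minimum duration
#' (inclusive), a 5-70% effect window (inclusive) for ECx/ICx/LCx
#' statistics, NOEC/LOEC/MATC always admissible, and the effect-token
#' whitelist.
#'
#' @param relevant_trophic_levels Character set of retained trophic levels.
#' @param min_duration_hours Minimum test duration in hours (inclusive).
#' @param effect_percent_window Inclusive integer interval for ECx/ICx/LCx.
#' @param allowed_statistics Statistic kinds admissible without a percent
#'   window.
#' @param effect_whitelist Endpoint tokens retained at acceptability.
#' @return A list of class `sift_config`.
#' @export
sift_config <- function(relevant_trophic_levels = c("fish", "amphibian",
                                                    "invertebrate", "algae"),
                        min_duration_hours = 24,
                        effect_percent_window = c(5L, 70L),
                        allowed_statistics = c("NOEC", "LOEC", "MATC"),
                        effect_whitelist = .default_effect_whitelist) {
  stopifnot(length(effect_percent_window) == 2,
            effect_percent_window[1] <= effect_percent_window[2],
            length(effect_whitelist) > 0,
            min_duration_hours >= 0)
  structure(list(
    relevant_trophic_levels = relevant_trophic_levels,
    min_duration_hours = min_duration_hours,
    effect_percent_window = as.integer(effect_percent_window),
    allowed_statistics = allowed_statistics,
    effect_whitelist = tolower(effect_whitelist)
  ), class = "sift_config")
}

#' Read a SIFT configuration from YAML
#' @param path YAML file with any subset of the [sift_config()] fields.
#' @return A `sift_config` list.
#' @export
read_sift_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(sift_config, vals[intersect(names(vals), names(formals(sift_config)))])
}

# ---- filter machinery -------------------------------------------------------

.partition <- function(records, reason) {
  removed_idx <- !is.na(reason)
  list(
    kept = records[!removed_idx, , drop = FALSE],
    removed = tibble(record_id = records$record_id[removed_idx],
                     reason_code = reason[removed_idx]),
    archive = records[removed_idx, , drop = FALSE]
  )
}

# first non-NA reason across ordered checks
.first_reason <- function(n, ...) {
  checks <- list(...)
  reason <- rep(NA_character_, n)
  for (nm in names(checks)) {
    hit <- checks[[nm]]
    hit[is.na(hit)] <- FALSE
    hit <- hit & is.na(reason)
    reason[hit] <- nm
  }
  reason
}

#' Relevance filter (SIFT Step 1)
#'
#' Keeps records whose taxon resolves in the taxonomy, has a relevant
#' trophic level (fish, amphibian, invertebrate, algae by default) and a
#' taxonomic resolution of species or genus. Adds `trophic_level` and
#' `habitat` columns to the kept records. Failures become removals with
#' reasons `unresolved_taxon`, `mixed_community`, `above_genus` or
#' `trophic_not_relevant`.
#'
#' @param records Parsed records tibble.
#' @param taxonomy Taxonomy tibble.
#' @param config A [sift_config()].
#' @param synonyms Optional synonym map.
#' @return List with `kept`, `removed` (record_id, reason_code), `archive`.
#' @export
filter_relevance <- function(records, taxonomy, config = sift_config(),
                             synonyms = NULL) {
  records <- as_tibble(records)
  idx <- .match_taxa(records$latin_name, taxonomy, synonyms)
  trophic <- taxonomy$trophic_level[idx]
  habitat <- taxonomy$habitat[idx]
  resolution <- taxonomy$resolution[idx]
  reason <- .first_reason(nrow(records),
    unresolved_taxon = is.na(idx),
    mixed_community = !is.na(resolution) & resolution == "mixed_community",
    above_genus = !is.na(resolution) & resolution == "above_genus",
    trophic_not_relevant = !is.na(trophic) &
      !trophic %in% config$relevant_trophic_levels
  )
  records$trophic_level <- trophic
  records$habitat <- habitat
  .partition(records, reason)
}

#' Validity filter (SIFT Step 2)
#'
#' Removes records with a missing CAS, any missing required field (effect
#' value, unit, duration, statistic, effect, source), an unparseable
#' statistic, a `<`/`>` qualifier on the effect value, or a failed
#' unit/duration conversion. Reason codes, in precedence order:
#' `missing_cas`, `missing_field`, `statistic_unparsed`, `qualifier`,
#' `unit_conversion`, `duration_conversion`.
#'
#' @inheritParams filter_relevance
#' @return List with `kept`, `removed`, `archive`.
#' @export
filter_validity <- function(records, config = sift_config()) {
  records <- as_tibble(records)
  blank <- function(x) is.na(x) | (is.character(x) & !nzchar(trimws(x)))
  missing_field <- blank(records$effect_value_raw) | blank(records$unit_raw) |
    blank(records$duration_raw) | blank(records$statistic_raw) |
    blank(records$effect) | blank(records$source)
  reason <- .first_reason(nrow(records),
    missing_cas = blank(records$cas),
    missing_field = missing_field,
    statistic_unparsed = is.na(records$stat_kind),
    qualifier = !is.na(records$stat_qualifier) &
      records$stat_qualifier != "none",
    unit_conversion = is.na(records$effect_value),
    duration_conversion = is.na(records$duration_hours)
  )
  .partition(records, reason)
}

#' Acceptability filter (SIFT Step 3)
#'
#' Keeps records with duration at least the configured minimum (24 h,
#' inclusive), a statistic that is NOEC/LOEC/MATC or an ECx/ICx/LCx with x
#' inside the inclusive 5-70% window, and an effect token on the whitelist.
#' Reason codes: `duration`, `statistic_window`, `effect_not_whitelisted`.
#'
#' @inheritParams filter_relevance
#' @return List with `kept`, `removed`, `archive`.
#' @export
filter_acceptability <- function(records, config = sift_config()) {
  records <- as_tibble(records)
  win <- config$effect_percent_window
  has_pct <- records$stat_kind %in% c("EC", "IC", "LC")
  stat_ok <- (records$stat_kind %in% config$allowed_statistics) |
    (has_pct & !is.na(records$stat_percent) &
       records$stat_percent >= win[1] & records$stat_percent <= win[2])
  reason <- .first_reason(nrow(records),
    duration = is.na(records$duration_hours) |
      records$duration_hours < config$min_duration_hours,
    statistic_window = !stat_ok,
    effect_not_whitelisted = !records$effect %in% config$effect_whitelist
  )
  .partition(records, reason)
}

#' Construct a filter report
#'
#' Accumulates per-step counts and removals across the pipeline. For every
#' step, `n_kept + n_removed == n_in`, and each removed record appears
#' exactly once per removing step.
#'
#' @param step_counts Tibble with columns `step`, `n_in`, `n_kept`,
#'   `n_removed`.
#' @param removals Tibble with columns `record_id`, `step_name`,
#'   `reason_code`.
#' @param archive Tibble of the removed records' original rows.
#' @return Object of class `filter_report`.
#' @export
filter_report <- function(step_counts = tibble(step = character(),
                                               n_in = integer(),
                                               n_kept = integer(),
                                               n_removed = integer()),
                          removals = tibble(record_id = character(),
                                            step_name = character(),
                                            reason_code = character()),
                          archive = tibble()) {
  stopifnot(all(step_counts$n_kept + step_counts$n_removed == step_counts$n_in))
  structure(list(step_counts = step_counts, removals = removals,
                 archive = archive),
            class = "filter_report")
}

#' @export
print.filter_report <- function(x, ...) {
  cat("SIFT filter report\n")
  print(as.data.frame(x$step_counts), row.names = FALSE)
  cat(nrow(x$removals), "removals archived\n")
  invisible(x)
}

.report_add_step <- function(report, step, part) {
  n_removed <- nrow(part$removed)
  n_kept <- nrow(part$kept)
  report$step_counts <- bind_rows(report$step_counts, tibble(
    step = step, n_in = n_kept + n_removed, n_kept = n_kept,
    n_removed = n_removed))
  if (n_removed > 0) {
    report$removals <- bind_rows(report$removals, tibble(
      record_id = part$removed$record_id, step_name = step,
      reason_code = part$removed$reason_code))
    report$archive <- bind_rows(report$archive, part$archive)
  }
  report
}

#' Run SIFT Steps 1-3
#'
#' Applies relevance, validity and acceptability in order and returns the
#' surviving records plus a [filter_report()] with per-step counts. A record
#' removed at one step is not re-examined by later steps, so each removal
#' carries the first failing reason. Chemical harmonization, duplicate and
#' outlier removal (Step 4) are applied by [curate()].
#'
#' @inheritParams filter_relevance
#' @return List with `curated` (kept records) and `report`.
#' @export
run_sift <- function(records, taxonomy, config = sift_config(),
                     synonyms = NULL) {
  report <- filter_report()
  p1 <- filter_relevance(records, taxonomy, config, synonyms)
  report <- .report_add_step(report, "relevance", p1)
  p2 <- filter_validity(p1$kept, config)
  report <- .report_add_step(report, "validity", p2)
  p3 <- filter_acceptability(p2$kept, config)
  report <- .report_add_step(report, "acceptability", p3)
  list(curated = p3$kept, report = report)
}
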