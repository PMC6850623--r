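# Duplicate removal and order-of-magnitude outlier rules.
#
# Outliers are judged against geometric means computed INCLUSIVE of the
# candidate record, on a single pre-removal snapshot:
#   rule A (species_3oom):      |log10 x - log10 GM(cas, species)| >= 3
#                               when the (cas, species) group has >= 3 records
#   rule B (trophic_4oom):      |log10 x - log10 GM(cas, trophic)| >= 4
#                               when the (cas, trophic) group has >= 3 records
#   rule C (rare_species_3oom): |log10 x - log10 GM(cas, trophic)| >= 3
#                               when the (cas, trophic) group has >= 30
#                               records and x's species has <= 2 records in
#                               that group
# All thresholds are inclusive and configurable; removal happens in one
# pass with no re-evaluation cascade.

#' Geometric mean of positive concentrations
#'
#' `10^(mean of log10 values)` — the aggregation unit for replicate tests
#' of a chemical-species pair.
#'
#' @param values Numeric vector, all positive.
#' @return The geometric mean.
#' @examples
#' geometric_mean(c(1, 10, 100))  # 10
#' @export
geometric_mean <- function(values) {
  if (length(values) == 0 || anyNA(values) || any(values <= 0)) {
    abort("geometric mean requires a non-empty vector of positive values",
          class = "toxsift_domain_error")
  }
  10^mean(log10(values))
}

# Key fields defining a full duplicate: citation, species, test duration,
# test statistic, measured effect, effect level (test_type and smiles are
# deliberately not part of the key).
.duplicate_key_fields <- c("cas", "latin_name", "duration_hours",
                           "stat_kind", "stat_percent", "stat_qualifier",
                           "effect", "effect_value", "source")

#' Find groups of exact duplicate records
#'
#' Records match when all key study identifiers agree exactly: chemical,
#' species, duration, statistic (kind/percent/qualifier), measured effect,
#' effect value and citation.
#'
#' @param records Parsed records tibble.
#' @param key_fields Character vector of grouping columns.
#' @return Tibble with columns `group` (integer id) and `record_id`;
#'   zero rows when no duplicates exist.
#' @export
find_duplicates <- function(records, key_fields = .duplicate_key_fields) {
  records <- as_tibble(records)
  miss <- setdiff(key_fields, names(records))
  if (length(miss) > 0) {
    abort(paste0("missing key field(s): ", paste(miss, collapse = ", ")),
          class = "toxsift_schema_error")
  }
  if (nrow(records) == 0) {
    return(tibble(group = integer(), record_id = character()))
  }
  key <- do.call(paste, c(lapply(key_fields, function(f) {
    v <- records[[f]]
    if (is.numeric(v)) sprintf("%.15g", v) else as.character(v)
  }), sep = "\r"))
  grp <- match(key, key)
  sizes <- table(grp)
  dup_heads <- as.integer(names(sizes)[sizes >= 2])
  idx <- which(grp %in% dup_heads)
  tibble(group = match(grp[idx], dup_heads), record_id = records$record_id[idx])
}

#' Drop duplicates, keeping one representative per group
#'
#' Within each duplicate group the representative is the first record under
#' the canonical sort (all key fields, then `record_id`); the rest are
#' removed with reason `duplicate`.
#'
#' @param records Parsed records tibble.
#' @param groups Output of [find_duplicates()].
#' @param key_fields Grouping columns used for the canonical sort.
#' @return List with `kept`, `removed` (record_id, reason_code), `archive`.
#' @export
drop_duplicates <- function(records, groups,
                            key_fields = .duplicate_key_fields) {
  records <- as_tibble(records)
  if (nrow(groups) == 0) {
    return(list(kept = records,
                removed = tibble(record_id = character(),
                                 reason_code = character()),
                archive = records[0, , drop = FALSE]))
  }
  sub <- records[match(groups$record_id, records$record_id), , drop = FALSE]
  ord <- do.call(order, c(list(groups$group),
                          lapply(key_fields, function(f) sub[[f]]),
                          list(sub$record_id), list(method = "radix")))
  first_of_group <- !duplicated(groups$group[ord])
  drop_ids <- groups$record_id[ord][!first_of_group]
  removed_idx <- records$record_id %in% drop_ids
  list(kept = records[!removed_idx, , drop = FALSE],
       removed = tibble(record_id = records$record_id[removed_idx],
                        reason_code = "duplicate"),
       archive = records[removed_idx, , drop = FALSE])
}

#' Outlier thresholds
#'
#' @param species_oom Log10 distance for rule A (default 3).
#' @param trophic_oom Log10 distance for rule B (default 4).
#' @param rare_oom Log10 distance for rule C (default 3).
#' @param species_min_n Minimum (cas, species) group size for rule A
#'   (default 3).
#' @param trophic_min_n Minimum (cas, trophic) group size for rule B
#'   (default 3).
#' @param rare_group_min_n Minimum (cas, trophic) group size for rule C
#'   (default 30).
#' @param rare_species_max_n Maximum records for a species to count as rare
#'   within its (cas, trophic) group (default 2).
#' @return List of thresholds.
#' @export
outlier_config <- function(species_oom = 3, trophic_oom = 4, rare_oom = 3,
                           species_min_n = 3, trophic_min_n = 3,
                           rare_group_min_n = 30, rare_species_max_n = 2) {
  list(species_oom = species_oom, trophic_oom = trophic_oom,
       rare_oom = rare_oom, species_min_n = species_min_n,
       trophic_min_n = trophic_min_n, rare_group_min_n = rare_group_min_n,
       rare_species_max_n = rare_species_max_n)
}

#' Detect order-of-magnitude outliers
#'
#' Evaluates the three rules simultaneously on the same snapshot, with
#' group geometric means computed inclusive of the candidate record, and
#' emits one flag row per (record, rule) hit.
#'
#' @param records Parsed records tibble with positive `effect_value` (mg/L)
#'   and `trophic_level` columns.
#' @param config An [outlier_config()].
#' @return Tibble with columns `record_id`, `rule` (`species_3oom`,
#'   `trophic_4oom`, `rare_species_3oom`), `group_key`, `group_geomean`,
#'   `log10_distance`.
#' @export
detect_outliers <- function(records, config = outlier_config()) {
  records <- as_tibble(records)
  empty <- tibble(record_id = character(), rule = character(),
                  group_key = character(), group_geomean = numeric(),
                  log10_distance = numeric())
  if (nrow(records) == 0) return(empty)
  stopifnot(all(records$effect_value > 0))
  lg <- log10(records$effect_value)

  sp_key <- paste(records$cas, records$latin_name, sep = "\r")
  tr_key <- paste(records$cas, records$trophic_level, sep = "\r")
  sp_mean <- ave(lg, sp_key, FUN = mean)
  sp_n <- ave(lg, sp_key, FUN = length)
  tr_mean <- ave(lg, tr_key, FUN = mean)
  tr_n <- ave(lg, tr_key, FUN = length)
  # species size within the (cas, trophic) group for the rare-species rule
  sp_in_tr_n <- ave(lg, paste(tr_key, records$latin_name, sep = "\r"),
                    FUN = length)

  dist_sp <- abs(lg - sp_mean)
  dist_tr <- abs(lg - tr_mean)

  flag_a <- sp_n >= config$species_min_n & dist_sp >= config$species_oom
  flag_b <- tr_n >= config$trophic_min_n & dist_tr >= config$trophic_oom
  flag_c <- tr_n >= config$rare_group_min_n &
    sp_in_tr_n <= config$rare_species_max_n & dist_tr >= config$rare_oom

  mk <- function(flag, rule, key, gmean, dist) {
    idx <- which(flag)
    tibble(record_id = records$record_id[idx], rule = rule,
           group_key = gsub("\r", "|", key[idx], fixed = TRUE),
           group_geomean = 10^gmean[idx], log10_distance = dist[idx])
  }
  bind_rows(
    mk(flag_a, "species_3oom", sp_key, sp_mean, dist_sp),
    mk(flag_b, "trophic_4oom", tr_key, tr_mean, dist_tr),
    mk(flag_c, "rare_species_3oom", tr_key, tr_mean, dist_tr)
  )
}

#' Remove flagged outliers in a single pass
#'
#' All flagged records are removed at once against the pre-removal
#' snapshot; there is no iterative re-evaluation. A record flagged by
#' several rules is removed once, with every triggering rule recorded in
#' its reason code (`outlier:<rule>[+<rule>...]`).
#'
#' @param records Parsed records tibble.
#' @param flags Output of [detect_outliers()] on these records.
#' @return List with `kept`, `removed` (record_id, reason_code), `archive`.
#' @export
remove_outliers <- function(records, flags) {
  records <- as_tibble(records)
  if (nrow(flags) == 0) {
    return(list(kept = records,
                removed = tibble(record_id = character(),
                                 reason_code = character()),
                archive = records[0, , drop = FALSE]))
  }
  reason <- flags %>%
    group_by(.data$record_id) %>%
    summarise(reason_code = paste0(
      "outlier:", paste(sort(unique(.data$rule)), collapse = "+")),
      .groups = "drop")
  removed_idx <- records$record_id %in% reason$record_id
  removed <- tibble(record_id = records$record_id[removed_idx])
  removed$reason_code <- reason$reason_code[match(removed$record_id,
                                                  reason$record_id)]
  list(kept = records[!removed_idx, , drop = FALSE],
       removed = removed,
       archive = records[removed_idx, , drop = FALSE])
}
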