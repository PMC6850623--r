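# End-to-end curation: SIFT Steps 1-3, then Step 4 harmonization
# (salt exclusion, dummy-metal grouping, category and solubility flags,
# acute/chronic designation, exact-duplicate removal, order-of-magnitude
# outlier removal). Step order within Step 4 is fixed: salts are excluded
# first, duplicates removed second, outliers detected last on a single
# snapshot — so duplicate copies never distort a geometric mean.

#' Coerce an input table to the internal record schema
#'
#' Accepts either the internal schema (with `*_raw` columns, e.g. from
#' [read_records()]) or the external input schema (`effect_value`, `unit`,
#' `duration`, `statistic`, e.g. a freshly generated fixture) and returns
#' the internal raw-column form. Generates `record_id`s when absent.
#'
#' @param records A data frame in either schema.
#' @return Tibble in the internal raw schema.
#' @export
as_record_table <- function(records) {
  out <- as_tibble(records)
  ren <- c(effect_value = "effect_value_raw", unit = "unit_raw",
           duration = "duration_raw", statistic = "statistic_raw")
  for (from in names(ren)) {
    to <- ren[[from]]
    if (!to %in% names(out) && from %in% names(out)) {
      names(out)[names(out) == from] <- to
    }
  }
  if (!"record_id" %in% names(out)) {
    out$record_id <- sprintf("R%05d", seq_len(nrow(out)))
  }
  if (!"smiles" %in% names(out)) out$smiles <- NA_character_
  out$effect_value_raw <- as.numeric(out$effect_value_raw)
  miss <- setdiff(setdiff(.canonical_columns, c("effect_value", "unit",
                                                "duration", "statistic")),
                  names(out))
  miss <- setdiff(miss, c("record_id", "smiles"))
  if (length(miss) > 0) {
    abort(paste0("missing record column(s): ", paste(miss, collapse = ", ")),
          class = "toxsift_schema_error")
  }
  out
}

#' Run the full curation pipeline
#'
#' Parses raw fields, applies the relevance/validity/acceptability filters,
#' excludes bare-ion salts, annotates dummy-metal CAS and category flags,
#' flags above-solubility effect values (flag only, never a removal),
#' assigns acute/chronic designations, removes exact duplicates and removes
#' order-of-magnitude outliers. Returns the curated table, a cumulative
#' [filter_report()], the outlier flags and the harmonized chemical table.
#'
#' @param records Raw records (either schema accepted by
#'   [as_record_table()]).
#' @param chemicals Chemical-properties table (see [read_chemicals()]).
#' @param taxonomy Taxonomy table (see [read_taxonomy()]).
#' @param synonyms Optional synonym map.
#' @param config A [sift_config()].
#' @param rules A `rule_table` for acute/chronic designation.
#' @param metal_rules A [metal_rule()].
#' @param outlier_cfg An [outlier_config()].
#' @param dummy_overrides Optional dummy-CAS override table.
#' @return List of class `curation_result`: `curated`, `report`,
#'   `outlier_flags`, `chemicals`.
#' @export
curate <- function(records, chemicals, taxonomy, synonyms = NULL,
                   config = sift_config(), rules = default_rule_table(),
                   metal_rules = metal_rule(),
                   outlier_cfg = outlier_config(),
                   dummy_overrides = NULL) {
  records <- as_record_table(records)
  chem <- harmonize_chemicals(chemicals, metal_rules, dummy_overrides)
  parsed <- parse_records(records, chem)

  sift <- run_sift(parsed, taxonomy, config, synonyms)
  report <- sift$report
  cur <- sift$curated

  # ---- Step 4a: salt exclusion ----------------------------------------
  excluded_cas <- chem$cas[chem$excluded_salt]
  is_salt <- cur$cas %in% excluded_cas
  part <- list(kept = cur[!is_salt, , drop = FALSE],
               removed = tibble(record_id = cur$record_id[is_salt],
                                reason_code = "excluded_salt"),
               archive = cur[is_salt, , drop = FALSE])
  report <- .report_add_step(report, "chemical", part)
  cur <- part$kept

  # annotations: dummy metal CAS (original CAS preserved), solubility flag
  idx <- match(cur$cas, chem$cas)
  cur$dummy_metal_cas <- chem$dummy_metal_cas[idx]
  cur$solubility_flag <- suppressWarnings(
    flag_solubility(cur$effect_value, chem$water_solubility[idx]))

  # ---- designation (annotation, not a filter) -------------------------
  cur <- assign_designations(cur, rules)

  # ---- Step 4b: exact duplicates --------------------------------------
  groups <- find_duplicates(cur)
  part <- drop_duplicates(cur, groups)
  report <- .report_add_step(report, "duplicates", part)
  cur <- part$kept

  # ---- Step 4c: outliers (single pass on one snapshot) ----------------
  flags <- detect_outliers(cur, outlier_cfg)
  part <- remove_outliers(cur, flags)
  report <- .report_add_step(report, "outliers", part)
  cur <- part$kept

  structure(list(curated = cur, report = report, outlier_flags = flags,
                 chemicals = chem),
            class = "curation_result")
}

#' @export
print.curation_result <- function(x, ...) {
  print(x$report)
  cat(nrow(x$curated), "curated records;",
      sum(x$curated$solubility_flag), "solubility-flagged\n")
  invisible(x)
}
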