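# Record schema, readers/writers, and parsers that bring units, durations and
# effect statistics into canonical form (concentrations in mg/L, durations in
# hours, statistics as kind/percent/qualifier).

# Canonical raw column names expected in an input table. `record_id` and
# `smiles` are optional on read (ids are generated, SMILES may arrive later
# via the chemical table join).
.canonical_columns <- c(
  "record_id", "cas", "chemical_name", "smiles", "latin_name",
  "effect_value", "unit", "duration", "test_type", "statistic",
  "effect", "source"
)
.mandatory_columns <- setdiff(.canonical_columns, c("record_id", "smiles"))

#' Read ecotoxicity test records from a CSV file
#'
#' Reads a flat table of toxicity test results into the canonical record
#' schema. Column names in the file are mapped to the canonical schema via
#' `dialect`, a named character vector or list `c(canonical = "file column")`;
#' unmapped canonical names are looked up verbatim. Raw fields are preserved
#' as read (`effect_value_raw`, `unit_raw`, `duration_raw`, `statistic_raw`);
#' missing cells become `NA`, never empty strings.
#'
#' Rows whose effect value is present but not numeric are dropped from the
#' returned table and collected into the `row_errors` attribute (a tibble
#' with columns `row`, `message`) rather than aborting the read.
#'
#' @param path Path to a UTF-8, comma-separated file with one header row.
#' @param dialect Optional named mapping from canonical column names
#'   (`cas`, `chemical_name`, `smiles`, `latin_name`, `effect_value`, `unit`,
#'   `duration`, `test_type`, `statistic`, `effect`, `source`, `record_id`)
#'   to the column names used in the file.
#' @return A tibble of raw records (one per readable data row) with attribute
#'   `row_errors`.
#' @export
read_records <- function(path, dialect = NULL) {
  if (!file.exists(path)) {
    abort(paste0("file not found: ", path), class = "toxsift_io_error")
  }
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         na = c("", "NA"), progress = FALSE)
  dialect <- as.list(dialect %||% list())
  col_for <- function(canon) {
    nm <- dialect[[canon]] %||% canon
    if (nm %in% names(raw)) nm else NA_character_
  }
  for (canon in .mandatory_columns) {
    if (is.na(col_for(canon))) {
      abort(paste0("missing mandatory column: ", canon),
            class = "toxsift_schema_error")
    }
  }
  get_col <- function(canon) {
    nm <- col_for(canon)
    if (is.na(nm)) rep(NA_character_, nrow(raw)) else raw[[nm]]
  }
  out <- tibble(
    record_id        = get_col("record_id"),
    cas              = get_col("cas"),
    chemical_name    = get_col("chemical_name"),
    smiles           = get_col("smiles"),
    latin_name       = get_col("latin_name"),
    effect_value_raw = get_col("effect_value"),
    unit_raw         = get_col("unit"),
    duration_raw     = get_col("duration"),
    test_type        = get_col("test_type"),
    statistic_raw    = get_col("statistic"),
    effect           = get_col("effect"),
    source           = get_col("source")
  )
  if (all(is.na(out$record_id))) {
    out$record_id <- sprintf("R%05d", seq_len(nrow(out)))
  }
  ev <- suppressWarnings(as.numeric(out$effect_value_raw))
  bad <- !is.na(out$effect_value_raw) & is.na(ev)
  row_errors <- tibble(
    row = which(bad),
    message = paste0("effect value not numeric: '",
                     out$effect_value_raw[bad], "'")
  )
  out$effect_value_raw <- ev
  out <- out[!bad, , drop = FALSE]
  attr(out, "row_errors") <- row_errors
  out
}

#' Parse a test-statistic token
#'
#' Normalizes strings such as `"LC50"`, `"noec"` or `">EC50"` into the
#' controlled statistic vocabulary: a kind (`EC`, `IC`, `LC`, `NOEC`, `LOEC`,
#' `MATC`), an effect percentage (present only for EC/IC/LC) and a qualifier
#' (`none`, `less_than`, `greater_than`) captured from a leading `<` or `>`.
#' Matching is case-insensitive and ignores surrounding whitespace.
#'
#' @param raw Character vector of statistic tokens.
#' @param strict If `TRUE` (default), an unrecognized token raises a parse
#'   error carrying the raw text; if `FALSE`, unrecognized tokens yield an
#'   `NA` kind so callers can route the record to a removal step.
#' @return A tibble with one row per input and columns `kind`, `percent`
#'   (integer or `NA`), `qualifier`.
#' @examples
#' parse_statistic("LC50")
#' parse_statistic(c("NOEC", ">EC50"))
#' @export
parse_statistic <- function(raw, strict = TRUE) {
  stopifnot(is.character(raw))
  s <- toupper(trimws(raw))
  m <- regmatches(s, regexec(
    "^([<>]?)\\s*(EC|IC|LC|NOEC|LOEC|MATC)\\s*([0-9]{1,3})?$", s))
  one <- function(i) {
    hit <- m[[i]]
    if (length(hit) == 0 || is.na(s[i]) || !nzchar(s[i])) {
      return(list(kind = NA_character_, percent = NA_integer_,
                  qualifier = NA_character_))
    }
    kind <- hit[3]
    pct <- if (nzchar(hit[4])) as.integer(hit[4]) else NA_integer_
    needs_pct <- kind %in% c("EC", "IC", "LC")
    ok <- (needs_pct && !is.na(pct) && pct >= 0 && pct <= 100) ||
      (!needs_pct && is.na(pct))
    if (!ok) {
      return(list(kind = NA_character_, percent = NA_integer_,
                  qualifier = NA_character_))
    }
    qual <- switch(hit[2], "<" = "less_than", ">" = "greater_than", "none")
    list(kind = kind, percent = pct, qualifier = qual)
  }
  parsed <- lapply(seq_along(s), one)
  out <- tibble(
    kind = vapply(parsed, `[[`, character(1), "kind"),
    percent = vapply(parsed, `[[`, integer(1), "percent"),
    qualifier = vapply(parsed, `[[`, character(1), "qualifier")
  )
  if (strict && anyNA(out$kind)) {
    bad <- raw[is.na(out$kind)][1]
    abort(paste0("unrecognized test statistic: '", bad, "'"),
          class = "toxsift_parse_error")
  }
  out
}

# Multipliers to mg/L for mass-per-volume units; ppm/ppb follow the dilute
# aqueous convention (1 ppm = 1 mg/L).
.mass_units <- c(
  "g/l" = 1e3, "mg/l" = 1, "ug/l" = 1e-3, "ng/l" = 1e-6, "pg/l" = 1e-9,
  "mg/ml" = 1e3, "ug/ml" = 1, "ng/ml" = 1e-3,
  "ppm" = 1, "ppb" = 1e-3
)
# Multipliers to mol/L for molar units (converted via molecular weight).
.molar_units <- c("mol/l" = 1, "mmol/l" = 1e-3, "umol/l" = 1e-6,
                  "nmol/l" = 1e-9)

.normalize_unit <- function(unit) {
  u <- tolower(trimws(unit))
  u <- gsub("µ|μ", "u", u)
  u <- gsub("\\s+", "", u)
  u <- gsub("litre|liter", "l", u)
  u <- sub("/dm3$", "/l", u)
  u <- sub("^um$", "umol/l", u)
  u <- sub("^(m?mol|umol|nmol|mol)$", "\\1/l", u)
  u
}

#' Convert an effect concentration to mg/L
#'
#' Mass-per-volume units are rescaled exactly; molar units are converted via
#' the molecular weight (g/mol); `ppm`/`ppb` are treated as mg/L and ug/L
#' under the dilute aqueous convention.
#'
#' @param value Positive numeric vector of concentrations.
#' @param unit_raw Character vector of unit strings (recycled against value).
#' @param molecular_weight Molecular weight in g/mol, required for molar
#'   units; may be `NA` otherwise.
#' @param strict If `TRUE` (default) unknown units or molar units without a
#'   molecular weight raise a conversion error; if `FALSE` they yield `NA`.
#' @return Numeric vector of concentrations in mg/L.
#' @examples
#' harmonize_units(100, "µg/L")       # 0.1
#' harmonize_units(1, "mmol/L", 100)       # 100
#' @export
harmonize_units <- function(value, unit_raw, molecular_weight = NA_real_,
                            strict = TRUE) {
  stopifnot(is.numeric(value))
  if (strict && any(!is.na(value) & value <= 0)) {
    abort("effect values must be positive", class = "toxsift_domain_error")
  }
  n <- max(length(value), length(unit_raw))
  value <- rep_len(value, n)
  unit <- rep_len(.normalize_unit(unit_raw), n)
  mw <- rep_len(as.numeric(molecular_weight), n)
  out <- rep(NA_real_, n)
  is_mass <- unit %in% names(.mass_units)
  out[is_mass] <- value[is_mass] * unname(.mass_units[unit[is_mass]])
  is_molar <- unit %in% names(.molar_units)
  has_mw <- is_molar & !is.na(mw)
  # mol/L * g/mol * 1000 mg/g = mg/L
  out[has_mw] <- value[has_mw] * unname(.molar_units[unit[has_mw]]) *
    mw[has_mw] * 1000
  if (strict) {
    unknown <- !is_mass & !is_molar & !is.na(unit)
    if (any(unknown)) {
      abort(paste0("unknown concentration unit: '", unit_raw[unknown][1], "'"),
            class = "toxsift_conversion_error")
    }
    if (any(is_molar & is.na(mw))) {
      abort("molar unit requires a molecular weight",
            class = "toxsift_conversion_error")
    }
  }
  out[value <= 0] <- NA_real_
  out
}

#' Parse a test duration into hours
#'
#' Recognizes hours (`h`, `hr`, `hrs`, `hour(s)`), days (`d`, `day(s)`;
#' multiplied by 24), minutes (`min`, `minute(s)`; divided by 60) and weeks
#' (`w`, `wk`, `week(s)`; multiplied by 168).
#'
#' @param raw Character vector such as `"96 h"`, `"4 d"`, `"30 min"`.
#' @param strict If `TRUE` (default) unitless or unrecognized strings raise a
#'   parse error; if `FALSE` they yield `NA`.
#' @return Numeric vector of durations in hours.
#' @export
parse_duration <- function(raw, strict = TRUE) {
  s <- tolower(trimws(as.character(raw)))
  m <- regmatches(s, regexec(
    "^([0-9]*\\.?[0-9]+)\\s*(h|hr|hrs|hour|hours|d|day|days|min|mins|minute|minutes|w|wk|wks|week|weeks)$",
    s))
  one <- function(hit) {
    if (length(hit) == 0) return(NA_real_)
    val <- as.numeric(hit[2])
    mult <- switch(hit[3],
      h = , hr = , hrs = , hour = , hours = 1,
      d = , day = , days = 24,
      min = , mins = , minute = , minutes = 1 / 60,
      w = , wk = , wks = , week = , weeks = 168)
    val * mult
  }
  out <- vapply(m, one, numeric(1))
  if (strict && anyNA(out[!is.na(s) & nzchar(s)])) {
    bad <- raw[is.na(out)][1]
    abort(paste0("unparseable duration: '", bad, "'"),
          class = "toxsift_parse_error")
  }
  out
}

#' Parse raw record fields into canonical form
#'
#' Adds the parsed/harmonized columns used by the filters: `duration_hours`,
#' `stat_kind`, `stat_percent`, `stat_qualifier`, `effect_value` (mg/L),
#' plus `effect` lower-cased and alias-mapped. Failed parses become `NA`
#' (the validity filter removes them with a reason code); ingestion never
#' crashes on a bad unit or duration.
#'
#' @param records Tibble from [read_records()].
#' @param chemicals Optional chemical-properties table (see
#'   [read_chemicals()]) supplying `molecular_weight` by `cas` for molar
#'   unit conversion, and `smiles` where the record lacks one.
#' @param effect_aliases Optional two-column tibble/data.frame
#'   (`alias`, `canonical`) applied to lower-cased effect tokens. Defaults to
#'   the table shipped in `inst/extdata/effect_aliases.csv`.
#' @return The records tibble with parsed columns appended and
#'   `designation = "unset"`, `solubility_flag = FALSE` initialized.
#' @export
parse_records <- function(records, chemicals = NULL, effect_aliases = NULL) {
  stopifnot(is.data.frame(records))
  out <- as_tibble(records)
  if (is.null(effect_aliases)) effect_aliases <- default_effect_aliases()
  mw <- rep(NA_real_, nrow(out))
  if (!is.null(chemicals) && nrow(out) > 0) {
    idx <- match(out$cas, chemicals$cas)
    mw <- chemicals$molecular_weight[idx]
    if ("smiles" %in% names(out)) {
      take <- is.na(out$smiles) & !is.na(idx)
      out$smiles[take] <- chemicals$smiles[idx[take]]
    }
  }
  st <- parse_statistic(out$statistic_raw %||% character(0), strict = FALSE)
  out$stat_kind <- st$kind
  out$stat_percent <- st$percent
  out$stat_qualifier <- st$qualifier
  out$duration_hours <- parse_duration(out$duration_raw, strict = FALSE)
  out$effect_value <- harmonize_units(out$effect_value_raw, out$unit_raw,
                                      mw, strict = FALSE)
  eff <- tolower(trimws(out$effect))
  hit <- match(eff, effect_aliases$alias)
  eff[!is.na(hit)] <- effect_aliases$canonical[hit[!is.na(hit)]]
  out$effect <- eff
  out$solubility_flag <- FALSE
  out$designation <- "unset"
  out
}

#' Default effect-token alias map
#'
#' Maps common spelling variants of measured-effect designations onto the
#' canonical whitelist tokens (heterogeneous sources report e.g. "growth"
#' under many labels). Shipped as an editable CSV in `inst/extdata`.
#'
#' @return Tibble with columns `alias`, `canonical`.
#' @export
default_effect_aliases <- function() {
  path <- system.file("extdata", "effect_aliases.csv", package = "toxsift")
  readr::read_csv(path, col_types = "cc", progress = FALSE)
}

#' Write curated outputs deterministically
#'
#' Writes three files into `out_dir`: `curated.csv` (the kept records, rows
#' sorted by `cas`, `latin_name`, `record_id`, floats at 10 significant
#' digits), `removals.csv` (one row per removed record: `record_id`,
#' `step_name`, `reason_code`, plus all original columns) and `summary.json`
#' (per-step counts and a configuration hash). Output is byte-stable: the
#' same inputs always produce byte-identical files.
#'
#' @param table Curated records tibble.
#' @param report A `filter_report` (see [filter_report()]) consistent with
#'   `table`.
#' @param out_dir Output directory, created if needed.
#' @param config Optional configuration list, hashed into the summary.
#' @return Invisibly, the paths written.
#' @export
write_curated <- function(table, report, out_dir, config = NULL) {
  stopifnot(inherits(report, "filter_report"))
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) abort(paste0("cannot create ", out_dir), class = "toxsift_io_error")
  }
  curated_path <- file.path(out_dir, "curated.csv")
  removals_path <- file.path(out_dir, "removals.csv")
  summary_path <- file.path(out_dir, "summary.json")

  tab <- as_tibble(table)
  ord <- order(tab$cas, tab$latin_name, tab$record_id, method = "radix")
  .write_stable_csv(tab[ord, , drop = FALSE], curated_path)

  rem <- report$removals
  arch <- report$archive %||% tibble()
  if (nrow(rem) > 0 && nrow(arch) > 0) {
    rem <- left_join(rem, arch, by = "record_id")
  }
  rem <- rem[order(rem$record_id, rem$step_name, method = "radix"), ,
             drop = FALSE]
  .write_stable_csv(rem, removals_path)

  summary <- list(
    step_counts = report$step_counts,
    config_hash = .fnv1a_hash(config)
  )
  jsonlite::write_json(summary, summary_path, auto_unbox = TRUE, digits = NA)
  invisible(c(curated_path, removals_path, summary_path))
}

# Fixed float formatting (10 significant digits) so repeated writes are
# byte-identical across platforms.
.write_stable_csv <- function(df, path) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  for (nm in names(df)) {
    if (is.numeric(df[[nm]]) && !is.integer(df[[nm]])) {
      v <- df[[nm]]
      s <- sprintf("%.10g", v)
      s[is.na(v)] <- NA_character_
      df[[nm]] <- s
    }
  }
  readr::write_csv(df, path, na = "", progress = FALSE)
}

# Polynomial rolling hash over the JSON serialization of a config list;
# a deterministic non-cryptographic fingerprint without extra dependencies.
.fnv1a_hash <- function(x) {
  bytes <- utf8ToInt(jsonlite::toJSON(x %||% list(), auto_unbox = TRUE,
                                      digits = NA, force = TRUE))
  h <- 0
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", h)
}
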