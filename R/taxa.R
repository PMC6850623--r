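# Taxonomic lookup: trophic level, lineage, habitat and the
# genus-resolution inclusion rule. The taxonomy is a curated input table —
# never a network lookup — with an optional two-column synonym map
# (old_name, current_name) applied before matching.

.trophic_levels <- c("algae", "invertebrate", "fish", "amphibian",
                     "macrophyte", "fungi")
.resolutions <- c("species", "genus", "above_genus", "mixed_community")

#' Read a taxonomy table
#'
#' Expected columns: `latin_name`, `trophic_level` (one of algae,
#' invertebrate, fish, amphibian, macrophyte, fungi), `habitat`
#' (freshwater/saltwater) and optionally the lineage columns (`kingdom`,
#' `phylum_or_division`, `subphylum`, `superclass`, `class`, `order`,
#' `family`) and `resolution` (species/genus/above_genus/mixed_community;
#' inferred from the name when absent).
#'
#' @param path CSV file path.
#' @return Tibble of taxon entries.
#' @export
read_taxonomy <- function(path) {
  tax <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  validate_taxonomy(tax)
}

#' Validate (and complete) a taxonomy tibble
#'
#' @param tax Tibble with at least `latin_name`, `trophic_level`, `habitat`.
#' @return The validated tibble with a `resolution` column.
#' @export
validate_taxonomy <- function(tax) {
  tax <- as_tibble(tax)
  need <- c("latin_name", "trophic_level", "habitat")
  miss <- setdiff(need, names(tax))
  if (length(miss) > 0) {
    abort(paste0("taxonomy missing column(s): ", paste(miss, collapse = ", ")),
          class = "toxsift_schema_error")
  }
  bad <- !tax$trophic_level %in% .trophic_levels
  if (any(bad)) {
    abort(paste0("unknown trophic level: ", tax$trophic_level[bad][1]),
          class = "toxsift_schema_error")
  }
  if (!"resolution" %in% names(tax)) tax$resolution <- NA_character_
  infer <- is.na(tax$resolution)
  tax$resolution[infer] <- vapply(tax$latin_name[infer], resolution_of,
                                  character(1))
  bad <- !tax$resolution %in% .resolutions
  if (any(bad)) {
    abort(paste0("unknown resolution: ", tax$resolution[bad][1]),
          class = "toxsift_schema_error")
  }
  tax
}

.normalize_name <- function(x) {
  x <- gsub("\\s+", " ", trimws(x))
  tolower(x)
}

#' Resolve a Latin name against the taxonomy
#'
#' Exact-match lookup after whitespace/case normalization, with the synonym
#' map (columns `old_name`, `current_name`) applied first so that historical
#' names resolve to the current entry.
#'
#' @param latin_name A single Latin name.
#' @param taxonomy Taxonomy tibble (see [read_taxonomy()]).
#' @param synonyms Optional tibble with columns `old_name`, `current_name`.
#' @return The matching one-row taxon tibble.
#' @export
resolve_taxon <- function(latin_name, taxonomy, synonyms = NULL) {
  idx <- .match_taxa(latin_name, taxonomy, synonyms)
  if (is.na(idx)) {
    abort(paste0("unresolved taxon: '", latin_name, "'"),
          class = "toxsift_unresolved_taxon")
  }
  taxonomy[idx, , drop = FALSE]
}

# Vectorized index lookup; NA where unresolved.
.match_taxa <- function(latin_names, taxonomy, synonyms = NULL) {
  key <- .normalize_name(latin_names)
  if (!is.null(synonyms) && nrow(synonyms) > 0) {
    hit <- match(key, .normalize_name(synonyms$old_name))
    key[!is.na(hit)] <- .normalize_name(synonyms$current_name[hit[!is.na(hit)]])
  }
  match(key, .normalize_name(taxonomy$latin_name))
}

#' Classify the taxonomic resolution of a name
#'
#' A binomial is `species`; a bare genus or "Genus sp." is `genus` (retained
#' by the relevance filter); names flagged in the taxonomy as family or
#' higher are `above_genus` (removed); multi-taxon descriptors (containing
#' "/", "," or " and ") are `mixed_community`. Classification is total:
#' every non-empty name receives a resolution.
#'
#' @param latin_name A single name.
#' @param taxonomy Optional taxonomy tibble whose explicit `resolution`
#'   column overrides the heuristic.
#' @return One of `"species"`, `"genus"`, `"above_genus"`,
#'   `"mixed_community"`.
#' @export
resolution_of <- function(latin_name, taxonomy = NULL) {
  stopifnot(length(latin_name) == 1, nzchar(trimws(latin_name)))
  if (!is.null(taxonomy)) {
    idx <- .match_taxa(latin_name, taxonomy)
    if (!is.na(idx) && "resolution" %in% names(taxonomy) &&
        !is.na(taxonomy$resolution[idx])) {
      return(taxonomy$resolution[idx])
    }
  }
  nm <- gsub("\\s+", " ", trimws(latin_name))
  if (grepl("/|,| and | & ", nm, ignore.case = TRUE)) return("mixed_community")
  tokens <- strsplit(nm, " ", fixed = TRUE)[[1]]
  if (length(tokens) >= 2 && tolower(tokens[2]) %in% c("sp.", "sp", "spp.", "spp")) {
    return("genus")
  }
  if (length(tokens) == 1) return("genus")
  "species"
}
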