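# Chemical harmonization: SMILES desalting/canonicalization (Open Babel
# backend via ChemmineOB), exclusion of bare hydroxide/chloride/ammonium/
# amino ions, dummy-metal-ion grouping for dissociable metal salts,
# halogen/heavy-metal category flags and the 5x water-solubility flag.

# Heavy metals: metallic elements with density > 5 g/cm3 (configurable).
.heavy_metals <- c(
  "Cr", "Mn", "Fe", "Co", "Ni", "Cu", "Zn", "Ga", "Ge", "As", "Se", "Y",
  "Zr", "Nb", "Mo", "Tc", "Ru", "Rh", "Pd", "Ag", "Cd", "In", "Sn", "Sb",
  "Te", "La", "Ce", "Pr", "Nd", "Sm", "Eu", "Gd", "Tb", "Dy", "Ho", "Er",
  "Tm", "Yb", "Lu", "Hf", "Ta", "W", "Re", "Os", "Ir", "Pt", "Au", "Hg",
  "Tl", "Pb", "Bi", "Po", "Th", "U", "V"
)
# All metallic elements relevant to the multi-metal exclusion.
.all_metals <- c(.heavy_metals, "Li", "Na", "K", "Rb", "Cs", "Be", "Mg",
                 "Ca", "Sr", "Ba", "Al", "Sc", "Ti")

# Tokenize element symbols out of a SMILES string. Handles bracket atoms
# ([Na+], [13CH4], [nH]) and the organic subset (B, C, N, O, P, S, F, Cl,
# Br, I plus aromatic b, c, n, o, p, s).
.smiles_elements <- function(smiles) {
  if (is.na(smiles) || !nzchar(smiles)) return(character(0))
  out <- character(0)
  i <- 1L
  chars <- strsplit(smiles, "", fixed = TRUE)[[1]]
  n <- length(chars)
  while (i <= n) {
    ch <- chars[i]
    if (ch == "[") {
      j <- i
      while (j <= n && chars[j] != "]") j <- j + 1L
      body <- paste(chars[(i + 1):(j - 1)], collapse = "")
      body <- sub("^[0-9]+", "", body)          # isotope
      m <- regmatches(body, regexpr("^([A-Z][a-z]?|[a-z])", body))
      if (length(m) == 1) {
        el <- m
        substr(el, 1, 1) <- toupper(substr(el, 1, 1))
        out <- c(out, el)
      }
      i <- j + 1L
    } else if (ch %in% c("C", "B") && i < n && chars[i + 1] %in% c("l", "r") &&
               paste0(ch, chars[i + 1]) %in% c("Cl", "Br")) {
      out <- c(out, paste0(ch, chars[i + 1]))
      i <- i + 2L
    } else if (ch %in% c("B", "C", "N", "O", "P", "S", "F", "I")) {
      out <- c(out, ch)
      i <- i + 1L
    } else if (ch %in% c("b", "c", "n", "o", "p", "s")) {
      out <- c(out, toupper(ch))
      i <- i + 1L
    } else {
      i <- i + 1L
    }
  }
  out
}

# Heavy (non-hydrogen) atom count of a SMILES fragment.
.heavy_atom_count <- function(smiles) length(.smiles_elements(smiles))

# Total atom count including explicit/implicit bracket hydrogens, used only
# as a desalting tie-break so that [OH-] outranks a bare metal cation.
.total_atom_count <- function(smiles) {
  h <- 0L
  for (m in regmatches(smiles, gregexpr("\\[[^]]*\\]", smiles))[[1]]) {
    hm <- regmatches(m, regexpr("H[0-9]*", m))
    if (length(hm) == 1) {
      cnt <- sub("^H", "", hm)
      h <- h + if (nzchar(cnt)) as.integer(cnt) else 1L
    }
  }
  .heavy_atom_count(smiles) + h
}

# Canonicalize one SMILES via the Open Babel backend; "" on parse failure
# (Open Babel reports parse problems on stderr and returns an empty string).
.ob_canonical <- function(smiles) {
  res <- tryCatch(ChemmineOB::convertFormat("SMI", "CAN", smiles),
                  error = function(e) "")
  sub("[\t\n ]+$", "", res)
}

#' Desalt and canonicalize a SMILES string
#'
#' Splits the structure into fragments at "." separators, keeps the largest
#' organic fragment (preferring carbon-containing fragments, then most heavy
#' atoms, then most total atoms, with a lexicographic tie-break for full
#' determinism) and returns its canonical SMILES from the Open Babel
#' backend. Idempotent: desalting a desalted structure is a no-op.
#'
#' @param smiles A single SMILES string.
#' @return Canonical SMILES of the retained fragment.
#' @examples
#' \dontrun{
#' desalt_canonicalize("CC(=O)[O-].[Na+]")  # acetate fragment
#' }
#' @export
desalt_canonicalize <- function(smiles) {
  stopifnot(length(smiles) == 1)
  if (is.na(smiles) || !nzchar(trimws(smiles))) {
    abort("empty SMILES", class = "toxsift_structure_error")
  }
  can_full <- .ob_canonical(smiles)
  if (!nzchar(can_full)) {
    abort(paste0("invalid SMILES: '", smiles, "'"),
          class = "toxsift_structure_error")
  }
  frags <- strsplit(can_full, ".", fixed = TRUE)[[1]]
  if (length(frags) == 1) return(can_full)
  cans <- vapply(frags, .ob_canonical, character(1))
  has_c <- vapply(cans, function(f) "C" %in% .smiles_elements(f), logical(1))
  heavy <- vapply(cans, .heavy_atom_count, integer(1))
  total <- vapply(cans, .total_atom_count, integer(1))
  ord <- order(-as.integer(has_c), -heavy, -total, cans, method = "radix")
  unname(cans[ord[1]])
}

# Canonical forms of the four excluded bare ions, computed lazily through
# the same backend so string comparison is consistent.
.excluded_ion_cache <- new.env(parent = emptyenv())
.excluded_ions <- function() {
  if (is.null(.excluded_ion_cache$ions)) {
    .excluded_ion_cache$ions <- vapply(
      c("[OH-]", "[Cl-]", "[NH4+]", "[NH2+]", "[NH2-]"),
      .ob_canonical, character(1))
  }
  .excluded_ion_cache$ions
}

#' Is a desalted structure an excluded bare ion?
#'
#' After desalting, compounds reduced to a bare hydroxide, chloride,
#' ammonium or amino ion carry no interpretable toxic moiety; their records
#' are removed from the curated table.
#'
#' @param desalted_smiles A single desalted canonical SMILES.
#' @return `TRUE` iff the structure is exactly one of the excluded ions.
#' @export
is_excluded_salt <- function(desalted_smiles) {
  if (is.na(desalted_smiles) || !nzchar(desalted_smiles)) return(FALSE)
  .ob_canonical(desalted_smiles) %in% .excluded_ions()
}

#' Flag halogen and heavy-metal content of a structure
#'
#' @param desalted_smiles A single SMILES (by convention the desalted form).
#' @param heavy_metals Element symbols counted as heavy metals (density
#'   above 5 g/cm3).
#' @return Named logical vector `c(halogenated = , heavy_metal = )`.
#' @export
flag_categories <- function(desalted_smiles, heavy_metals = .heavy_metals) {
  els <- .smiles_elements(desalted_smiles)
  c(halogenated = any(els %in% c("F", "Cl", "Br", "I")),
    heavy_metal = any(els %in% heavy_metals))
}

#' Default metal-grouping rules
#'
#' Divalent-metal salts with a dissociable counter-ion are grouped under a
#' synthetic per-metal "dummy CAS" token (`DM-<symbol>` by default). A
#' compound is not grouped when the metal is bound to hydroxide or ammonia,
#' when more than one metallic element is present, or when its CAS appears
#' on the reactive exclusion list.
#'
#' @param metal_elements Metals eligible for grouping.
#' @param dissociable_anions SMILES of counter-ions treated as dissociable.
#' @param reactive_cas CAS strings excluded as caustic/highly reactive.
#' @param dummy_prefix Prefix for generated dummy CAS tokens.
#' @return List of class `metal_rule`.
#' @export
metal_rule <- function(metal_elements = c("Zn", "Cu", "Cd", "Ni", "Pb",
                                          "Co", "Mn", "Hg", "Fe"),
                       dissociable_anions = c(
                         "CC(=O)[O-]",            # acetate
                         "CC(O)C(=O)[O-]",        # lactate
                         "[O-]S(=O)(=O)[O-]",     # sulfate
                         "[O-][N+](=O)[O-]",      # nitrate
                         "[O-]C(=O)C([O-])=O",    # oxalate
                         "[Cl-]", "[Br-]", "[I-]",
                         "[O-]C([O-])=O"          # carbonate
                       ),
                       reactive_cas = character(0),
                       dummy_prefix = "DM-") {
  canon <- vapply(dissociable_anions, .ob_canonical, character(1))
  structure(list(
    metal_elements = metal_elements,
    dissociable_anions = unname(canon[nzchar(canon)]),
    reactive_cas = reactive_cas,
    dummy_cas_map = setNames(paste0(dummy_prefix, metal_elements),
                             metal_elements)
  ), class = "metal_rule")
}

#' Read metal-grouping rules from YAML
#' @param path YAML file with any subset of the [metal_rule()] fields.
#' @return A `metal_rule`.
#' @export
read_metal_rules <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(metal_rule, vals[intersect(names(vals), names(formals(metal_rule)))])
}

#' Assign a dummy metal-ion CAS to a metal salt
#'
#' Inspects the original (pre-desalting) structure: when exactly one
#' rule-listed metal is present, every non-metal fragment is a dissociable
#' counter-ion, and no exclusion applies (hydroxide or ammonia ligand,
#' more than one metallic element, reactive CAS), the metal's dummy CAS is
#' returned. The original CAS is never overwritten; curated tables carry
#' both. An entry in `overrides` (columns `cas`, `dummy_metal_cas`) wins
#' over the rule engine.
#'
#' @param profile One-row chemical profile (needs `cas`, `smiles`).
#' @param rules A [metal_rule()].
#' @param overrides Optional curated override tibble.
#' @return The dummy CAS string, or `NA_character_` when not grouped.
#' @export
assign_dummy_metal <- function(profile, rules = metal_rule(),
                               overrides = NULL) {
  cas <- profile$cas[1]
  smiles <- profile$smiles[1]
  if (!is.null(overrides) && cas %in% overrides$cas) {
    return(overrides$dummy_metal_cas[match(cas, overrides$cas)])
  }
  if (is.na(smiles) || !nzchar(smiles)) return(NA_character_)
  if (cas %in% rules$reactive_cas) return(NA_character_)
  can <- .ob_canonical(smiles)
  if (!nzchar(can)) return(NA_character_)
  frags <- strsplit(can, ".", fixed = TRUE)[[1]]
  els_by_frag <- lapply(frags, .smiles_elements)
  all_els <- unique(unlist(els_by_frag))
  metals_present <- intersect(all_els, .all_metals)
  if (length(metals_present) != 1) return(NA_character_)   # none or multi
  metal <- metals_present[1]
  if (!metal %in% rules$metal_elements) return(NA_character_)
  is_metal_frag <- vapply(els_by_frag, function(e) metal %in% e, logical(1))
  counter <- frags[!is_metal_frag]
  # hydroxide / ammonia ligands block grouping, whether as separate
  # fragments or bound within the metal fragment
  counter_can <- vapply(counter, .ob_canonical, character(1))
  blocked <- c(.ob_canonical("[OH-]"), .ob_canonical("N"),
               .ob_canonical("[NH3]"))
  if (any(counter_can %in% blocked)) return(NA_character_)
  # the metal must appear as a bare ion/atom fragment; covalently drawn
  # complexes (hydroxides, ammines, organometallics) are not grouped
  metal_frags <- frags[is_metal_frag]
  if (length(metal_frags) != 1 ||
      .heavy_atom_count(metal_frags[1]) > 1) return(NA_character_)
  if (length(counter) == 0) return(NA_character_)           # bare ion/metal
  if (!all(counter_can %in% rules$dissociable_anions)) return(NA_character_)
  unname(rules$dummy_cas_map[metal])
}

#' Flag an effect value exceeding 5x water solubility
#'
#' Effect concentrations at or above five times the chemical's water
#' solubility are flagged as suspect but never removed; the flag lets the
#' end-user drop them in downstream analyses. The comparator is inclusive
#' by default and configurable.
#'
#' @param effect_value Effect concentration(s) in mg/L.
#' @param water_solubility Water solubility in mg/L (may be `NA`).
#' @param factor Multiplier over solubility (default 5).
#' @param inclusive Use `>=` (default) rather than `>`.
#' @return Logical vector; `FALSE` with a warning when solubility is absent.
#' @export
flag_solubility <- function(effect_value, water_solubility, factor = 5,
                            inclusive = TRUE) {
  n <- max(length(effect_value), length(water_solubility))
  ev <- rep_len(effect_value, n)
  ws <- rep_len(water_solubility, n)
  if (anyNA(ws)) {
    warning("water solubility absent for some chemicals; flag set to FALSE",
            call. = FALSE)
  }
  out <- if (inclusive) ev >= factor * ws else ev > factor * ws
  out[is.na(out)] <- FALSE
  out
}

#' Read a chemical-properties table
#'
#' Expected columns: `cas` (digits-only string), `name`, `smiles`, and
#' optionally `desalted_smiles`, `molecular_weight` (g/mol), `log_kow`,
#' `water_solubility` (mg/L), `ecosar_classes`, `ecosar_collapsed`,
#' `usepa_category`, `moa_verhaar`/`moa_test`/`moa_oasis`/`moa_aster`
#' (consumed as given, never computed), `validated`.
#'
#' @param path CSV file path.
#' @return Tibble of chemical profiles.
#' @export
read_chemicals <- function(path) {
  chem <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                          progress = FALSE)
  for (nm in c("molecular_weight", "log_kow", "water_solubility")) {
    if (nm %in% names(chem)) chem[[nm]] <- as.numeric(chem[[nm]])
  }
  if ("validated" %in% names(chem)) chem$validated <- as.logical(chem$validated)
  as_tibble(chem)
}

#' Harmonize a chemical table
#'
#' Computes, for every profile lacking them: the desalted canonical SMILES,
#' the excluded-salt indicator, the halogen/heavy-metal category flags and
#' the dummy metal CAS. MOA labels and ECOSAR classes are taken as input
#' columns, never computed.
#'
#' @param chemicals Tibble from [read_chemicals()].
#' @param rules A [metal_rule()].
#' @param overrides Optional dummy-CAS override table (`cas`,
#'   `dummy_metal_cas`).
#' @return The chemical tibble with `desalted_smiles`, `excluded_salt`,
#'   `halogenated`, `heavy_metal`, `dummy_metal_cas`, `structure_error`
#'   columns.
#' @export
harmonize_chemicals <- function(chemicals, rules = metal_rule(),
                                overrides = NULL) {
  chem <- as_tibble(chemicals)
  n <- nrow(chem)
  if (!"desalted_smiles" %in% names(chem)) chem$desalted_smiles <- NA_character_
  chem$structure_error <- FALSE
  for (i in seq_len(n)) {
    if (!is.na(chem$desalted_smiles[i])) next
    des <- tryCatch(desalt_canonicalize(chem$smiles[i]),
                    error = function(e) NA_character_)
    chem$desalted_smiles[i] <- des
    chem$structure_error[i] <- is.na(des)
  }
  chem$excluded_salt <- vapply(chem$desalted_smiles, is_excluded_salt,
                               logical(1), USE.NAMES = FALSE)
  cats <- lapply(chem$desalted_smiles,
                 function(s) flag_categories(if (is.na(s)) "" else s))
  chem$halogenated <- vapply(cats, `[[`, logical(1), "halogenated")
  chem$heavy_metal <- vapply(cats, `[[`, logical(1), "heavy_metal")
  chem$dummy_metal_cas <- vapply(seq_len(n), function(i) {
    assign_dummy_metal(chem[i, , drop = FALSE], rules, overrides)
  }, character(1))
  chem
}
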