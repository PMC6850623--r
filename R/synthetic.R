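# Deterministic generator of record/chemical/taxonomy tables with a
# ground-truth manifest. Every condition the pipeline must detect is
# planted explicitly: exact duplicates, the three outlier rules, sub-24-h
# durations, qualifier-bearing statistics, off-whitelist endpoints,
# excluded salts, dummy-metal compounds and solubility-flag records.
#
# Planting strategy: every anomaly type lives on its own dedicated
# chemical so group geometric means are fully controlled, and outliers are
# planted with a safety margin (>= 0.3 log10 units beyond the inclusive
# threshold) so floating-point evaluation cannot flip an outcome. Baseline
# effect values are drawn from per-chemical log10-normals truncated at
# +/- 3 sigma, which caps the within-group spread well below the 3-oom
# outlier threshold: unplanned records can never be flagged.

.fixture_species <- function() {
  tibble(
    latin_name = c(
      "Danio rerio", "Pimephales promelas", "Oncorhynchus mykiss",
      "Lepomis macrochirus", "Oryzias latipes", "Gasterosteus aculeatus",
      "Daphnia magna", "Ceriodaphnia dubia", "Chironomus riparius",
      "Hyalella azteca", "Gammarus pulex", "Americamysis bahia",
      "Raphidocelis subcapitata", "Desmodesmus subspicatus",
      "Chlorella vulgaris", "Navicula pelliculosa", "Skeletonema costatum",
      "Xenopus laevis", "Lithobates pipiens", "Ambystoma mexicanum",
      "Chironomus sp.", "Lemna minor", "Saccharomyces cerevisiae",
      "Chironomidae", "Mixed plankton community"
    ),
    trophic_level = c(
      rep("fish", 6), rep("invertebrate", 6), rep("algae", 5),
      rep("amphibian", 3), "invertebrate", "macrophyte", "fungi",
      "invertebrate", "algae"
    ),
    habitat = c(
      rep("freshwater", 11), "saltwater", rep("freshwater", 4),
      "saltwater", rep("freshwater", 6), "freshwater", "freshwater"
    ),
    resolution = c(rep("species", 20), "genus", "species", "species",
                   "above_genus", "mixed_community")
  )
}

.fixture_synonyms <- function() {
  tibble(old_name = c("Brachydanio rerio", "Selenastrum capricornutum"),
         current_name = c("Danio rerio", "Raphidocelis subcapitata"))
}

.fixture_baseline_chemicals <- function() {
  tibble(
    cas = c("108952", "108883", "91203", "108907", "62533", "65850",
            "64175", "67641", "110861", "98953", "120832", "100527"),
    name = c("phenol", "toluene", "naphthalene", "chlorobenzene", "aniline",
             "benzoic acid", "ethanol", "acetone", "pyridine",
             "nitrobenzene", "2,4-dichlorophenol", "benzaldehyde"),
    smiles = c("Oc1ccccc1", "Cc1ccccc1", "c1ccc2ccccc2c1", "Clc1ccccc1",
               "Nc1ccccc1", "OC(=O)c1ccccc1", "CCO", "CC(C)=O", "c1ccncc1",
               "O=[N+]([O-])c1ccccc1", "Oc1ccc(Cl)cc1Cl", "O=Cc1ccccc1"),
    molecular_weight = c(94.11, 92.14, 128.17, 112.56, 93.13, 122.12,
                         46.07, 58.08, 79.10, 123.11, 163.00, 106.12),
    log_kow = c(1.46, 2.73, 3.30, 2.84, 0.90, 1.87, -0.31, -0.24, 0.65,
                1.85, 3.06, 1.48),
    water_solubility = rep(1e5, 12),
    validated = TRUE
  )
}

.fixture_salt_chemicals <- function() {
  tibble(
    cas = c("7647145", "7447407", "12125029", "1310732"),
    name = c("sodium chloride", "potassium chloride", "ammonium chloride",
             "sodium hydroxide"),
    smiles = c("[Na+].[Cl-]", "[K+].[Cl-]", "[NH4+].[Cl-]", "[Na+].[OH-]"),
    molecular_weight = c(58.44, 74.55, 53.49, 40.00),
    log_kow = NA_real_, water_solubility = 3.6e5, validated = TRUE
  )
}

.fixture_metal_chemicals <- function() {
  tibble(
    cas = c("557346", "7758987", "10108642", "13138459", "301042",
            "10124433"),
    name = c("zinc acetate", "copper(II) sulfate", "cadmium chloride",
             "nickel(II) nitrate", "lead(II) acetate", "cobalt(II) sulfate"),
    smiles = c("[Zn+2].CC(=O)[O-].CC(=O)[O-]",
               "[Cu+2].[O-]S(=O)(=O)[O-]",
               "[Cd+2].[Cl-].[Cl-]",
               "[Ni+2].[O-][N+](=O)[O-].[O-][N+](=O)[O-]",
               "[Pb+2].CC(=O)[O-].CC(=O)[O-]",
               "[Co+2].[O-]S(=O)(=O)[O-]"),
    metal = c("Zn", "Cu", "Cd", "Ni", "Pb", "Co"),
    molecular_weight = c(183.48, 159.61, 183.32, 182.70, 325.29, 155.00),
    log_kow = NA_real_, water_solubility = 4e5, validated = TRUE
  )
}

#' Fixture generator configuration
#'
#' Counts of planted conditions and baseline generator parameters. The
#' defaults define the standard validation scenario: 1000 baseline records
#' over 12 organic chemicals, 50 exact duplicates, 10/5/3 outliers for the
#' species/trophic/rare-species rules, 20 sub-24-h records, 15 qualifier
#' records, 10 off-whitelist endpoints, 4 excluded salts and 6
#' solubility-flagged records, plus 6 dummy-metal compounds.
#'
#' @param n_baseline Baseline record count.
#' @param n_duplicates Planted exact duplicate pairs.
#' @param n_rule_a,n_rule_b,n_rule_c Planted outliers per rule.
#' @param n_sub24h Records with duration below 24 h.
#' @param n_qualifier Records with `<`/`>` qualifiers.
#' @param n_whitelist Records with off-whitelist effect tokens.
#' @param n_salts Excluded salt chemicals (max 4).
#' @param n_dummy_metal Dummy-metal compounds (max 6).
#' @param n_solubility Solubility-flagged records.
#' @param records_per_salt,records_per_metal Records per salt/metal
#'   chemical.
#' @param baseline_sigma Log10 scale of the per-chemical log-normals.
#' @param baseline_mu_range Range the per-chemical log10 locations are
#'   drawn from (log10 mg/L).
#' @param rule_c_group_size Trophic-group size for rule-C plants (must be
#'   at least the rule-C minimum of 30).
#' @return List of class `fixture_config`.
#' @export
fixture_config <- function(n_baseline = 1000, n_duplicates = 50,
                           n_rule_a = 10, n_rule_b = 5, n_rule_c = 3,
                           n_sub24h = 20, n_qualifier = 15,
                           n_whitelist = 10, n_salts = 4,
                           n_dummy_metal = 6, n_solubility = 6,
                           records_per_salt = 3, records_per_metal = 3,
                           baseline_sigma = 0.4,
                           baseline_mu_range = c(-1, 2),
                           rule_c_group_size = 30) {
  counts <- c(n_baseline, n_duplicates, n_rule_a, n_rule_b, n_rule_c,
              n_sub24h, n_qualifier, n_whitelist, n_salts, n_dummy_metal,
              n_solubility)
  if (any(counts < 0)) {
    abort("fixture counts must be non-negative",
          class = "toxsift_config_error")
  }
  if (n_salts > 4 || n_dummy_metal > 6) {
    abort("at most 4 salt and 6 metal chemicals are defined",
          class = "toxsift_config_error")
  }
  if (n_rule_c > 0 && rule_c_group_size < 30) {
    abort("rule-C outliers require a trophic group of at least 30 records",
          class = "toxsift_config_error")
  }
  if (n_duplicates > n_baseline) {
    abort("cannot plant more duplicates than baseline records",
          class = "toxsift_config_error")
  }
  structure(list(
    n_baseline = n_baseline, n_duplicates = n_duplicates,
    n_rule_a = n_rule_a, n_rule_b = n_rule_b, n_rule_c = n_rule_c,
    n_sub24h = n_sub24h, n_qualifier = n_qualifier,
    n_whitelist = n_whitelist, n_salts = n_salts,
    n_dummy_metal = n_dummy_metal, n_solubility = n_solubility,
    records_per_salt = records_per_salt,
    records_per_metal = records_per_metal,
    baseline_sigma = baseline_sigma,
    baseline_mu_range = baseline_mu_range,
    rule_c_group_size = rule_c_group_size
  ), class = "fixture_config")
}

#' Draw a seeded log-normal sample
#'
#' `log10` of the returned values is Normal(`mu`, `sigma`). The caller's
#' RNG state is preserved.
#'
#' @param mu Location on the log10 scale.
#' @param sigma Scale on the log10 scale (>= 0).
#' @param n Sample size (>= 1).
#' @param seed Integer seed.
#' @return Numeric vector of `n` positive values.
#' @export
generate_lognormal_sample <- function(mu, sigma, n, seed = 1L) {
  if (!is.numeric(sigma) || sigma < 0 || !is.numeric(n) || n < 1) {
    abort("require sigma >= 0 and n >= 1", class = "toxsift_domain_error")
  }
  with_preserved_seed(seed, 10^rnorm(n, mu, sigma))
}

# truncated normal draw on the log10 scale (+/- 3 sigma, by clamping)
.rnorm_trunc <- function(n, mu, sigma) {
  pmin(pmax(rnorm(n, mu, sigma), mu - 3 * sigma), mu + 3 * sigma)
}

#' Generate a synthetic fixture dataset with a ground-truth manifest
#'
#' Produces raw (pre-parsing) record, chemical, taxonomy and synonym
#' tables whose curation outcome is known exactly, plus a manifest listing
#' the record ids of every planted condition. Reproducible: the same
#' `config` and `seed` always produce identical tables.
#'
#' @param config A [fixture_config()].
#' @param seed Integer seed.
#' @return List with `records`, `chemicals`, `taxonomy`, `synonyms`,
#'   `manifest`.
#' @export
generate_dataset <- function(config = fixture_config(), seed = 1L) {
  stopifnot(inherits(config, "fixture_config"))
  with_preserved_seed(seed, .generate_dataset_impl(config, seed))
}

.generate_dataset_impl <- function(config, seed) {
  taxonomy <- .fixture_species()
  synonyms <- .fixture_synonyms()
  base_chem <- .fixture_baseline_chemicals()
  species <- taxonomy[taxonomy$resolution %in% c("species", "genus") &
                        taxonomy$trophic_level %in%
                        c("fish", "invertebrate", "algae", "amphibian"), ]
  fish_sp <- species$latin_name[species$trophic_level == "fish"]
  sigma <- config$baseline_sigma
  mu_chem <- stats::runif(nrow(base_chem), config$baseline_mu_range[1],
                          config$baseline_mu_range[2])

  sources <- sprintf("Ecotox Study %03d", 1:200)
  test_types <- c("static", "flow-through", "semi-static", "renewal")
  rows <- list()
  tags <- character(0)
  add <- function(tag, cas, name, smiles, latin, value, unit, duration,
                  test_type, statistic, effect, source) {
    rows[[length(rows) + 1]] <<- tibble(
      cas = cas, chemical_name = name, smiles = smiles, latin_name = latin,
      effect_value = value, unit = unit, duration = duration,
      test_type = test_type, statistic = statistic, effect = effect,
      source = source)
    tags <<- c(tags, tag)
  }

  stat_menu <- list(
    fish = list(c("LC50", "mortality"), c("NOEC", "growth"),
                c("NOEC", "reproduction"), c("EC50", "mortality")),
    invertebrate = list(c("EC50", "intoxication"), c("LC50", "mortality"),
                        c("NOEC", "reproduction"), c("MATC", "growth")),
    algae = list(c("EC50", "growth"), c("IC50", "growth"),
                 c("NOEC", "growth"), c("EC10", "biomass")),
    amphibian = list(c("LC50", "mortality"), c("NOEC", "growth"),
                     c("LOEC", "growth"))
  )
  durations <- c("48 h", "96 h", "4 d", "7 d", "14 d", "21 d", "28 d")

  # ---- baseline records -----------------------------------------------
  for (i in seq_len(config$n_baseline)) {
    ci <- sample.int(nrow(base_chem), 1)
    si <- sample.int(nrow(species), 1)
    sp <- species[si, ]
    menu <- stat_menu[[sp$trophic_level]]
    se <- menu[[sample.int(length(menu), 1)]]
    val <- 10^.rnorm_trunc(1, mu_chem[ci], sigma)
    u <- sample(c("mg/L", "ug/L", "mmol/L"), 1, prob = c(0.7, 0.2, 0.1))
    raw <- switch(u, "mg/L" = val, "ug/L" = val * 1000,
                  "mmol/L" = val / base_chem$molecular_weight[ci])
    add(sprintf("base_%04d", i), base_chem$cas[ci], base_chem$name[ci],
        base_chem$smiles[ci], sp$latin_name, raw, u,
        sample(durations, 1), sample(test_types, 1), se[1], se[2],
        sample(sources, 1))
  }

  # ---- rule-A outliers: dedicated chemical, 3-record species group ----
  for (k in seq_len(config$n_rule_a)) {
    cas <- sprintf("%d", 900000 + k)
    mu <- stats::runif(1, -1, 1)
    delta <- 5.25 * sample(c(-1, 1), 1)   # inclusive distance 3.5
    sp <- fish_sp[(k - 1) %% length(fish_sp) + 1]
    vals <- 10^c(mu - 0.05, mu + 0.05, mu + delta)
    for (j in 1:3) {
      add(if (j == 3) sprintf("ruleA_%02d", k) else
            sprintf("ruleA_%02d_bg%d", k, j),
          cas, paste0("test compound A", k), "CCCCO", sp, vals[j], "mg/L",
          "96 h", "static", "LC50", "mortality",
          sprintf("Planted Study A%02d-%d", k, j))
    }
  }

  # ---- rule-B outliers: 3 single-record species in one trophic group --
  for (k in seq_len(config$n_rule_b)) {
    cas <- sprintf("%d", 910000 + k)
    mu <- stats::runif(1, -1, 1)
    delta <- 6.75 * sample(c(-1, 1), 1)   # inclusive distance 4.5
    sps <- fish_sp[1:3]
    vals <- 10^c(mu - 0.05, mu + 0.05, mu + delta)
    for (j in 1:3) {
      add(if (j == 3) sprintf("ruleB_%02d", k) else
            sprintf("ruleB_%02d_bg%d", k, j),
          cas, paste0("test compound B", k), "CCCCCO", sps[j], vals[j],
          "mg/L", "96 h", "static", "LC50", "mortality",
          sprintf("Planted Study B%02d-%d", k, j))
    }
  }

  # ---- rule-C outliers: 30-record trophic group with one rare species -
  for (k in seq_len(config$n_rule_c)) {
    cas <- sprintf("%d", 920000 + k)
    mu <- stats::runif(1, -1, 1)
    n_bg <- config$rule_c_group_size - 1
    delta <- 3.5 * config$rule_c_group_size / n_bg * sample(c(-1, 1), 1)
    jit <- stats::runif(n_bg, -0.1, 0.1)
    jit <- jit - mean(jit)              # center so the trophic mean is exact
    for (j in seq_len(n_bg)) {
      add(sprintf("ruleC_%02d_bg%02d", k, j), cas,
          paste0("test compound C", k), "CCCCCCO", "Danio rerio",
          10^(mu + jit[j]), "mg/L", "96 h", "static", "LC50", "mortality",
          sprintf("Planted Study C%02d-%02d", k, j))
    }
    add(sprintf("ruleC_%02d", k), cas, paste0("test compound C", k),
        "CCCCCCO", "Oryzias latipes", 10^(mu + delta), "mg/L", "96 h",
        "static", "LC50", "mortality", sprintf("Planted Study C%02d-XX", k))
  }

  # ---- sub-24-h, qualifier and off-whitelist records ------------------
  for (k in seq_len(config$n_sub24h)) {
    ci <- sample.int(nrow(base_chem), 1)
    add(sprintf("sub24_%02d", k), base_chem$cas[ci], base_chem$name[ci],
        base_chem$smiles[ci], sample(fish_sp, 1),
        10^.rnorm_trunc(1, mu_chem[ci], sigma), "mg/L",
        sample(c("6 h", "12 h", "18 h"), 1), "static", "LC50", "mortality",
        sample(sources, 1))
  }
  for (k in seq_len(config$n_qualifier)) {
    ci <- sample.int(nrow(base_chem), 1)
    add(sprintf("qual_%02d", k), base_chem$cas[ci], base_chem$name[ci],
        base_chem$smiles[ci], sample(fish_sp, 1),
        10^.rnorm_trunc(1, mu_chem[ci], sigma), "mg/L", "96 h", "static",
        sample(c("<LC50", ">EC50", "<NOEC"), 1), "mortality",
        sample(sources, 1))
  }
  for (k in seq_len(config$n_whitelist)) {
    ci <- sample.int(nrow(base_chem), 1)
    add(sprintf("wl_%02d", k), base_chem$cas[ci], base_chem$name[ci],
        base_chem$smiles[ci], "Daphnia magna",
        10^.rnorm_trunc(1, mu_chem[ci], sigma), "mg/L", "17 d",
        "semi-static", "NOEC",
        sample(c("biomarker", "enzyme activity"), 1), sample(sources, 1))
  }

  # ---- excluded salts, dummy metals, solubility flags -----------------
  salt_chem <- head(.fixture_salt_chemicals(), config$n_salts)
  for (k in seq_len(nrow(salt_chem))) {
    for (j in seq_len(config$records_per_salt)) {
      add(sprintf("salt_%02d_%d", k, j), salt_chem$cas[k],
          salt_chem$name[k], salt_chem$smiles[k], sample(fish_sp, 1),
          10^stats::runif(1, 1, 3), "mg/L", "96 h", "static", "LC50",
          "mortality", sprintf("Planted Study S%02d-%d", k, j))
    }
  }
  metal_chem <- head(.fixture_metal_chemicals(), config$n_dummy_metal)
  for (k in seq_len(nrow(metal_chem))) {
    for (j in seq_len(config$records_per_metal)) {
      add(sprintf("metal_%02d_%d", k, j), metal_chem$cas[k],
          metal_chem$name[k], metal_chem$smiles[k], sample(fish_sp, 1),
          10^stats::runif(1, -1, 1), "mg/L", "96 h", "static", "LC50",
          "mortality", sprintf("Planted Study M%02d-%d", k, j))
    }
  }
  sol_chem <- tibble(cas = "950001", name = "octan-1-ol (test)",
                     smiles = "CCCCCCCCO", molecular_weight = 130.23,
                     log_kow = 3.0, water_solubility = 1.0,
                     validated = TRUE)
  for (k in seq_len(config$n_solubility)) {
    # ratio to solubility spans exactly 5 (inclusive boundary) upward
    add(sprintf("sol_%02d", k), sol_chem$cas, sol_chem$name,
        sol_chem$smiles, "Pimephales promelas", 5 + (k - 1), "mg/L",
        "96 h", "flow-through", "LC50", "mortality",
        sprintf("Planted Study W-%02d", k))
  }

  records <- bind_rows(rows)
  records$.tag <- tags

  # ---- exact duplicates of baseline records ---------------------------
  if (config$n_duplicates > 0) {
    base_idx <- which(startsWith(records$.tag, "base_"))
    dup_src <- sort(sample(base_idx, config$n_duplicates))
    dups <- records[dup_src, , drop = FALSE]
    dups$.tag <- sprintf("dup_%03d", seq_len(config$n_duplicates))
    records <- bind_rows(records, dups)
  }

  # shuffle rows, then assign final ids in row order
  records <- records[sample.int(nrow(records)), , drop = FALSE]
  records$record_id <- sprintf("R%05d", seq_len(nrow(records)))
  records <- records[, c("record_id", setdiff(names(records), "record_id"))]

  chemicals <- bind_rows(
    base_chem,
    salt_chem[, setdiff(names(salt_chem), "metal")],
    metal_chem[, setdiff(names(metal_chem), "metal")],
    sol_chem
  )

  ids_for <- function(prefix) {
    records$record_id[startsWith(records$.tag, prefix) &
                        !grepl("_bg", records$.tag)]
  }
  # a planted duplicate pair is (original, copy); the canonical sort keeps
  # the lexicographically smaller record_id, so the larger id is removed
  dup_removed <- character(0)
  if (config$n_duplicates > 0) {
    copies <- records[startsWith(records$.tag, "dup_"), , drop = FALSE]
    origs <- records[startsWith(records$.tag, "base_"), , drop = FALSE]
    key <- function(df) paste(df$cas, df$latin_name, df$duration,
                              df$statistic, df$effect,
                              sprintf("%.15g", df$effect_value), df$source,
                              sep = "\r")
    m <- match(key(copies), key(origs))
    dup_removed <- pmax(copies$record_id, origs$record_id[m])
  }

  manifest <- list(
    seed = seed,
    counts = list(
      baseline = config$n_baseline, duplicates = config$n_duplicates,
      rule_a_outliers = config$n_rule_a, rule_b_outliers = config$n_rule_b,
      rule_c_outliers = config$n_rule_c, sub24h = config$n_sub24h,
      qualifier_records = config$n_qualifier,
      whitelist_violations = config$n_whitelist,
      excluded_salts = config$n_salts,
      dummy_metal_compounds = config$n_dummy_metal,
      solubility_flagged = config$n_solubility
    ),
    duplicates_removed = sort(dup_removed),
    rule_a_outliers = sort(ids_for("ruleA_")),
    rule_b_outliers = sort(ids_for("ruleB_")),
    rule_c_outliers = sort(ids_for("ruleC_")),
    sub24h = sort(ids_for("sub24_")),
    qualifier_records = sort(ids_for("qual_")),
    whitelist_violations = sort(ids_for("wl_")),
    excluded_salt_cas = salt_chem$cas,
    excluded_salt_records = sort(records$record_id[
      startsWith(records$.tag, "salt_")]),
    dummy_metal_cas = setNames(paste0("DM-", metal_chem$metal),
                               metal_chem$cas),
    dummy_metal_records = sort(records$record_id[
      startsWith(records$.tag, "metal_")]),
    solubility_flagged = sort(ids_for("sol_")),
    params = list(baseline_sigma = sigma,
                  baseline_mu = setNames(mu_chem, base_chem$cas))
  )
  records$.tag <- NULL
  list(records = records, chemicals = chemicals, taxonomy = taxonomy,
       synonyms = synonyms, manifest = manifest)
}

#' Write a generated fixture to disk
#'
#' Emits `records.csv`, `chemicals.csv`, `taxonomy.csv`, `synonyms.csv`
#' and `manifest.json` with byte-stable formatting.
#'
#' @param fixture Output of [generate_dataset()].
#' @param out_dir Target directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_fixture <- function(fixture, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  paths <- c(
    records = file.path(out_dir, "records.csv"),
    chemicals = file.path(out_dir, "chemicals.csv"),
    taxonomy = file.path(out_dir, "taxonomy.csv"),
    synonyms = file.path(out_dir, "synonyms.csv"),
    manifest = file.path(out_dir, "manifest.json")
  )
  .write_stable_csv(fixture$records, paths["records"])
  .write_stable_csv(fixture$chemicals, paths["chemicals"])
  .write_stable_csv(fixture$taxonomy, paths["taxonomy"])
  .write_stable_csv(fixture$synonyms, paths["synonyms"])
  jsonlite::write_json(fixture$manifest, paths["manifest"],
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(paths)
}
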