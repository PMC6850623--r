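# Independent brute-force reimplementation of the outlier rules: for every
# record, recompute each group mean and distance naively with explicit
# subsetting. Deliberately shares no code with detect_outliers().
oracle_outliers <- function(records, cfg = outlier_config()) {
  lg <- log10(records$effect_value)
  out <- list()
  for (i in seq_len(nrow(records))) {
    sp <- which(records$cas == records$cas[i] &
                  records$latin_name == records$latin_name[i])
    if (length(sp) >= cfg$species_min_n) {
      d <- abs(lg[i] - mean(lg[sp]))
      if (d >= cfg$species_oom) {
        out[[length(out) + 1]] <- data.frame(
          record_id = records$record_id[i], rule = "species_3oom")
      }
    }
    tr <- which(records$cas == records$cas[i] &
                  records$trophic_level == records$trophic_level[i])
    if (length(tr) >= cfg$trophic_min_n) {
      d <- abs(lg[i] - mean(lg[tr]))
      if (d >= cfg$trophic_oom) {
        out[[length(out) + 1]] <- data.frame(
          record_id = records$record_id[i], rule = "trophic_4oom")
      }
    }
    if (length(tr) >= cfg$rare_group_min_n) {
      n_sp_in_tr <- sum(records$latin_name[tr] == records$latin_name[i])
      d <- abs(lg[i] - mean(lg[tr]))
      if (n_sp_in_tr <= cfg$rare_species_max_n && d >= cfg$rare_oom) {
        out[[length(out) + 1]] <- data.frame(
          record_id = records$record_id[i], rule = "rare_species_3oom")
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(record_id = character(), rule = character()))
  }
  res <- do.call(rbind, out)
  res[order(res$record_id, res$rule), , drop = FALSE]
}

# Random record tables exercising all three rules: few chemicals and
# species so groups of size >= 3 and >= 30 occur, values spread over ten
# orders of magnitude so flags are common.
random_outlier_table <- function(seed, max_n = 200) {
  set.seed(seed)
  n <- sample(20:max_n, 1)
  species <- c("Danio rerio", "Oncorhynchus mykiss", "Oryzias latipes",
               "Daphnia magna", "Gammarus pulex", "Chironomus riparius")
  trophic <- c(rep("fish", 3), rep("invertebrate", 3))
  si <- sample(6, n, replace = TRUE)
  tibble::tibble(
    record_id = sprintf("T%04d", seq_len(n)),
    cas = sample(c("111", "222", "333"), n, replace = TRUE),
    latin_name = species[si],
    trophic_level = trophic[si],
    effect_value = 10^runif(n, -5, 5)
  )
}

flags_as_key <- function(flags) {
  k <- paste(flags$record_id, flags$rule)
  sort(k)
}

# Minimal valid raw record used as a template in several tests.
template_record <- function(...) {
  defaults <- list(
    record_id = "R00001", cas = "108952", chemical_name = "phenol",
    smiles = "Oc1ccccc1", latin_name = "Danio rerio", effect_value = 1.5,
    unit = "mg/L", duration = "96 h", test_type = "static",
    statistic = "LC50", effect = "mortality", source = "Study 1")
  args <- list(...)
  defaults[names(args)] <- args
  tibble::as_tibble(defaults)
}

fixture_taxonomy <- function() {
  tibble::tibble(
    latin_name = c("Danio rerio", "Daphnia magna", "Raphidocelis subcapitata",
                   "Xenopus laevis", "Lemna minor", "Chironomidae",
                   "Chironomus sp.", "Mixed plankton community"),
    trophic_level = c("fish", "invertebrate", "algae", "amphibian",
                      "macrophyte", "invertebrate", "invertebrate", "algae"),
    habitat = rep("freshwater", 8),
    resolution = c(rep("species", 5), "above_genus", "genus",
                   "mixed_community")
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
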