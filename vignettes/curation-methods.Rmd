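---
title: "Stepwise curation of aquatic ecotoxicity data: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stepwise curation of aquatic ecotoxicity data: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Aquatic ecotoxicity test results are scattered across heterogeneous sources
that disagree on units, duration formats, statistic spellings, endpoint
vocabulary and taxonomic nomenclature, and that contain duplicated studies
and implausible values. Before species sensitivity distributions (SSDs),
predicted-no-effect concentrations (PNECs) or ecological thresholds of
toxicological concern (ecoTTCs) can be derived from such data, the records
must be filtered and harmonized in a way that is objective, reproducible and
auditable. `toxsift` implements a stepwise information-filtering (SIFT)
workflow as a pipeline of pure, deterministic table transformations: every
removal is archived with a machine-readable reason code, and the whole run
is reproducible byte for byte.

```{r, eval = FALSE}
library(toxsift)
fx  <- generate_dataset(fixture_config(), seed = 1)
res <- curate(fx$records, fx$chemicals, fx$taxonomy, fx$synonyms)
res$report
```

## The filtering model

Curation proceeds through ordered stages; a record is judged by the first
stage it fails and is never re-examined afterwards, so each removal carries
exactly one step name and reason code.

1. **Relevance.** The Latin name is resolved against a curated taxonomy
   table (synonym map applied first, then whitespace/case normalization).
   Records are kept when the taxon belongs to one of the four relevant
   trophic levels — fish, amphibian, invertebrate, algae — and is resolved
   at species or genus rank. Family-or-higher identifications, multi-taxon
   descriptors and unresolved names are removed. Taxonomy is always a local
   input table: results must not depend on the changing state of a remote
   nomenclature service.
2. **Validity.** Requires a CAS number, an effect value with a convertible
   unit, a parseable duration and test statistic, a measured-effect token
   and a citation. Effect values carrying `<`/`>` qualifiers are removed:
   a censored bound is not an estimate of the effect concentration.
   Unparseable units or durations do not crash ingestion; they surface
   here as `unit_conversion` / `duration_conversion` removals.
3. **Acceptability.** Keeps tests of at least 24 h (inclusive) whose
   statistic is NOEC, LOEC or MATC, or an ECx/ICx/LCx with x in the
   inclusive 5–70% window, and whose effect token is on the whitelist of
   endpoints used in regulatory decision-making (abundance, biomass,
   cells, chlorophyll, emergence, filtration rate, gross primary
   productivity, growth, hatchability, intoxication, mortality, nitrogen
   fixation, population growth, population reduction, population change,
   primary production, regeneration, reproduction, shell deposition,
   teratogenesis). Spelling variants are mapped through an editable alias
   table (`effect_aliases.csv`); the default map is deliberately small and
   exact, because silently merging distinct endpoints is worse than
   leaving a variant unmatched.
4. **Chemical harmonization.** Concentrations are converted to mg/L
   (molar units via the molecular weight; ppm treated as mg/L under the
   dilute aqueous convention — a stated approximation, exact only at unit
   water density). Structures are desalted and canonicalized; compounds
   whose desalted form is a bare hydroxide, chloride, ammonium or amino
   ion are excluded together with all their records, since the
   toxicologically active moiety cannot be identified. Single-metal salts
   with dissociable counter-ions are grouped under a synthetic per-metal
   "dummy CAS" (`DM-Zn`, `DM-Cu`, …) while the original CAS is always
   preserved. Effect values at or above 5× the water solubility are
   flagged — never removed — so downstream users can decide.
5. **Designation.** Each record is classified acute, chronic or
   unassignable by per-trophic-group decision tables (below).
6. **Duplicates.** Records matching exactly on chemical, species,
   duration, statistic, measured effect, effect value and citation are
   collapsed to one representative — the first under a canonical sort of
   the key fields and then the record id, which makes the choice
   order-independent.
7. **Outliers.** Three order-of-magnitude rules against geometric means
   (all thresholds inclusive, distances in log10 space):
   within-species at ≥ 3 orders when a chemical–species pair has ≥ 3
   records; within-trophic-group at ≥ 4 orders when the group has ≥ 3
   records; and rare species (≤ 2 records in the group) at ≥ 3 orders when
   the trophic group holds ≥ 30 records for the chemical.

### Numerical choices in the outlier stage

Group geometric means are computed *inclusive* of the candidate record.
The leave-one-out alternative is equally defensible; the inclusive form
was chosen because it reads directly off the rule definitions and makes a
single vectorized pass possible. With k other members at a common level, a
candidate displaced by δ log10 units sits δ·k/(k+1) from the inclusive
mean, so the inclusive test is slightly more conservative — users
calibrating against leave-one-out expectations should account for this
shrinkage. All three rules are evaluated simultaneously on one pre-removal
snapshot and flagged records are removed in a single pass: iterative
re-evaluation after each removal is order-dependent and therefore not
reproducible. A record flagged by several rules is removed once with all
triggering rules recorded. The "rare species" count is interpreted within
the chemical's trophic group (not database-wide); both this and the
species-rule pooling across acute/chronic designations are configurable
interpretations, with the defaults stated here. `detect_outliers` is
verified against an independent brute-force implementation (naive
per-record recomputation of every group mean) on hundreds of randomized
tables.

## Acute/chronic designation is data, not code

The decision logic differs by trophic group and is encoded as ordered CSV
rule tables (`inst/extdata/rules/`), one row per rule, first match wins,
default `unassignable`. The shipped tables encode standard conventions —
e.g. fish acute: lethal/effective concentrations on mortality at ≤ 96 h;
fish chronic: NOEC/LOEC/MATC, or ECx with x ≤ 20, on
growth/reproduction/hatchability at ≥ 7 d; 96 h mortality is acute at the
boundary. They are documented approximations meant to be replaced wholesale
by tables transcribed from whichever regulatory decision trees a user works
under; the engine itself only guarantees determinism, totality and
first-match ordering. Note the two-sided consequence: an endpoint off the
acceptability whitelist (e.g. a biomarker response measured as a 17-d
cladoceran NOEC) is removed before designation and can never acquire a
chronic label, however chronic-like its species, duration and statistic.

## Distributional tools

All three analysis tools operate on species geometric means (one value per
species × designation) and a normal model for log10 concentrations:
`mu` is the mean and `sigma` the sample standard deviation (n−1
denominator, the common SSD convention rather than the MLE) of the log10
values, and quantiles are `10^(mu + z_p·sigma)`.

* **PNEC.** With fewer than 8 species geometric means, an assessment-factor
  ladder is applied to the lowest value: acute-only data → AF 1000;
  chronic data covering 1 / 2 / ≥ 3 trophic levels → AF 100 / 50 / 10.
  With ≥ 8 species means an SSD is fitted and PNEC = HC5 / 5. The ladder,
  the 8-species switch, the HC5 percentile and the SSD assessment factor
  are implementation defaults in `pnec_config()`, chosen to match common
  regulatory practice — they are configuration, not fixed constants.
  Chronic data take precedence over acute when both exist.
* **ecoTTC.** A log-normal is fitted to the PNECs of a chemical group and
  the threshold is its 5th percentile (configurable `p`, minimum group
  size 5).
* **CTD.** Identical machinery applied to per-chemical toxicity values for
  one fixed biological receiver; the two tools deliberately share one
  fitting core so they cannot drift apart.

Uncertainty is quantified by a parametric bootstrap (1000 resamples,
explicit seed, 2.5/97.5 percentile intervals). All seeded code paths
restore the caller's RNG state.

## The synthetic-data generator

`generate_dataset()` emulates the shape of a merged multi-source effects
table: per-chemical log-normal effect concentrations (locations drawn from
[−1, 2] log10 mg/L, scale σ = 0.4) over 12 organic chemicals and a
20-taxon freshwater/saltwater taxonomy spanning all four relevant trophic
levels plus deliberately irrelevant entries (a macrophyte, a fungus, a
family-level and a mixed-community name) and a genus-level taxon that must
be *retained*. Units are mixed (mg/L, µg/L, mmol/L) so conversion is
exercised on every run. Into this baseline it plants, each on its own
dedicated chemical so that group means stay fully controlled: exact
duplicate pairs; outliers for each of the three rules; sub-24-h,
qualifier-bearing and off-whitelist records; bare-ion salts (NaCl, KCl,
NH₄Cl, NaOH); six dissociable metal salts with known dummy-CAS
assignments; and six records at ≥ 5× solubility. The manifest lists every
planted record id, and the end-to-end test requires the pipeline's
removals and flags to equal it *exactly* — no tolerance.

Two design rules make that exactness honest rather than fragile. First,
baseline draws are truncated at ±3σ (±1.2 log10 units), which bounds any
unplanned within-group spread below the 3-order threshold, so false
positives are impossible by construction rather than improbable. Second,
outliers are planted with a margin of at least 0.3 log10 units beyond
their inclusive threshold (e.g. the species-rule plant sits at distance
3.5), so floating-point evaluation at the boundary cannot flip an outcome;
exact-threshold behavior is exercised only by dedicated boundary tests
built from values whose log10 is exactly representable. The default
scenario (1000 baseline records plus plants, ~1266 rows) curates in a few
seconds; the oracle-equivalence checks use 200 random tables of ≤ 200
records.

What passing these tests shows — and what it does not. The generator
produces clean canonical structures, one habitat per taxon and
well-behaved log-normal noise. It does not mimic real-world pathologies
such as near-duplicate citations with variant spellings, source-specific
column dialects beyond the mapping layer, censored-data SSDs, or the true
frequency composition of species and chemical classes. Green tests
demonstrate that the rules are implemented exactly as specified, not that
the rules themselves are sufficient for any particular real data source.

## Degenerate inputs and tie-breaks

* Desalting keeps the largest organic fragment: carbon-containing
  fragments first, then most heavy atoms, then most total atoms (so
  hydroxide outranks a bare metal counter-ion), then lexicographic
  canonical SMILES. The final tie-break is arbitrary but fixed —
  determinism is the contract. Canonicalization itself is delegated to
  the Open Babel backend (via ChemmineOB); invalid SMILES yield a
  structure error that flags the chemical instead of crashing the run.
* A two-record group is never evaluated by any outlier rule, regardless
  of spread; a single-record species cannot trigger the species rule.
* `fit_lognormal` on identical values returns σ = 0 and degenerate
  quantiles equal to the common value; fewer than two values is an
  insufficient-data error, as is an ecoTTC/CTD group below the minimum
  size.
* Missing water solubility logs a warning and leaves the flag `FALSE`;
  it never removes a record.
* Written outputs are byte-stable: fixed column order, rows sorted by
  (cas, latin_name, record_id) with radix ordering, floats at 10
  significant digits.

## Known limitations

* The solubility comparator is inclusive (≥ 5×) by default and
  configurable, since "greater than 5×" and "≥ 5-fold" both circulate in
  practice.
* The dummy-metal rule engine handles dissociable single-metal salts
  drawn as ion fragments; covalent organometallics are never grouped, and
  "caustic or highly reactive" is undecidable from structure, so it is an
  explicit CAS exclusion list plus a curated override table (the override
  wins over the engine).
* Category flags are computed from the desalted structure, so a stripped
  metal counter-ion no longer sets the heavy-metal flag for the parent
  salt; metal content of the whole compound remains visible through the
  dummy-CAS assignment.
* Duplicate detection is exact-match only; near-duplicates arising from
  citation variants are out of scope.
* Idempotence of the full pipeline (re-curating its own output changes
  nothing) holds on data whose outlier groups shrink below the evaluation
  minima after removal — as in the planted scenarios; it is not a theorem
  for arbitrary data, because removing a record shifts the remaining
  geometric means.
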