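# Distributional analysis tools built on species geometric means and
# log10-scale normal fits: PNEC calculator (assessment-factor ladder or
# SSD HC5 route), ecoTTC distribution over a group's PNECs, and chemical
# toxicity distribution (CTD) over chemicals for a fixed receiver. The
# ecoTTC and CTD tools share one fitting core.

#' Species geometric means for one chemical
#'
#' Aggregates curated, designated records to one row per (species,
#' designation) with the geometric mean of the effect values — the
#' aggregation unit for every downstream distribution.
#'
#' @param records Curated records for a single chemical.
#' @return Tibble with `latin_name`, `trophic_level`, `designation`,
#'   `geomean` (mg/L) and `n`.
#' @export
species_geomeans <- function(records) {
  records <- as_tibble(records)
  if (nrow(records) == 0) {
    return(tibble(latin_name = character(), trophic_level = character(),
                  designation = character(), geomean = numeric(),
                  n = integer()))
  }
  records %>%
    group_by(.data$latin_name, .data$trophic_level, .data$designation) %>%
    summarise(geomean = geometric_mean(.data$effect_value),
              n = dplyr::n(), .groups = "drop")
}

#' Fit a log-normal distribution on the log10 scale
#'
#' `mu` is the mean and `sigma` the sample standard deviation (n-1
#' denominator, the common SSD convention) of the log10-transformed
#' values. Optional parametric bootstrap confidence intervals for a set of
#' quantiles are seeded and reported as 2.5/97.5 percentiles.
#'
#' @param values Positive concentrations, length >= 2.
#' @param seed Integer seed for the bootstrap.
#' @param ci_p Quantile fractions for which bootstrap CIs are computed,
#'   or `NULL` to skip the bootstrap.
#' @param n_boot Number of parametric bootstrap resamples (default 1000).
#' @return Object of class `dist_fit` with fields `mu`, `sigma`, `n`,
#'   `ci` (tibble or `NULL`) and `seed`.
#' @export
fit_lognormal <- function(values, seed = 1L, ci_p = NULL, n_boot = 1000L) {
  if (length(values) < 2) {
    abort("log-normal fit requires at least 2 values",
          class = "toxsift_insufficient_data")
  }
  if (anyNA(values) || any(values <= 0)) {
    abort("values must be positive and non-missing",
          class = "toxsift_domain_error")
  }
  lg <- log10(values)
  fit <- structure(list(mu = mean(lg), sigma = sd(lg),
                        n = length(values), ci = NULL,
                        seed = as.integer(seed)),
                   class = "dist_fit")
  if (!is.null(ci_p)) {
    fit$ci <- .bootstrap_ci(fit, ci_p, n_boot, seed)
  }
  fit
}

#' @export
print.dist_fit <- function(x, ...) {
  cat(sprintf("log-normal fit (log10 scale): mu = %.4g, sigma = %.4g, n = %d\n",
              x$mu, x$sigma, x$n))
  if (!is.null(x$ci)) print(as.data.frame(x$ci), row.names = FALSE)
  invisible(x)
}

# Parametric bootstrap: resample n values from the fitted log-normal,
# refit, and take the 2.5/97.5 percentiles of each requested quantile.
.bootstrap_ci <- function(fit, ci_p, n_boot, seed) {
  est <- with_preserved_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      lg <- rnorm(fit$n, fit$mu, fit$sigma)
      vapply(ci_p, function(p) 10^(mean(lg) + qnorm(p) * sd(lg)), numeric(1))
    }, numeric(length(ci_p)))
  })
  est <- matrix(est, nrow = length(ci_p))
  tibble(
    p = ci_p,
    lower = apply(est, 1, quantile, probs = 0.025, names = FALSE),
    upper = apply(est, 1, quantile, probs = 0.975, names = FALSE)
  )
}

#' Hazard quantile of a fitted distribution
#'
#' `10^(mu + z_p * sigma)` — e.g. the HC5 of a species sensitivity
#' distribution at `p = 0.05`.
#'
#' @param fit A `dist_fit`.
#' @param p Fraction in (0, 1).
#' @return Concentration in mg/L.
#' @export
hazard_quantile <- function(fit, p) {
  if (!is.numeric(p) || any(p <= 0) || any(p >= 1)) {
    abort("p must lie strictly inside (0, 1)", class = "toxsift_domain_error")
  }
  10^(fit$mu + qnorm(p) * fit$sigma)
}

#' PNEC configuration
#'
#' Assessment-factor ladder and SSD settings. Defaults follow the standard
#' regulatory convention: an acute-only base set receives AF 1000 on the
#' lowest species geometric mean; chronic values covering 1/2/3 trophic
#' levels receive AF 100/50/10; when at least `min_ssd_points` species
#' geometric means are available an SSD is fitted and PNEC = HC5 / `ssd_af`.
#'
#' @param af_acute AF for acute-only data (default 1000).
#' @param af_chronic AFs for chronic data covering 1, 2, >=3 trophic levels.
#' @param min_ssd_points Species geomeans needed for the SSD route
#'   (default 8).
#' @param ssd_af AF applied to the HC5 (default 5).
#' @param ssd_p SSD quantile (default 0.05).
#' @return List of settings.
#' @export
pnec_config <- function(af_acute = 1000, af_chronic = c(100, 50, 10),
                        min_ssd_points = 8, ssd_af = 5, ssd_p = 0.05) {
  list(af_acute = af_acute, af_chronic = af_chronic,
       min_ssd_points = min_ssd_points, ssd_af = ssd_af, ssd_p = ssd_p)
}

#' Compute a predicted-no-effect concentration for one chemical
#'
#' Uses chronic species geometric means when any exist, acute ones
#' otherwise. With at least `min_ssd_points` species geomeans the SSD route
#' is taken: a log-normal is fitted and PNEC = hazard quantile at `ssd_p`
#' divided by `ssd_af`. Otherwise the assessment-factor route divides the
#' minimum species geomean by the ladder AF.
#'
#' @param records Curated, designated records for one chemical.
#' @param config A [pnec_config()].
#' @param seed Seed for the SSD bootstrap.
#' @return Object of class `pnec_result`: `cas`, `pnec` (mg/L), `method`,
#'   `assessment_factor`, `basis` (minimum species geomean row or
#'   `dist_fit`), `trophic_coverage`.
#' @export
compute_pnec <- function(records, config = pnec_config(), seed = 1L) {
  records <- as_tibble(records)
  usable <- records %>% filter(.data$designation %in% c("acute", "chronic"))
  if (nrow(usable) == 0) {
    abort("no usable (acute or chronic) records for PNEC derivation",
          class = "toxsift_insufficient_data")
  }
  cas <- usable$cas[1]
  gm <- species_geomeans(usable)
  chronic <- gm %>% filter(.data$designation == "chronic")
  basis_set <- if (nrow(chronic) > 0) chronic else
    gm %>% filter(.data$designation == "acute")

  if (nrow(basis_set) >= config$min_ssd_points) {
    fit <- fit_lognormal(basis_set$geomean, seed = seed,
                         ci_p = config$ssd_p)
    hc <- hazard_quantile(fit, config$ssd_p)
    res <- list(cas = cas, pnec = hc / config$ssd_af, method = "ssd",
                assessment_factor = config$ssd_af, basis = fit,
                trophic_coverage = sort(unique(basis_set$trophic_level)))
  } else {
    n_trophic <- length(unique(basis_set$trophic_level))
    af <- if (nrow(chronic) > 0) {
      config$af_chronic[min(n_trophic, length(config$af_chronic))]
    } else {
      config$af_acute
    }
    i_min <- which.min(basis_set$geomean)
    res <- list(cas = cas, pnec = basis_set$geomean[i_min] / af,
                method = "assessment_factor", assessment_factor = af,
                basis = basis_set[i_min, , drop = FALSE],
                trophic_coverage = sort(unique(basis_set$trophic_level)))
  }
  structure(res, class = "pnec_result")
}

#' @export
print.pnec_result <- function(x, ...) {
  cat(sprintf("PNEC for CAS %s: %.6g mg/L (%s, AF = %g)\n",
              x$cas, x$pnec, x$method, x$assessment_factor))
  invisible(x)
}

# Shared fitting core of the ecoTTC and CTD tools.
.group_distribution <- function(values, p, seed, min_group, n_boot = 1000L) {
  if (length(values) < min_group) {
    abort(sprintf("group too small: %d values (minimum %d)",
                  length(values), min_group),
          class = "toxsift_insufficient_data")
  }
  fit <- fit_lognormal(values, seed = seed, ci_p = p, n_boot = n_boot)
  list(fit = fit, threshold = hazard_quantile(fit, p))
}

#' ecoTTC distribution over a chemical group's PNECs
#'
#' Fits a log-normal to the PNEC values of a group of chemicals and
#' returns the de minimis threshold at quantile `p` (default 0.05) with a
#' seeded parametric bootstrap CI.
#'
#' @param pnecs A list of `pnec_result` objects or a numeric vector of
#'   PNECs (mg/L).
#' @param p Threshold quantile (default 0.05).
#' @param seed Bootstrap seed.
#' @param min_group Minimum group size (default 5).
#' @return List with `fit` (a `dist_fit`) and `threshold` (mg/L).
#' @export
ecottc_distribution <- function(pnecs, p = 0.05, seed = 1L, min_group = 5L) {
  values <- if (is.numeric(pnecs)) pnecs else
    vapply(pnecs, function(x) x$pnec, numeric(1))
  .group_distribution(values, p, seed, min_group)
}

#' Chemical toxicity distribution for a fixed receiver
#'
#' Same machinery as [ecottc_distribution()], applied to per-chemical
#' toxicity summaries (e.g. species geomeans of a single species, or
#' trophic-level summaries) rather than PNECs.
#'
#' @param values Per-chemical toxicity values (mg/L) for one species or
#'   trophic group.
#' @inheritParams ecottc_distribution
#' @return List with `fit` and `percentile` (mg/L).
#' @export
ctd <- function(values, p = 0.05, seed = 1L, min_group = 5L) {
  out <- .group_distribution(values, p, seed, min_group)
  list(fit = out$fit, percentile = out$threshold)
}
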