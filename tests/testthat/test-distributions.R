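test_that("species_geomeans aggregates per (species, designation)", {
  recs <- tibble::tibble(
    cas = "111",
    latin_name = c("Danio rerio", "Danio rerio", "Daphnia magna"),
    trophic_level = c("fish", "fish", "invertebrate"),
    designation = c("acute", "acute", "chronic"),
    effect_value = c(2, 8, 5))
  gm <- species_geomeans(recs)
  expect_equal(nrow(gm), 2)
  danio <- gm[gm$latin_name == "Danio rerio", ]
  expect_equal(danio$geomean, 4)
  expect_equal(danio$n, 2L)
  single <- gm[gm$latin_name == "Daphnia magna", ]
  expect_equal(single$geomean, 5)
  expect_equal(nrow(species_geomeans(recs[0, ])), 0)
})

test_that("fit_lognormal uses log10 mean and n-1 standard deviation", {
  fit <- fit_lognormal(c(10, 10, 10))
  expect_equal(fit$mu, 1)
  expect_equal(fit$sigma, 0)
  fit2 <- fit_lognormal(c(1, 10, 100))
  expect_equal(fit2$mu, 1)
  expect_equal(fit2$sigma, 1)   # sd of {0,1,2} with n-1 denominator
  expect_error(fit_lognormal(5), class = "toxsift_insufficient_data")
  expect_error(fit_lognormal(c(-1, 2)), class = "toxsift_domain_error")
})

test_that("hazard_quantile matches the closed form", {
  fit0 <- structure(list(mu = 1, sigma = 0), class = "dist_fit")
  expect_equal(hazard_quantile(fit0, 0.05), 10)
  fit1 <- structure(list(mu = 1, sigma = 1), class = "dist_fit")
  expect_equal(hazard_quantile(fit1, 0.5), 10)
  expect_equal(hazard_quantile(fit1, 0.05), 10^(1 + qnorm(0.05)))
  expect_equal(hazard_quantile(fit1, 0.05), 0.2265, tolerance = 1e-3)
  expect_error(hazard_quantile(fit1, 0), class = "toxsift_domain_error")
  expect_error(hazard_quantile(fit1, 1), class = "toxsift_domain_error")
})

test_that("hazard_quantile is monotone in p, mu and sigma", {
  f <- function(mu, sigma) structure(list(mu = mu, sigma = sigma),
                                     class = "dist_fit")
  expect_lt(hazard_quantile(f(0, 1), 0.05), hazard_quantile(f(0, 1), 0.10))
  expect_lt(hazard_quantile(f(0, 1), 0.05), hazard_quantile(f(1, 1), 0.05))
  # decreasing in sigma below the median
  expect_gt(hazard_quantile(f(0, 0.5), 0.05), hazard_quantile(f(0, 2), 0.05))
})

pnec_recs <- function(geomeans, designation, trophic = NULL) {
  n <- length(geomeans)
  tibble::tibble(
    cas = "111",
    latin_name = sprintf("Species %02d", seq_len(n)),
    trophic_level = trophic %||% rep("fish", n),
    designation = rep_len(designation, n),
    effect_value = geomeans)
}

test_that("compute_pnec applies the assessment-factor ladder", {
  # acute-only base set: lowest species geomean / 1000
  acute <- pnec_recs(c(1, 5, 20), "acute")
  r <- compute_pnec(acute)
  expect_equal(r$pnec, 0.001)
  expect_equal(r$method, "assessment_factor")
  expect_equal(r$assessment_factor, 1000)

  # chronic over three trophic levels: AF 10
  chronic <- pnec_recs(c(0.1, 2, 3), "chronic",
                       trophic = c("fish", "invertebrate", "algae"))
  r3 <- compute_pnec(chronic)
  expect_equal(r3$pnec, 0.01)
  expect_equal(r3$assessment_factor, 10)

  # chronic limited to one / two trophic levels: AF 100 / 50
  r1 <- compute_pnec(pnec_recs(c(0.5, 1), "chronic"))
  expect_equal(r1$assessment_factor, 100)
  r2 <- compute_pnec(pnec_recs(c(0.5, 1), "chronic",
                               trophic = c("fish", "algae")))
  expect_equal(r2$assessment_factor, 50)

  expect_error(compute_pnec(pnec_recs(1, "unassignable")),
               class = "toxsift_insufficient_data")
})

test_that("compute_pnec switches to the SSD route with enough species", {
  flat <- pnec_recs(rep(10, 10), "acute")
  r <- compute_pnec(flat)
  expect_equal(r$method, "ssd")
  expect_equal(r$assessment_factor, 5)
  expect_equal(r$pnec, 2)  # sigma = 0 so HC5 = 10, PNEC = 10/5
  expect_s3_class(r$basis, "dist_fit")
})

test_that("assessment-factor PNEC is monotone under removing the minimum", {
  recs <- pnec_recs(c(0.2, 1, 4), "acute")
  full <- compute_pnec(recs)
  dropped <- compute_pnec(recs[-1, ])
  expect_gte(dropped$pnec, full$pnec)
})

test_that("PNECs and thresholds scale with the input units", {
  recs <- pnec_recs(c(0.3, 2, 7), "acute")
  k <- 1000
  scaled <- recs
  scaled$effect_value <- scaled$effect_value * k
  expect_equal(compute_pnec(scaled)$pnec, k * compute_pnec(recs)$pnec)

  vals <- 10^seq(-2, 1, length.out = 8)
  t1 <- ecottc_distribution(vals, seed = 3)
  t2 <- ecottc_distribution(vals * k, seed = 3)
  expect_equal(t2$threshold, k * t1$threshold)
})

test_that("ecoTTC threshold sits below the median for spread groups", {
  pnecs <- 10^seq(log10(0.001), log10(10), length.out = 20)
  res <- ecottc_distribution(pnecs, p = 0.05, seed = 1)
  expect_lt(res$threshold, median(pnecs))
  # all-equal group: threshold equals the common value
  same <- ecottc_distribution(rep(0.05, 6), seed = 1)
  expect_equal(same$threshold, 0.05)
  expect_error(ecottc_distribution(c(1, 2), seed = 1),
               class = "toxsift_insufficient_data")
})

test_that("ecoTTC and CTD share the same fitting core", {
  vals <- 10^rnorm(50, -1, 0.7)
  a <- ecottc_distribution(vals, p = 0.05, seed = 11)
  b <- ctd(vals, p = 0.05, seed = 11)
  expect_identical(a$fit$mu, b$fit$mu)
  expect_identical(a$fit$sigma, b$fit$sigma)
  expect_identical(a$threshold, b$percentile)
  expect_error(ctd(1, seed = 1), class = "toxsift_insufficient_data")
})

test_that("parameter recovery improves with sample size", {
  err <- vapply(c(100, 10000), function(n) {
    vals <- generate_lognormal_sample(-2, 0.5, n, seed = 5)
    fit <- fit_lognormal(vals)
    abs(fit$mu - (-2)) + abs(fit$sigma - 0.5)
  }, numeric(1))
  expect_lt(err[2], err[1])
  vals <- generate_lognormal_sample(-2, 0.5, 10000, seed = 5)
  fit <- fit_lognormal(vals)
  expect_lt(abs(fit$mu + 2), 0.05)
  expect_lt(abs(fit$sigma - 0.5), 0.05)
})

test_that("bootstrap confidence intervals are seeded and bracket the estimate", {
  vals <- generate_lognormal_sample(0, 1, 200, seed = 8)
  f1 <- fit_lognormal(vals, seed = 4, ci_p = 0.05)
  f2 <- fit_lognormal(vals, seed = 4, ci_p = 0.05)
  expect_identical(f1$ci, f2$ci)
  hc5 <- hazard_quantile(f1, 0.05)
  expect_lt(f1$ci$lower, hc5)
  expect_gt(f1$ci$upper, hc5)
})
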