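test_that("latent correlation solver matches closed forms", {
  # independence
  expect_equal(solve_latent_correlation(0.5, 0.5, 1), 0)
  # at prevalence 0.5/0.5 the joint cell is 1/4 + asin(r)/(2*pi):
  # r = 0.5 gives cells (1/3, 1/6, 1/6, 1/3), OR = 4
  expect_equal(solve_latent_correlation(0.5, 0.5, 4), 0.5, tolerance = 1e-5)
  # and the negative side: OR = 1/4 should give r = -0.5 by symmetry
  expect_equal(solve_latent_correlation(0.5, 0.5, 1 / 4), -0.5,
               tolerance = 1e-5)
})

test_that("latent correlation solver agrees with a brute-force grid oracle", {
  # oracle: joint cell via mvtnorm's bivariate-normal orthant probability,
  # scanned over a grid of r (independent of the bisection route),
  # coarse pass then a fine pass around the coarse optimum
  pa <- 0.2; pb <- 0.3; target <- 2
  a <- qnorm(1 - pa); b <- qnorm(1 - pb)
  or_at <- function(r) {
    p11 <- mvtnorm::pmvnorm(lower = c(a, b), upper = c(Inf, Inf),
                            corr = matrix(c(1, r, r, 1), 2))[1]
    (p11 * (1 - pa - pb + p11)) / ((pa - p11) * (pb - p11))
  }
  coarse <- seq(-0.95, 0.95, by = 0.01)
  r0 <- coarse[which.min(abs(vapply(coarse, or_at, numeric(1)) - target))]
  fine <- seq(r0 - 0.01, r0 + 0.01, by = 1e-4)
  r_oracle <- fine[which.min(abs(vapply(fine, or_at, numeric(1)) - target))]
  expect_equal(solve_latent_correlation(pa, pb, target), r_oracle,
               tolerance = 1e-4)
})

test_that("solver validates inputs and handles extreme targets", {
  expect_error(solve_latent_correlation(0, 0.5, 2))
  expect_error(solve_latent_correlation(0.5, 1, 2))
  expect_error(solve_latent_correlation(0.5, 0.5, -1))
  # an extreme but achievable OR drives r toward (not past) the boundary
  r <- solve_latent_correlation(0.3, 0.3, 1e6)
  expect_true(r > 0.99 && r < 1)
})

test_that("marginal prevalences concentrate around their targets", {
  cfg <- cohort_config(n_patients = 10000, years = 2024,
                       codes = c(I10 = 0.3), seed = 11)
  ind <- sample_disease_indicators(cfg)
  freq <- mean(ind$I10)
  expect_lt(abs(freq - 0.3), 3 * sqrt(0.3 * 0.7 / 10000))
})

test_that("planted odds ratios are recovered empirically", {
  cfg <- cohort_config(
    n_patients = 50000, years = 2024, codes = c(A01 = 0.5, B02 = 0.5),
    associations = tibble::tibble(code_a = "A01", code_b = "B02",
                                  odds_ratio = 4),
    seed = 101)
  ind <- sample_disease_indicators(cfg)
  expect_true(empirical_or(ind$A01, ind$B02) >= 3.7 &&
                empirical_or(ind$A01, ind$B02) <= 4.3)
})

test_that("unplanted pairs stay independent", {
  cfg <- cohort_config(n_patients = 5000, years = 2024,
                       codes = c(A01 = 0.4, B02 = 0.4), seed = 5)
  ind <- sample_disease_indicators(cfg)
  expect_lt(abs(cor(rank(ind$A01), rank(ind$B02))), 0.05)
})

test_that("inconsistent association structure is caught as non-PD", {
  # a 3-cycle of extreme ORs: strong + with A-B and A-C but strong - B-C
  cfg <- cohort_config(
    n_patients = 10, years = 2024,
    codes = c(A01 = 0.5, B02 = 0.5, C03 = 0.5),
    associations = tibble::tibble(
      code_a = c("A01", "A01", "B02"), code_b = c("B02", "C03", "C03"),
      odds_ratio = c(500, 500, 1 / 500)),
    seed = 1)
  expect_error(sample_disease_indicators(cfg), "positive definite")
  cfg$repair_pd <- TRUE
  expect_silent(ind <- sample_disease_indicators(cfg))
  expect_equal(nrow(ind), 10)
})

test_that("generated claims respect demographics, dates and emission model", {
  cfg <- cohort_config(n_patients = 2000, years = 2021:2022,
                       codes = c(I10 = 0.5),
                       encounters_per_condition = 2,
                       disruption = c("2022" = 0.5), seed = 3)
  claims <- simulate_cohort(cfg)
  expect_s3_class(claims, "claims_tbl")
  yr <- as.integer(format(claims$service_date, "%Y"))
  expect_true(all(yr %in% 2021:2022))
  expect_true(all(claims$age >= 0 & claims$age <= 90))
  expect_true(all(claims$sex %in% c("F", "M")))
  # demographics fixed per patient across years
  per_pat <- dplyr::n_distinct(paste(claims$patient_id, claims$age, claims$sex))
  expect_equal(per_pat, dplyr::n_distinct(claims$patient_id))
  # disruption halves emission: 2022 claim count near half of 2021's
  expect_lt(sum(yr == 2022) / sum(yr == 2021), 0.6)
  expect_gt(sum(yr == 2022) / sum(yr == 2021), 0.4)
})

test_that("generation is bit-identical under a fixed seed", {
  cfg <- default_cohort_config(n_patients = 300, seed = 9)
  c1 <- simulate_cohort(cfg)
  c2 <- simulate_cohort(cfg)
  expect_identical(tibble::as_tibble(c1), tibble::as_tibble(c2))
  f1 <- tempfile(); f2 <- tempfile()
  write_claims(c1, f1); write_claims(c2, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("a present condition can emit zero claims under heavy disruption", {
  cfg <- cohort_config(n_patients = 500, years = 2024,
                       codes = c(I10 = 0.8),
                       encounters_per_condition = 0.2, seed = 21)
  ind <- sample_disease_indicators(cfg)
  claims <- generate_claims(ind, cfg)
  expect_lt(dplyr::n_distinct(claims$patient_id), sum(ind$I10))
})
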