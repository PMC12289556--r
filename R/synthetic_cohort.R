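#' Upper-orthant probability of a standard bivariate normal
#'
#' `P(X > a, Y > b)` for standard normal margins with correlation `r`,
#' evaluated by 1-D quadrature of `phi(x) * Phi((r*x - b)/sqrt(1-r^2))`
#' over `x > a`. The copula solver bisects on this evaluator.
#'
#' @param a,b Thresholds.
#' @param r Correlation in `[-1, 1]`.
#' @return Probability in `[0, 1]`.
#' @keywords internal
bvn_upper_prob <- function(a, b, r) {
  if (abs(r) >= 1 - 1e-12) {
    if (r > 0) return(1 - stats::pnorm(max(a, b)))
    return(max(0, stats::pnorm(-b) - stats::pnorm(a)))
  }
  s <- sqrt(1 - r^2)
  f <- function(x) stats::dnorm(x) * stats::pnorm((r * x - b) / s)
  stats::integrate(f, lower = a, upper = Inf,
                   rel.tol = 1e-11, abs.tol = 1e-13)$value
}

or_from_cells <- function(p11, pa, pb) {
  # clamp to the Frechet bounds so quadrature round-off near |r| = 1 cannot
  # produce negative cells
  p11 <- min(max(p11, max(0, pa + pb - 1)), min(pa, pb))
  p10 <- pa - p11
  p01 <- pb - p11
  p00 <- 1 - pa - pb + p11
  if (p11 <= 0 || p00 <= 0) return(0)
  if (p10 <= 0 || p01 <= 0) return(Inf)
  (p11 * p00) / (p10 * p01)
}

#' Latent correlation matching a target odds ratio
#'
#' Finds the correlation `r` of a standard bivariate normal such that
#' thresholding each margin at its `(1 - prevalence)` quantile yields a
#' 2x2 joint distribution with the requested odds ratio. This is the
#' calibration step of the Gaussian-copula (latent-threshold) generator:
#' the odds ratio is a monotone function of `r`, so `r` is found by
#' bisection against [bvn_upper_prob()].
#'
#' @param prev_a,prev_b Marginal prevalences in (0, 1).
#' @param target_or Target odds ratio (> 0). `target_or = 1` gives `r = 0`.
#' @param tol Tolerance on the achieved odds ratio (default `1e-6`).
#' @return Latent correlation in (-1, 1).
#' @examples
#' solve_latent_correlation(0.5, 0.5, 4)  # 0.5 (closed form via arcsin)
#' @export
solve_latent_correlation <- function(prev_a, prev_b, target_or, tol = 1e-6) {
  stopifnot(prev_a > 0, prev_a < 1, prev_b > 0, prev_b < 1, target_or > 0)
  if (abs(target_or - 1) < .Machine$double.eps^0.5) return(0)
  a <- stats::qnorm(1 - prev_a)
  b <- stats::qnorm(1 - prev_b)
  or_at <- function(r) or_from_cells(bvn_upper_prob(a, b, r), prev_a, prev_b)
  lo <- -1 + 1e-9
  hi <- 1 - 1e-9
  or_lo <- or_at(lo)
  or_hi <- or_at(hi)
  if (target_or <= or_lo || target_or >= or_hi) {
    stop(sprintf(
      "no latent correlation in (-1, 1) achieves OR = %g at prevalences (%g, %g); achievable range is (%.4g, %.4g)",
      target_or, prev_a, prev_b, or_lo, or_hi), call. = FALSE)
  }
  # bisect on log-OR, which is monotone increasing in r
  target <- log(target_or)
  for (i in seq_len(200)) {
    mid <- (lo + hi) / 2
    v <- log(or_at(mid))
    if (abs(exp(v) - target_or) < tol) return(mid)
    if (v < target) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Synthetic cohort configuration
#'
#' Bundles everything the claims generator needs: the code vocabulary with
#' per-code annual prevalences, the planted pairwise associations (odds
#' ratios on patient-year presence), claim-emission intensity, per-year
#' utilization multipliers, demographics and the seed. Presence is drawn
#' independently per patient-year from the Gaussian copula; claims are then
#' emitted per present condition.
#'
#' @param n_patients Number of patients.
#' @param years Integer vector of calendar years.
#' @param codes Named numeric vector: names are ICD-10 codes (any dialect;
#'   normalized on the way in), values are annual prevalences in (0, 1).
#' @param associations Tibble/data frame with columns `code_a`, `code_b`,
#'   `odds_ratio` (one row per planted pair); may be empty.
#' @param encounters_per_condition Mean claims emitted per present
#'   condition per year (Poisson mean), before disruption scaling.
#' @param disruption Named numeric vector mapping year (as name) to an
#'   emission multiplier in (0, 1]; unnamed years default to 1.
#' @param age_mean,age_sd Age distribution (normal truncated to [0, 90]).
#' @param female_fraction Probability a patient is female.
#' @param seed Integer seed; fixed seed gives bit-identical output.
#' @param repair_pd If `TRUE`, a non-positive-definite latent correlation
#'   matrix is repaired by clipping eigenvalues at `1e-8` and rescaling to
#'   unit diagonal; if `FALSE` (default), it is an error.
#' @return A validated list of class `cohort_config`.
#' @export
cohort_config <- function(n_patients,
                          years = 2020:2024,
                          codes,
                          associations = NULL,
                          encounters_per_condition = 2,
                          disruption = NULL,
                          age_mean = 53.8, age_sd = 21.7,
                          female_fraction = 0.574,
                          seed = 1L,
                          repair_pd = FALSE) {
  stopifnot(n_patients >= 1, length(years) >= 1,
            encounters_per_condition >= 0,
            female_fraction >= 0, female_fraction <= 1, age_sd > 0)
  names(codes) <- normalize_icd10(names(codes))
  if (any(codes <= 0 | codes >= 1)) {
    stop("all prevalences must lie in (0, 1)", call. = FALSE)
  }
  if (anyDuplicated(names(codes))) stop("duplicate codes", call. = FALSE)
  if (is.null(associations) || NROW(associations) == 0) {
    associations <- tibble::tibble(code_a = character(), code_b = character(),
                                   odds_ratio = numeric())
  } else {
    associations <- tibble::as_tibble(associations)
    associations$code_a <- normalize_icd10(associations$code_a)
    associations$code_b <- normalize_icd10(associations$code_b)
    stopifnot(all(associations$odds_ratio > 0))
    if (any(associations$code_a == associations$code_b)) {
      stop("association pairs must involve two distinct codes", call. = FALSE)
    }
    missing <- setdiff(c(associations$code_a, associations$code_b), names(codes))
    if (length(missing) > 0) {
      stop("association codes not in vocabulary: ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    key <- paste(pmin(associations$code_a, associations$code_b),
                 pmax(associations$code_a, associations$code_b))
    if (anyDuplicated(key)) stop("duplicate association pairs", call. = FALSE)
  }
  disr <- stats::setNames(rep(1, length(years)), years)
  if (!is.null(disruption)) {
    if (any(disruption <= 0 | disruption > 1)) {
      stop("disruption multipliers must lie in (0, 1]", call. = FALSE)
    }
    disr[names(disruption)] <- disruption
  }
  structure(list(
    n_patients = as.integer(n_patients), years = as.integer(years),
    codes = codes, associations = associations,
    encounters_per_condition = encounters_per_condition,
    disruption = disr, age_mean = age_mean, age_sd = age_sd,
    female_fraction = female_fraction, seed = as.integer(seed),
    repair_pd = isTRUE(repair_pd)
  ), class = "cohort_config")
}

#' Default study-conditions cohort configuration
#'
#' The package's reference synthetic cohort: the ten focal respiratory and
#' systemic codes at realistic annual claims prevalences, comorbidity
#' structure planted around the two respiratory hubs (COPD J44.9 and asthma
#' J45.909) and the cardiometabolic cluster, demographics matching a
#' middle-aged, moderately female claims population, five study years and a
#' mid-period utilization dip in 2022.
#'
#' @param n_patients Number of patients (default 5000).
#' @param seed Integer seed.
#' @return A `cohort_config`.
#' @export
default_cohort_config <- function(n_patients = 5000, seed = 1L) {
  codes <- c(I10 = 0.25, E785 = 0.22, F419 = 0.12, E119 = 0.10, K219 = 0.10,
             J45909 = 0.08, J449 = 0.06, J189 = 0.02, J441 = 0.015,
             J9601 = 0.01)
  assoc <- tibble::tribble(
    ~code_a,  ~code_b, ~odds_ratio,
    "J449",   "E785",  3.0,
    "J449",   "E119",  3.0,
    "J449",   "F419",  2.5,
    "J449",   "I10",   2.5,
    "J449",   "J441",  4.0,
    "J45909", "E785",  2.5,
    "J45909", "F419",  3.0,
    "J45909", "K219",  2.5,
    "J45909", "I10",   2.0,
    "E785",   "I10",   4.0,
    "E785",   "E119",  3.5,
    "E119",   "I10",   3.0
  )
  cohort_config(n_patients = n_patients, years = 2020:2024, codes = codes,
                associations = assoc, encounters_per_condition = 2,
                disruption = c("2022" = 0.6), seed = seed)
}

# Latent correlation matrix implied by the planted associations;
# unspecified pairs are 0 in latent space.
latent_correlation_matrix <- function(config) {
  codes <- names(config$codes)
  k <- length(codes)
  R <- diag(k)
  dimnames(R) <- list(codes, codes)
  if (nrow(config$associations) > 0) {
    for (i in seq_len(nrow(config$associations))) {
      a <- config$associations$code_a[i]
      b <- config$associations$code_b[i]
      r <- solve_latent_correlation(config$codes[[a]], config$codes[[b]],
                                    config$associations$odds_ratio[i])
      R[a, b] <- r
      R[b, a] <- r
    }
  }
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) {
    if (!config$repair_pd) {
      stop("latent correlation matrix is not positive definite; ",
           "offending pairs: ",
           paste(sprintf("%s-%s", config$associations$code_a,
                         config$associations$code_b), collapse = ", "),
           ". Set repair_pd = TRUE to clip eigenvalues.", call. = FALSE)
    }
    e <- eigen(R, symmetric = TRUE)
    vals <- pmax(e$values, 1e-8)
    R <- e$vectors %*% diag(vals) %*% t(e$vectors)
    d <- sqrt(diag(R))
    R <- R / tcrossprod(d)
    dimnames(R) <- list(codes, codes)
  }
  R
}

# Draw n iid rows from N(0, R) via the Cholesky factor.
rmvn_chol <- function(n, R) {
  k <- ncol(R)
  L <- chol(R)
  matrix(stats::rnorm(n * k), n, k) %*% L
}

#' Sample patient-year disease indicators
#'
#' Draws, for every patient and study year, a latent multivariate normal
#' with the correlation structure implied by the planted odds ratios, and
#' thresholds each code at its `(1 - prevalence)` quantile. Presence is
#' i.i.d. across patient-years given the prevalences (no carry-over of
#' disease state between years).
#'
#' @param config A [cohort_config()].
#' @return Tibble with `patient_id`, `year`, and one 0/1 column per code.
#' @export
sample_disease_indicators <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  R <- latent_correlation_matrix(config)
  codes <- names(config$codes)
  n <- config$n_patients * length(config$years)
  thresholds <- stats::qnorm(1 - unlist(config$codes))
  ind <- withr::with_seed(config$seed, {
    z <- rmvn_chol(n, R)
    matrix(as.integer(t(t(z) > thresholds)), n, length(codes),
           dimnames = list(NULL, codes))
  })
  out <- tibble::tibble(
    patient_id = rep(sprintf("P%06d", seq_len(config$n_patients)),
                     times = length(config$years)),
    year = rep(config$years, each = config$n_patients)
  )
  dplyr::bind_cols(out, tibble::as_tibble(ind))
}

# truncated-normal ages on [0, 90] by inverse-CDF sampling
rtruncnorm_age <- function(n, mean, sd, lo = 0, hi = 90) {
  plo <- stats::pnorm(lo, mean, sd)
  phi <- stats::pnorm(hi, mean, sd)
  stats::qnorm(stats::runif(n, plo, phi), mean, sd)
}

#' Generate a synthetic claims table from disease indicators
#'
#' For each (patient, year, present condition) the number of claims emitted
#' is Poisson with mean `encounters_per_condition * disruption[year]`; each
#' claim gets a uniformly random service date within the year and carries
#' that one condition as its primary diagnosis. A utilization shock (a
#' disruption multiplier below 1) therefore thins claims without altering
#' disease presence -- exactly the mechanism a mid-pandemic care dip
#' exercises. Demographics are sampled once per patient (age truncated
#' normal on [0, 90], sex Bernoulli on the female fraction) and held fixed
#' across years.
#'
#' @param indicators Output of [sample_disease_indicators()].
#' @param config The same [cohort_config()].
#' @return A `claims_tbl` (possibly with fewer patient-years represented
#'   than `indicators`, since a present condition may emit zero claims).
#' @export
generate_claims <- function(indicators, config) {
  stopifnot(inherits(config, "cohort_config"))
  codes <- names(config$codes)
  long <- tidyr::pivot_longer(indicators, dplyr::all_of(codes),
                              names_to = "code", values_to = "present")
  long <- dplyr::filter(long, .data$present == 1L)
  claims <- withr::with_seed(config$seed + 1L, {
    mult <- config$disruption[as.character(long$year)]
    n_claims <- stats::rpois(nrow(long), config$encounters_per_condition * mult)
    emitted <- long[rep.int(seq_len(nrow(long)), n_claims), c("patient_id", "year", "code")]
    year_start <- as.Date(paste0(emitted$year, "-01-01"))
    year_len <- as.integer(as.Date(paste0(emitted$year, "-12-31")) - year_start) + 1L
    emitted$service_date <- year_start +
      floor(stats::runif(nrow(emitted)) * year_len)
    patients <- sprintf("P%06d", seq_len(config$n_patients))
    demo <- tibble::tibble(
      patient_id = patients,
      age = as.integer(round(rtruncnorm_age(config$n_patients,
                                            config$age_mean, config$age_sd))),
      sex = ifelse(stats::runif(config$n_patients) < config$female_fraction,
                   "F", "M")
    )
    out <- dplyr::left_join(emitted, demo, by = "patient_id")
    out <- dplyr::arrange(out, .data$patient_id, .data$service_date, .data$code)
    tibble::tibble(
      patient_id = out$patient_id,
      service_date = out$service_date,
      diagnoses = as.list(out$code),
      age = out$age,
      sex = out$sex
    )
  })
  new_claims_tbl(claims, span = range(config$years),
                 load_report = list(n_read = nrow(claims), dropped = 0L))
}

#' Simulate a full synthetic claims cohort
#'
#' Convenience wrapper: [sample_disease_indicators()] then
#' [generate_claims()] under one configuration.
#'
#' @param config A [cohort_config()].
#' @return A `claims_tbl`.
#' @export
simulate_cohort <- function(config) {
  generate_claims(sample_disease_indicators(config), config)
}
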