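# Independent oracles and small fixture builders shared across tests.

# mid-ranks computed from first principles (order + tie averaging),
# deliberately not via rank()
oracle_midrank <- function(x) {
  ord <- order(x)
  r <- numeric(length(x))
  i <- 1
  while (i <= length(x)) {
    j <- i
    while (j < length(x) && x[ord[j + 1]] == x[ord[i]]) j <- j + 1
    r[ord[i:j]] <- mean(i:j)
    i <- j + 1
  }
  r
}

# Pearson correlation via explicit sum formula
oracle_pearson <- function(a, b) {
  n <- length(a)
  num <- sum(a * b) - n * mean(a) * mean(b)
  den <- sqrt((sum(a^2) - n * mean(a)^2) * (sum(b^2) - n * mean(b)^2))
  num / den
}

# brute-force Spearman: rank by hand, then the Pearson sum formula
oracle_spearman <- function(x, y) {
  oracle_pearson(oracle_midrank(x), oracle_midrank(y))
}

# phi coefficient from the 2x2 contingency table of binary vectors
oracle_phi <- function(x, y) {
  n11 <- sum(x == 1 & y == 1); n10 <- sum(x == 1 & y == 0)
  n01 <- sum(x == 0 & y == 1); n00 <- sum(x == 0 & y == 0)
  (n11 * n00 - n10 * n01) /
    sqrt((n11 + n10) * (n01 + n00) * (n11 + n01) * (n10 + n00))
}

# direct-definition BH step-up: adjusted p_i = min_{j: p_j >= p_i over the
# step-up path} ... computed literally as min over ranks >= rank(i)
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- numeric(m)
  for (i in seq_len(m)) {
    rank_i <- which(ord == i)
    candidates <- vapply(rank_i:m, function(k) p[ord[k]] * m / k, numeric(1))
    adj[i] <- min(1, min(candidates))
  }
  adj
}

# brute-force patient-year co-occurrence by a double loop over entries
oracle_cooccurrence <- function(sets, codes) {
  entries <- unique(sets[, c("patient_id", "year")])
  k <- length(codes)
  m <- matrix(0L, k, k, dimnames = list(codes, codes))
  for (e in seq_len(nrow(entries))) {
    present <- sets$code[sets$patient_id == entries$patient_id[e] &
                           sets$year == entries$year[e]]
    present <- intersect(codes, present)
    for (a in present) for (b in present) m[a, b] <- m[a, b] + 1L
  }
  m
}

# empirical odds ratio of two binary vectors
empirical_or <- function(a, b) {
  (sum(a & b) * sum(!a & !b)) / (sum(a & !b) * sum(!a & b))
}

# small claims tibble fixture built in code
make_claims <- function(patient_id, date, codes, age = 50, sex = "F") {
  tbl <- tibble::tibble(
    patient_id = patient_id,
    service_date = as.Date(date),
    diagnoses = codes,
    age = as.integer(age),
    sex = sex
  )
  comorbnet:::new_claims_tbl(
    tbl, span = range(as.integer(format(tbl$service_date, "%Y"))))
}

# write a small claims CSV fixture and return its path
write_claims_fixture <- function(lines, file = tempfile(fileext = ".csv")) {
  writeLines(lines, file)
  file
}
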