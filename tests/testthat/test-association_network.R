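test_that("spearman rho matches hand cases and the rank-then-Pearson oracle", {
  expect_equal(spearman_association(c(0, 0, 1, 1), c(0, 0, 1, 1))$rho, 1)
  expect_equal(spearman_association(c(0, 1, 0, 1), c(0, 1, 1, 0))$rho, 0)
  set.seed(31)
  for (i in 1:200) {
    x <- rbinom(200, 1, runif(1, 0.2, 0.8))
    y <- rbinom(200, 1, runif(1, 0.2, 0.8))
    if (length(unique(x)) < 2 || length(unique(y)) < 2) next
    res <- spearman_association(x, y)
    expect_equal(res$rho, oracle_spearman(x, y), tolerance = 1e-12)
    expect_equal(res$rho, oracle_phi(x, y), tolerance = 1e-12)
  }
  # non-binary ordinal vectors against the oracle too
  for (i in 1:50) {
    x <- sample(0:4, 100, TRUE)
    y <- sample(0:4, 100, TRUE)
    expect_equal(spearman_association(x, y)$rho, oracle_spearman(x, y),
                 tolerance = 1e-12)
  }
})

test_that("large-sample p-values agree with the t-approximation reference", {
  set.seed(37)
  x <- rbinom(500, 1, 0.4)
  y <- rbinom(500, 1, 0.4)
  res <- spearman_association(x, y)
  ref <- suppressWarnings(
    cor.test(x, y, method = "spearman", exact = FALSE))
  expect_equal(res$rho, unname(ref$estimate), tolerance = 1e-12)
  expect_equal(res$p_value, ref$p.value, tolerance = 1e-10)
})

test_that("small samples use permutation p-values", {
  # n = 6 binary: distinct permutations = choose(6,3) = 20, enumerable
  x <- c(0, 0, 0, 1, 1, 1)
  y <- c(0, 0, 1, 0, 1, 1)
  res <- spearman_association(x, y)
  expect_equal(res$method, "exact permutation")
  # enumeration oracle: all 20 arrangements of y
  perms <- unique(combinat_perms <- t(apply(
    expand.grid(rep(list(0:1), 6)), 1, identity)))
  perms <- perms[rowSums(perms) == 3, , drop = FALSE]
  rhos <- apply(perms, 1, function(p) oracle_spearman(x, p))
  expect_equal(res$p_value, mean(abs(rhos) >= abs(oracle_spearman(x, y)) - 1e-12))
  # many distinct values at n = 20 -> 20! >> 10^4, so Monte-Carlo
  set.seed(41)
  res_mc <- spearman_association(rnorm(20), rnorm(20))
  expect_equal(res_mc$method, "monte-carlo permutation")
  expect_true(res_mc$p_value > 0 && res_mc$p_value <= 1)
})

test_that("degenerate and malformed inputs are handled per contract", {
  expect_error(spearman_association(1:4, 1:5), "equal length")
  expect_error(spearman_association(c(0, 1), c(1, 0)), "at least 3")
  res <- spearman_association(c(1, 1, 1, 1), c(0, 1, 0, 1))
  expect_true(res$degenerate)
  expect_true(is.na(res$rho))
})

test_that("pairwise_associations tests every pair on aligned presence vectors", {
  claims <- make_claims(
    rep(sprintf("P%02d", 1:20), each = 1),
    rep("2024-06-01", 20),
    c(rep(list(c("A01", "B02")), 10), rep(list("C03"), 10)))
  sets <- aggregate_patient_windows(claims)
  tests <- pairwise_associations(sets, vocabulary = c("A01", "B02", "C03"))
  expect_equal(nrow(tests), 3)
  ab <- tests[tests$code_a == "A01" & tests$code_b == "B02", ]
  expect_equal(ab$rho, 1)
  expect_true(ab$significant)
  expect_equal(unique(tests$n), 20)
})

test_that("k codes yield exactly k(k-1)/2 tests", {
  cfg <- default_cohort_config(n_patients = 300, seed = 43)
  sets <- aggregate_patient_windows(simulate_cohort(cfg))
  tests <- pairwise_associations(sets, names(cfg$codes))
  expect_equal(nrow(tests), choose(10, 2))
})

test_that("BH adjustment matches hand computation and two oracles", {
  expect_equal(adjust_bh(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(adjust_bh(0.5), 0.5)
  expect_error(adjust_bh(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(47)
  for (i in 1:100) {
    p <- runif(sample(3:40, 1))
    adj <- adjust_bh(p)
    expect_equal(adj, oracle_bh(p))
    expect_equal(adj, p.adjust(p, method = "BH"))
    expect_true(all(adj >= p))
  }
})

test_that("build_network applies the strict p < alpha rule", {
  tests <- tibble::tibble(
    code_a = c("A01", "B02", "C03"), code_b = c("B02", "C03", "A01"),
    rho = c(0.5, 0.4, 0.3), p_value = c(0.01, 0.04, 0.06),
    p_adjusted = NA_real_, n = 100L, method = "t-approximation",
    degenerate = FALSE, significant = NA)
  net <- build_network(tests, alpha = 0.05)
  expect_equal(nrow(net$edges), 2)
  expect_setequal(net$nodes$code, c("A01", "B02", "C03"))
  # nothing passes -> empty network, not an error
  net0 <- build_network(dplyr::mutate(tests, p_value = 0.9), alpha = 0.05)
  expect_equal(nrow(net0$edges), 0)
  # degenerate rows never become edges
  netd <- build_network(dplyr::mutate(tests, degenerate = TRUE), alpha = 0.05)
  expect_equal(nrow(netd$edges), 0)
})

test_that("edge set is invariant to the order pairs are tested in", {
  cfg <- default_cohort_config(n_patients = 400, seed = 53)
  sets <- aggregate_patient_windows(simulate_cohort(cfg))
  tests <- pairwise_associations(sets, names(cfg$codes))
  shuffled <- tests[sample(nrow(tests)), ]
  e1 <- build_network(tests)$edges
  e2 <- build_network(shuffled)$edges
  expect_equal(e1, e2)
})

test_that("node centrality: triangle, star, deterministic tie-break", {
  tri <- tibble::tibble(code_a = c("A01", "B02", "A01"),
                        code_b = c("B02", "C03", "C03"),
                        rho = 0.5, p_value = 0.01, p_adjusted = NA_real_,
                        n = 50L, method = "t", degenerate = FALSE,
                        significant = TRUE)
  cen <- node_centrality(build_network(tri, alpha = 0.05))
  expect_equal(cen$degree, rep(2L, 3))
  expect_equal(cen$strength, rep(1.0, 3))
  expect_equal(cen$code, c("A01", "B02", "C03"))  # lexicographic tie-break
  star <- tibble::tibble(code_a = "H35", code_b = c("A01", "B02", "C03", "D04"),
                         rho = 0.3, p_value = 0.01, p_adjusted = NA_real_,
                         n = 50L, method = "t", degenerate = FALSE,
                         significant = TRUE)
  cen_s <- node_centrality(build_network(star, alpha = 0.05))
  expect_equal(cen_s$code[1], "H35")
  expect_equal(cen_s$degree[1], 4L)
  expect_equal(cen_s$degree[-1], rep(1L, 4))
})

test_that("planted hub is recovered with its full degree at n = 10000", {
  codes <- stats::setNames(rep(0.2, 10),
                           c("H35", sprintf("A%02d", 1:5), sprintf("B%02d", 1:4)))
  assoc <- tibble::tibble(code_a = "H35", code_b = sprintf("A%02d", 1:5),
                          odds_ratio = 3)
  cfg <- cohort_config(n_patients = 10000, years = 2024, codes = codes,
                       associations = assoc, seed = 59)
  sets <- aggregate_patient_windows(simulate_cohort(cfg))
  net <- build_network(pairwise_associations(sets, names(codes)))
  cen <- node_centrality(net)
  expect_equal(cen$code[1], "H35")
  hub_edges <- net$edges[net$edges$code_a == "H35" | net$edges$code_b == "H35", ]
  planted <- hub_edges[pmin(hub_edges$code_a, hub_edges$code_b) %in%
                         c("H35", sprintf("A%02d", 1:5)) &
                       pmax(hub_edges$code_a, hub_edges$code_b) %in%
                         c("H35", sprintf("A%02d", 1:5)), ]
  expect_equal(nrow(planted), 5)
})

test_that("layout is reproducible, collision-free, and cluster-revealing", {
  tests <- tibble::tibble(
    code_a = c("A01", "A01", "B02", "X01", "X01", "Y02"),
    code_b = c("B02", "C03", "C03", "Y02", "Z03", "Z03"),
    rho = 0.6, p_value = 0.001, p_adjusted = NA_real_, n = 100L,
    method = "t", degenerate = FALSE, significant = TRUE)
  net <- build_network(tests, alpha = 0.05)
  l1 <- compute_layout(net, seed = 7)$layout
  l2 <- compute_layout(net, seed = 7)$layout
  expect_identical(l1, l2)
  # two disconnected triangles: no coincident coordinates
  d <- as.matrix(dist(cbind(l1$x, l1$y)))
  expect_gt(min(d[upper.tri(d)]), 0)
  # intra-cluster distances smaller than inter-cluster on average
  c1 <- l1$code %in% c("A01", "B02", "C03")
  intra <- mean(c(d[c1, c1][upper.tri(d[c1, c1])],
                  d[!c1, !c1][upper.tri(d[!c1, !c1])]))
  inter <- mean(d[c1, !c1])
  expect_lt(intra, inter)
})

test_that("GraphML export round-trips nodes, edges, weights and layout", {
  tests <- tibble::tibble(
    code_a = c("A01", "B02"), code_b = c("B02", "C03"),
    rho = c(0.52, -0.31), p_value = c(0.001, 0.02), p_adjusted = NA_real_,
    n = 120L, method = "t", degenerate = FALSE, significant = TRUE)
  net <- compute_layout(build_network(tests, alpha = 0.05), seed = 3)
  f <- tempfile(fileext = ".graphml")
  export_network(net, f, "graphml")
  back <- import_network(f)
  expect_equal(back$nodes$code, net$nodes$code)
  expect_equal(back$edges$code_a, net$edges$code_a)
  expect_equal(back$edges$rho, net$edges$rho)
  expect_equal(back$layout$x, net$layout$x)
  # edge-list export: header + one line per edge
  f2 <- tempfile(fileext = ".csv")
  export_network(net, f2, "edge-list")
  expect_equal(length(readLines(f2)), nrow(net$edges) + 1)
  # empty network still exports a valid file
  net0 <- build_network(dplyr::mutate(tests, p_value = 1), alpha = 0.05)
  f3 <- tempfile(fileext = ".csv")
  export_network(net0, f3, "edge-list")
  expect_equal(length(readLines(f3)), 1)
  expect_error(export_network(net, tempfile(), "dot"))
})

test_that("tidy/glance/autoplot methods work on networks", {
  tests <- tibble::tibble(
    code_a = "J449", code_b = "E785", rho = 0.4, p_value = 0.01,
    p_adjusted = NA_real_, n = 100L, method = "t", degenerate = FALSE,
    significant = TRUE)
  net <- build_network(tests, alpha = 0.05)
  expect_equal(nrow(tidy(net)), 1)
  g <- glance(net)
  expect_equal(g$n_nodes, 2)
  expect_equal(g$n_edges, 1)
  p <- autoplot(net)
  expect_s3_class(p, "ggplot")
})
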