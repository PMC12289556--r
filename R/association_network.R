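# --- Spearman rank association -------------------------------------------

# distinct permutations of a multiset, in lexicographic order; caller
# guarantees the count is small (<= exact_limit)
multiset_permutations <- function(values) {
  values <- sort(values)
  out <- list()
  recurse <- function(prefix, remaining) {
    if (length(remaining) == 0) {
      out[[length(out) + 1]] <<- prefix
      return(invisible())
    }
    for (v in unique(remaining)) {
      idx <- match(v, remaining)
      recurse(c(prefix, v), remaining[-idx])
    }
  }
  recurse(numeric(0), values)
  out
}

n_distinct_permutations <- function(y) {
  n <- length(y)
  tab <- table(y)
  exp(lgamma(n + 1) - sum(lgamma(tab + 1)))
}

#' Spearman rank-order association between two vectors
#'
#' The pairwise test at the heart of the network: `rho` is the Pearson
#' correlation of mid-ranks (tie-corrected, so on binary vectors it equals
#' the phi coefficient of the 2x2 table). The two-sided p-value uses the
#' t-distribution approximation for `n >= 30`; for smaller samples it is a
#' permutation p-value -- full enumeration of the distinct permutations of
#' `y` when there are at most `exact_limit` of them, otherwise a seeded
#' Monte-Carlo permutation test with `n_mc` draws.
#'
#' A constant vector has no rank variation: the test is flagged degenerate
#' (`rho` and `p_value` are `NA`) rather than raising an error, so rare
#' all-absent codes do not abort a batch run.
#'
#' @param x,y Numeric (typically binary presence) vectors of equal length
#'   `>= 3`, aligned on the same patient-year observations.
#' @param exact_limit Enumerate exactly when the number of distinct
#'   permutations is at most this (default 10000).
#' @param n_mc Monte-Carlo permutation draws (default 10000).
#' @param mc_seed Seed for the Monte-Carlo branch.
#' @return One-row tibble: `rho`, `p_value`, `n`, `method`, `degenerate`.
#' @export
spearman_association <- function(x, y, exact_limit = 10000, n_mc = 10000,
                                 mc_seed = 1L) {
  if (length(x) != length(y)) stop("x and y must have equal length", call. = FALSE)
  n <- length(x)
  if (n < 3) stop("need at least 3 observations", call. = FALSE)
  if (length(unique(x)) < 2 || length(unique(y)) < 2) {
    return(tibble::tibble(rho = NA_real_, p_value = NA_real_, n = n,
                          method = "degenerate", degenerate = TRUE))
  }
  rx <- rank(x)
  rho <- stats::cor(rx, rank(y))
  rho_of <- function(yy) stats::cor(rx, rank(yy))
  if (n >= 30) {
    if (abs(rho) >= 1) {
      p <- 0
    } else {
      tt <- rho * sqrt((n - 2) / (1 - rho^2))
      p <- 2 * stats::pt(-abs(tt), df = n - 2)
    }
    method <- "t-approximation"
  } else if (n_distinct_permutations(y) <= exact_limit) {
    perms <- multiset_permutations(y)
    rhos <- vapply(perms, rho_of, numeric(1))
    p <- mean(abs(rhos) >= abs(rho) - 1e-12)
    method <- "exact permutation"
  } else {
    rhos <- withr::with_seed(mc_seed, {
      vapply(seq_len(n_mc), function(i) rho_of(sample(y)), numeric(1))
    })
    # add-one correction keeps Monte-Carlo p-values valid (never 0)
    p <- (sum(abs(rhos) >= abs(rho) - 1e-12) + 1) / (n_mc + 1)
    method <- "monte-carlo permutation"
  }
  tibble::tibble(rho = rho, p_value = p, n = n, method = method,
                 degenerate = FALSE)
}

#' Test all pairwise code associations on patient-year presence vectors
#'
#' For every unordered pair of vocabulary codes, builds the binary
#' presence vectors indexed by the patient-year observations in the window
#' and applies [spearman_association()]. All pairs are returned,
#' significant or not; degenerate pairs (a code absent or ubiquitous in
#' the window) are flagged, never dropped silently.
#'
#' @param sets A `diagnosis_sets` table from [aggregate_patient_windows()].
#' @param vocabulary Codes to test (default: all codes in `sets`).
#' @param window A year or `"pooled"` (default).
#' @param alpha Two-sided significance level (default 0.05).
#' @param use_adjusted Apply Benjamini-Hochberg adjustment and use the
#'   adjusted p-values for the significance flag? Default `FALSE`,
#'   i.e. raw p-values -- the convention for uncorrected claims-network
#'   screens (the correction remains available for sensitivity analyses).
#' @return Tibble of edge tests: `code_a`, `code_b`, `rho`, `p_value`,
#'   `p_adjusted` (NA unless `use_adjusted`), `n`, `method`, `degenerate`,
#'   `significant`. Exactly `k*(k-1)/2` rows for `k` codes.
#' @export
pairwise_associations <- function(sets, vocabulary = NULL, window = "pooled",
                                  alpha = 0.05, use_adjusted = FALSE) {
  stopifnot(alpha > 0, alpha < 1)
  m <- presence_matrix(sets, window, vocabulary)
  if (ncol(m) < 2) stop("need at least 2 codes to test", call. = FALSE)
  if (nrow(m) < 3) stop("need at least 3 patient-year observations", call. = FALSE)
  codes <- colnames(m)
  pairs <- utils::combn(codes, 2)
  tests <- purrr::map_dfr(seq_len(ncol(pairs)), function(j) {
    a <- pairs[1, j]; b <- pairs[2, j]
    dplyr::bind_cols(tibble::tibble(code_a = a, code_b = b),
                     spearman_association(m[, a], m[, b]))
  })
  ok <- !tests$degenerate
  tests$p_adjusted <- NA_real_
  if (use_adjusted) tests$p_adjusted[ok] <- adjust_bh(tests$p_value[ok])
  p_used <- if (use_adjusted) tests$p_adjusted else tests$p_value
  tests$significant <- !tests$degenerate & !is.na(p_used) & p_used < alpha
  attr(tests, "window") <- if (identical(window, "pooled")) "pooled" else as.integer(window)
  attr(tests, "alpha") <- alpha
  attr(tests, "use_adjusted") <- use_adjusted
  tests
}

#' Benjamini-Hochberg step-up adjustment
#'
#' The classical FDR step-up: sort p-values ascending, compute
#' `p_(i) * m / i`, enforce monotonicity from the largest rank down by a
#' running minimum, cap at 1, and return in the original order.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, same length and order.
#' @examples
#' adjust_bh(c(0.01, 0.02, 0.03))  # all 0.03
#' @export
adjust_bh <- function(p) {
  if (length(p) == 0) return(numeric(0))
  if (any(is.na(p)) || any(p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  m <- length(p)
  ord <- order(p)
  scaled <- p[ord] * m / seq_len(m)
  adj <- rev(cummin(rev(scaled)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[ord] <- adj
  out
}

# --- Network construction -------------------------------------------------

#' Build the disease association network
#'
#' Assembles the undirected weighted network from a table of edge tests:
#' edges are the pairs whose (chosen) p-value falls below `alpha`, weighted
#' by Spearman's rho; nodes are the codes incident to at least one retained
#' edge (plus, optionally, isolated vocabulary codes). Degenerate tests
#' never become edges.
#'
#' @param tests Edge-test tibble from [pairwise_associations()] (one
#'   window).
#' @param alpha Significance threshold (default: the alpha recorded on
#'   `tests`, else 0.05).
#' @param use_adjusted Use BH-adjusted p-values for the cut? Default: as
#'   recorded on `tests`, else `FALSE`.
#' @param labels Optional named character vector of node labels (default
#'   [icd10_labels()]).
#' @param keep_isolates Include vocabulary codes with no significant edge
#'   as isolated nodes? Default `FALSE`.
#' @param vocabulary Code list used when `keep_isolates = TRUE` (default:
#'   all codes appearing in `tests`).
#' @return Object of class `disease_network`: list with tibbles `nodes`
#'   (`code`, `label`), `edges` (`code_a`, `code_b`, `rho`, `p_value`,
#'   `p_adjusted`, `n`), `layout` (`NULL` until [compute_layout()]), and
#'   fields `alpha`, `use_adjusted`, `window`.
#' @export
build_network <- function(tests, alpha = NULL, use_adjusted = NULL,
                          labels = icd10_labels(), keep_isolates = FALSE,
                          vocabulary = NULL) {
  if (is.null(alpha)) alpha <- attr(tests, "alpha") %||% 0.05
  if (is.null(use_adjusted)) use_adjusted <- attr(tests, "use_adjusted") %||% FALSE
  stopifnot(alpha > 0, alpha < 1)
  p_used <- if (use_adjusted) tests$p_adjusted else tests$p_value
  keep <- !tests$degenerate & !is.na(p_used) & p_used < alpha
  edges <- tests[keep, c("code_a", "code_b", "rho", "p_value", "p_adjusted", "n")]
  # canonical unordered representation, one edge per pair, no self-loops
  swap <- edges$code_a > edges$code_b
  tmp <- edges$code_a[swap]
  edges$code_a[swap] <- edges$code_b[swap]
  edges$code_b[swap] <- tmp
  edges <- dplyr::distinct(edges, .data$code_a, .data$code_b, .keep_all = TRUE)
  edges <- edges[edges$code_a != edges$code_b, ]
  edges <- dplyr::arrange(edges, .data$code_a, .data$code_b)
  node_codes <- sort(unique(c(edges$code_a, edges$code_b)))
  if (keep_isolates) {
    vocab <- vocabulary %||% sort(unique(c(tests$code_a, tests$code_b)))
    node_codes <- sort(unique(c(node_codes, normalize_icd10(vocab))))
  }
  nodes <- tibble::tibble(code = node_codes,
                          label = unname(labels[node_codes]))
  nodes$label[is.na(nodes$label)] <- nodes$code[is.na(nodes$label)]
  structure(list(nodes = nodes, edges = tibble::as_tibble(edges),
                 layout = NULL, alpha = alpha, use_adjusted = use_adjusted,
                 window = attr(tests, "window") %||% "pooled"),
            class = "disease_network")
}

#' @export
print.disease_network <- function(x, ...) {
  cat(sprintf(
    "<disease_network> %d nodes, %d edges (alpha = %g, %s p-values, window %s)\n",
    nrow(x$nodes), nrow(x$edges), x$alpha,
    if (x$use_adjusted) "BH-adjusted" else "raw", x$window))
  if (!is.null(x$layout)) cat("  layout: computed\n")
  invisible(x)
}

#' Tidy a disease network into its edge table
#'
#' @param x A `disease_network`.
#' @param ... Unused.
#' @return The edge tibble (`code_a`, `code_b`, `rho`, `p_value`,
#'   `p_adjusted`, `n`).
#' @method tidy disease_network
#' @export
tidy.disease_network <- function(x, ...) x$edges

#' One-row summary of a disease network
#'
#' @param x A `disease_network`.
#' @param ... Unused.
#' @return Tibble: `n_nodes`, `n_edges`, `density`, `mean_abs_rho`,
#'   `alpha`, `use_adjusted`.
#' @method glance disease_network
#' @export
glance.disease_network <- function(x, ...) {
  k <- nrow(x$nodes)
  tibble::tibble(
    n_nodes = k,
    n_edges = nrow(x$edges),
    density = if (k > 1) nrow(x$edges) / (k * (k - 1) / 2) else NA_real_,
    mean_abs_rho = if (nrow(x$edges)) mean(abs(x$edges$rho)) else NA_real_,
    alpha = x$alpha,
    use_adjusted = x$use_adjusted
  )
}

#' Convert a disease network to an igraph graph
#'
#' @param network A `disease_network`.
#' @return An undirected `igraph` graph with `weight = rho` and `p`, `n`
#'   edge attributes; node attributes `label` and, if a layout has been
#'   computed, `x`/`y`.
#' @export
as_igraph <- function(network) {
  stopifnot(inherits(network, "disease_network"))
  g <- igraph::graph_from_data_frame(
    d = data.frame(from = network$edges$code_a, to = network$edges$code_b,
                   weight = network$edges$rho, p = network$edges$p_value,
                   n = network$edges$n),
    directed = FALSE,
    vertices = data.frame(name = network$nodes$code,
                          label = network$nodes$label)
  )
  if (!is.null(network$layout)) {
    idx <- match(igraph::V(g)$name, network$layout$code)
    g <- igraph::set_vertex_attr(g, "x", value = network$layout$x[idx])
    g <- igraph::set_vertex_attr(g, "y", value = network$layout$y[idx])
  }
  g
}

#' Degree and strength centrality of network nodes
#'
#' Degree is the number of incident significant edges; strength is the sum
#' of `|rho|` over them -- the hub statistics used to rank comorbidity
#' centres such as COPD and asthma. Ties are broken lexicographically by
#' code so the ranking is deterministic.
#'
#' @param network A `disease_network`.
#' @return Tibble `code`, `label`, `degree`, `strength`, `rank`, sorted by
#'   decreasing degree then decreasing strength then code.
#' @export
node_centrality <- function(network) {
  stopifnot(inherits(network, "disease_network"))
  if (nrow(network$nodes) == 0) {
    return(tibble::tibble(code = character(), label = character(),
                          degree = integer(), strength = numeric(),
                          rank = integer()))
  }
  incident <- dplyr::bind_rows(
    tibble::tibble(code = network$edges$code_a, w = abs(network$edges$rho)),
    tibble::tibble(code = network$edges$code_b, w = abs(network$edges$rho))
  )
  stats_tbl <- dplyr::summarise(dplyr::group_by(incident, .data$code),
                                degree = dplyr::n(),
                                strength = sum(.data$w), .groups = "drop")
  out <- dplyr::left_join(network$nodes, stats_tbl, by = "code")
  out$degree <- as.integer(dplyr::coalesce(out$degree, 0L))
  out$strength <- dplyr::coalesce(out$strength, 0)
  out <- dplyr::arrange(out, dplyr::desc(.data$degree),
                        dplyr::desc(.data$strength), .data$code)
  out$rank <- seq_len(nrow(out))
  out
}

#' Seeded force-directed layout
#'
#' Fruchterman-Reingold layout with a fixed iteration count and seeded
#' initial positions, so the same network and seed always give the same
#' coordinates. Coordinates are stored on the network (`$layout`) and
#' travel with GraphML exports.
#'
#' @param network A `disease_network` with at least one node.
#' @param seed Integer seed (default 1).
#' @param niter Iterations (default 100).
#' @return The network with `$layout` set (tibble `code`, `x`, `y`).
#' @export
compute_layout <- function(network, seed = 1L, niter = 100) {
  stopifnot(inherits(network, "disease_network"), nrow(network$nodes) >= 1)
  g <- as_igraph(network)
  coords <- withr::with_seed(as.integer(seed), {
    igraph::layout_with_fr(g, niter = niter,
                           weights = abs(igraph::E(g)$weight))
  })
  network$layout <- tibble::tibble(code = igraph::V(g)$name,
                                   x = coords[, 1], y = coords[, 2])
  network$layout <- network$layout[match(network$nodes$code,
                                         network$layout$code), ]
  network
}

#' Export a disease network to GraphML or a delimited edge list
#'
#' GraphML keeps node labels and any computed layout as attributes and can
#' be re-imported with [import_network()] round-tripping node/edge sets and
#' weights exactly; the edge list is a long CSV
#' (`code_a, code_b, rho, p, n`).
#'
#' @param network A `disease_network`.
#' @param path Output file path.
#' @param format `"graphml"` or `"edge-list"`.
#' @return `path`, invisibly.
#' @export
export_network <- function(network, path, format = c("graphml", "edge-list")) {
  format <- match.arg(format)
  if (format == "graphml") {
    igraph::write_graph(as_igraph(network), path, format = "graphml")
  } else {
    out <- network$edges[, c("code_a", "code_b", "rho", "p_value", "n")]
    names(out) <- c("code_a", "code_b", "rho", "p", "n")
    readr::write_csv(out, path)
  }
  invisible(path)
}

#' Import a GraphML disease network
#'
#' Inverse of [export_network()] for the GraphML format.
#'
#' @param path GraphML file written by [export_network()].
#' @return A `disease_network` (alpha/use_adjusted are not stored in
#'   GraphML and come back as `NA`/`FALSE`).
#' @export
import_network <- function(path) {
  g <- igraph::read_graph(path, format = "graphml")
  va <- igraph::vertex_attr(g)
  nodes <- tibble::tibble(code = va$name,
                          label = va$label %||% va$name)
  ed <- igraph::as_data_frame(g, what = "edges")
  edges <- tibble::tibble(
    code_a = pmin(ed$from, ed$to), code_b = pmax(ed$from, ed$to),
    rho = ed$weight, p_value = ed$p %||% rep(NA_real_, nrow(ed)),
    p_adjusted = NA_real_, n = as.integer(ed$n %||% rep(NA, nrow(ed)))
  )
  edges <- dplyr::arrange(edges, .data$code_a, .data$code_b)
  layout <- NULL
  if (!is.null(va$x) && !is.null(va$y)) {
    layout <- tibble::tibble(code = va$name, x = va$x, y = va$y)
  }
  ord <- order(nodes$code)
  nodes <- nodes[ord, ]
  if (!is.null(layout)) layout <- layout[ord, ]
  structure(list(nodes = nodes, edges = edges, layout = layout,
                 alpha = NA_real_, use_adjusted = FALSE, window = "pooled"),
            class = "disease_network")
}

#' Plot a disease network
#'
#' ggplot2 rendering of the force-directed layout: edges drawn with width
#' proportional to `|rho|`, nodes labelled with their clinical description.
#' Computes a layout (seed 1) if none is stored.
#'
#' @param object A `disease_network`.
#' @param label_nodes Draw node labels? Default `TRUE`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot disease_network
#' @export
autoplot.disease_network <- function(object, label_nodes = TRUE, ...) {
  if (is.null(object$layout)) object <- compute_layout(object)
  lay <- object$layout
  seg <- dplyr::left_join(object$edges,
                          stats::setNames(lay, c("code_a", "x0", "y0")),
                          by = "code_a")
  seg <- dplyr::left_join(seg, stats::setNames(lay, c("code_b", "x1", "y1")),
                          by = "code_b")
  deg <- node_centrality(object)
  pts <- dplyr::left_join(lay, deg[, c("code", "label", "degree")], by = "code")
  p <- ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = seg,
      ggplot2::aes(x = .data$x0, y = .data$y0, xend = .data$x1,
                   yend = .data$y1, linewidth = abs(.data$rho)),
      colour = "grey60", alpha = 0.7) +
    ggplot2::geom_point(
      data = pts,
      ggplot2::aes(x = .data$x, y = .data$y, size = .data$degree),
      colour = "#2C6E8F") +
    ggplot2::scale_linewidth(range = c(0.2, 2), name = "|rho|") +
    ggplot2::scale_size(range = c(2, 8), name = "degree") +
    ggplot2::theme_void()
  if (label_nodes) {
    p <- p + ggplot2::geom_text(
      data = pts,
      ggplot2::aes(x = .data$x, y = .data$y, label = .data$label),
      vjust = -1.2, size = 3)
  }
  p
}
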