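#' Pipeline configuration
#'
#' Collects everything one reproducible run needs: the input (a claims file
#' or a synthetic cohort configuration), the analysis vocabulary, the
#' window policy, the significance rule, the trend pairs and disruption
#' thresholds, and the layout seed. Round-trips losslessly through YAML
#' via [write_pipeline_config()] / [read_pipeline_config()].
#'
#' @param claims_file Path to a delimited claims file, or `NULL` to
#'   simulate.
#' @param synthetic A [cohort_config()] used when `claims_file` is `NULL`.
#' @param vocabulary Character vector of codes to analyze (default: the
#'   synthetic config's codes, or all codes in the claims file).
#' @param window `"pooled"` or a year, for the network stage.
#' @param alpha Significance level in (0, 1), default 0.05.
#' @param use_adjusted Use BH-adjusted p-values? Default `FALSE`.
#' @param trend_pairs Tibble (`code_a`, `code_b`) of pairs for the trends
#'   stage; default: the synthetic config's planted pairs, else the top 5
#'   pooled co-occurrence pairs.
#' @param coverage Named year -> fraction vector for partial years.
#' @param drop_threshold,rise_threshold Disruption thresholds.
#' @param layout_seed Seed for the force-directed layout.
#' @param keep_isolates Keep isolated vocabulary nodes in the network?
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(claims_file = NULL, synthetic = NULL,
                            vocabulary = NULL, window = "pooled",
                            alpha = 0.05, use_adjusted = FALSE,
                            trend_pairs = NULL, coverage = NULL,
                            drop_threshold = 0.2, rise_threshold = 0.2,
                            layout_seed = 1L, keep_isolates = FALSE) {
  if (!(is.numeric(alpha) && alpha > 0 && alpha < 1)) {
    stop("alpha must lie in (0, 1)", call. = FALSE)
  }
  if (is.null(claims_file) && is.null(synthetic)) {
    stop("provide claims_file or a synthetic cohort_config", call. = FALSE)
  }
  if (!is.null(claims_file) && !file.exists(claims_file)) {
    stop("claims file not found: ", claims_file, call. = FALSE)
  }
  if (!is.null(synthetic)) stopifnot(inherits(synthetic, "cohort_config"))
  structure(list(
    claims_file = claims_file, synthetic = synthetic,
    vocabulary = vocabulary, window = window, alpha = alpha,
    use_adjusted = isTRUE(use_adjusted), trend_pairs = trend_pairs,
    coverage = coverage, drop_threshold = drop_threshold,
    rise_threshold = rise_threshold, layout_seed = as.integer(layout_seed),
    keep_isolates = isTRUE(keep_isolates)
  ), class = "pipeline_config")
}

config_to_list <- function(config) {
  out <- unclass(config)
  if (!is.null(out$synthetic)) {
    s <- unclass(out$synthetic)
    s$codes <- as.list(s$codes)
    s$disruption <- as.list(s$disruption)
    s$associations <- as.list(as.data.frame(s$associations))
    out$synthetic <- s
  }
  if (!is.null(out$trend_pairs)) {
    out$trend_pairs <- as.list(as.data.frame(out$trend_pairs))
  }
  if (!is.null(out$coverage)) out$coverage <- as.list(out$coverage)
  out
}

#' Write / read a pipeline configuration as YAML
#'
#' @param config A [pipeline_config()].
#' @param path YAML file path.
#' @return `write_pipeline_config()`: `path`, invisibly.
#'   `read_pipeline_config()`: a `pipeline_config`.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(config_to_list(config), path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  x <- yaml::read_yaml(path)
  synthetic <- NULL
  if (!is.null(x$synthetic)) {
    s <- x$synthetic
    synthetic <- cohort_config(
      n_patients = s$n_patients, years = unlist(s$years),
      codes = unlist(s$codes),
      associations = if (length(s$associations$code_a))
        tibble::as_tibble(s$associations) else NULL,
      encounters_per_condition = s$encounters_per_condition,
      disruption = unlist(s$disruption),
      age_mean = s$age_mean, age_sd = s$age_sd,
      female_fraction = s$female_fraction, seed = s$seed,
      repair_pd = s$repair_pd
    )
  }
  pipeline_config(
    claims_file = x$claims_file, synthetic = synthetic,
    vocabulary = unlist(x$vocabulary), window = x$window, alpha = x$alpha,
    use_adjusted = x$use_adjusted,
    trend_pairs = if (length(x$trend_pairs$code_a))
      tibble::as_tibble(x$trend_pairs) else NULL,
    coverage = unlist(x$coverage),
    drop_threshold = x$drop_threshold, rise_threshold = x$rise_threshold,
    layout_seed = x$layout_seed, keep_isolates = x$keep_isolates
  )
}

log_line <- function(con, fmt, ...) {
  msg <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), sprintf(fmt, ...))
  writeLines(msg, con)
  message(msg)
}

#' Run the full claims-to-network pipeline
#'
#' Orchestrates generate/ingest -> patient-year aggregation ->
#' co-occurrence -> Spearman network -> centrality -> trends -> disruption,
#' writing every artifact under `out_dir` together with a manifest (JSON)
#' recording the resolved configuration hash, seed, package version and an
#' MD5 checksum per artifact. Two runs with the same configuration produce
#' identical artifact checksums, layout included.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if absent).
#' @return Invisibly, a list with the in-memory results (`claims_summary`,
#'   `cooccurrence`, `edge_tests`, `network`, `centrality`, `trends`,
#'   `disruption`) and `manifest`.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "run.log")
  con <- file(log_path, open = "wt")
  on.exit(close(con), add = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      log_line(con, "stage %s FAILED: %s", name, conditionMessage(e))
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  claims <- stage("input", {
    if (!is.null(config$claims_file)) {
      log_line(con, "reading claims from %s", config$claims_file)
      read_claims(config$claims_file)
    } else {
      log_line(con, "simulating cohort: %d patients, seed %d",
               config$synthetic$n_patients, config$synthetic$seed)
      simulate_cohort(config$synthetic)
    }
  })
  vocab <- config$vocabulary %||%
    (if (!is.null(config$synthetic)) names(config$synthetic$codes) else NULL)

  summary_tbl <- stage("summary", summarize_cohort(claims))
  readr::write_csv(summary_tbl, file.path(out_dir, "cohort_summary.csv"))
  log_line(con, "cohort: %d records, mean age %.1f, %%F %.1f",
           summary_tbl$n_records, summary_tbl$age_mean, summary_tbl$pct_female)

  sets <- stage("aggregate", aggregate_patient_windows(claims, vocab))
  cooc <- stage("cooccurrence", count_cooccurrence(sets, config$window,
                                                   vocabulary = vocab))
  write_cooccurrence(cooc, file.path(out_dir, "cooccurrence"))
  log_line(con, "co-occurrence: %d codes over %d patient-years (window %s)",
           ncol(cooc), attr(cooc, "n_entries"), config$window)

  tests <- stage("associations",
                 pairwise_associations(sets, vocab, config$window,
                                       alpha = config$alpha,
                                       use_adjusted = config$use_adjusted))
  readr::write_csv(tests, file.path(out_dir, "edge_tests.csv"))
  log_line(con, "tested %d pairs at alpha = %g (%s p-values): %d significant",
           nrow(tests), config$alpha,
           if (config$use_adjusted) "BH-adjusted" else "raw",
           sum(tests$significant))

  network <- stage("network", {
    net <- build_network(tests, keep_isolates = config$keep_isolates,
                         vocabulary = vocab)
    compute_layout(net, seed = config$layout_seed)
  })
  export_network(network, file.path(out_dir, "network.graphml"), "graphml")
  export_network(network, file.path(out_dir, "network_edges.csv"), "edge-list")
  centrality <- stage("centrality", node_centrality(network))
  readr::write_csv(centrality, file.path(out_dir, "centrality.csv"))
  log_line(con, "network: %d nodes, %d edges; top hub %s (degree %d)",
           nrow(network$nodes), nrow(network$edges),
           if (nrow(centrality)) centrality$code[1] else "none",
           if (nrow(centrality)) centrality$degree[1] else 0L)

  pairs <- config$trend_pairs
  if (is.null(pairs) && !is.null(config$synthetic) &&
      nrow(config$synthetic$associations) > 0) {
    pairs <- config$synthetic$associations[, c("code_a", "code_b")]
  }
  if (is.null(pairs)) {
    top <- tidy.cooccurrence_matrix(cooc)
    top <- dplyr::slice_max(top, .data$count, n = 5, with_ties = FALSE)
    pairs <- top[, c("code_a", "code_b")]
  }
  trends <- stage("trends", {
    trend_series(pair_counts_by_year(sets, pairs), config$coverage)
  })
  readr::write_csv(trends, file.path(out_dir, "trends.csv"))
  disruption <- stage("disruption", {
    detect_disruption(annualize_partial(trends, "flag"),
                      config$drop_threshold, config$rise_threshold)
  })
  readr::write_csv(disruption, file.path(out_dir, "disruption.csv"))
  dips <- glance.disruption_report(disruption)
  log_line(con, "trends: %d pairs, %d with a dip year",
           nrow(dips), sum(dips$n_dips > 0))

  cfg_path <- file.path(out_dir, "config.yaml")
  write_pipeline_config(config, cfg_path)
  artifacts <- c("cohort_summary.csv", "cooccurrence_matrix.csv",
                 "cooccurrence_pairs.csv", "edge_tests.csv",
                 "network.graphml", "network_edges.csv", "centrality.csv",
                 "trends.csv", "disruption.csv", "config.yaml")
  checksums <- tools::md5sum(file.path(out_dir, artifacts))
  manifest <- list(
    package = "comorbnet",
    version = as.character(utils::packageVersion("comorbnet")),
    config_hash = unname(tools::md5sum(cfg_path)),
    seed = if (!is.null(config$synthetic)) config$synthetic$seed else NA,
    layout_seed = config$layout_seed,
    artifacts = as.list(stats::setNames(unname(checksums), artifacts))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  log_line(con, "wrote %d artifacts + manifest to %s", length(artifacts), out_dir)
  invisible(list(claims_summary = summary_tbl, cooccurrence = cooc,
                 edge_tests = tests, network = network,
                 centrality = centrality, trends = trends,
                 disruption = disruption, manifest = manifest))
}
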