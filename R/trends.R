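#' Attach per-year observation coverage to a pair-count trend table
#'
#' Claims extracts often end mid-year (e.g. a final year observed only
#' through June); `coverage` records the fraction of each year observed so
#' partial years can be flagged or rescaled before change statistics.
#'
#' @param counts Tibble from [pair_counts_by_year()] (`code_a`, `code_b`,
#'   `year`, `count`).
#' @param coverage Named numeric vector, year -> fraction observed in
#'   (0, 1]; years not named default to 1.
#' @return Tibble of class `trend_series` with an added `coverage` column
#'   and `estimated = FALSE`.
#' @export
trend_series <- function(counts, coverage = NULL) {
  counts <- tibble::as_tibble(counts)
  stopifnot(all(c("code_a", "code_b", "year", "count") %in% names(counts)),
            all(counts$count >= 0))
  cov <- rep(1, nrow(counts))
  if (!is.null(coverage)) {
    if (any(coverage <= 0 | coverage > 1)) {
      stop("coverage fractions must lie in (0, 1]", call. = FALSE)
    }
    hit <- match(as.character(counts$year), names(coverage))
    cov[!is.na(hit)] <- coverage[hit[!is.na(hit)]]
  }
  counts$coverage <- cov
  if (!"estimated" %in% names(counts)) counts$estimated <- FALSE
  structure(counts, class = c("trend_series", class(counts)))
}

#' Handle partial-year counts in a trend series
#'
#' Two policies for years observed only in part: `"flag"` (default) leaves
#' counts untouched and marks partial years for exclusion from change
#' statistics; `"scale"` divides counts by coverage (rounding to the
#' nearest integer) and marks them as estimated. With full coverage
#' everywhere, both modes return the series unchanged.
#'
#' @param series A `trend_series`.
#' @param mode `"flag"` or `"scale"`.
#' @return A `trend_series`; under `"scale"`, coverage is reset to 1 on
#'   rescaled rows (so rescaling is idempotent) and `estimated` is `TRUE`
#'   for them.
#' @export
annualize_partial <- function(series, mode = c("flag", "scale")) {
  mode <- match.arg(mode)
  if (any(series$coverage <= 0)) stop("coverage must be positive", call. = FALSE)
  if (mode == "scale") {
    partial <- series$coverage < 1
    series$count[partial] <- as.integer(round(series$count[partial] /
                                                series$coverage[partial]))
    series$estimated[partial] <- TRUE
    series$coverage[partial] <- 1
  }
  series
}

#' Detect utilization dips and rebounds in pair co-occurrence trends
#'
#' Screens each pair's yearly counts for disruption: a dip year is one
#' whose relative change from the previous usable year is at most
#' `-drop_threshold`; a rebound year is one with relative change at least
#' `+rise_threshold` occurring after some dip year of the same pair.
#' Relative change is `(c_t - c_{t-1}) / c_{t-1}`, undefined (and skipped)
#' when the previous count is 0. Partial-coverage years are excluded from
#' change statistics (the `"flag"` policy of [annualize_partial()]);
#' apply `"scale"` first to use rescaled estimates instead.
#'
#' Relative (not absolute) change is used so pairs of very different
#' magnitude are screened uniformly.
#'
#' @param series A `trend_series` (or plain tibble with `code_a`,
#'   `code_b`, `year`, `count`, optional `coverage`).
#' @param drop_threshold Minimum relative drop to call a dip (default 0.2).
#' @param rise_threshold Minimum relative rise to call a rebound
#'   (default 0.2).
#' @return Tibble of class `disruption_report`: one row per pair-year with
#'   `code_a`, `code_b`, `year`, `count`, `relative_change` (`NA` for the
#'   first year, excluded years, or zero-denominator years), `is_dip`,
#'   `is_rebound`.
#' @export
detect_disruption <- function(series, drop_threshold = 0.2,
                              rise_threshold = 0.2) {
  stopifnot(drop_threshold > 0, rise_threshold > 0)
  if (!"coverage" %in% names(series)) series$coverage <- 1
  usable <- dplyr::filter(series, .data$coverage >= 1)
  if (dplyr::n_distinct(usable$year) < 3) {
    stop("need at least 3 full-coverage years to screen for disruption",
         call. = FALSE)
  }
  out <- usable |>
    dplyr::group_by(.data$code_a, .data$code_b) |>
    dplyr::arrange(.data$year, .by_group = TRUE) |>
    dplyr::mutate(
      prev = dplyr::lag(.data$count),
      relative_change = dplyr::if_else(
        !is.na(.data$prev) & .data$prev > 0,
        (.data$count - .data$prev) / .data$prev,
        NA_real_),
      is_dip = !is.na(.data$relative_change) &
        .data$relative_change <= -drop_threshold,
      is_rebound = !is.na(.data$relative_change) &
        .data$relative_change >= rise_threshold &
        cumsum(dplyr::lag(.data$is_dip, default = FALSE)) > 0
    ) |>
    dplyr::ungroup() |>
    dplyr::select(-"prev")
  structure(out, drop_threshold = drop_threshold,
            rise_threshold = rise_threshold,
            class = c("disruption_report", class(tibble::as_tibble(out))))
}

#' Summarise a disruption report per pair
#'
#' @param x A `disruption_report` from [detect_disruption()].
#' @param ... Unused.
#' @return One row per pair: `code_a`, `code_b`, `dip_years`,
#'   `rebound_years` (comma-separated), `n_dips`, `n_rebounds`,
#'   `max_drop` (most negative relative change).
#' @method glance disruption_report
#' @export
glance.disruption_report <- function(x, ...) {
  x |>
    dplyr::group_by(.data$code_a, .data$code_b) |>
    dplyr::summarise(
      dip_years = paste(.data$year[.data$is_dip], collapse = ","),
      rebound_years = paste(.data$year[.data$is_rebound], collapse = ","),
      n_dips = sum(.data$is_dip),
      n_rebounds = sum(.data$is_rebound),
      max_drop = ifelse(all(is.na(.data$relative_change)), NA_real_,
                        min(.data$relative_change, na.rm = TRUE)),
      .groups = "drop"
    )
}

#' Plot pair co-occurrence trends
#'
#' Line plot of yearly co-occurrence counts, one line per code pair;
#' partial-coverage years are drawn with open points.
#'
#' @param series A `trend_series` (or [pair_counts_by_year()] output).
#' @return A ggplot object.
#' @export
plot_trends <- function(series) {
  if (!"coverage" %in% names(series)) series$coverage <- 1
  df <- dplyr::mutate(series,
                      pair = paste(.data$code_a, .data$code_b, sep = "-"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$year, y = .data$count,
                                   colour = .data$pair, group = .data$pair)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(ggplot2::aes(shape = .data$coverage < 1), size = 2) +
    ggplot2::scale_shape_manual(values = c(`FALSE` = 16, `TRUE` = 1),
                                name = "partial year") +
    ggplot2::labs(x = "year", y = "patient-year co-occurrence count",
                  colour = "code pair") +
    ggplot2::theme_minimal()
}
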