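#' Aggregate claims into patient-year diagnosis sets
#'
#' The unit of analysis downstream is the patient-year: all diagnosis codes
#' (primary and secondary) recorded for a patient within one calendar year
#' collapse to a set, so repeated claims for the same condition count once
#' per patient per year. The same patient observed in two years contributes
#' two observations.
#'
#' @param claims A `claims_tbl` (or tibble with `patient_id`,
#'   `service_date`, `diagnoses` list-column).
#' @param vocabulary Optional character vector of codes; codes outside it
#'   are dropped (normalized on the way in).
#' @return Tibble of class `diagnosis_sets`, one row per
#'   (patient, year, code): columns `patient_id`, `year`, `code`. Attribute
#'   `years` records the full study span for zero-filling yearly counts.
#' @export
aggregate_patient_windows <- function(claims, vocabulary = NULL) {
  span <- attr(claims, "span")
  sets <- tibble::tibble(
    patient_id = rep(claims$patient_id, lengths(claims$diagnoses)),
    year = rep(as.integer(format(claims$service_date, "%Y")),
               lengths(claims$diagnoses)),
    code = unlist(claims$diagnoses, use.names = FALSE)
  )
  if (!is.null(vocabulary)) {
    vocabulary <- normalize_icd10(vocabulary)
    sets <- dplyr::filter(sets, .data$code %in% vocabulary)
  }
  sets <- dplyr::distinct(sets)
  sets <- dplyr::arrange(sets, .data$patient_id, .data$year, .data$code)
  years <- if (!is.null(span)) span[1]:span[2] else
    if (nrow(sets) > 0) min(sets$year):max(sets$year) else integer(0)
  structure(sets, years = years,
            class = c("diagnosis_sets", class(tibble::as_tibble(sets))))
}

# entries x codes binary presence matrix for one window
presence_matrix <- function(sets, window = "pooled", vocabulary = NULL) {
  years <- attr(sets, "years")
  if (!identical(window, "pooled")) {
    window <- suppressWarnings(as.integer(window))
    if (is.na(window) || (length(years) > 0 && !window %in% years)) {
      stop("unknown window: must be \"pooled\" or a year in the study span",
           call. = FALSE)
    }
    sets <- dplyr::filter(sets, .data$year == window)
  }
  codes <- if (is.null(vocabulary)) sort(unique(sets$code))
           else normalize_icd10(vocabulary)
  entry <- paste(sets$patient_id, sets$year, sep = "\r")
  entries <- sort(unique(entry))
  m <- matrix(0L, length(entries), length(codes),
              dimnames = list(entries, codes))
  keep <- sets$code %in% codes
  m[cbind(match(entry[keep], entries), match(sets$code[keep], codes))] <- 1L
  m
}

#' Patient-year co-occurrence matrix
#'
#' Counts, for every unordered code pair, the number of patient-year
#' observations whose diagnosis set contains both codes; the diagonal holds
#' single-code occurrence counts. Each pair is counted at most once per
#' patient per year by construction, so duplicating claim rows never
#' changes the matrix.
#'
#' @param sets A `diagnosis_sets` table from [aggregate_patient_windows()].
#' @param window A calendar year, or `"pooled"` (default) for the whole
#'   span. The pooled matrix equals the element-wise sum of the per-year
#'   matrices.
#' @param vocabulary Optional code ordering/restriction for the matrix.
#' @return Object of class `cooccurrence_matrix`: integer matrix with code
#'   dimnames plus attributes `window` and `n_entries` (patient-year
#'   observations in the window).
#' @export
count_cooccurrence <- function(sets, window = "pooled", vocabulary = NULL) {
  if (nrow(sets) == 0) stop("empty diagnosis-set table", call. = FALSE)
  m <- presence_matrix(sets, window, vocabulary)
  counts <- crossprod(m)
  storage.mode(counts) <- "integer"
  structure(counts, window = if (identical(window, "pooled")) "pooled"
            else as.integer(window),
            n_entries = nrow(m), class = "cooccurrence_matrix")
}

#' @export
print.cooccurrence_matrix <- function(x, ...) {
  cat(sprintf("<cooccurrence_matrix> %d codes, window %s, %d patient-years\n",
              ncol(x), attr(x, "window"), attr(x, "n_entries")))
  print(unclass(x))
  invisible(x)
}

#' @export
as.matrix.cooccurrence_matrix <- function(x, ...) {
  structure(unclass(x), window = NULL, n_entries = NULL)
}

#' Tidy a co-occurrence matrix into a long pair-count table
#'
#' @param x A `cooccurrence_matrix`.
#' @param diagonal Include single-code (diagonal) counts? Default `FALSE`.
#' @param ... Unused.
#' @return Tibble `code_a`, `code_b`, `window`, `count` with
#'   `code_a < code_b` (plus `code_a == code_b` rows when
#'   `diagonal = TRUE`).
#' @method tidy cooccurrence_matrix
#' @export
tidy.cooccurrence_matrix <- function(x, diagonal = FALSE, ...) {
  codes <- colnames(x)
  idx <- which(upper.tri(x, diag = diagonal), arr.ind = TRUE)
  tibble::tibble(
    code_a = codes[idx[, 1]],
    code_b = codes[idx[, 2]],
    window = as.character(attr(x, "window")),
    count = as.integer(x[idx])
  )
}

#' Write a co-occurrence matrix as delimited text
#'
#' Writes both the square labelled matrix (`<stem>_matrix.csv`) and the
#' long pair-count table (`<stem>_pairs.csv`, diagonal included).
#'
#' @param x A `cooccurrence_matrix`.
#' @param stem Output path stem (without extension).
#' @return The two paths, invisibly.
#' @export
write_cooccurrence <- function(x, stem) {
  sq <- paste0(stem, "_matrix.csv")
  lg <- paste0(stem, "_pairs.csv")
  wide <- tibble::as_tibble(as.matrix(x), rownames = "code")
  readr::write_csv(wide, sq)
  readr::write_csv(tidy.cooccurrence_matrix(x, diagonal = TRUE), lg)
  invisible(c(sq, lg))
}

#' Yearly co-occurrence counts for selected code pairs
#'
#' The longitudinal counterpart of [count_cooccurrence()]: for each
#' requested pair, the per-year patient-year co-occurrence count, with
#' years in the study span that have no co-occurrences reported as 0
#' rather than missing.
#'
#' @param sets A `diagnosis_sets` table.
#' @param pairs Tibble/data frame with columns `code_a`, `code_b`, or a
#'   list of 2-element character vectors.
#' @param years Optional integer vector of years to report (default: the
#'   study span recorded on `sets`).
#' @return Tibble `code_a`, `code_b`, `year`, `count`.
#' @export
pair_counts_by_year <- function(sets, pairs, years = NULL) {
  if (is.list(pairs) && !is.data.frame(pairs)) {
    pairs <- tibble::tibble(code_a = vapply(pairs, `[`, "", 1),
                            code_b = vapply(pairs, `[`, "", 2))
  }
  pairs <- tibble::as_tibble(pairs)[, c("code_a", "code_b")]
  pairs$code_a <- normalize_icd10(pairs$code_a)
  pairs$code_b <- normalize_icd10(pairs$code_b)
  if (is.null(years)) years <- attr(sets, "years")
  # per-year presence join: count patient-years holding both codes
  counts <- purrr::map_dfr(seq_len(nrow(pairs)), function(i) {
    a <- pairs$code_a[i]; b <- pairs$code_b[i]
    has_a <- dplyr::filter(sets, .data$code == a)[, c("patient_id", "year")]
    has_b <- dplyr::filter(sets, .data$code == b)[, c("patient_id", "year")]
    both <- dplyr::inner_join(has_a, has_b, by = c("patient_id", "year"))
    tally <- dplyr::count(both, .data$year, name = "count")
    dplyr::left_join(tibble::tibble(code_a = a, code_b = b, year = years),
                     tally, by = "year")
  })
  counts$count <- as.integer(dplyr::coalesce(counts$count, 0L))
  counts
}
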