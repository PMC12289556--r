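#' Normalize ICD-10 diagnosis codes
#'
#' Claims sources mix two dialects of the same code: dotted (`"E78.5"`) and
#' undotted (`"E785"`). All comorbnet stages work on the undotted, uppercase
#' form, so `normalize_icd10()` is applied at every ingestion point.
#' Normalization trims whitespace, uppercases, removes a single dot, and
#' validates against the ICD-10 shape: one letter, two digits, then up to
#' four further alphanumerics (total length 3--7).
#'
#' Normalization is idempotent: applying it to an already-normalized code
#' returns the code unchanged.
#'
#' @param x Character vector of raw codes.
#' @param strict If `TRUE` (default), malformed codes raise an error naming
#'   the offending raw value; if `FALSE` they become `NA` so callers can
#'   drop and count them.
#' @return Character vector of normalized codes (with `NA` for malformed
#'   input when `strict = FALSE`).
#' @examples
#' normalize_icd10(c("E78.5", " j45.909 "))  # "E785" "J45909"
#' @export
normalize_icd10 <- function(x, strict = TRUE) {
  if (length(x) == 0) return(character(0))
  raw <- x
  out <- toupper(gsub("\\s", "", as.character(x)))
  # remove at most one dot; a second dot fails the pattern below
  out <- sub(".", "", out, fixed = TRUE)
  ok <- grepl("^[A-Z][0-9]{2}[A-Z0-9]{0,4}$", out) & !is.na(out)
  if (any(!ok)) {
    if (strict) {
      bad <- unique(raw[!ok])
      stop("malformed ICD-10 code(s): ",
           paste(utils::head(bad, 5), collapse = ", "),
           if (length(bad) > 5) " ..." else "",
           call. = FALSE)
    }
    out[!ok] <- NA_character_
  }
  out
}

#' Default column mapping for claims files
#'
#' Maps the canonical record fields onto the column names of a delimited
#' claims file. `diagnosis` names the primary-diagnosis column; any columns
#' whose names start with `secondary_prefix` are read as secondary
#' diagnoses, in order.
#'
#' @param patient_id,service_date,diagnosis,age,sex Column names in the file.
#' @param secondary_prefix Prefix shared by secondary-diagnosis columns.
#' @return Named list used by [read_claims()].
#' @export
claims_cols <- function(patient_id = "patient_id",
                        service_date = "service_date",
                        diagnosis = "dx1",
                        secondary_prefix = "dx",
                        age = "age",
                        sex = "sex") {
  list(patient_id = patient_id, service_date = service_date,
       diagnosis = diagnosis, secondary_prefix = secondary_prefix,
       age = age, sex = sex)
}

# Sex recoding: F and M pass through, everything else (incl. NA) is
# "unspecified or other".
recode_sex <- function(x) {
  x <- toupper(trimws(as.character(x)))
  out <- rep("U", length(x))
  out[x %in% c("F", "M")] <- x[x %in% c("F", "M")]
  out
}

parse_claim_dates <- function(x, date_format = c("iso", "us")) {
  date_format <- match.arg(date_format)
  fmt <- if (date_format == "iso") "%Y-%m-%d" else "%m/%d/%Y"
  as.Date(as.character(x), format = fmt)
}

#' Read a delimited claims table
#'
#' Reads one-claim-per-row delimited text (CSV by default) into a validated
#' claims tibble: `patient_id`, `service_date`, a `diagnoses` list-column of
#' normalized ICD-10 codes (first element primary, the rest secondary),
#' `age` and `sex`. Rows with unparseable dates, or whose diagnosis cells
#' are all malformed/blank, are dropped and counted in the load report
#' (`attr(x, "load_report")`). Ages above 90 are top-coded to 90 and
#' negative ages dropped; sex values other than F/M map to `"U"`.
#'
#' @param path Path to the delimited file.
#' @param col_map Column mapping from [claims_cols()].
#' @param date_format `"iso"` (`YYYY-MM-DD`, default) or `"us"`
#'   (`MM/DD/YYYY`).
#' @param study_span Optional integer vector of length 2 (first and last
#'   calendar year); records outside the span are dropped and counted.
#'   Defaults to the span observed in the data.
#' @param delim Field delimiter, default `","`.
#' @return A tibble of class `claims_tbl` with attributes `span` (first and
#'   last year) and `load_report` (named list of drop counts).
#' @export
read_claims <- function(path, col_map = claims_cols(),
                        date_format = c("iso", "us"),
                        study_span = NULL, delim = ",") {
  date_format <- match.arg(date_format)
  raw <- readr::read_delim(path, delim = delim, col_types = readr::cols(.default = "c"),
                           progress = FALSE, show_col_types = FALSE)
  if (nrow(raw) == 0) stop("empty claims file: ", path, call. = FALSE)
  required <- c(col_map$patient_id, col_map$service_date, col_map$diagnosis)
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0) {
    stop("claims file missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  dx_cols <- grep(paste0("^", col_map$secondary_prefix), names(raw), value = TRUE)
  dx_cols <- union(col_map$diagnosis, dx_cols)

  dates <- parse_claim_dates(raw[[col_map$service_date]], date_format)
  dx_mat <- as.matrix(raw[dx_cols])
  dx_mat[dx_mat == ""] <- NA_character_
  norm_mat <- matrix(normalize_icd10(dx_mat, strict = FALSE),
                     nrow = nrow(dx_mat), dimnames = dimnames(dx_mat))
  diagnoses <- apply(norm_mat, 1L, function(r) unname(r[!is.na(r)]),
                     simplify = FALSE)

  bad_date <- is.na(dates)
  no_code <- lengths(diagnoses) == 0
  age <- if (!is.null(col_map$age) && col_map$age %in% names(raw)) {
    suppressWarnings(as.numeric(raw[[col_map$age]]))
  } else rep(NA_real_, nrow(raw))
  bad_age <- !is.na(age) & age < 0
  age <- pmin(age, 90)

  sex <- if (!is.null(col_map$sex) && col_map$sex %in% names(raw)) {
    recode_sex(raw[[col_map$sex]])
  } else rep("U", nrow(raw))

  out_of_span <- rep(FALSE, nrow(raw))
  if (!is.null(study_span)) {
    yr <- as.integer(format(dates, "%Y"))
    out_of_span <- !is.na(yr) & (yr < study_span[1] | yr > study_span[2])
  }
  drop <- bad_date | no_code | bad_age | out_of_span
  report <- list(
    n_read = nrow(raw),
    dropped = sum(drop),
    dropped_bad_date = sum(bad_date),
    dropped_no_valid_code = sum(no_code & !bad_date),
    dropped_bad_age = sum(bad_age & !bad_date & !no_code),
    dropped_out_of_span = sum(out_of_span & !bad_date & !no_code & !bad_age)
  )
  keep <- !drop
  tbl <- tibble::tibble(
    patient_id = as.character(raw[[col_map$patient_id]][keep]),
    service_date = dates[keep],
    diagnoses = diagnoses[keep],
    age = as.integer(round(age[keep])),
    sex = sex[keep]
  )
  if (nrow(tbl) == 0) stop("no valid claim rows in ", path, call. = FALSE)
  years <- as.integer(format(tbl$service_date, "%Y"))
  span <- if (is.null(study_span)) range(years) else as.integer(study_span)
  new_claims_tbl(tbl, span = span, load_report = report)
}

new_claims_tbl <- function(tbl, span, load_report = NULL) {
  structure(tbl, span = span, load_report = load_report,
            class = c("claims_tbl", class(tibble::as_tibble(tbl))))
}

#' @export
print.claims_tbl <- function(x, ...) {
  span <- attr(x, "span")
  cat(sprintf("<claims_tbl> %d claims, %d patients, span %d-%d\n",
              nrow(x), dplyr::n_distinct(x$patient_id), span[1], span[2]))
  NextMethod()
}

#' Write a claims tibble back to delimited text
#'
#' Writes the `read_claims()` dialect: `patient_id`, `service_date`
#' (ISO-8601), diagnosis columns `dx1..dxK` (primary first), `age`, `sex`.
#' `read_claims(write_claims(x))` round-trips the table.
#'
#' @param claims A `claims_tbl`.
#' @param path Output path.
#' @param delim Field delimiter.
#' @return `path`, invisibly.
#' @export
write_claims <- function(claims, path, delim = ",") {
  k <- max(lengths(claims$diagnoses))
  dx <- matrix(vapply(claims$diagnoses,
                      function(d) c(d, rep("", k - length(d))), character(k)),
               nrow = nrow(claims), ncol = k, byrow = TRUE)
  dx_tbl <- tibble::as_tibble(dx, .name_repair = ~ paste0("dx", seq_len(k)))
  out <- dplyr::bind_cols(
    tibble::tibble(patient_id = claims$patient_id,
                   service_date = format(claims$service_date, "%Y-%m-%d")),
    dx_tbl,
    tibble::tibble(age = claims$age, sex = claims$sex)
  )
  readr::write_delim(out, path, delim = delim, na = "")
  invisible(path)
}

# Round half away from zero at `digits` decimals (the reporting convention
# for percentages; base round() would round half to even).
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Quartiles by the median-of-halves convention: split the sorted values at
# the median (the median itself excluded when n is odd) and take the median
# of each half.
quartiles_moh <- function(x) {
  x <- sort(x)
  n <- length(x)
  if (n == 1) return(c(q25 = x, q75 = x))
  lower <- x[seq_len(floor(n / 2))]
  upper <- x[seq.int(ceiling(n / 2) + 1L, n)]
  c(q25 = stats::median(lower), q75 = stats::median(upper))
}

#' Sex percentages from record counts
#'
#' The reporting rule used throughout: `100 * count / total`, rounded half
#' up to one decimal. Exposed separately so the rule can be applied to
#' externally reported count tables as well as to claims read in full.
#'
#' @param counts Named numeric vector of record counts per sex category.
#' @return Tibble with `sex`, `n`, `pct`.
#' @export
sex_percentages <- function(counts) {
  total <- sum(counts)
  tibble::tibble(
    sex = names(counts),
    n = as.numeric(counts),
    pct = round_half_up(100 * as.numeric(counts) / total, 1)
  )
}

#' Summarize a claims cohort at the record level
#'
#' Record-level (not patient-level) demographic summary: every claim row
#' contributes once, mirroring how claims datasets report utilization
#' demographics ("female records"). Age quartiles use the median-of-halves
#' convention; sex percentages use [sex_percentages()].
#'
#' @param claims A `claims_tbl` (or any tibble with `age` and `sex`).
#' @return One-row tibble: `n_records`, `age_mean`, `age_sd`, `age_median`,
#'   `age_q25`, `age_q75`, `n_female`, `n_male`, `n_unspecified`,
#'   `pct_female`, `pct_male`, `pct_unspecified`.
#' @export
summarize_cohort <- function(claims) {
  if (nrow(claims) == 0) stop("empty claims table", call. = FALSE)
  age <- claims$age[!is.na(claims$age)]
  qs <- quartiles_moh(age)
  counts <- c(F = sum(claims$sex == "F"),
              M = sum(claims$sex == "M"),
              U = sum(claims$sex == "U"))
  pct <- sex_percentages(counts)
  tibble::tibble(
    n_records = nrow(claims),
    age_mean = mean(age),
    age_sd = stats::sd(age),
    age_median = stats::median(age),
    age_q25 = qs[["q25"]],
    age_q75 = qs[["q75"]],
    n_female = counts[["F"]],
    n_male = counts[["M"]],
    n_unspecified = counts[["U"]],
    pct_female = pct$pct[pct$sex == "F"],
    pct_male = pct$pct[pct$sex == "M"],
    pct_unspecified = pct$pct[pct$sex == "U"]
  )
}

#' Clinical labels for the focal ICD-10 vocabulary
#'
#' Human-readable labels for the respiratory and systemic codes the package
#' ships as its default vocabulary, in normalized (undotted) form.
#'
#' @param codes Optional character vector; returns labels for those codes
#'   (`NA` where unknown). Default: the full built-in table.
#' @return Named character vector, names are normalized codes.
#' @export
icd10_labels <- function(codes = NULL) {
  labs <- c(
    J45909 = "Asthma", J449 = "COPD", J9601 = "Acute respiratory failure",
    J189 = "Pneumonia", J441 = "COPD with acute exacerbation",
    I10 = "Hypertension", E785 = "Hyperlipidemia",
    E119 = "Type 2 diabetes", K219 = "GERD", F419 = "Anxiety disorder",
    F329 = "Depressive disorder", E6601 = "Morbid obesity",
    E669 = "Obesity", E876 = "Hyperpotassemia",
    E1122 = "Type 2 diabetes with kidney disease",
    E1151 = "Type 2 diabetes with angiopathy"
  )
  if (is.null(codes)) return(labs)
  out <- labs[codes]
  names(out) <- codes
  out
}
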