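# Value-level normalizers: the small, heavily exercised cleaning rules the
# ETL applies to messy source cells.

# ER / PR / HR value codes used by the receptor-status truth table.
.ER_POS <- 4167696L; .ER_NEG <- 4261933L
.PR_POS <- 4194663L; .PR_NEG <- 4194662L
.HR_POS <- 4035444L; .HR_NEG <- 4035445L
.LAT_LEFT <- 4218674L; .LAT_RIGHT <- 4218675L
.BREAST_NOS <- 35941059L

#' Canonical token normalization
#'
#' Trims, collapses internal whitespace and lowercases a source token;
#' recode maps are keyed on this canonical form so case and spacing noise
#' in source files never matters.
#'
#' @param x Character vector.
#' @return Normalized character vector.
#' @export
normalize_token <- function(x) {
  x <- gsub("\\s+", " ", trimws(as.character(x)))
  tolower(x)
}

#' Derive hormone-receptor status from ER and PR status
#'
#' The clinical disjunction: HR-positive if either receptor is positive,
#' HR-negative if both are negative, otherwise (no positive and at least
#' one receptor unknown) Not provided.
#'
#' @param er,pr ER / PR value codes (positive, negative, or the
#'   Not-provided code).
#' @return The HR status value code.
#' @export
derive_hr_status <- function(er, pr) {
  er <- as.integer(er); pr <- as.integer(pr)
  if (!er %in% c(.ER_POS, .ER_NEG, NOT_PROVIDED))
    stop("derive_hr_status: unregistered ER code ", er)
  if (!pr %in% c(.PR_POS, .PR_NEG, NOT_PROVIDED))
    stop("derive_hr_status: unregistered PR code ", pr)
  if (er == .ER_POS || pr == .PR_POS) return(.HR_POS)
  if (er == .ER_NEG && pr == .PR_NEG) return(.HR_NEG)
  NOT_PROVIDED
}

#' Encode a multi-valued cell
#'
#' Canonical form for `coded_multi` cells: deduplicated, sorted ascending
#' by OMOP ID, joined with a vertical bar. An empty list encodes as the
#' Not-provided code, so the cell is never empty.
#'
#' @param values Integer vector of value codes (possibly empty).
#' @return Single cell string.
#' @export
encode_multivalue <- function(values) {
  values <- unique(as.integer(values))
  values <- values[!is.na(values)]
  if (!length(values)) return(as.character(NOT_PROVIDED))
  paste(sort(values), collapse = "|")
}

#' Decode a multi-valued cell
#' @param cell Cell string as produced by [encode_multivalue()].
#' @return Integer vector of value codes.
#' @export
decode_multivalue <- function(cell) {
  as.integer(strsplit(as.character(cell), "|", fixed = TRUE)[[1]])
}

#' Recode a detailed value to its generic parent
#'
#' Dual-granularity value sets (TNM categories, stage groups) register both
#' detailed codes (N1a, N0(i-), Stage IIA) and their generic parents (N1,
#' N0, Stage II). This maps a detailed code to its parent; generic codes
#' and Not provided map to themselves, making the operation idempotent.
#'
#' @param value_id A registered value code of `field`.
#' @param field CDM field name.
#' @param cdm A `cdm_definition`.
#' @return The generic value code.
#' @export
recode_generic <- function(value_id, field, cdm) {
  value_id <- as.integer(value_id)
  cc <- cdm_concept(cdm, field)
  vals <- cc$values
  i <- match(value_id, vals$omop_id)
  if (is.na(i))
    stop("recode_generic: value ", value_id,
         " is not registered for field '", field, "'")
  parent <- vals$generic_parent[i]
  if (is.na(parent)) value_id else parent
}

#' The shipped clock-face to breast-quadrant table
#'
#' Patient-facing clock convention, boundary hours assigned to the
#' clockwise-following quadrant; shipped as configuration so it can be
#' re-curated without touching code.
#'
#' @return Data frame with `laterality`, `hour`, `quadrant`, `icdo3`,
#'   `omop_id`.
#' @export
clock_quadrant_table <- function() {
  path <- system.file("extdata", "cdm", "clock_quadrant.csv",
                      package = "omopmri", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

# Extracts the clock hour (possibly fractional) from a position string:
# tolerates half hours ("11:30") and ranges ("4-5", midpoint taken).
.parse_clock_hour <- function(text) {
  m <- regmatches(text, regexec(
    "(\\d{1,2})(?::(\\d{2}))?(?:\\s*-\\s*(\\d{1,2})(?::(\\d{2}))?)?",
    text))[[1]]
  if (!length(m) || !nzchar(m[2])) return(NA_real_)
  h1 <- as.numeric(m[2]) + ifelse(nzchar(m[3]), as.numeric(m[3]) / 60, 0)
  if (h1 < 1 || h1 >= 13) return(NA_real_)
  if (nzchar(m[4])) {
    h2 <- as.numeric(m[4]) + ifelse(nzchar(m[5]), as.numeric(m[5]) / 60, 0)
    if (h2 >= 1 && h2 < 13) h1 <- (h1 + h2) / 2
  }
  h1
}

.parse_laterality_letter <- function(text) {
  t <- normalize_token(text)
  # leading bare letter ("L 2", "r4-5") or the spelled-out word
  if (grepl("^l(?![a-z])", t, perl = TRUE) || grepl("\\bleft\\b", t))
    return("L")
  if (grepl("^r(?![a-z])", t, perl = TRUE) || grepl("\\bright\\b", t))
    return("R")
  NA_character_
}

#' Parse a free-text tumor-position string
#'
#' Total on strings. Extracts laterality (L/R, or the words left/right) and
#' the clock position, tolerating half hours ("L 11:30"), ranges ("R4-5",
#' midpoint taken) and trailing noise ("L 2 with calcs"). The clock hour is
#' mapped to a breast quadrant via the shipped clock table and the quadrant
#' to its ICD-O-3 topography code. A parsable laterality without a clock
#' maps to the breast-NOS code; nothing parsable maps to Not provided.
#'
#' @param text Position string (e.g. `"L 2 with calcs"`).
#' @return List with `site` and `laterality` value codes.
#' @export
parse_tumor_position <- function(text) {
  if (is.null(text) || length(text) == 0L || is.na(text) ||
      !nzchar(trimws(text)))
    return(list(site = NOT_PROVIDED, laterality = NOT_PROVIDED))
  lat <- .parse_laterality_letter(text)
  if (is.na(lat))
    return(list(site = NOT_PROVIDED, laterality = NOT_PROVIDED))
  lat_id <- if (lat == "L") .LAT_LEFT else .LAT_RIGHT
  hour <- .parse_clock_hour(text)
  if (is.na(hour))
    return(list(site = .BREAST_NOS, laterality = lat_id))
  key <- floor(hour %% 12)
  if (key == 0) key <- 12
  tab <- clock_quadrant_table()
  hit <- tab[tab$laterality == lat & tab$hour == key, , drop = FALSE]
  if (nrow(hit) != 1L)  # clock table incomplete: fall back to breast NOS
    return(list(site = .BREAST_NOS, laterality = lat_id))
  list(site = as.integer(hit$omop_id), laterality = lat_id)
}
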