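# The harmonization engine: applies a mapping spec to a source table and
# emits the fully coded CDM table with per-cell provenance. Every retained
# subject gets a value for every CDM field; anything the rules cannot code
# is imputed with the Not-provided concept, so no cell is ever empty.

.YES <- 4188539L
.NO <- 4188540L
.CYCLOPHOSPHAMIDE <- 19010482L

# ---- named derivations / parsers ------------------------------------------
# A parser maps the raw token(s) of one subject to one canonical cell
# string; failures demote to Not provided (never fatal). Registered here by
# name so mapping specs stay declarative.

.as_numeric_cell <- function(tokens, ctx) {
  tok <- trimws(tokens[[1]])
  if (!nzchar(tok) || is.na(tok)) return(as.character(NOT_PROVIDED))
  num <- suppressWarnings(as.numeric(tok))
  if (is.na(num)) return(as.character(NOT_PROVIDED))
  as.character(num)
}

.medication_lexicon <- function(cdm) {
  vals <- cdm_concept(cdm, "neoadjuvant_chemo_medication")$values
  vals <- vals[vals$omop_id != NOT_PROVIDED, , drop = FALSE]
  stats::setNames(vals$omop_id, tolower(vals$label))
}

.scan_medications <- function(token, cdm) {
  tok <- normalize_token(token)
  if (!nzchar(tok)) return(integer(0))
  lex <- .medication_lexicon(cdm)
  hits <- vapply(names(lex), function(drug) grepl(drug, tok, fixed = TRUE),
                 logical(1))
  unname(lex[hits])
}

.medication_list_cell <- function(tokens, ctx) {
  encode_multivalue(.scan_medications(tokens[[1]], ctx$cdm))
}

.ispy2_arm_medication_cell <- function(tokens, ctx) {
  drugs <- .scan_medications(tokens[[1]], ctx$cdm)
  if (!length(drugs)) return(as.character(NOT_PROVIDED))
  # cyclophosphamide was administered in every arm in addition to the
  # arm-specific agents listed in the source file
  encode_multivalue(c(drugs, .CYCLOPHOSPHAMIDE))
}

.binary_receptor <- function(token, pos, neg) {
  switch(normalize_token(token), "1" = pos, "0" = neg, NOT_PROVIDED)
}

.text_receptor <- function(token, pos, neg) {
  switch(normalize_token(token), positive = pos, negative = neg,
         NOT_PROVIDED)
}

.hr_from_er_pr_cell <- function(tokens, ctx) {
  er <- .binary_receptor(tokens[[1]], .ER_POS, .ER_NEG)
  pr <- .binary_receptor(tokens[[2]], .PR_POS, .PR_NEG)
  as.character(derive_hr_status(er, pr))
}

.hr_from_er_pr_text_cell <- function(tokens, ctx) {
  er <- .text_receptor(tokens[[1]], .ER_POS, .ER_NEG)
  pr <- .text_receptor(tokens[[2]], .PR_POS, .PR_NEG)
  as.character(derive_hr_status(er, pr))
}

.pcr_from_rcb_cell <- function(tokens, ctx) {
  tok <- normalize_token(tokens[[1]])
  if (tok == "0") return(as.character(.YES))
  if (tok %in% c("1", "2", "3")) return(as.character(.NO))
  as.character(NOT_PROVIDED)
}

.tumor_position_site_cell <- function(tokens, ctx) {
  as.character(parse_tumor_position(tokens[[1]])$site)
}

.tumor_position_laterality_cell <- function(tokens, ctx) {
  as.character(parse_tumor_position(tokens[[1]])$laterality)
}

.ETL_FNS <- list(
  as_numeric = .as_numeric_cell,
  medication_list = .medication_list_cell,
  ispy2_arm_medication = .ispy2_arm_medication_cell,
  hr_from_er_pr = .hr_from_er_pr_cell,
  hr_from_er_pr_text = .hr_from_er_pr_text_cell,
  pcr_from_rcb = .pcr_from_rcb_cell,
  tumor_position_site = .tumor_position_site_cell,
  tumor_position_laterality = .tumor_position_laterality_cell)

.etl_fn <- function(name) .ETL_FNS[[name]]

# ---- source tables --------------------------------------------------------

#' Load a source clinical table
#'
#' Reads a dataset's clinical CSV with the dataset-specific preparatory
#' cleanup applied (header-row skipping, as configured in the mapping
#' spec); cell values are otherwise untouched (all columns read as text).
#'
#' @param path CSV file.
#' @param dataset_id One of the known dataset identifiers.
#' @param spec Mapping spec (defaults to the shipped spec for
#'   `dataset_id`), used for the subject-id column and rows to skip.
#' @return A `source_table` object.
#' @export
load_source_table <- function(path, dataset_id,
                              spec = load_mapping_spec(
                                mapping_spec_path(dataset_id))) {
  dataset_id <- match.arg(dataset_id, .DATASET_IDS)
  if (!file.exists(path)) stop("source file not found: ", path)
  df <- tryCatch(
    utils::read.csv(path, skip = spec$skip_rows, colClasses = "character",
                    check.names = FALSE),
    error = function(e) stop("load error for '", path, "': ",
                             conditionMessage(e)))
  idcol <- spec$subject_id_column
  if (!idcol %in% names(df))
    stop("load error: subject-id column '", idcol, "' not present in '",
         path, "'")
  ids <- trimws(df[[idcol]])
  dup <- ids[nzchar(ids) & duplicated(ids)]
  if (length(dup))
    stop("load error: duplicate subject id '", dup[1], "' in '", path, "'")
  structure(list(dataset_id = dataset_id, data = df,
                 subject_id_column = idcol),
            class = "source_table")
}

# Subjects retained after the explicit exclusion predicate: by default only
# rows with an unparseable (blank) identifier are dropped, plus any ids the
# spec lists explicitly.
.retained_subjects <- function(table, spec) {
  ids <- trimws(table$data[[table$subject_id_column]])
  keep <- nzchar(ids) & !is.na(ids)
  excl <- as.character(unlist(spec$exclusions))
  if (length(excl)) keep <- keep & !ids %in% excl
  keep
}

# ---- harmonization --------------------------------------------------------

.apply_rule <- function(rule, row, ctx) {
  if (rule$kind == "constant") return(as.character(rule$value))
  tokens <- lapply(rule$source, function(col) {
    v <- row[[col]]
    if (is.null(v) || is.na(v)) "" else v
  })
  if (rule$kind == "direct_recode") {
    tok <- normalize_token(tokens[[1]])
    if (!nzchar(tok)) return(as.character(NOT_PROVIDED))
    hit <- rule$map[[tok]]
    return(if (is.null(hit)) as.character(NOT_PROVIDED)
           else as.character(hit))
  }
  fn <- .etl_fn(rule$derivation %||% rule$parser)
  fn(tokens, ctx)
}

#' Harmonize a source table into the CDM
#'
#' For each retained subject and each CDM field, applies the spec's rule if
#' one exists, otherwise emits Not provided; per-subject overrides are
#' applied last. Every emitted coded value is checked against the registry
#' (an unregistered value is a spec bug and a hard error); parser failures
#' demote the cell to Not provided with a log entry. Deterministic: the
#' same inputs always produce an identical table.
#'
#' @param table A `source_table`.
#' @param spec The matching `mapping_spec`.
#' @param cdm A `cdm_definition`.
#' @return A `harmonized_table`: `table` (data frame with `subject_id`,
#'   `dataset_id` and one column per CDM field), `provenance` (rule kind
#'   per cell), `log` (character vector of demotions), and `coverage`
#'   (see [coverage_report()]).
#' @export
harmonize <- function(table, spec, cdm) {
  stopifnot(inherits(table, "source_table"), inherits(spec, "mapping_spec"),
            inherits(cdm, "cdm_definition"))
  if (table$dataset_id != spec$dataset_id)
    stop("spec is for dataset '", spec$dataset_id, "' but table is '",
         table$dataset_id, "'")
  validate_mapping_spec(spec, cdm)

  fields <- cdm_fields(cdm)
  rules <- stats::setNames(spec$rules,
                           vapply(spec$rules, `[[`, character(1), "target"))
  keep <- .retained_subjects(table, spec)
  data <- table$data[keep, , drop = FALSE]
  ids <- trimws(data[[table$subject_id_column]])
  ctx <- list(cdm = cdm, spec = spec)
  log <- character(0)

  out <- matrix(as.character(NOT_PROVIDED), nrow = nrow(data),
                ncol = length(fields), dimnames = list(NULL, fields))
  prov <- matrix("imputed", nrow = nrow(data), ncol = length(fields),
                 dimnames = list(NULL, fields))

  for (i in seq_len(nrow(data))) {
    row <- as.list(data[i, , drop = FALSE])
    for (fn in names(rules)) {
      rule <- rules[[fn]]
      cell <- .apply_rule(rule, row, ctx)
      if (cell == as.character(NOT_PROVIDED) &&
          rule$kind != "constant") {
        raw <- paste(vapply(rule$source, function(col)
          if (is.null(row[[col]]) || is.na(row[[col]])) "" else row[[col]],
          character(1)), collapse = "/")
        if (nzchar(trimws(raw)))
          log <- c(log, paste0(spec$dataset_id, " subject ", ids[i], " ",
                               fn, ": token '", raw,
                               "' not mapped; imputed Not provided"))
      }
      out[i, fn] <- cell
      prov[i, fn] <- rule$kind
    }
  }

  for (ov in spec$overrides) {
    j <- which(ids == as.character(ov$subject))
    if (length(j)) {
      out[j, ov$field] <- as.character(ov$value)
      prov[j, ov$field] <- "override"
    }
  }

  # closed over the registry: any non-imputed coded cell must validate
  for (fn in fields) {
    cc <- cdm_concept(cdm, fn)
    if (cc$value_domain == "scalar_numeric") next
    codes <- unique(unlist(strsplit(out[, fn], "|", fixed = TRUE)))
    unreg <- setdiff(as.integer(codes), registered_values(cdm, fn))
    if (length(unreg))
      stop("spec bug: rule for '", fn, "' emitted unregistered value(s) ",
           paste(unreg, collapse = ", "))
  }

  tab <- data.frame(subject_id = ids, dataset_id = spec$dataset_id,
                    out, check.names = FALSE, stringsAsFactors = FALSE)
  res <- structure(list(table = tab, provenance = prov, log = log,
                        dataset_id = spec$dataset_id),
                   class = "harmonized_table")
  res$coverage <- coverage_report(spec, cdm, table)
  res
}

#' Coverage report for one dataset's mapping
#'
#' Counts the subjects retained and the CDM fields with a rule, with
#' percentages relative to the original file (mapped concepts over the
#' source file's concept count, which may exceed 100% when one source
#' concept feeds several CDM fields). Percentages are stored unrounded;
#' the print method rounds to integer percent.
#'
#' @param spec A `mapping_spec`.
#' @param cdm A `cdm_definition`.
#' @param table A `source_table` for the same dataset.
#' @return A `coverage_report` list.
#' @export
coverage_report <- function(spec, cdm, table) {
  stopifnot(inherits(spec, "mapping_spec"))
  info <- source_dataset_info()[[spec$dataset_id]]
  subjects_in <- nrow(table$data)
  subjects_included <- sum(.retained_subjects(table, spec))
  concepts_mapped <- length(spec$rules)
  structure(list(
    dataset_id = spec$dataset_id,
    subjects_in = subjects_in,
    subjects_included = subjects_included,
    concepts_mapped = concepts_mapped,
    source_concepts = info$concepts,
    percent_subjects = if (subjects_in > 0)
      100 * subjects_included / subjects_in else 0,
    percent_concepts = if (info$concepts > 0)
      100 * concepts_mapped / info$concepts else 0),
    class = "coverage_report")
}

#' @export
print.coverage_report <- function(x, ...) {
  cat(sprintf("%s: %d/%d subjects (%d%%), %d concepts mapped (%d%%)\n",
              x$dataset_id, x$subjects_included, x$subjects_in,
              round(x$percent_subjects), x$concepts_mapped,
              round(x$percent_concepts)))
  invisible(x)
}

#' Write a harmonized table to CSV
#'
#' Byte-stable across repeated runs on the same inputs.
#'
#' @param h A `harmonized_table`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_harmonized_csv <- function(h, path) {
  stopifnot(inherits(h, "harmonized_table"))
  utils::write.csv(h$table, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}
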