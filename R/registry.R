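#' @title Common data model registry
#' @description Load, validate, save and summarize the coded common data
#'   model (CDM): concepts, their OMOP IDs and vocabularies, and the curated
#'   value sets every harmonized cell must come from.
#' @name cdm-registry
NULL

#' Reserved OMOP concept ID for "Not provided"
#'
#' Every coded concept's value set implicitly contains this code; it is the
#' imputation value for missing, unparseable, or unmapped source cells, so
#' the harmonized table never has an empty cell.
#'
#' @export
NOT_PROVIDED <- 763013L

# Vocabulary of the reserved Not-provided concept (its OMOP source
# vocabulary); it is counted exactly once in vocabulary usage.
.NOT_PROVIDED_VOCAB <- "PPI"

.CONCEPT_GROUPS <- c("demographic", "pathology", "treatment", "outcome",
                     "imaging_context")
.VALUE_DOMAINS <- c("scalar_numeric", "coded_single", "coded_multi")

.not_provided_valuedef <- function() {
  data.frame(omop_id = NOT_PROVIDED, vocabulary = .NOT_PROVIDED_VOCAB,
             label = "Not provided", granularity = "generic",
             generic_parent = NA_integer_, stringsAsFactors = FALSE)
}

#' Path of the registry shipped with the package
#'
#' @return Path to the installed `registry.csv`.
#' @export
cdm_registry_path <- function() {
  system.file("extdata", "cdm", "registry.csv", package = "omopmri",
              mustWork = TRUE)
}

#' Load a CDM registry file
#'
#' The registry is a single reviewable CSV: `concept` rows define a field
#' (name, OMOP ID, vocabulary, group, value domain, units for scalars) and
#' `value` rows attach coded values to the concept named in their
#' `field_name` column. Dual-granularity value sets carry a
#' `generic_parent` OMOP ID on each detailed code. The reserved
#' Not-provided code is attached to every coded value set by the loader and
#' is not stored in the file.
#'
#' @param path Registry CSV; defaults to the registry shipped with the
#'   package.
#' @return A `cdm_definition`: ordered list of concept definitions plus a
#'   version string. Loading is order-preserving and deterministic.
#' @export
load_cdm_registry <- function(path = cdm_registry_path()) {
  if (!file.exists(path)) stop("registry file not found: ", path)
  raw <- tryCatch(
    utils::read.csv(path, colClasses = "character", check.names = FALSE),
    error = function(e) stop("registry parse failure in '", path, "': ",
                             conditionMessage(e)))
  need <- c("record", "field_name", "omop_id", "vocabulary", "label",
            "concept_group", "value_domain", "granularity",
            "generic_parent", "units")
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols))
    stop("registry format error: missing column(s) ",
         paste(missing_cols, collapse = ", "))
  bad <- which(!raw$record %in% c("concept", "value"))
  if (length(bad))
    stop("registry format error at line ", bad[1] + 1L,
         ": record must be 'concept' or 'value'")

  concepts <- list()
  order_names <- character(0)
  for (i in seq_len(nrow(raw))) {
    row <- raw[i, ]
    if (row$record == "concept") {
      fn <- row$field_name
      if (fn %in% order_names)
        stop("registry validation error: duplicate field_name '", fn, "'")
      if (!row$concept_group %in% .CONCEPT_GROUPS)
        stop("registry validation error: unknown concept_group '",
             row$concept_group, "' for '", fn, "'")
      if (!row$value_domain %in% .VALUE_DOMAINS)
        stop("registry validation error: unknown value_domain '",
             row$value_domain, "' for '", fn, "'")
      oid <- suppressWarnings(as.integer(row$omop_id))
      if (is.na(oid) || oid <= 0L)
        stop("registry validation error: omop_id must be a positive ",
             "integer for '", fn, "'")
      concepts[[fn]] <- list(
        field_name = fn, omop_id = oid, vocabulary = row$vocabulary,
        label = row$label, concept_group = row$concept_group,
        value_domain = row$value_domain,
        units = if (nzchar(row$units)) row$units else NA_character_,
        values = NULL)
      order_names <- c(order_names, fn)
    } else {
      fn <- row$field_name
      if (is.null(concepts[[fn]]))
        stop("registry format error at line ", i + 1L,
             ": value row for unknown concept '", fn, "'")
      vd <- data.frame(
        omop_id = suppressWarnings(as.integer(row$omop_id)),
        vocabulary = row$vocabulary, label = row$label,
        granularity = if (nzchar(row$granularity)) row$granularity
                      else "generic",
        generic_parent = suppressWarnings(as.integer(row$generic_parent)),
        stringsAsFactors = FALSE)
      if (is.na(vd$omop_id) || vd$omop_id <= 0L)
        stop("registry validation error: bad value omop_id at line ", i + 1L)
      concepts[[fn]]$values <- rbind(concepts[[fn]]$values, vd)
    }
  }

  for (fn in order_names) {
    cc <- concepts[[fn]]
    if (cc$value_domain == "scalar_numeric") {
      if (!is.null(cc$values))
        stop("registry validation error: scalar concept '", fn,
             "' must not carry a value set")
      concepts[[fn]]$values <- .not_provided_valuedef()[0, ]
    } else {
      if (is.null(cc$values) || nrow(cc$values) == 0L)
        stop("registry validation error: coded concept '", fn,
             "' has an empty value_set")
      if (anyDuplicated(cc$values$omop_id))
        stop("registry validation error: duplicate value omop_id within '",
             fn, "'")
      concepts[[fn]]$values <- rbind(cc$values, .not_provided_valuedef())
    }
  }

  structure(list(concepts = concepts[order_names], version = "1.0",
                 path = path),
            class = "cdm_definition")
}

#' Save a CDM registry
#'
#' Inverse of [load_cdm_registry()]; the implicit Not-provided rows are not
#' written. `load_cdm_registry(save_cdm_registry(cdm, f))` is the identity.
#'
#' @param cdm A `cdm_definition`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
save_cdm_registry <- function(cdm, path) {
  stopifnot(inherits(cdm, "cdm_definition"))
  rows <- lapply(cdm$concepts, function(cc) {
    head <- data.frame(record = "concept", field_name = cc$field_name,
                       omop_id = cc$omop_id, vocabulary = cc$vocabulary,
                       label = cc$label, concept_group = cc$concept_group,
                       value_domain = cc$value_domain, granularity = "",
                       generic_parent = "",
                       units = if (is.na(cc$units)) "" else cc$units,
                       stringsAsFactors = FALSE)
    vals <- cc$values[cc$values$omop_id != NOT_PROVIDED, , drop = FALSE]
    if (nrow(vals)) {
      vrows <- data.frame(record = "value", field_name = cc$field_name,
                          omop_id = vals$omop_id,
                          vocabulary = vals$vocabulary, label = vals$label,
                          concept_group = "", value_domain = "",
                          granularity = vals$granularity,
                          generic_parent = ifelse(is.na(vals$generic_parent),
                                                  "",
                                                  as.character(vals$generic_parent)),
                          units = "", stringsAsFactors = FALSE)
      head <- rbind(head, vrows)
    }
    head
  })
  out <- do.call(rbind, rows)
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Look up one concept definition
#'
#' @param cdm A `cdm_definition`.
#' @param field_name Concept field name.
#' @return The concept definition list.
#' @export
cdm_concept <- function(cdm, field_name) {
  cc <- cdm$concepts[[field_name]]
  if (is.null(cc)) stop("unknown CDM field: ", field_name)
  cc
}

#' Field names of a CDM definition
#' @param cdm A `cdm_definition`.
#' @return Character vector in registry order.
#' @export
cdm_fields <- function(cdm) names(cdm$concepts)

#' Registered value IDs for a coded concept (including Not provided)
#' @param cdm A `cdm_definition`.
#' @param field_name Concept field name.
#' @return Integer vector of registered OMOP value IDs.
#' @export
registered_values <- function(cdm, field_name) {
  cdm_concept(cdm, field_name)$values$omop_id
}

#' Vocabulary usage of a registry
#'
#' Tallies, per vocabulary, the number of concepts mapped to it and the
#' number of distinct coded values drawn from it (the inner/outer-arc
#' summary of the model's semantic footprint). A value code shared by
#' several concepts (e.g. yes/no) counts once, as does the reserved
#' Not-provided code, under its own source vocabulary.
#'
#' @param cdm A `cdm_definition`.
#' @return A `vocabulary_usage` list with `concept_counts`, `value_counts`,
#'   `n_concepts`, `n_values`, `n_vocabularies`.
#' @export
vocabulary_usage <- function(cdm) {
  stopifnot(inherits(cdm, "cdm_definition"))
  cvoc <- vapply(cdm$concepts, function(cc) cc$vocabulary, character(1))
  concept_counts <- table(cvoc)

  vals <- do.call(rbind, lapply(cdm$concepts, function(cc)
    cc$values[, c("omop_id", "vocabulary")]))
  vals <- vals[!duplicated(vals$omop_id), , drop = FALSE]
  value_counts <- table(vals$vocabulary)

  structure(list(
    concept_counts = as.list(concept_counts),
    value_counts = as.list(value_counts),
    n_concepts = length(cdm$concepts),
    n_values = nrow(vals),
    n_vocabularies = length(union(names(concept_counts),
                                  names(value_counts)))),
    class = "vocabulary_usage")
}

#' Validate one harmonized record against the registry
#'
#' Checks, per field, that the cell is (i) a registered value ID for
#' `coded_single` fields, (ii) a vertical-bar-joined sequence of registered
#' IDs for `coded_multi` fields, or (iii) numeric (or the Not-provided
#' code) for `scalar_numeric` fields. Empty cells are violations.
#' Violations are reported, never thrown.
#'
#' @param record Named list or named character vector, names being CDM
#'   field names (a subset of the registry's).
#' @param cdm A `cdm_definition`.
#' @return Data frame with columns `field`, `ok`, `message`.
#' @export
validate_record <- function(record, cdm) {
  stopifnot(inherits(cdm, "cdm_definition"))
  record <- as.list(record)
  unknown <- setdiff(names(record), cdm_fields(cdm))
  if (length(unknown))
    stop("record has fields outside the registry: ",
         paste(unknown, collapse = ", "))
  res <- lapply(names(record), function(fn) {
    cell <- as.character(record[[fn]])
    cc <- cdm_concept(cdm, fn)
    if (length(cell) != 1L || is.na(cell) || !nzchar(cell))
      return(data.frame(field = fn, ok = FALSE,
                        message = "empty cell", stringsAsFactors = FALSE))
    msg <- ""
    ok <- TRUE
    if (cc$value_domain == "scalar_numeric") {
      num <- suppressWarnings(as.numeric(cell))
      if (is.na(num)) { ok <- FALSE; msg <- "not numeric" }
    } else {
      ids <- if (cc$value_domain == "coded_multi")
        strsplit(cell, "|", fixed = TRUE)[[1]] else cell
      parsed <- suppressWarnings(as.integer(ids))
      if (anyNA(parsed)) {
        ok <- FALSE; msg <- paste0("non-integer code '", cell, "'")
      } else {
        unreg <- setdiff(parsed, registered_values(cdm, fn))
        if (length(unreg)) {
          ok <- FALSE
          msg <- paste0("unregistered value ", paste(unreg, collapse = "|"),
                        " for field ", fn)
        }
      }
    }
    data.frame(field = fn, ok = ok, message = msg, stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' @export
print.cdm_definition <- function(x, ...) {
  vu <- vocabulary_usage(x)
  cat("CDM definition: ", vu$n_concepts, " concepts, ", vu$n_values,
      " distinct coded values, ", vu$n_vocabularies, " vocabularies\n",
      sep = "")
  invisible(x)
}

#' @export
print.vocabulary_usage <- function(x, ...) {
  cat("Concept mapping (", x$n_concepts, " concepts):\n", sep = "")
  for (v in names(x$concept_counts))
    cat("  ", v, ": ", x$concept_counts[[v]], "\n", sep = "")
  cat("Value-set mapping (", x$n_values, " distinct values):\n", sep = "")
  for (v in names(x$value_counts))
    cat("  ", v, ": ", x$value_counts[[v]], "\n", sep = "")
  invisible(x)
}
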