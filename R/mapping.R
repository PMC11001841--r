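# Declarative per-dataset mapping specifications: the "content as
# configuration" half of the ETL. One YAML file per source dataset.

.DATASET_IDS <- c("ISPY2", "DUKE", "ISPY1", "TCGA_BRCA", "NACT")
.RULE_KINDS <- c("direct_recode", "derived", "constant", "parser")

#' Path of a shipped mapping specification
#'
#' @param dataset_id One of `ISPY2`, `DUKE`, `ISPY1`, `TCGA_BRCA`, `NACT`.
#' @return Path to the installed YAML spec.
#' @export
mapping_spec_path <- function(dataset_id) {
  dataset_id <- match.arg(dataset_id, .DATASET_IDS)
  system.file("extdata", "mappings",
              paste0(tolower(dataset_id), ".yaml"),
              package = "omopmri", mustWork = TRUE)
}

#' Load a mapping specification
#'
#' A spec names the subject-identifier column, the number of header rows to
#' skip before auto-import, the transformation rules (one per target CDM
#' field: `direct_recode` with a token-to-code map, `derived` or `parser`
#' with a named derivation, or `constant`), per-subject overrides applied
#' last, and an explicit subject-exclusion list.
#'
#' @param path YAML spec file.
#' @return A `mapping_spec` object.
#' @export
load_mapping_spec <- function(path) {
  if (!file.exists(path)) stop("mapping spec not found: ", path)
  spec <- yaml::read_yaml(path)
  for (f in c("dataset_id", "subject_id_column", "rules"))
    if (is.null(spec[[f]]))
      stop("mapping spec '", path, "' missing field '", f, "'")
  if (!spec$dataset_id %in% .DATASET_IDS)
    stop("mapping spec '", path, "' has unknown dataset_id '",
         spec$dataset_id, "'")
  spec$skip_rows <- if (is.null(spec$skip_rows)) 0L else
    as.integer(spec$skip_rows)
  spec$overrides <- spec$overrides %||% list()
  spec$exclusions <- spec$exclusions %||% list()
  targets <- vapply(spec$rules, function(r) r$target %||% "", character(1))
  if (any(!nzchar(targets)))
    stop("mapping spec '", path, "' has a rule without a target")
  dup <- targets[duplicated(targets)]
  if (length(dup))
    stop("mapping spec '", path, "' maps field '", dup[1],
         "' more than once")
  for (r in spec$rules) {
    if (!(r$kind %||% "") %in% .RULE_KINDS)
      stop("rule for '", r$target, "': unknown kind '", r$kind, "'")
    if (r$kind == "constant" && length(r$source %||% character(0)))
      stop("constant rule for '", r$target, "' must not list source columns")
    if (r$kind == "direct_recode" && !length(r$map %||% list()))
      stop("direct_recode rule for '", r$target, "' has an empty value map")
  }
  structure(spec, class = "mapping_spec")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Validate a mapping spec against a CDM definition
#'
#' Checks every rule targets a registered CDM field and that every value a
#' `direct_recode` map or `constant` can emit is registered in that field's
#' value set. Derivations and parsers are checked to be known by name;
#' their outputs are re-validated at harmonization time.
#'
#' @param spec A `mapping_spec`.
#' @param cdm A `cdm_definition`.
#' @return `TRUE` invisibly; stops with a named violation otherwise.
#' @export
validate_mapping_spec <- function(spec, cdm) {
  stopifnot(inherits(spec, "mapping_spec"), inherits(cdm, "cdm_definition"))
  for (r in spec$rules) {
    if (!r$target %in% cdm_fields(cdm))
      stop("mapping spec targets unknown CDM field '", r$target, "'")
    if (r$kind == "direct_recode") {
      emitted <- as.integer(unlist(r$map))
      unreg <- setdiff(emitted, registered_values(cdm, r$target))
      if (length(unreg))
        stop("rule for '", r$target, "' emits unregistered value(s) ",
             paste(unreg, collapse = ", "))
    }
    if (r$kind == "constant") {
      cc <- cdm_concept(cdm, r$target)
      if (cc$value_domain != "scalar_numeric" &&
          !as.integer(r$value) %in% registered_values(cdm, r$target))
        stop("constant rule for '", r$target, "' emits unregistered value ",
             r$value)
    }
    if (r$kind %in% c("derived", "parser")) {
      nm <- r$derivation %||% r$parser
      if (is.null(.etl_fn(nm)))
        stop("rule for '", r$target, "': unknown derivation/parser '",
             nm, "'")
    }
  }
  for (ov in spec$overrides) {
    if (!ov$field %in% cdm_fields(cdm))
      stop("override targets unknown CDM field '", ov$field, "'")
    if (!as.integer(ov$value) %in% registered_values(cdm, ov$field))
      stop("override for '", ov$field, "' uses unregistered value ",
           ov$value)
  }
  invisible(TRUE)
}

#' Source-collection metadata shipped with the package
#'
#' Subject and concept counts of the original public clinical files
#' (concept counts exclude identifier columns); used by coverage reports.
#'
#' @return Named list, one entry per dataset.
#' @export
source_dataset_info <- function() {
  path <- system.file("extdata", "config", "source_datasets.yaml",
                      package = "omopmri", mustWork = TRUE)
  yaml::read_yaml(path)
}
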