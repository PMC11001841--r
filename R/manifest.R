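# NBIA Retriever manifest files (.tcia): the plain-text handoff format
# consumed by the archive's bulk downloader. Header key spelling --
# including the historical "noOfrRetry" -- is preserved bit-exactly for
# compatibility with the consuming tool.

.MANIFEST_MARKER <- "ListOfSeriesToDownload="
.MANIFEST_KEYS <- c(server_url = "downloadServerUrl",
                    include_annotation = "includeAnnotation",
                    retries = "noOfrRetry",
                    basket_id = "databasketId",
                    manifest_version = "manifestVersion")

.manifest_defaults <- function() {
  path <- system.file("extdata", "config", "manifest_defaults.yaml",
                      package = "omopmri", mustWork = TRUE)
  yaml::read_yaml(path)
}

#' Construct a manifest specification
#'
#' @param series_uids Ordered, non-empty, duplicate-free character vector
#'   of series instance UIDs.
#' @param server_url,include_annotation,retries,basket_id,manifest_version
#'   Header fields; defaults come from the shipped configuration.
#' @param extra Named list of unknown header keys to pass through (kept so
#'   reading a foreign manifest is lossless).
#' @return A `manifest_spec`.
#' @export
manifest_spec <- function(series_uids,
                          server_url = NULL, include_annotation = NULL,
                          retries = NULL, basket_id = NULL,
                          manifest_version = NULL, extra = list()) {
  defaults <- .manifest_defaults()
  series_uids <- as.character(series_uids)
  if (!length(series_uids))
    stop("manifest validation error: series_uids must be non-empty")
  dup <- series_uids[duplicated(series_uids)]
  if (length(dup))
    stop("manifest validation error: duplicate series UID '", dup[1], "'")
  structure(list(
    server_url = server_url %||% defaults$server_url,
    include_annotation = include_annotation %||% defaults$include_annotation,
    retries = as.integer(retries %||% defaults$retries),
    basket_id = basket_id %||% defaults$basket_id,
    manifest_version = as.character(manifest_version %||%
                                      defaults$manifest_version),
    series_uids = series_uids,
    extra = extra),
    class = "manifest_spec")
}

#' Write an NBIA Retriever manifest
#'
#' Emits the documented template: five `key=value` header lines, the
#' literal `ListOfSeriesToDownload=` marker, then one UID per line.
#' Identical specs produce byte-identical files.
#'
#' @param spec A `manifest_spec`.
#' @param path Output `.tcia` path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(spec, path) {
  stopifnot(inherits(spec, "manifest_spec"))
  if (!length(spec$series_uids))
    stop("manifest validation error: series_uids must be non-empty")
  lines <- c(
    paste0("downloadServerUrl=", spec$server_url),
    paste0("includeAnnotation=", tolower(as.character(spec$include_annotation))),
    paste0("noOfrRetry=", spec$retries),
    paste0("databasketId=", spec$basket_id),
    paste0("manifestVersion=", spec$manifest_version),
    vapply(names(spec$extra), function(k)
      paste0(k, "=", spec$extra[[k]]), character(1)),
    .MANIFEST_MARKER,
    spec$series_uids)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n")
  invisible(path)
}

#' Read an NBIA Retriever manifest
#'
#' Inverse of [write_manifest()] on its image. Unknown header keys raise a
#' warning and are preserved in the spec's `extra` passthrough list; a
#' file without the `ListOfSeriesToDownload=` marker is a parse error.
#'
#' @param path Manifest file.
#' @return A `manifest_spec`.
#' @export
read_manifest <- function(path) {
  lines <- readLines(path, warn = FALSE)
  marker <- which(lines == .MANIFEST_MARKER)
  if (!length(marker))
    stop("manifest parse error: no '", .MANIFEST_MARKER, "' line in '",
         path, "'")
  marker <- marker[1]
  header <- lines[seq_len(marker - 1L)]
  uids <- lines[-seq_len(marker)]
  uids <- uids[nzchar(trimws(uids))]
  kv <- strsplit(header, "=", fixed = TRUE)
  keys <- vapply(kv, `[`, character(1), 1)
  vals <- vapply(kv, function(p) paste(p[-1], collapse = "="), character(1))
  known <- match(keys, .MANIFEST_KEYS)
  extra <- list()
  fields <- list()
  for (i in seq_along(keys)) {
    if (is.na(known[i])) {
      warning("unknown manifest header key '", keys[i],
              "'; preserved as passthrough")
      extra[[keys[i]]] <- vals[i]
    } else {
      fields[[names(.MANIFEST_KEYS)[known[i]]]] <- vals[i]
    }
  }
  manifest_spec(series_uids = uids,
                server_url = fields$server_url,
                include_annotation = identical(fields$include_annotation,
                                               "true"),
                retries = fields$retries,
                basket_id = fields$basket_id,
                manifest_version = fields$manifest_version,
                extra = extra)
}
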