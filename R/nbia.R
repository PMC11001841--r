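# Series-metadata acquisition behind an injectable client interface. A
# client is a plain list with two functions: `list_series(collection)`
# returning the series UIDs of a collection, and `series_tags(uid)`
# returning that series' tag record. The live NBIA Advanced REST API, a
# local JSON dump directory, and the in-memory fixture client below all
# satisfy the same contract, so the whole layer is testable offline.
# Acquisition is two-step (one listing call, then one call per series) and
# expensive at archive scale, hence the write-through per-series cache.

.series_to_json <- function(meta) {
  list(series_uid = meta$series_uid, collection = meta$collection,
       subject_id = meta$subject_id, tags = meta$tags)
}

.series_from_json <- function(j) {
  tags <- lapply(j$tags, function(v) unlist(v))
  series_metadata(j$series_uid, j$collection,
                  j$subject_id %||% NA_character_, tags)
}

#' Write one series-metadata record as JSON
#' @param meta A `series_metadata`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_series_json <- function(meta, path) {
  jsonlite::write_json(.series_to_json(meta), path, auto_unbox = TRUE,
                       null = "null", digits = NA)
  invisible(path)
}

#' Read one series-metadata record from JSON
#' @param path JSON file produced by [write_series_json()] (or an
#'   equivalent API dump).
#' @return A `series_metadata`.
#' @export
read_series_json <- function(path) {
  j <- tryCatch(jsonlite::read_json(path),
                error = function(e) stop("parse error reading series JSON '",
                                         path, "': ", conditionMessage(e)))
  if (is.null(j$series_uid))
    stop("parse error: no series_uid in '", path, "'")
  .series_from_json(j)
}

#' In-memory fixture client
#'
#' Serves a fixed list of `series_metadata` through the client interface
#' and counts the per-series requests it receives, so cache behavior is
#' observable in tests.
#'
#' @param series List of `series_metadata`.
#' @return Client list with `list_series`, `series_tags`, `calls`.
#' @export
nbia_fixture_client <- function(series) {
  by_uid <- stats::setNames(series,
                            vapply(series, function(s) s$series_uid,
                                   character(1)))
  env <- new.env(parent = emptyenv())
  env$calls <- 0L
  list(
    list_series = function(collection) {
      uids <- names(by_uid)[vapply(by_uid, function(s)
        identical(s$collection, collection), logical(1))]
      sort(uids)
    },
    series_tags = function(uid) {
      env$calls <- env$calls + 1L
      s <- by_uid[[uid]]
      if (is.null(s)) stop("unknown series uid: ", uid)
      s
    },
    calls = function() env$calls)
}

#' Local-directory client
#'
#' Treats a directory of per-series JSON dumps as a metadata source.
#'
#' @param dir Directory containing `<series_uid>.json` files.
#' @return Client list with the standard interface.
#' @export
nbia_local_client <- function(dir) {
  list(
    list_series = function(collection) {
      files <- list.files(dir, pattern = "\\.json$", full.names = TRUE)
      metas <- lapply(files, read_series_json)
      uids <- vapply(metas, function(s) s$series_uid, character(1))
      keep <- vapply(metas, function(s) identical(s$collection, collection),
                     logical(1))
      sort(uids[keep])
    },
    series_tags = function(uid) {
      read_series_json(file.path(dir, paste0(uid, ".json")))
    },
    calls = function() NA_integer_)
}

#' Fetch all series metadata of a collection, with caching
#'
#' Lists the collection's series through the client, then acquires each
#' series' tag record, reading from the write-through cache (one JSON
#' document per series UID under `cache_dir/<collection>/`) when warm.
#' A fully warm cache issues zero per-series requests and returns output
#' identical to a cold fetch.
#'
#' @param collection Collection name.
#' @param client Metadata source (see [nbia_fixture_client()]).
#' @param cache_dir Cache directory; created if needed. `NULL` disables
#'   caching.
#' @return List of `series_metadata`, ordered by series UID.
#' @export
fetch_collection_series <- function(collection, client, cache_dir = NULL) {
  uids <- sort(client$list_series(collection))
  subdir <- if (!is.null(cache_dir)) {
    d <- file.path(cache_dir, collection)
    dir.create(d, recursive = TRUE, showWarnings = FALSE)
    d
  } else NULL
  lapply(uids, function(uid) {
    cache_file <- if (!is.null(subdir)) file.path(subdir,
                                                  paste0(uid, ".json"))
    if (!is.null(cache_file) && file.exists(cache_file))
      return(read_series_json(cache_file))
    meta <- client$series_tags(uid)
    if (!inherits(meta, "series_metadata"))
      stop("parse error: client returned malformed record for series ", uid)
    if (!is.null(cache_file)) write_series_json(meta, cache_file)
    meta
  })
}

#' Read all cached series of a collection
#' @param collection Collection name.
#' @param cache_dir Cache directory used by [fetch_collection_series()].
#' @return List of `series_metadata`, ordered by series UID.
#' @export
read_cached_series <- function(collection, cache_dir) {
  d <- file.path(cache_dir, collection)
  files <- sort(list.files(d, pattern = "\\.json$", full.names = TRUE))
  lapply(files, read_series_json)
}
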