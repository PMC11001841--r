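# Classification of MRI series from sparse DICOM tag records: technique
# (DCE / DWI / T1W / T2W / OTHER / UNKNOWN), orientation from the image
# direction cosines, and diffusion b-values including the GE private-tag
# encoding. Public-archive series are anonymized, so every rule must
# tolerate missing tags; classification is total and never raises.

.TECHNIQUES <- c("DCE", "DWI", "T1W", "T2W", "OTHER", "UNKNOWN")
.ORIENTATIONS <- c("AXIAL", "SAGITTAL", "CORONAL", "OBLIQUE", "UNKNOWN")

.TAG_SCANNING_SEQUENCE <- "0018,0020"
.TAG_ACQUISITION_TYPE  <- "0018,0023"
.TAG_SEQUENCE_NAME     <- "0018,0024"
.TAG_IOP               <- "0020,0037"
.TAG_SERIES_DESC       <- "0008,103E"
.TAG_IMAGE_TYPE        <- "0008,0008"
.TAG_FLIP_ANGLE        <- "0018,1314"
.TAG_DIFF_DIRECTION    <- "0018,9075"
.TAG_BVALUE_GE         <- "0043,1039"
.TAG_BVALUE            <- "0018,9087"
.TAG_TEMPORAL_POS      <- "0020,0105"

#' Normalize a DICOM tag key
#'
#' Tag keys are uppercase zero-padded `"GGGG,EEEE"` hex pairs so records
#' from API JSON and local header dumps round-trip identically (except the
#' element letters, e.g. `103E`, which keep DICOM's conventional
#' upper-case hex).
#'
#' @param key Tag key in any common spelling: `"(0020,0105)"`,
#'   `"0020x0105"`, `"0008,103e"`.
#' @return Canonical `"GGGG,EEEE"` string.
#' @export
normalize_tag_key <- function(key) {
  hex <- toupper(gsub("[^0-9a-fA-F]", "", key))
  if (nchar(hex) != 8L) stop("not a DICOM tag key: ", key)
  paste0(substr(hex, 1, 4), ",", substr(hex, 5, 8))
}

#' Construct a series-metadata record
#'
#' @param series_uid DICOM series instance UID (non-empty).
#' @param collection Collection (public dataset) name.
#' @param subject_id Subject identifier.
#' @param tags Named list mapping tag keys to raw values (string or
#'   vector); keys are normalized, values may be arbitrarily sparse.
#' @return A `series_metadata` object.
#' @export
series_metadata <- function(series_uid, collection, subject_id = NA_character_,
                            tags = list()) {
  if (!nzchar(series_uid)) stop("series_uid must be non-empty")
  if (length(tags))
    names(tags) <- vapply(names(tags), normalize_tag_key, character(1))
  structure(list(series_uid = series_uid, collection = collection,
                 subject_id = subject_id, tags = tags),
            class = "series_metadata")
}

.tag <- function(meta, key) {
  v <- meta$tags[[key]]
  if (is.null(v) || !length(v)) NULL else v
}

.tag_chr <- function(meta, key) {
  v <- .tag(meta, key)
  if (is.null(v)) NULL else paste(as.character(v), collapse = "\\")
}

#' Classifier rule configuration
#'
#' Keyword lists (case-insensitive regular expressions over the free-text
#' series description and sequence name) and numeric thresholds, shipped
#' as an editable YAML file.
#'
#' @return Named list of keyword vectors and thresholds.
#' @export
classifier_config <- function() {
  path <- system.file("extdata", "config", "classifier.yaml",
                      package = "omopmri", mustWork = TRUE)
  yaml::read_yaml(path)
}

#' Orientation from the image direction cosines
#'
#' The slice normal is the cross product of the row and column direction
#' vectors of tag (0020,0037); the orientation is the axis of the normal's
#' largest absolute component (x sagittal, y coronal, z axial) when that
#' component dominates, else OBLIQUE. Total: missing or invalid input
#' yields UNKNOWN.
#'
#' @param iop Six direction cosines, as a numeric vector or a
#'   backslash-separated DICOM string.
#' @param obliquity_threshold Minimum |largest normal component| to call a
#'   cardinal plane (default 0.8).
#' @return One of `AXIAL`, `SAGITTAL`, `CORONAL`, `OBLIQUE`, `UNKNOWN`.
#' @export
orientation_from_cosines <- function(iop,
                                     obliquity_threshold =
                                       classifier_config()$obliquity_threshold) {
  if (is.null(iop)) return("UNKNOWN")
  if (is.character(iop))
    iop <- suppressWarnings(as.numeric(strsplit(
      paste(iop, collapse = "\\"), "\\", fixed = TRUE)[[1]]))
  iop <- suppressWarnings(as.numeric(iop))
  if (length(iop) != 6L || anyNA(iop) || any(!is.finite(iop)))
    return("UNKNOWN")
  r <- iop[1:3]; cl <- iop[4:6]
  n <- c(r[2] * cl[3] - r[3] * cl[2],
         r[3] * cl[1] - r[1] * cl[3],
         r[1] * cl[2] - r[2] * cl[1])
  if (all(abs(n) < 1e-6)) return("UNKNOWN")
  k <- which.max(abs(n))
  if (abs(n[k]) < obliquity_threshold) return("OBLIQUE")
  c("SAGITTAL", "CORONAL", "AXIAL")[k]
}

#' Diffusion b-value of a series
#'
#' Prefers the standard tag (0018,9087); otherwise takes the first element
#' of the GE private tag (0043,1039), correcting its encoding: GE scanners
#' store the b-value offset by 1e9 (their internal ordering of the b-value
#' acquisitions), so values at or above 1e9 are reduced by 1e9. Returns
#' `NULL` when no diffusion tag is present or parseable.
#'
#' @param tags Named tag list (or a `series_metadata`).
#' @return Numeric b-value in s/mm2, or `NULL`.
#' @export
parse_diffusion_bvalue <- function(tags) {
  meta <- if (inherits(tags, "series_metadata")) tags
          else series_metadata("x", "x", tags = tags)
  std <- .tag(meta, .TAG_BVALUE)
  if (!is.null(std)) {
    num <- suppressWarnings(as.numeric(std[[1]]))
    if (!is.na(num)) return(num)
  }
  ge <- .tag(meta, .TAG_BVALUE_GE)
  if (!is.null(ge)) {
    first <- suppressWarnings(as.numeric(unlist(ge)[1]))
    if (!is.na(first)) {
      if (first >= 1e9) first <- first - 1e9
      return(first)
    }
  }
  NULL
}

.matches_any <- function(text, patterns) {
  if (is.null(text) || !nzchar(text)) return(FALSE)
  any(vapply(patterns, function(p) grepl(p, text, ignore.case = TRUE,
                                         perl = TRUE), logical(1)))
}

#' Classify one series by MRI technique and orientation
#'
#' Rule precedence (most specific evidence first):
#' 1. DWI: echo-planar scanning sequence (0018,0020 contains "EP") or a
#'    diffusion keyword in the sequence name / series description, AND any
#'    diffusion tag present (standard or GE-private b-value, or diffusion
#'    directionality).
#' 2. DCE: number of temporal positions (0020,0105) above 1; fallback for
#'    anonymized series: gradient-echo ("GR") 3D acquisition with a flip
#'    angle below the configured threshold.
#' 3. T2W / T1W: series-description or sequence-name keywords (spin-echo
#'    scanning sequence is recorded as supporting evidence).
#' 4. OTHER when tags are present but no rule fires; UNKNOWN when the tag
#'    map is empty.
#'
#' @param meta A `series_metadata`.
#' @param config Classifier configuration (see [classifier_config()]).
#' @return A `series_label`: `technique`, `orientation`, `evidence`
#'   (fired predicates), and `b_values` for DWI.
#' @export
classify_series <- function(meta, config = classifier_config()) {
  stopifnot(inherits(meta, "series_metadata"))
  orientation <- orientation_from_cosines(.tag_chr(meta, .TAG_IOP),
                                          config$obliquity_threshold)
  label <- function(technique, evidence, b_values = NULL)
    structure(list(technique = technique, orientation = orientation,
                   evidence = evidence, b_values = b_values),
              class = "series_label")

  if (!length(meta$tags)) {
    lab <- label("UNKNOWN", character(0))
    lab$orientation <- "UNKNOWN"
    return(lab)
  }

  seqs <- .tag_chr(meta, .TAG_SCANNING_SEQUENCE)
  desc <- paste(c(.tag_chr(meta, .TAG_SERIES_DESC),
                  .tag_chr(meta, .TAG_SEQUENCE_NAME)), collapse = " ")
  evidence <- character(0)

  # 1. DWI ------------------------------------------------------------
  ep <- !is.null(seqs) && grepl("EP", seqs, ignore.case = TRUE)
  diff_kw <- .matches_any(desc, config$diffusion_keywords)
  diff_tags <- c(.TAG_BVALUE, .TAG_DIFF_DIRECTION, .TAG_BVALUE_GE)
  diff_present <- diff_tags[vapply(diff_tags, function(k)
    !is.null(.tag(meta, k)), logical(1))]
  if ((ep || diff_kw) && length(diff_present)) {
    if (ep) evidence <- c(evidence, paste0(.TAG_SCANNING_SEQUENCE, "=",
                                           seqs, " echo-planar"))
    if (diff_kw) evidence <- c(evidence, "description diffusion keyword")
    evidence <- c(evidence, paste0(diff_present, " diffusion tag present"))
    b <- parse_diffusion_bvalue(meta)
    return(label("DWI", evidence, b_values = if (is.null(b)) NULL else b))
  }

  # 2. DCE ------------------------------------------------------------
  tp <- suppressWarnings(as.numeric(.tag_chr(meta, .TAG_TEMPORAL_POS)))
  if (length(tp) && !is.na(tp) && tp > 1)
    return(label("DCE", paste0(.TAG_TEMPORAL_POS, "=", tp,
                               " temporal positions")))
  gr <- !is.null(seqs) && grepl("GR", seqs, ignore.case = TRUE)
  acq3d <- identical(toupper(.tag_chr(meta, .TAG_ACQUISITION_TYPE) %||% ""),
                     "3D")
  flip <- suppressWarnings(as.numeric(.tag_chr(meta, .TAG_FLIP_ANGLE)))
  low_flip <- length(flip) && !is.na(flip) &&
    flip < config$dce_flip_angle_max_deg
  if (gr && acq3d && low_flip)
    return(label("DCE", c(paste0(.TAG_SCANNING_SEQUENCE, "=", seqs,
                                 " gradient-echo"),
                          "0018,0023=3D acquisition",
                          paste0(.TAG_FLIP_ANGLE, "=", flip,
                                 " below DCE flip-angle threshold"))))

  # 3. anatomical T2W / T1W -------------------------------------------
  se <- !is.null(seqs) && grepl("SE", seqs, ignore.case = TRUE)
  se_ev <- if (se) paste0(.TAG_SCANNING_SEQUENCE, "=", seqs, " spin-echo")
           else NULL
  if (.matches_any(desc, config$t2_keywords))
    return(label("T2W", c("description T2 keyword", se_ev)))
  if (.matches_any(desc, config$t1_keywords))
    return(label("T1W", c("description T1 keyword", se_ev)))

  label("OTHER", "tags present but no technique rule fired")
}

#' Per-collection technique statistics
#'
#' Classifies each series and tallies techniques; counts always sum to the
#' number of input series.
#'
#' @param series List of `series_metadata` from one collection.
#' @param config Classifier configuration.
#' @return A `technique_stats` object.
#' @export
technique_statistics <- function(series, config = classifier_config()) {
  collections <- unique(vapply(series, function(s) s$collection,
                               character(1)))
  if (length(collections) > 1L)
    stop("technique_statistics: series from mixed collections: ",
         paste(collections, collapse = ", "))
  counts <- stats::setNames(integer(length(.TECHNIQUES)), .TECHNIQUES)
  for (s in series) {
    lab <- classify_series(s, config)
    counts[lab$technique] <- counts[lab$technique] + 1L
  }
  structure(list(collection = if (length(collections)) collections else NA,
                 counts = counts, total = length(series)),
            class = "technique_stats")
}

#' @export
print.technique_stats <- function(x, ...) {
  cat("Collection:", x$collection, "-", x$total, "series\n")
  for (t in names(x$counts))
    if (x$counts[[t]] > 0) cat(sprintf("  %-8s %d\n", t, x$counts[[t]]))
  invisible(x)
}

#' @export
print.series_label <- function(x, ...) {
  cat(x$technique, "/", x$orientation)
  if (!is.null(x$b_values)) cat(" b =", paste(x$b_values, collapse = ","))
  cat("\n")
  invisible(x)
}
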