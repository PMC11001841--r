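# Seeded synthetic fixtures: source clinical CSVs emulating each public
# dataset's schema and value messiness with a known ground-truth CDM table,
# and DICOM tag records realizing each MRI technique. Every perturbation the
# mess generator applies is semantics-preserving by construction (the
# parsers must tolerate it without the truth changing), so fixtures validate
# the mechanics of the pipeline, not the epidemiology of the real cohorts.

.POSITION_NOISE <- c(" with calcs", " with clip", " (biopsy proven)",
                     " anterior", " posterior")

#' Fixture configuration
#'
#' @param dataset_id Which source schema to emulate.
#' @param n_subjects Number of subjects (> 0).
#' @param mess_rate Fraction in `[0, 1]` of eligible cells perturbed with
#'   realistic noise (trailing text on free-text positions, case changes,
#'   padding whitespace).
#' @param seed Integer seed; identical configs give byte-identical files.
#' @param dir Output directory.
#' @return A `fixture_config` list.
#' @export
fixture_config <- function(dataset_id, n_subjects = 10, mess_rate = 0,
                           seed = 1, dir = tempdir()) {
  dataset_id <- match.arg(dataset_id, .DATASET_IDS)
  stopifnot(n_subjects > 0, mess_rate >= 0, mess_rate <= 1)
  structure(list(dataset_id = dataset_id,
                 n_subjects = as.integer(n_subjects),
                 mess_rate = mess_rate, seed = as.integer(seed), dir = dir),
            class = "fixture_config")
}

.fixture_seed <- function(seed, dataset_id) {
  as.integer((as.numeric(seed) * 7919 +
                match(dataset_id, .DATASET_IDS) * 104729) %% 2147483647)
}

.sample_numeric_token <- function(target) {
  switch(target,
         age = as.character(sample(25:84, 1)),
         tumor_size_mm = as.character(sample(4:90, 1)),
         positive_lymph_nodes = as.character(sample(0:15, 1)),
         days_to_last_followup = as.character(sample(100:4000, 1)),
         days_to_death = as.character(sample(200:4000, 1)),
         mri_field_strength = as.character(sample(c(1.5, 3), 1)),
         as.character(sample(1:100, 1)))
}

.mess_case_ws <- function(token) {
  if (stats::runif(1) < 0.5) token <- toupper(token)
  pad_l <- strrep(" ", sample(0:2, 1)); pad_r <- strrep(" ", sample(0:2, 1))
  paste0(pad_l, token, pad_r)
}

.mess_position <- function(token, hour) {
  kind <- sample(c("suffix", "half_hour", "range", "case"), 1)
  # a range across the 12-to-1 boundary would move the midpoint to the
  # opposite quadrant, so hour 12 never gets range noise
  if (kind == "range" && hour == 12) kind <- "suffix"
  token <- switch(kind,
    suffix = paste0(token, sample(.POSITION_NOISE, 1)),
    half_hour = sub(paste0(hour, "$"), paste0(hour, ":30"), token),
    range = sub(paste0(hour, "$"), paste0(hour, "-", hour + 1), token),
    case = tolower(token))
  token
}

# generator-side mirror of the receptor disjunction (kept independent of
# derive_hr_status so the ETL is checked against it, not with it)
.truth_hr <- function(er_pos, pr_pos) {
  if (isTRUE(er_pos) || isTRUE(pr_pos)) return(.HR_POS)
  if (identical(er_pos, FALSE) && identical(pr_pos, FALSE)) return(.HR_NEG)
  NOT_PROVIDED
}

.truth_site <- function(lat, hour) {
  tab <- clock_quadrant_table()
  as.integer(tab$omop_id[tab$laterality == lat & tab$hour == hour])
}

.generator_drug_scan <- function(text, lexicon) {
  hits <- vapply(names(lexicon), function(drug)
    grepl(drug, tolower(text), fixed = TRUE), logical(1))
  unname(lexicon[hits])
}

#' Generate a source CSV and its ground-truth CDM table
#'
#' Emulates the configured dataset's column conventions (binary 0/1 flags,
#' categorical TNM text, free-text clock-face tumor positions,
#' concatenated medication lists, a header banner row where the real file
#' has one) and writes, alongside, the CDM value every cell should
#' harmonize to. At `mess_rate` 1 every eligible cell is perturbed, yet
#' the truth is unchanged.
#'
#' @param config A [fixture_config()].
#' @return List with `source_path`, `truth_path`, `source` (data frame)
#'   and `truth` (data frame over all CDM fields).
#' @export
generate_source_csv <- function(config) {
  stopifnot(inherits(config, "fixture_config"))
  cdm <- load_cdm_registry()
  spec <- load_mapping_spec(mapping_spec_path(config$dataset_id))
  set.seed(.fixture_seed(config$seed, config$dataset_id))

  n <- config$n_subjects
  ids <- as.character(seq_len(n))
  fields <- cdm_fields(cdm)
  truth <- matrix(as.character(NOT_PROVIDED), nrow = n,
                  ncol = length(fields), dimnames = list(NULL, fields))
  cols <- list()
  cols[[spec$subject_id_column]] <- ids
  latent <- list()
  lexicon <- .medication_lexicon(cdm)
  rules <- spec$rules

  # regimen map (needed to sample arms for the Arm column)
  regimen_rule <- Filter(function(r) r$target == "neoadjuvant_regimen" &&
                           r$kind == "direct_recode", rules)
  arm_keys <- if (length(regimen_rule)) names(regimen_rule[[1]]$map)

  # ---- phase A: realize source columns -----------------------------------
  for (r in rules) {
    if (r$kind == "constant") next
    col <- r$source[[1]]
    if (!is.null(cols[[col]])) next
    if (identical(r$parser %||% r$derivation, "tumor_position_site") ||
        identical(r$parser %||% r$derivation, "tumor_position_laterality")) {
      lat <- sample(c("L", "R"), n, replace = TRUE)
      hour <- sample(1:12, n, replace = TRUE)
      latent[[col]] <- list(lat = lat, hour = hour)
      cols[[col]] <- paste(lat, hour)
    } else if (identical(r$parser %||% "", "ispy2_arm_medication") ||
               (r$kind == "direct_recode" &&
                r$target == "neoadjuvant_regimen")) {
      arm <- sample(arm_keys, n, replace = TRUE)
      latent[[col]] <- list(arm = arm)
      cols[[col]] <- arm
    } else if (identical(r$parser %||% "", "medication_list")) {
      toks <- character(n)
      med_truth <- character(n)
      for (i in seq_len(n)) {
        k <- sample(0:3, 1)
        drugs <- if (k > 0) sample(names(lexicon), k) else character(0)
        toks[i] <- paste(drugs, collapse = " + ")
        med_truth[i] <- encode_multivalue(unname(lexicon[drugs]))
      }
      latent[[col]] <- list(med_truth = med_truth)
      cols[[col]] <- toks
    } else if (identical(r$parser %||% "", "as_numeric")) {
      toks <- vapply(seq_len(n), function(i) {
        if (stats::runif(1) < 0.15) "" else .sample_numeric_token(r$target)
      }, character(1))
      cols[[col]] <- toks
    } else if (r$kind == "direct_recode") {
      cols[[col]] <- sample(names(r$map), n, replace = TRUE)
    }
  }

  # ---- phase B: ground truth per rule ------------------------------------
  for (r in rules) {
    tgt <- r$target
    if (r$kind == "constant") {
      truth[, tgt] <- as.character(r$value)
      next
    }
    col <- r$source[[1]]
    dnm <- r$derivation %||% r$parser %||% ""
    if (dnm %in% c("tumor_position_site", "tumor_position_laterality")) {
      li <- latent[[col]]
      truth[, tgt] <- if (dnm == "tumor_position_site")
        vapply(seq_len(n), function(i)
          as.character(.truth_site(li$lat[i], li$hour[i])), character(1))
      else as.character(ifelse(li$lat == "L", .LAT_LEFT, .LAT_RIGHT))
    } else if (dnm == "ispy2_arm_medication") {
      arms <- latent[[col]]$arm
      truth[, tgt] <- vapply(arms, function(a)
        encode_multivalue(c(.generator_drug_scan(a, lexicon),
                            .CYCLOPHOSPHAMIDE)), character(1))
    } else if (dnm == "medication_list") {
      truth[, tgt] <- latent[[col]]$med_truth
    } else if (dnm == "as_numeric") {
      toks <- cols[[col]]
      truth[, tgt] <- ifelse(nzchar(toks),
                             as.character(as.numeric(toks)),
                             as.character(NOT_PROVIDED))
    } else if (dnm == "pcr_from_rcb") {
      toks <- normalize_token(cols[[col]])
      truth[, tgt] <- vapply(toks, function(tk) {
        if (tk == "0") as.character(.YES)
        else if (tk %in% c("1", "2", "3")) as.character(.NO)
        else as.character(NOT_PROVIDED)
      }, character(1))
    } else if (dnm %in% c("hr_from_er_pr", "hr_from_er_pr_text")) {
      er_tok <- normalize_token(cols[[r$source[[1]]]])
      pr_tok <- normalize_token(cols[[r$source[[2]]]])
      pos <- if (dnm == "hr_from_er_pr") "1" else "positive"
      neg <- if (dnm == "hr_from_er_pr") "0" else "negative"
      truth[, tgt] <- vapply(seq_len(n), function(i) {
        er <- if (er_tok[i] == pos) TRUE else if (er_tok[i] == neg) FALSE
              else NA
        pr <- if (pr_tok[i] == pos) TRUE else if (pr_tok[i] == neg) FALSE
              else NA
        as.character(.truth_hr(er, pr))
      }, character(1))
    } else if (r$kind == "direct_recode") {
      toks <- normalize_token(cols[[col]])
      truth[, tgt] <- vapply(toks, function(tk)
        as.character(r$map[[tk]] %||% NOT_PROVIDED), character(1))
    }
  }

  for (ov in spec$overrides) {
    j <- which(ids == as.character(ov$subject))
    if (length(j)) truth[j, ov$field] <- as.character(ov$value)
  }

  # the comment field the override encodes, for realism
  if (config$dataset_id == "NACT") {
    comments <- rep("", n)
    j <- which(ids == "27")
    if (length(j))
      comments[j] <- paste("declined standard-of-care post-surgery",
                           "radiation and hormonal treatments")
    cols[["COMMENTS"]] <- comments
  }

  # ---- phase C: semantics-preserving mess --------------------------------
  if (config$mess_rate > 0) {
    position_cols <- names(latent)[vapply(latent, function(l)
      !is.null(l$lat), logical(1))]
    for (col in setdiff(names(cols), spec$subject_id_column)) {
      for (i in seq_len(n)) {
        if (!nzchar(cols[[col]][i])) next
        if (stats::runif(1) >= config$mess_rate) next
        cols[[col]][i] <- if (col %in% position_cols)
          .mess_position(cols[[col]][i], latent[[col]]$hour[i])
        else .mess_case_ws(cols[[col]][i])
      }
    }
  }

  source_df <- data.frame(cols, check.names = FALSE,
                          stringsAsFactors = FALSE)
  truth_df <- data.frame(subject_id = ids, truth, check.names = FALSE,
                         stringsAsFactors = FALSE)

  dir.create(config$dir, recursive = TRUE, showWarnings = FALSE)
  source_path <- file.path(config$dir,
                           paste0(tolower(config$dataset_id), "_source.csv"))
  truth_path <- file.path(config$dir,
                          paste0(tolower(config$dataset_id), "_truth.csv"))
  con <- file(source_path, open = "wb")
  if (spec$skip_rows > 0)  # emulate the export banner the real file carries
    writeLines(rep(paste(config$dataset_id, "clinical data export"),
                   spec$skip_rows), con, sep = "\n")
  utils::write.csv(source_df, con, row.names = FALSE)
  close(con)
  utils::write.csv(truth_df, truth_path, row.names = FALSE)
  list(source_path = source_path, truth_path = truth_path,
       source = source_df, truth = truth_df)
}

#' Series composition for the metadata generator
#'
#' @param counts Named integer vector/list: technique to series count
#'   (techniques among DCE, DWI, T1W, T2W, OTHER, UNKNOWN).
#' @param orientation_mix Named weights over orientations (default all
#'   axial, the dominant breast-MRI orientation).
#' @param anonymized_fraction Fraction of series stripped of their primary
#'   identifying tag, which must still classify via the fallback route.
#' @param seed Integer seed.
#' @param collection Collection name stamped on every series.
#' @return A `series_composition` list.
#' @export
series_composition <- function(counts, orientation_mix = c(AXIAL = 1),
                               anonymized_fraction = 0.25, seed = 1,
                               collection = "FIXTURE") {
  counts <- unlist(counts)
  if (!length(counts) || sum(counts) <= 0)
    stop("series composition must request at least one series")
  if (!all(names(counts) %in% .TECHNIQUES))
    stop("unknown technique in composition: ",
         paste(setdiff(names(counts), .TECHNIQUES), collapse = ", "))
  structure(list(counts = counts, orientation_mix = orientation_mix,
                 anonymized_fraction = anonymized_fraction,
                 seed = as.integer(seed), collection = collection),
            class = "series_composition")
}

.IOP_BY_ORIENTATION <- list(
  AXIAL = "1\\0\\0\\0\\1\\0",
  SAGITTAL = "0\\1\\0\\0\\0\\-1",
  CORONAL = "1\\0\\0\\0\\0\\-1",
  OBLIQUE = "1\\0\\0\\0\\0.7071\\0.7071")

.fixture_tags <- function(technique, orientation, anonymized) {
  tags <- list()
  if (technique == "UNKNOWN") return(tags)
  tags[["0020,0037"]] <- .IOP_BY_ORIENTATION[[orientation]]
  if (stats::runif(1) < 0.3)  # redundant tag that fires no rule
    tags[["0008,0008"]] <- "ORIGINAL\\PRIMARY"
  if (technique == "DCE") {
    tags[["0018,0020"]] <- "GR"
    tags[["0018,0023"]] <- "3D"
    tags[["0018,1314"]] <- as.character(sample(8:15, 1))
    tags[["0008,103E"]] <- "dynamic post-contrast"
    if (!anonymized)
      tags[["0020,0105"]] <- as.character(sample(30:90, 1))
  } else if (technique == "DWI") {
    b <- sample(c(0, 50, 400, 600, 800, 1000), 1)
    if (anonymized) {
      tags[["0008,103E"]] <- "diffusion weighted"
    } else {
      tags[["0018,0020"]] <- "EP"
      tags[["0008,103E"]] <- paste0("dwi b", b)
    }
    if (stats::runif(1) < 0.5) {
      tags[["0018,9087"]] <- as.character(b)
    } else {
      tags[["0043,1039"]] <- c(1e9 + b, 8, 0, 0)
    }
    if (stats::runif(1) < 0.5) tags[["0018,9075"]] <- "ISOTROPIC"
  } else if (technique == "T1W") {
    if (!anonymized) tags[["0018,0020"]] <- "SE"
    tags[["0008,103E"]] <- sample(c("t1 fse", "ax t1w post"), 1)
  } else if (technique == "T2W") {
    if (!anonymized) tags[["0018,0020"]] <- "SE"
    tags[["0008,103E"]] <- sample(c("t2 fatsat", "stir sagittal"), 1)
  } else if (technique == "OTHER") {
    tags[["0018,0020"]] <- "IR"
    tags[["0018,1314"]] <- "90"
    tags[["0008,103E"]] <- "localizer"
  }
  tags
}

#' Generate series metadata with ground-truth labels
#'
#' Each series carries tags sufficient for its ground-truth technique; an
#' `anonymized_fraction` of them drop the primary tag (number of temporal
#' positions for DCE, the echo-planar scanning sequence for DWI, the
#' spin-echo tag for anatomical series) and must still classify correctly
#' through the fallback route.
#'
#' @param comp A [series_composition()].
#' @return List with `series` (list of `series_metadata`) and `truth`
#'   (data frame: `series_uid`, `technique`, `orientation`).
#' @export
generate_series_metadata <- function(comp) {
  stopifnot(inherits(comp, "series_composition"))
  set.seed(comp$seed %% 2147483647L)
  series <- list()
  truth <- NULL
  idx <- 0L
  for (technique in names(comp$counts)) {
    for (i in seq_len(comp$counts[[technique]])) {
      idx <- idx + 1L
      uid <- sprintf("1.3.6.1.4.1.9999.%d.%d.%d", comp$seed,
                     match(technique, .TECHNIQUES), i)
      orientation <- if (technique == "UNKNOWN") "UNKNOWN" else
        sample(names(comp$orientation_mix), 1,
               prob = unlist(comp$orientation_mix))
      anonymized <- stats::runif(1) < comp$anonymized_fraction
      tags <- .fixture_tags(technique, orientation, anonymized)
      series[[idx]] <- series_metadata(uid, comp$collection,
                                       sprintf("SUBJ%03d", idx), tags)
      truth <- rbind(truth, data.frame(
        series_uid = uid, technique = technique, orientation = orientation,
        stringsAsFactors = FALSE))
    }
  }
  list(series = series, truth = truth)
}
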