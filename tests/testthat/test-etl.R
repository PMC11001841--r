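cdm <- load_cdm_registry()

test_that("source loading applies preparatory cleanup and rejects bad files", {
  cfg <- fixture_config("DUKE", n_subjects = 10, seed = 5, dir = tempfile())
  fx <- generate_source_csv(cfg)
  tab <- load_source_table(fx$source_path, "DUKE")
  expect_s3_class(tab, "source_table")
  expect_equal(nrow(tab$data), 10)  # banner row skipped

  f <- tempfile(fileext = ".csv")
  writeLines(character(0), f)
  expect_error(load_source_table(f, "ISPY1"), "load error")

  writeLines(c("SUBJECTID,AGE", "1,50", "1,60"), f)
  expect_error(load_source_table(f, "ISPY1"), "duplicate subject id '1'")

  writeLines(c("WRONG,AGE", "1,50"), f)
  expect_error(load_source_table(f, "ISPY1"), "subject-id column")
})

test_that("NACT constants and the subject-27 override are applied", {
  yes <- "4188539"; no <- "4188540"
  spec <- load_mapping_spec(mapping_spec_path("NACT"))

  # n = 5: no subject 27, every row gets the radiotherapy constant
  fx5 <- generate_source_csv(fixture_config("NACT", 5, seed = 2,
                                            dir = tempfile()))
  h5 <- harmonize(load_source_table(fx5$source_path, "NACT", spec), spec,
                  cdm)
  expect_true(all(h5$table$adjuvant_radiotherapy == yes))
  expect_true(all(h5$table$neoadjuvant_chemotherapy == yes))

  # n = 30: subject 27 exists and both adjuvant fields are overridden
  fx30 <- generate_source_csv(fixture_config("NACT", 30, seed = 2,
                                             dir = tempfile()))
  h30 <- harmonize(load_source_table(fx30$source_path, "NACT", spec), spec,
                   cdm)
  r27 <- h30$table[h30$table$subject_id == "27", ]
  expect_equal(r27$adjuvant_radiotherapy, no)
  expect_equal(r27$adjuvant_hormone_therapy, no)
  expect_equal(unname(h30$provenance[h30$table$subject_id == "27",
                                     "adjuvant_radiotherapy"]), "override")
  expect_true(all(h30$table$adjuvant_radiotherapy[
    h30$table$subject_id != "27"] == yes))
})

test_that("ISPY2 arm feeds medication (with cyclophosphamide), regimen and pCR", {
  spec <- load_mapping_spec(mapping_spec_path("ISPY2"))
  fx <- generate_source_csv(fixture_config("ISPY2", 20, seed = 9,
                                           dir = tempfile()))
  h <- harmonize(load_source_table(fx$source_path, "ISPY2", spec), spec,
                 cdm)
  cyclo <- "19010482"
  meds <- h$table$neoadjuvant_chemo_medication
  expect_true(all(vapply(meds, function(m)
    cyclo %in% strsplit(m, "|", fixed = TRUE)[[1]], logical(1))))
  paclitaxel <- "1378382"
  expect_true(all(vapply(meds, function(m)
    paclitaxel %in% strsplit(m, "|", fixed = TRUE)[[1]], logical(1))))
  expect_true(all(h$table$neoadjuvant_chemotherapy == "4188539"))
  # pCR is yes exactly when RCB class is 0
  rcb0 <- h$table$rcb_class == "36768514"
  expect_equal(h$table$pathologic_complete_response == "4188539",
               unname(rcb0))
})

test_that("an empty mapping spec imputes every cell and maps zero concepts", {
  spec <- load_mapping_spec(mapping_spec_path("ISPY1"))
  fx <- generate_source_csv(fixture_config("ISPY1", 4, seed = 1,
                                           dir = tempfile()))
  tab <- load_source_table(fx$source_path, "ISPY1", spec)
  empty <- spec
  empty$rules <- list()
  h <- harmonize(tab, empty, cdm)
  cells <- as.matrix(h$table[, cdm_fields(cdm)])
  expect_true(all(cells == as.character(NOT_PROVIDED)))
  expect_equal(h$coverage$concepts_mapped, 0)
  expect_equal(h$coverage$percent_concepts, 0)
})

test_that("a rule emitting an unregistered value is a hard spec error", {
  spec <- load_mapping_spec(mapping_spec_path("ISPY1"))
  fx <- generate_source_csv(fixture_config("ISPY1", 3, seed = 4,
                                           dir = tempfile()))
  tab <- load_source_table(fx$source_path, "ISPY1", spec)
  bad <- spec
  bad$rules[[2]]$map[["1"]] <- 424242L
  expect_error(harmonize(tab, bad, cdm), "unregistered value")
})

test_that("harmonization is deterministic and byte-stable on disk", {
  spec <- load_mapping_spec(mapping_spec_path("TCGA_BRCA"))
  fx <- generate_source_csv(fixture_config("TCGA_BRCA", 15, mess_rate = 1,
                                           seed = 13, dir = tempfile()))
  tab <- load_source_table(fx$source_path, "TCGA_BRCA", spec)
  h1 <- harmonize(tab, spec, cdm)
  h2 <- harmonize(tab, spec, cdm)
  expect_identical(h1$table, h2$table)
  f1 <- tempfile(); f2 <- tempfile()
  write_harmonized_csv(h1, f1); write_harmonized_csv(h2, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})

test_that("all-blank rows still harmonize with total imputation", {
  spec <- load_mapping_spec(mapping_spec_path("ISPY1"))
  fx <- generate_source_csv(fixture_config("ISPY1", 3, seed = 6,
                                           dir = tempfile()))
  src <- utils::read.csv(fx$source_path, colClasses = "character",
                         check.names = FALSE)
  src[2, -1] <- ""               # wipe everything except the id
  src[3, "RACE_ID"] <- "weird"   # unmapped non-empty token: logged demotion
  f <- tempfile(fileext = ".csv")
  utils::write.csv(src, f, row.names = FALSE)
  h <- harmonize(load_source_table(f, "ISPY1", spec), spec, cdm)
  cells <- as.matrix(h$table[, cdm_fields(cdm)])
  expect_true(all(nzchar(cells)))
  row2 <- cells[2, ]
  # everything except the constant collapses to Not provided
  expect_true(all(row2[names(row2) != "neoadjuvant_chemotherapy"] ==
                    as.character(NOT_PROVIDED)))
  expect_equal(unname(row2[["neoadjuvant_chemotherapy"]]), "4188539")
  expect_equal(unname(cells[3, "race"]), as.character(NOT_PROVIDED))
  expect_match(h$log, "weird", all = FALSE)
})

test_that("coverage percentages follow the source concept denominators", {
  for (ds in c("ISPY2", "DUKE", "ISPY1", "TCGA_BRCA", "NACT")) {
    spec <- load_mapping_spec(mapping_spec_path(ds))
    fx <- generate_source_csv(fixture_config(ds, 5, seed = 3,
                                             dir = tempfile()))
    tab <- load_source_table(fx$source_path, ds, spec)
    cov <- coverage_report(spec, cdm, tab)
    info <- source_dataset_info()[[ds]]
    expect_equal(cov$percent_concepts,
                 100 * cov$concepts_mapped / info$concepts)
    expect_equal(cov$subjects_included, 5)
  }
  # one source concept can feed several CDM fields: ISPY2 exceeds 100%
  spec <- load_mapping_spec(mapping_spec_path("ISPY2"))
  fx <- generate_source_csv(fixture_config("ISPY2", 5, seed = 3,
                                           dir = tempfile()))
  cov <- coverage_report(spec, cdm,
                         load_source_table(fx$source_path, "ISPY2", spec))
  expect_gt(cov$percent_concepts, 100)
})
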