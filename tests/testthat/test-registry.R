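cdm <- load_cdm_registry()

test_that("shipped registry loads with coherent structure", {
  expect_s3_class(cdm, "cdm_definition")
  expect_true(all(vapply(cdm$concepts, function(cc) cc$omop_id > 0,
                         logical(1))))
  # every coded value set contains the Not-provided code; scalars have none
  for (fn in cdm_fields(cdm)) {
    cc <- cdm_concept(cdm, fn)
    if (cc$value_domain == "scalar_numeric") {
      expect_equal(nrow(cc$values), 0)
    } else {
      expect_true(NOT_PROVIDED %in% cc$values$omop_id)
      expect_gt(nrow(cc$values), 1)
      expect_false(anyDuplicated(cc$values$omop_id) > 0)
    }
  }
  # the deliberate dual concept: two fields sharing one OMOP ID
  expect_equal(cdm_concept(cdm, "neoadjuvant_chemotherapy")$omop_id,
               cdm_concept(cdm, "neoadjuvant_chemo_medication")$omop_id)
})

test_that("registry save/load round trip is the identity", {
  f <- tempfile(fileext = ".csv")
  save_cdm_registry(cdm, f)
  cdm2 <- load_cdm_registry(f)
  expect_equal(cdm_fields(cdm2), cdm_fields(cdm))
  for (fn in cdm_fields(cdm)) {
    a <- cdm_concept(cdm, fn); b <- cdm_concept(cdm2, fn)
    expect_equal(b$omop_id, a$omop_id)
    expect_equal(b$vocabulary, a$vocabulary)
    expect_equal(b$values$omop_id, a$values$omop_id)
    expect_equal(b$values$generic_parent, a$values$generic_parent)
  }
  expect_identical(unclass(vocabulary_usage(cdm2))[c("n_concepts",
                                                     "n_values")],
                   unclass(vocabulary_usage(cdm))[c("n_concepts",
                                                    "n_values")])
})

test_that("loader rejects malformed registries with named errors", {
  f <- tempfile(fileext = ".csv")
  write_mini_registry(f)
  mini <- load_cdm_registry(f)
  expect_equal(length(mini$concepts), 2)

  # single scalar concept, no values: valid
  write_mini_registry(f, c(
    "record,field_name,omop_id,vocabulary,label,concept_group,value_domain,granularity,generic_parent,units",
    "concept,age,4265453,SNOMED,Age,demographic,scalar_numeric,,,years"))
  expect_equal(length(load_cdm_registry(f)$concepts), 1)

  # duplicate field name
  write_mini_registry(f, c(
    "record,field_name,omop_id,vocabulary,label,concept_group,value_domain,granularity,generic_parent,units",
    "concept,age,1,SNOMED,Age,demographic,scalar_numeric,,,years",
    "concept,age,2,SNOMED,Age,demographic,scalar_numeric,,,years"))
  expect_error(load_cdm_registry(f), "duplicate field_name 'age'")

  # coded concept with empty value set
  write_mini_registry(f, c(
    "record,field_name,omop_id,vocabulary,label,concept_group,value_domain,granularity,generic_parent,units",
    "concept,flag,123,SNOMED,Flag,outcome,coded_single,,,"))
  expect_error(load_cdm_registry(f), "empty value_set")

  expect_error(load_cdm_registry(tempfile()), "not found")
})

test_that("vocabulary usage counts each concept once and dedupes values", {
  f <- tempfile(fileext = ".csv")
  write_mini_registry(f)
  vu <- vocabulary_usage(load_cdm_registry(f))
  expect_equal(vu$concept_counts$SNOMED, 2)
  # yes + no + Not provided, the latter under its own vocabulary
  expect_equal(vu$value_counts$SNOMED, 2)
  expect_equal(vu$value_counts$PPI, 1)
  expect_equal(sum(unlist(vu$concept_counts)), vu$n_concepts)
  expect_equal(sum(unlist(vu$value_counts)), vu$n_values)
})

test_that("concept-count marginal sums to the concept total on random registries", {
  set.seed(42)
  header <- "record,field_name,omop_id,vocabulary,label,concept_group,value_domain,granularity,generic_parent,units"
  for (rep in 1:10) {
    k <- sample(1:12, 1)
    vocabs <- sample(c("SNOMED", "LOINC", "RxNorm", "HemOnc"), k,
                     replace = TRUE)
    lines <- c(header, vapply(seq_len(k), function(i) sprintf(
      "concept,f%d,%d,%s,F%d,outcome,scalar_numeric,,,", i, i, vocabs[i], i),
      character(1)))
    f <- tempfile(fileext = ".csv")
    writeLines(lines, f)
    vu <- vocabulary_usage(load_cdm_registry(f))
    expect_equal(sum(unlist(vu$concept_counts)), k)
  }
})

test_that("validate_record reports violations per field without throwing", {
  rec <- as.list(stats::setNames(rep(as.character(NOT_PROVIDED), 38),
                                 cdm_fields(cdm)))
  expect_true(all(validate_record(rec, cdm)$ok))

  rec$er_status <- "999999"       # unregistered code
  rec$age <- "abc"                # non-numeric scalar
  rec$neoadjuvant_chemo_medication <- ""  # empty cell
  rep_df <- validate_record(rec, cdm)
  expect_false(rep_df$ok[rep_df$field == "er_status"])
  expect_match(rep_df$message[rep_df$field == "er_status"], "999999")
  expect_false(rep_df$ok[rep_df$field == "age"])
  expect_false(rep_df$ok[rep_df$field == "neoadjuvant_chemo_medication"])

  # multi-valued cell with registered codes is valid
  rec2 <- list(neoadjuvant_chemo_medication = "1378382|19010482")
  expect_true(all(validate_record(rec2, cdm)$ok))
  expect_error(validate_record(list(nonexistent = "1"), cdm),
               "outside the registry")
})
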