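config <- classifier_config()

test_that("orientation follows the slice normal for cardinal frames", {
  expect_equal(orientation_from_cosines(c(1, 0, 0, 0, 1, 0)), "AXIAL")
  expect_equal(orientation_from_cosines(c(1, 0, 0, 0, 0, -1)), "CORONAL")
  expect_equal(orientation_from_cosines(c(0, 1, 0, 0, 0, -1)), "SAGITTAL")
  expect_equal(orientation_from_cosines("1\\0\\0\\0\\1\\0"), "AXIAL")
  # tilted 45 degrees: largest normal component below threshold
  expect_equal(orientation_from_cosines(c(1, 0, 0, 0, 0.7071, 0.7071)),
               "OBLIQUE")
  expect_equal(orientation_from_cosines(NULL), "UNKNOWN")
  expect_equal(orientation_from_cosines(c(1, 2, 3)), "UNKNOWN")
  expect_equal(orientation_from_cosines("a\\b\\c\\d\\e\\f"), "UNKNOWN")
})

test_that("orientation agrees with the cross-product oracle on random frames", {
  set.seed(101)
  for (i in 1:300) {
    iop <- random_frame()
    expect_equal(orientation_from_cosines(iop), orientation_oracle(iop),
                 label = paste("frame", i))
  }
})

test_that("diffusion b-value prefers the standard tag and decodes the GE offset", {
  expect_equal(parse_diffusion_bvalue(list(`0018,9087` = "1000")), 1000)
  # GE private encoding: first element, offset by 1e9
  ge <- parse_diffusion_bvalue(list(`0043,1039` = c(1000000600, 8, 0, 0)))
  expect_equal(ge, 600)
  expect_gte(ge, 0); expect_lte(ge, 5000)  # plausible diffusion weighting
  # already-plain GE values pass through
  expect_equal(parse_diffusion_bvalue(list(`0043,1039` = c(800, 8, 0, 0))),
               800)
  # standard tag wins when both present
  expect_equal(parse_diffusion_bvalue(
    list(`0018,9087` = "50", `0043,1039` = c(1000000600, 8))), 50)
  expect_null(parse_diffusion_bvalue(list(`0008,103E` = "dwi")))
  expect_null(parse_diffusion_bvalue(list(`0018,9087` = "n/a")))
})

test_that("classification rules fire in DWI > DCE > anatomical precedence", {
  s <- function(tags) classify_series(
    series_metadata("1.2.3", "C", tags = tags), config)

  dce <- s(list(`0020,0105` = "60", `0018,0020` = "GR"))
  expect_equal(dce$technique, "DCE")
  expect_match(dce$evidence, "temporal positions", all = FALSE)

  dwi <- s(list(`0018,0020` = "EP", `0018,9087` = "800"))
  expect_equal(dwi$technique, "DWI")
  expect_equal(dwi$b_values, 800)

  # diffusion evidence outranks temporal positions
  both <- s(list(`0018,0020` = "EP", `0018,9087` = "800",
                 `0020,0105` = "40"))
  expect_equal(both$technique, "DWI")

  # anonymized DCE: gradient-echo 3D low flip angle fallback
  anon <- s(list(`0018,0020` = "GR", `0018,0023` = "3D",
                 `0018,1314` = "10"))
  expect_equal(anon$technique, "DCE")
  # high flip angle blocks the fallback
  expect_equal(s(list(`0018,0020` = "GR", `0018,0023` = "3D",
                      `0018,1314` = "70"))$technique, "OTHER")

  expect_equal(s(list(`0018,0020` = "SE",
                      `0008,103E` = "sag t2 fatsat"))$technique, "T2W")
  expect_equal(s(list(`0008,103E` = "STIR"))$technique, "T2W")
  expect_equal(s(list(`0018,0020` = "SE",
                      `0008,103E` = "ax t1"))$technique, "T1W")
  expect_equal(s(list(`0018,0020` = "IR",
                      `0008,103E` = "localizer"))$technique, "OTHER")

  unk <- s(list())
  expect_equal(unk$technique, "UNKNOWN")
  expect_equal(unk$orientation, "UNKNOWN")
  expect_length(unk$evidence, 0)
})

test_that("classification is total, labelled with evidence, and noise-insensitive", {
  set.seed(55)
  comp <- series_composition(c(DCE = 3, DWI = 3, T1W = 2, T2W = 2,
                               OTHER = 2),
                             anonymized_fraction = 0.5, seed = 77)
  g <- generate_series_metadata(comp)
  for (i in seq_along(g$series)) {
    meta <- g$series[[i]]
    lab <- classify_series(meta, config)
    expect_true(lab$technique %in% c("DCE", "DWI", "T1W", "T2W", "OTHER",
                                     "UNKNOWN"))
    expect_gt(length(lab$evidence), 0)
    # monotone evidence: a tag that fires no rule never flips the label
    noisy <- meta
    noisy$tags[["0008,0070"]] <- "FIXTURE MEDICAL SYSTEMS"
    expect_equal(classify_series(noisy, config)$technique, lab$technique)
  }
})

test_that("tag keys normalize across dialects", {
  expect_equal(normalize_tag_key("(0020,0105)"), "0020,0105")
  expect_equal(normalize_tag_key("0008103e"), "0008,103E")
  expect_equal(normalize_tag_key("0043x1039"), "0043,1039")
  expect_error(normalize_tag_key("12,34"), "not a DICOM tag")
  m <- series_metadata("u1", "C", tags = list(`(0018,0020)` = "GR"))
  expect_named(m$tags, "0018,0020")
})

test_that("technique statistics tally to the input size and reject mixed collections", {
  comp <- series_composition(c(DWI = 5, DCE = 7, T1W = 3), seed = 31)
  g <- generate_series_metadata(comp)
  st <- technique_statistics(g$series, config)
  expect_equal(unname(st$counts[["DWI"]]), 5)
  expect_equal(unname(st$counts[["DCE"]]), 7)
  expect_equal(unname(st$counts[["T1W"]]), 3)
  expect_equal(sum(st$counts), st$total)
  expect_equal(st$total, 15)

  empty <- technique_statistics(list(), config)
  expect_equal(empty$total, 0)
  expect_true(all(empty$counts == 0))

  blanks <- lapply(1:4, function(i)
    series_metadata(paste0("u", i), "C", tags = list()))
  expect_equal(unname(technique_statistics(blanks,
                                           config)$counts[["UNKNOWN"]]), 4)

  mixed <- list(series_metadata("a", "C1"), series_metadata("b", "C2"))
  expect_error(technique_statistics(mixed, config), "mixed collections")
})
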