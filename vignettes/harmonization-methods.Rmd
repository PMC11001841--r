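---
title: "Methods: a coded common data model and technique-aware series selection for public breast-cancer MRI collections"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: coded CDM and series selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(omopmri)
```

## The problem

Public breast-cancer imaging collections ship their clinical tables in
whatever schema the original study used: binary 0/1 flags in one file,
categorical text in another, free-text answers where the request form asked
for a clock position, per-drug columns next to concatenated medication
strings, and TNM categories at different granularities. The matching MRI
series are just as heterogeneous, and after archive anonymization the DICOM
tags that would identify a series' technique (dynamic contrast-enhanced,
diffusion-weighted, anatomical) are often missing. Anyone assembling a
multi-collection cohort for model development faces the same two chores:
harmonize the clinical tables into one coded dataset, and select the
imaging series of the technique their model needs.

This package implements both chores as reviewable configuration plus a
deterministic engine, so the whole conversion can be re-run, audited and
extended.

## The common data model

The CDM admits only two kinds of fields: scalar numeric fields (with units
recorded in the registry) and nominal fields whose every value is a
concept code from a standardized vocabulary (SNOMED, LOINC, RxNorm,
HemOnc, Cancer Modifier, ICD-O-3 topography, and friends). The shipped
registry (`inst/extdata/cdm/registry.csv`) is one flat CSV so it can be
reviewed line by line: `concept` rows define the 38 fields, `value` rows
attach the 135 distinct coded values. The registry is curated, static
data: no live vocabulary service is consulted, and where a public OMOP
concept ID was not available during curation a registry-local placeholder
ID in a plausible range is used; re-curating an ID is a one-line edit that
no code depends on.

Design choices a reviewer should know about:

* **No empty cells, ever.** The reserved code `763013` ("Not provided")
  is a member of every coded value set and the imputation value for
  missing, unmapped, or unparseable source cells. The loader attaches it
  implicitly so the file does not repeat it 32 times; vocabulary-usage
  counts include it exactly once, under its own source vocabulary (PPI).
* **Detailed values over generic ones.** Receptor status is coded as
  "estrogen receptor positive tumor", not a bare yes -- the cell then
  carries its meaning without the column header.
* **Dual granularity.** Where sources disagree on granularity (pN as
  -1..4 in one collection, `N1a`/`N0 (i-)` text in another), the value
  set registers both levels and each detailed code carries its
  `generic_parent`; `recode_generic()` collapses to the generic level and
  is idempotent. The same device handles the deliberately duplicated
  concept pair `neoadjuvant_chemotherapy` / `neoadjuvant_chemo_medication`:
  two fields, one OMOP concept, binary and per-drug granularity.
  Field-name uniqueness, not concept-ID uniqueness, is the registry
  invariant.
* **Multi-valued cells** (medication lists) are encoded as the
  concept IDs deduplicated, sorted ascending and joined with a vertical
  bar. Sorting is not cosmetic: a canonical form makes repeated runs
  byte-identical and regression-testable.

## The ETL

Each dataset has one declarative mapping spec
(`inst/extdata/mappings/*.yaml`): recode maps keyed on
case/whitespace-normalized tokens, named derivations, constants implied by
study design (every subject in the two neoadjuvant trials received
chemotherapy; one trial's protocol included standard-of-care adjuvant
radiotherapy), and per-subject overrides for information hidden in comment
fields (the shipped NACT spec sets both adjuvant-therapy fields to "No"
for subject 27, whose comment declines them). `harmonize()` applies rules,
imputes the rest, applies overrides last, records per-cell provenance
(rule kind) and validates every emitted code against the registry -- an
unregistered code is a spec bug and a hard error, while an unmapped source
token is data dirt and demotes to Not provided with a log line.

Derivations worth documenting:

* **Hormone-receptor status** from ER and PR: positive if either is
  positive; negative if both negative; otherwise Not provided. This is
  the standard clinical disjunction; the nine-pair truth table is frozen
  in the tests.
* **pCR from residual cancer burden**: class 0 means complete response.
* **Tumor position.** One collection answers "tumor location" as
  free text around a clock convention ("L 2", "R4-5", "L 11:30",
  "L 2 with calcs"). The parser extracts laterality and clock hour,
  takes range midpoints, tolerates half hours and trailing noise, and
  maps hour x laterality to a breast quadrant through a shipped 24-row
  table (`clock_quadrant.csv`), then to the quadrant's ICD-O-3 C50.x
  code. The convention is patient-facing, with boundary hours (12, 3, 6,
  9) assigned to the clockwise-following quadrant -- the convention is
  a deliberate, documented choice (the alternative, mapping exact 12/6
  to an overlapping-lesion code, loses determinism at boundaries) and
  lives in configuration so it can be re-curated. Laterality without a
  parsable hour maps to breast-NOS; nothing parsable maps to Not
  provided.
* **Medication strings** are scanned against the registry's drug
  lexicon by substring, so "Paclitaxel + Veliparib-Carboplatin" yields
  three codes; the arm parser for the adaptive trial always appends
  cyclophosphamide, which that study administered in every arm.

Subject exclusion is an explicit spec field (the shipped default drops
only rows with blank identifiers); the real criteria by which the original
curators dropped subjects from two collections are not public, so no
implicit filtering is hard-coded. Coverage reports divide mapped-concept
counts by the source file's concept count (shipped metadata), which can
exceed 100% when one source column feeds several CDM fields; percentages
are stored unrounded and displayed rounded.

## Series classification

Classification is total on arbitrarily sparse tag maps and never raises.
Rule precedence is DWI > DCE > anatomical, because diffusion evidence
(b-value tags) is the most specific:

1. **DWI**: echo-planar scanning sequence (`(0018,0020)` contains `EP`)
   or a diffusion keyword in the free-text description, AND at least one
   diffusion tag present: standard b-value `(0018,9087)`, directionality
   `(0018,9075)`, or the GE private tag `(0043,1039)`. GE stores the
   b-value offset by 1e9 (an internal ordering of the b-value
   acquisitions that corrupts ADC computation if ignored), so values at
   or above 1e9 are reduced by 1e9 -- the rule is isolated in
   `parse_diffusion_bvalue()` and unit-tested.
2. **DCE**: number of temporal positions `(0020,0105)` above 1; when
   anonymization removed it, the fallback is gradient-echo (`GR`) 3D
   acquisition with flip angle below 20 degrees -- a typical T1-weighted
   dynamic setup. The threshold is configuration
   (`classifier.yaml`), default 20, chosen as a round value separating
   spoiled-gradient dynamic acquisitions (commonly 10-15 degrees) from
   high-flip anatomical ones.
3. **T2W / T1W** from case-insensitive description keywords (`t2`,
   `stir` / `t1`); a spin-echo scanning sequence is recorded as
   supporting evidence but is deliberately not sufficient on its own,
   since spin-echo weighting is set by timing parameters the public
   metadata rarely keeps.
4. **OTHER** when tags exist but nothing fires; **UNKNOWN** only for an
   empty tag map. Every label carries the fired predicates as evidence.

Orientation comes from the image-orientation cosines `(0020,0037)`: the
slice normal is the cross product of the row and column vectors, and the
dominant component names the plane (x sagittal, y coronal, z axial) when
its magnitude reaches the obliquity threshold (default 0.8, configurable),
else OBLIQUE. Missing or malformed cosines give UNKNOWN.

Metadata acquisition is two-step (a collection listing, then one request
per series), so `fetch_collection_series()` runs behind an injectable
client interface with a write-through JSON cache keyed by series UID: a
warm cache issues zero per-series requests and returns byte-identical
output. Manifest files for the archive's bulk downloader are written in
the fixed key=value template (including the historical `noOfrRetry` key
spelling, kept for bit-compatibility with the consuming tool) and
round-trip through `read_manifest()`.

## Synthetic fixtures: what they do and do not show

`generate_source_csv()` emulates each collection's schema and messiness
from a seed, writing the ground-truth CDM table alongside. Source tokens
are drawn by inverting the shipped mapping specs, latent state (receptor
flags, clock hour and laterality, trial arm) drives derived truths, and a
`mess_rate` fraction of eligible cells is perturbed only in
semantics-preserving ways: trailing annotations, case and whitespace
changes, half hours and in-sector ranges on clock positions (a range
across the 12-to-1 boundary would move the midpoint to the opposite
quadrant, so hour 12 never receives range noise). About 15% of numeric
cells are left blank to exercise imputation. Fixture sizes default small
(5-50 subjects); the tests use 50 subjects per dataset at mess rate 0.5,
the acceptance script the same, and the classifier suites use 100
generated collections of 6 series plus 1000 random orthonormal frames
against a brute-force cross-product oracle -- sizes chosen so the full
suite stays fast while every rule path is exercised.

What passing these suites shows: the machinery is correct -- rules,
parsers, imputation, canonical encodings, caching, manifest format, and
classification logic recover known truth exactly, including under full
mess and full anonymization. What it does not show: that the shipped maps
cover every token the real files contain (the real free-text fields have
hundreds of distinct values; unmapped ones demote safely to Not provided
rather than silently miscode), nor that real cohort statistics are
reproduced -- fixtures deliberately do not model joint clinical
distributions, and headline subject counts of the real collections are
not reproducible without the archive itself.

## Known limitations

* Registry OMOP IDs are curated data, partly placeholders; totals and
  structure, not individual IDs, are what the code guarantees.
* The DCE/anatomical decision logic beyond the listed tags is a
  reconstruction shipped as configuration, not hard-coded truth; sites
  with unusual keyword conventions will need the keyword lists extended.
* The ETL targets the five configured schemas; a new dataset requires a
  new mapping spec by design -- there is no schema inference.
* No pixel data is read, no images are downloaded, and no ADC maps are
  computed; the scope ends at metadata and manifests.
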