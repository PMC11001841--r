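# Independent oracles used across tests: small brute-force or closed-form
# re-derivations kept deliberately separate from the package code paths
# they check.

# Patient-facing clock convention, boundary hours clockwise-following:
# computed from sector arithmetic rather than the shipped lookup table.
quadrant_oracle <- function(laterality, hour) {
  sector <- floor((hour %% 12) / 3)  # 0:[12,3) 1:[3,6) 2:[6,9) 3:[9,12)
  left <- c("upper_outer", "lower_outer", "lower_inner", "upper_inner")
  right <- c("upper_inner", "lower_inner", "lower_outer", "upper_outer")
  if (laterality == "L") left[sector + 1] else right[sector + 1]
}

quadrant_code <- c(upper_outer = 35941054, lower_outer = 35941055,
                   upper_inner = 35941052, lower_inner = 35941053)

# Explicit cross product + argmax, the brute-force orientation oracle.
orientation_oracle <- function(iop, threshold = 0.8) {
  r <- iop[1:3]; cc <- iop[4:6]
  n <- c(r[2] * cc[3] - r[3] * cc[2],
         r[3] * cc[1] - r[1] * cc[3],
         r[1] * cc[2] - r[2] * cc[1])
  k <- which.max(abs(n))
  if (abs(n[k]) < threshold) "OBLIQUE"
  else c("SAGITTAL", "CORONAL", "AXIAL")[k]
}

# Random orthonormal (row, column) frame via QR of a random matrix.
random_frame <- function() {
  q <- qr.Q(qr(matrix(stats::rnorm(9), 3)))
  c(q[, 1], q[, 2])
}

# A minimal two-concept registry written to disk, for loader edge cases.
write_mini_registry <- function(path,
                                lines = c(
  "record,field_name,omop_id,vocabulary,label,concept_group,value_domain,granularity,generic_parent,units",
  "concept,age,4265453,SNOMED,Age,demographic,scalar_numeric,,,years",
  "concept,flag,123,SNOMED,Flag,outcome,coded_single,,,",
  "value,flag,4188539,SNOMED,Yes,,,generic,,",
  "value,flag,4188540,SNOMED,No,,,generic,,")) {
  writeLines(lines, path)
  path
}
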