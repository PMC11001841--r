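# Source-collection metadata: subject and concept counts of the original
# public clinical files (concept counts exclude case-identifier columns).
# Used by coverage reporting; percentages are mapped/source_concepts.
ISPY2:
  collection: "ISPY2"
  subjects: 985
  concepts: 9
  mri_series: 9391
DUKE:
  collection: "Duke-Breast-Cancer-MRI"
  subjects: 922
  concepts: 74
  mri_series: 45034
ISPY1:
  collection: "ISPY1"
  subjects: 221
  concepts: 17
  mri_series: 6464
TCGA_BRCA:
  collection: "TCGA-BRCA"
  subjects: 140
  concepts: 110
  mri_series: 1858
NACT:
  collection: "Breast-MRI-NACT-Pilot"
  subjects: 64
  concepts: 41
  mri_series: 1846
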