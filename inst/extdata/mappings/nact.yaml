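# Breast-MRI-NACT-Pilot: 23 CDM fields. By study design every subject
# received neoadjuvant chemotherapy and standard-of-care adjuvant
# radiotherapy, so both are constants; the comment field of subject 27
# ("declined standard-of-care post-surgery radiation and hormonal
# treatments") becomes explicit per-subject overrides.
dataset_id: NACT
subject_id_column: "SUBJECTID"
skip_rows: 0
rules:
  - target: age
    kind: parser
    source: ["AGE"]
    parser: as_numeric
  - target: race
    kind: direct_recode
    source: ["RACE"]
    map:
      white: 8527
      black: 8516
      asian: 8515
      american indian: 8657
      pacific islander: 8557
  - target: ethnicity
    kind: direct_recode
    source: ["ETHNICITY"]
    map:
      hispanic: 38003563
      not hispanic: 38003564
  - target: menopausal_status
    kind: direct_recode
    source: ["MENOPAUSAL STATUS"]
    map:
      pre: 4149084
      post: 4149085
  - target: er_status
    kind: direct_recode
    source: ["ER"]
    map:
      "0": 4261933
      "1": 4167696
  - target: pr_status
    kind: direct_recode
    source: ["PR"]
    map:
      "0": 4194662
      "1": 4194663
  - target: hr_status
    kind: derived
    source: ["ER", "PR"]
    derivation: hr_from_er_pr
  - target: her2_status
    kind: direct_recode
    source: ["HER2"]
    map:
      "0": 4117364
      "1": 4116087
  - target: tumor_grade
    kind: direct_recode
    source: ["GRADE"]
    map:
      "1": 4079476
      "2": 4079477
      "3": 4079478
  - target: laterality
    kind: direct_recode
    source: ["LATERALITY"]
    map:
      l: 4218674
      r: 4218675
  - target: tumor_size_mm
    kind: parser
    source: ["TUMOR SIZE"]
    parser: as_numeric
  - target: positive_lymph_nodes
    kind: parser
    source: ["POS NODES"]
    parser: as_numeric
  - target: pn_category
    kind: direct_recode
    source: ["PN STAGE"]
    map:
      "-1": 1634401
      "0": 1634402
      "1": 1634407
      "2": 1634412
      "3": 1634415
  - target: ajcc_stage
    kind: direct_recode
    source: ["STAGE"]
    map:
      i: 1634802
      ii: 1634805
      iii: 1634808
      iv: 1634812
  - target: adjuvant_hormone_therapy
    kind: direct_recode
    source: ["HORMONE THERAPY"]
    map:
      "0": 4188540
      "1": 4188539
  - target: surgery
    kind: direct_recode
    source: ["SURGERY"]
    map:
      "0": 4188540
      "1": 4188539
  - target: surgery_type
    kind: direct_recode
    source: ["SURGERY TYPE"]
    map:
      mastectomy: 4180932
      lumpectomy: 4180933
  - target: pathologic_complete_response
    kind: direct_recode
    source: ["PCR"]
    map:
      "0": 4188540
      "1": 4188539
  - target: recurrence
    kind: direct_recode
    source: ["RECURRENCE"]
    map:
      "0": 4188540
      "1": 4188539
  - target: vital_status
    kind: direct_recode
    source: ["VITAL STATUS"]
    map:
      "0": 4230556
      "1": 4306655
  - target: days_to_last_followup
    kind: parser
    source: ["DAYS TO LAST FU"]
    parser: as_numeric
  - target: neoadjuvant_chemotherapy
    kind: constant
    value: 4188539
  - target: adjuvant_radiotherapy
    kind: constant
    value: 4188539
overrides:
  - subject: "27"
    field: adjuvant_radiotherapy
    value: 4188540
  - subject: "27"
    field: adjuvant_hormone_therapy
    value: 4188540
exclusions: []
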