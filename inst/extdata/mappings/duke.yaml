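# Duke-Breast-Cancer-MRI: richest source file; 36 CDM fields mapped.
# HR status is derived from ER and PR (disjunction); tumor position is the
# free-text clock-face field cleaned by the position parser; pN/pT arrive as
# the numeric -1..4 convention (-1 = X category).
dataset_id: DUKE
subject_id_column: "Patient ID"
skip_rows: 1
rules:
  - target: age
    kind: parser
    source: ["Age at Diagnosis"]
    parser: as_numeric
  - target: race
    kind: direct_recode
    source: ["Race"]
    map:
      white: 8527
      black: 8516
      asian: 8515
      american indian: 8657
      pacific islander: 8557
  - target: ethnicity
    kind: direct_recode
    source: ["Ethnicity"]
    map:
      hispanic: 38003563
      not hispanic: 38003564
  - target: menopausal_status
    kind: direct_recode
    source: ["Menopause (at diagnosis)"]
    map:
      "0": 4149085
      "1": 4149084
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
      "2": 4117365
  - target: tumor_grade
    kind: direct_recode
    source: ["Nottingham grade"]
    map:
      "1": 4079476
      "2": 4079477
      "3": 4079478
  - target: histologic_type
    kind: direct_recode
    source: ["Histologic type"]
    map:
      ductal: 4083784
      lobular: 4083785
      dcis: 4083786
  - target: anatomic_site
    kind: parser
    source: ["Tumor Location"]
    parser: tumor_position_site
  - target: laterality
    kind: parser
    source: ["Tumor Location"]
    parser: tumor_position_laterality
  - target: pt_category
    kind: direct_recode
    source: ["T Stage"]
    map:
      "-1": 1634301
      "0": 1634302
      "is": 1634303
      "1": 1634304
      "2": 1634309
      "3": 1634310
      "4": 1634311
  - target: pn_category
    kind: direct_recode
    source: ["N Stage"]
    map:
      "-1": 1634401
      "0": 1634402
      "1": 1634407
      "2": 1634412
      "3": 1634415
  - target: pm_category
    kind: direct_recode
    source: ["M Stage"]
    map:
      "-1": 1634501
      "0": 1634502
      "1": 1634503
  - target: ct_category
    kind: direct_recode
    source: ["Clinical T Stage"]
    map:
      "-1": 1634601
      "0": 1634602
      "1": 1634603
      "2": 1634604
      "3": 1634605
      "4": 1634606
  - target: cn_category
    kind: direct_recode
    source: ["Clinical N Stage"]
    map:
      "-1": 1634701
      "0": 1634702
      "1": 1634703
      "2": 1634704
      "3": 1634705
  - target: ajcc_stage
    kind: direct_recode
    source: ["AJCC Stage"]
    map:
      "0": 1634801
      i: 1634802
      ia: 1634803
      ib: 1634804
      ii: 1634805
      iia: 1634806
      iib: 1634807
      iii: 1634808
      iiia: 1634809
      iiib: 1634810
      iiic: 1634811
      iv: 1634812
      x: 1634813
  - target: tumor_size_mm
    kind: parser
    source: ["Tumor Size (mm)"]
    parser: as_numeric
  - target: positive_lymph_nodes
    kind: parser
    source: ["Positive Lymph Nodes"]
    parser: as_numeric
  - target: lymphovascular_invasion
    kind: direct_recode
    source: ["Lymphovascular Invasion"]
    map:
      "0": 35919143
      "1": 35919142
  - target: neoadjuvant_chemotherapy
    kind: direct_recode
    source: ["Neoadjuvant Chemotherapy"]
    map:
      "0": 4188540
      "1": 4188539
  - target: neoadjuvant_chemo_medication
    kind: parser
    source: ["Neoadjuvant Medications"]
    parser: medication_list
  - target: adjuvant_radiotherapy
    kind: direct_recode
    source: ["Adjuvant Radiation Therapy"]
    map:
      "0": 4188540
      "1": 4188539
  - target: adjuvant_hormone_therapy
    kind: direct_recode
    source: ["Adjuvant Endocrine Therapy"]
    map:
      "0": 4188540
      "1": 4188539
  - target: adjuvant_chemotherapy
    kind: direct_recode
    source: ["Adjuvant Chemotherapy"]
    map:
      "0": 4188540
      "1": 4188539
  - target: her2_targeted_therapy
    kind: direct_recode
    source: ["HER2-Targeted Therapy"]
    map:
      "0": 4188540
      "1": 4188539
  - target: surgery_type
    kind: direct_recode
    source: ["Surgery Type"]
    map:
      mastectomy: 4180932
      lumpectomy: 4180933
  - target: surgery
    kind: direct_recode
    source: ["Surgery"]
    map:
      "0": 4188540
      "1": 4188539
  - target: pathologic_complete_response
    kind: direct_recode
    source: ["Pathologic Complete Response"]
    map:
      "0": 4188540
      "1": 4188539
  - target: recurrence
    kind: direct_recode
    source: ["Recurrence"]
    map:
      "0": 4188540
      "1": 4188539
  - target: vital_status
    kind: direct_recode
    source: ["Vital Status"]
    map:
      "0": 4230556
      "1": 4306655
  - target: days_to_last_followup
    kind: parser
    source: ["Days to Last Follow-up"]
    parser: as_numeric
  - target: days_to_death
    kind: parser
    source: ["Days to Death"]
    parser: as_numeric
  - target: breast_density
    kind: direct_recode
    source: ["Breast Density"]
    map:
      "1": 3036552
      "2": 3036552
      "3": 3036551
      "4": 3036551
  - target: mri_field_strength
    kind: parser
    source: ["Field Strength"]
    parser: as_numeric
overrides: []
exclusions: []
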