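# TCGA-BRCA: 27 of 110 source concepts map into the CDM. TNM categories come
# as categorical text including detailed sub-categories (N1a, N0 (i-)); the
# anatomic site is already ICD-O-3 coded (icd_o_3_site); HR is derived from
# ER and PR status text. Unmapped tokens (e.g. "indeterminate") demote to
# Not provided.
dataset_id: TCGA_BRCA
subject_id_column: "bcr_patient_barcode"
skip_rows: 0
rules:
  - target: age
    kind: parser
    source: ["age_at_initial_pathologic_diagnosis"]
    parser: as_numeric
  - target: race
    kind: direct_recode
    source: ["race"]
    map:
      white: 8527
      black or african american: 8516
      asian: 8515
      american indian or alaska native: 8657
      native hawaiian or other pacific islander: 8557
  - target: ethnicity
    kind: direct_recode
    source: ["ethnicity"]
    map:
      hispanic or latino: 38003563
      not hispanic or latino: 38003564
  - target: menopausal_status
    kind: direct_recode
    source: ["menopause_status"]
    map:
      pre: 4149084
      post: 4149085
  - target: er_status
    kind: direct_recode
    source: ["breast_carcinoma_estrogen_receptor_status"]
    map:
      positive: 4167696
      negative: 4261933
  - target: pr_status
    kind: direct_recode
    source: ["breast_carcinoma_progesterone_receptor_status"]
    map:
      positive: 4194663
      negative: 4194662
  - target: hr_status
    kind: derived
    source: ["breast_carcinoma_estrogen_receptor_status", "breast_carcinoma_progesterone_receptor_status"]
    derivation: hr_from_er_pr_text
  - target: her2_status
    kind: direct_recode
    source: ["lab_proc_her2_neu_immunohistochemistry_receptor_status"]
    map:
      positive: 4116087
      negative: 4117364
      equivocal: 4117365
  - target: histologic_type
    kind: direct_recode
    source: ["histological_type"]
    map:
      infiltrating ductal carcinoma: 4083784
      infiltrating lobular carcinoma: 4083785
      ductal carcinoma in situ: 4083786
  - target: anatomic_site
    kind: direct_recode
    source: ["icd_o_3_site"]
    map:
      c50.0: 35941050
      c50.1: 35941051
      c50.2: 35941052
      c50.3: 35941053
      c50.4: 35941054
      c50.5: 35941055
      c50.6: 35941056
      c50.8: 35941058
      c50.9: 35941059
  - target: laterality
    kind: direct_recode
    source: ["laterality"]
    map:
      left: 4218674
      right: 4218675
      bilateral: 4218676
  - target: pt_category
    kind: direct_recode
    source: ["pathologic_T"]
    map:
      tx: 1634301
      t0: 1634302
      tis: 1634303
      t1: 1634304
      t1mi: 1634305
      t1a: 1634306
      t1b: 1634307
      t1c: 1634308
      t2: 1634309
      t3: 1634310
      t4: 1634311
      t4a: 1634312
      t4b: 1634313
      t4c: 1634314
      t4d: 1634315
  - target: pn_category
    kind: direct_recode
    source: ["pathologic_N"]
    map:
      nx: 1634401
      n0: 1634402
      n0 (i-): 1634403
      n0 (i+): 1634404
      n0 (mol-): 1634405
      n0 (mol+): 1634406
      n1: 1634407
      n1mi: 1634408
      n1a: 1634409
      n1b: 1634410
      n1c: 1634411
      n2: 1634412
      n2a: 1634413
      n2b: 1634414
      n3: 1634415
      n3a: 1634416
      n3b: 1634417
      n3c: 1634418
  - target: pm_category
    kind: direct_recode
    source: ["pathologic_M"]
    map:
      mx: 1634501
      m0: 1634502
      m1: 1634503
  - target: ct_category
    kind: direct_recode
    source: ["clinical_T"]
    map:
      tx: 1634601
      t0: 1634602
      t1: 1634603
      t2: 1634604
      t3: 1634605
      t4: 1634606
  - target: cn_category
    kind: direct_recode
    source: ["clinical_N"]
    map:
      nx: 1634701
      n0: 1634702
      n1: 1634703
      n2: 1634704
      n3: 1634705
  - target: ajcc_stage
    kind: direct_recode
    source: ["pathologic_stage"]
    map:
      stage 0: 1634801
      stage i: 1634802
      stage ia: 1634803
      stage ib: 1634804
      stage ii: 1634805
      stage iia: 1634806
      stage iib: 1634807
      stage iii: 1634808
      stage iiia: 1634809
      stage iiib: 1634810
      stage iiic: 1634811
      stage iv: 1634812
      stage x: 1634813
  - target: positive_lymph_nodes
    kind: parser
    source: ["number_of_lymphnodes_positive_by_he"]
    parser: as_numeric
  - target: lymphovascular_invasion
    kind: direct_recode
    source: ["lymph_vessel_invasion"]
    map:
      "yes": 35919142
      "no": 35919143
  - target: neoadjuvant_chemotherapy
    kind: direct_recode
    source: ["history_neoadjuvant_treatment"]
    map:
      "yes": 4188539
      "no": 4188540
  - target: adjuvant_radiotherapy
    kind: direct_recode
    source: ["radiation_therapy"]
    map:
      "yes": 4188539
      "no": 4188540
  - target: adjuvant_chemotherapy
    kind: direct_recode
    source: ["pharmaceutical_therapy"]
    map:
      "yes": 4188539
      "no": 4188540
  - target: surgery_type
    kind: direct_recode
    source: ["breast_carcinoma_surgical_procedure_name"]
    map:
      modified radical mastectomy: 4180932
      simple mastectomy: 4180932
      lumpectomy: 4180933
  - target: vital_status
    kind: direct_recode
    source: ["vital_status"]
    map:
      alive: 4230556
      dead: 4306655
  - target: days_to_last_followup
    kind: parser
    source: ["days_to_last_followup"]
    parser: as_numeric
  - target: days_to_death
    kind: parser
    source: ["days_to_death"]
    parser: as_numeric
  - target: recurrence
    kind: direct_recode
    source: ["new_tumor_event_after_initial_treatment"]
    map:
      "yes": 4188539
      "no": 4188540
overrides: []
exclusions: []
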