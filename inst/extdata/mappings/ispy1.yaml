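# ISPY1 (ACRIN 6657): 14 CDM fields; HR status is provided directly
# ("HR Pos"), every subject received neoadjuvant chemotherapy by design.
dataset_id: ISPY1
subject_id_column: "SUBJECTID"
skip_rows: 0
rules:
  - target: age
    kind: parser
    source: ["AGE"]
    parser: as_numeric
  - target: race
    kind: direct_recode
    source: ["RACE_ID"]
    map:
      "1": 8527
      "2": 8516
      "3": 8515
      "4": 8657
      "5": 8557
  - target: er_status
    kind: direct_recode
    source: ["ERpos"]
    map:
      "0": 4261933
      "1": 4167696
  - target: pr_status
    kind: direct_recode
    source: ["PgRpos"]
    map:
      "0": 4194662
      "1": 4194663
  - target: hr_status
    kind: direct_recode
    source: ["HR Pos"]
    map:
      "0": 4035445
      "1": 4035444
  - target: her2_status
    kind: direct_recode
    source: ["Her2MostPos"]
    map:
      "0": 4117364
      "1": 4116087
  - target: menopausal_status
    kind: direct_recode
    source: ["Menopausal Status"]
    map:
      pre: 4149084
      post: 4149085
  - target: laterality
    kind: direct_recode
    source: ["Laterality"]
    map:
      "1": 4218674
      "2": 4218675
  - target: tumor_size_mm
    kind: parser
    source: ["MRI LD Baseline"]
    parser: as_numeric
  - target: pathologic_complete_response
    kind: direct_recode
    source: ["PCR"]
    map:
      "0": 4188540
      "1": 4188539
  - target: rcb_class
    kind: direct_recode
    source: ["RCB"]
    map:
      "0": 36768514
      "1": 36768515
      "2": 36768516
      "3": 36768517
  - target: recurrence
    kind: direct_recode
    source: ["Recurrence"]
    map:
      "0": 4188540
      "1": 4188539
  - target: days_to_last_followup
    kind: parser
    source: ["Days to Last Followup"]
    parser: as_numeric
  - target: neoadjuvant_chemotherapy
    kind: constant
    value: 4188539
overrides: []
exclusions: []
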