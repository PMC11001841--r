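# ISPY2: 9 source concepts (excluding SUBJECTID) feed 12 CDM fields.
# All subjects received neoadjuvant chemotherapy; cyclophosphamide was part of
# every regimen in addition to the arm-specific agents, so the medication
# parser always appends its code and neoadjuvant_chemotherapy is a constant.
dataset_id: ISPY2
subject_id_column: "SUBJECTID"
skip_rows: 0
rules:
  - target: age
    kind: parser
    source: ["Age"]
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
    source: ["Menopausal Status"]
    map:
      pre: 4149084
      post: 4149085
  - target: hr_status
    kind: direct_recode
    source: ["HR"]
    map:
      "0": 4035445
      "1": 4035444
  - target: her2_status
    kind: direct_recode
    source: ["HER2"]
    map:
      "0": 4117364
      "1": 4116087
  - target: rcb_class
    kind: direct_recode
    source: ["RCB"]
    map:
      "0": 36768514
      "1": 36768515
      "2": 36768516
      "3": 36768517
  - target: pathologic_complete_response
    kind: derived
    source: ["RCB"]
    derivation: pcr_from_rcb
  - target: tumor_size_mm
    kind: parser
    source: ["LD"]
    parser: as_numeric
  - target: neoadjuvant_chemo_medication
    kind: parser
    source: ["Arm"]
    parser: ispy2_arm_medication
  - target: neoadjuvant_regimen
    kind: direct_recode
    source: ["Arm"]
    map:
      paclitaxel: 35804762
      paclitaxel + trastuzumab: 35804764
      paclitaxel + ganitumab: 35804761
      paclitaxel + ganetespib: 35804762
      paclitaxel + veliparib-carboplatin: 35804763
      paclitaxel + neratinib: 35804766
      paclitaxel + trebananib: 35804765
  - target: neoadjuvant_chemotherapy
    kind: constant
    value: 4188539
overrides: []
exclusions: []
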