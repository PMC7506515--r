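# Default flag-extraction configuration. All lists are editable deployment
# configuration, not code: ICD-10-CM prefixes, antibiotic classification and
# day windows vary by site and coding era.
icd_codes:
  # cardiac device infection (device-related infection/inflammation codes)
  cied: ["T82.6", "T82.7"]
  # surgical site infection + wound dehiscence (dehiscence codes are included
  # per NHSN practice; in CIED data dehiscence is often the only SSI coding)
  ssi: ["T81.4", "T81.3"]
  # nonspecific infection codes (bacteremia, unspecified bacterial infection)
  unspecified: ["A49.9", "R78.81", "B99"]
antibiotics:
  # agents typically used to treat Staphylococcal infection
  staph_directed:
    [cefazolin, cephalexin, dicloxacillin, nafcillin, oxacillin, vancomycin,
     daptomycin, linezolid, doxycycline, trimethoprim-sulfamethoxazole,
     clindamycin, rifampin]
  # antibiotics not typically Staphylococcus-directed
  other:
    [azithromycin, ciprofloxacin, levofloxacin, metronidazole, amoxicillin,
     ampicillin, ceftriaxone, cefepime, piperacillin-tazobactam,
     nitrofurantoin, penicillin]
windows:
  # inclusive day offsets relative to the index procedure (day 0);
  # mortality window is [0, 90) i.e. death strictly before day 90
  fever: [0, 30]
  icd: [0, 90]
  micro: [0, 90]
  antibiotics: [6, 90]
  notes_post: [3, 90]
  notes_pre: [-90, -3]
  mortality_days: 90
fever_threshold_c: 38.0
min_consecutive_antibiotic_days: 3
keyword_rules: default
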