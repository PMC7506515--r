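# Default keyword ruleset for CIED infection surveillance.
# This file is configuration: replace it to change the shipped keyword lists.
# Each rule: ordered word groups (spelling variants per position), a maximum
# number of intervening tokens between consecutive matched words, a
# case-insensitive note-title substring filter, a day window relative to the
# index procedure (day 0), and a polarity.
rules:
  - id: post_pocket_infection
    words:
      - [pocket]
      - [infection, infected, abscess]
    max_gap_tokens: 1
    note_titles: [cardiology, infectious, "device clinic"]
    window_days: [3, 90]
    polarity: post_infection
  - id: post_device_infection
    words:
      - [cied, device, pacemaker, icd, generator, lead]
      - [infection, infected]
    max_gap_tokens: 1
    note_titles: [cardiology, infectious, "device clinic"]
    window_days: [3, 90]
    polarity: post_infection
  - id: post_endocarditis
    words:
      - [endocarditis]
    max_gap_tokens: 1
    note_titles: [cardiology, infectious, "device clinic"]
    window_days: [3, 90]
    polarity: post_infection
  - id: pre_pocket_infection
    words:
      - [pocket]
      - [infection, infected, abscess]
    max_gap_tokens: 1
    note_titles: [cardiology, infectious, "device clinic"]
    window_days: [-90, -3]
    polarity: pre_history
  - id: pre_device_infection
    words:
      - [cied, device, pacemaker, icd, generator, lead]
      - [infection, infected]
    max_gap_tokens: 1
    note_titles: [cardiology, infectious, "device clinic"]
    window_days: [-90, -3]
    polarity: pre_history
  - id: pre_endocarditis
    words:
      - [endocarditis]
    max_gap_tokens: 1
    note_titles: [cardiology, infectious, "device clinic"]
    window_days: [-90, -3]
    polarity: pre_history
  - id: s_aureus
    words:
      - [staphylococcus, staph]
      - [aureus]
    max_gap_tokens: 1
    note_titles: [any]
    window_days: [0, 90]
    polarity: organism
  - id: s_aureus_mrsa
    words:
      - [mrsa, mssa]
    max_gap_tokens: 0
    note_titles: [any]
    window_days: [0, 90]
    polarity: organism
  - id: cons_full
    words:
      - [coagulase, coag]
      - [negative, neg]
      - [staphylococcus, staphylococci, staphylococcal, staph]
    max_gap_tokens: 1
    note_titles: [any]
    window_days: [0, 90]
    polarity: organism
  - id: cons_epidermidis
    words:
      - [staphylococcus, staph]
      - [epidermidis, hominis, capitis, haemolyticus]
    max_gap_tokens: 1
    note_titles: [any]
    window_days: [0, 90]
    polarity: organism
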