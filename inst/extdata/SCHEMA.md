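# Cohort file schemas

All tabular streams are CSV (header row, UTF-8, ISO-8601 dates, logicals as
`TRUE`/`FALSE`); clinical notes are JSONL (one JSON object per line) because
free text contains delimiters and newlines. `read_cohort()` enforces these
columns and rejects files that do not conform. `write_cohort()` emits fixed
column order and rows sorted by primary id, so output is byte-stable.

## patients.csv
| column | type | notes |
|---|---|---|
| patient_id | string | unique |
| age | integer | years, >= 0 |
| sex | string | `male` / `female` / `unknown` |
| race | string | categorical; `unknown` allowed |
| ethnicity | string | categorical |
| congestive_heart_failure .. renal_failure | logical | the eight comorbidity flags, see `comorbidity_names()` |
| death_date | date | blank when alive |

## procedures.csv
`procedure_id` (unique), `patient_id` (must resolve), `procedure_date`
(day-0 anchor), `facility_id`, `emergent` (logical).

## diagnoses.csv
`patient_id`, `code` (ICD-10-CM, normalized uppercase), `event_date`.

## pharmacy.csv
`patient_id`, `drug_name`, `fill_date`, `days_supplied` (integer >= 1).

## micro.csv
`patient_id`, `order_date`, `specimen_class` (`blood` / `cardiac` /
`miscellaneous` / `other`), `culture_positive` (logical),
`susceptibility_tested` (logical), `result_text` (free text, may be empty).

## vitals.csv
`patient_id`, `measure` (`temperature_c`), `value` (degC, physiologic range
30-45 enforced; out-of-range rows are dropped at read time with a
line-numbered warning), `measured_at`.

## notes.jsonl
One object per line with keys `note_id` (unique), `patient_id`,
`note_title`, `note_date`, `text` (free text; newlines preserved by JSON
escaping).
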