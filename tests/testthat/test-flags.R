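cfg <- flag_config()

test_that("mortality flag uses the half-open [0, 90) day window", {
  expect_true(flag_mortality(day0, day0 + 89))
  expect_false(flag_mortality(day0, day0 + 90))
  expect_true(flag_mortality(day0, day0))
  expect_false(flag_mortality(day0, as.Date(NA)))
  expect_warning(out <- flag_mortality(day0, day0 - 5), "precedes")
  expect_false(out)
})

test_that("fever flag thresholds at 38.0 degC inside days 0-30", {
  vit <- function(value, day) {
    data.frame(measure = "temperature_c", value = value,
               measured_at = day0 + day)
  }
  expect_true(flag_fever(day0, vit(38.0, 10)))
  expect_false(flag_fever(day0, vit(37.9, 10)))
  expect_false(flag_fever(day0, vit(39.0, 31)))
  expect_true(flag_fever(day0, vit(38.5, 30)))
  expect_false(flag_fever(day0, NULL))
})

test_that("antibiotic classification honors the fill window, duration and config", {
  rx <- function(drug, day, supply) {
    data.frame(drug_name = drug, fill_date = day0 + day,
               days_supplied = supply)
  }
  expect_identical(flag_antibiotics(day0, rx("cephalexin", 10, 7), cfg),
                   "staph_directed")
  expect_identical(flag_antibiotics(day0, rx("azithromycin", 20, 5), cfg),
                   "non_staph")
  # fill before day 6 is outside the window even with a long supply
  expect_identical(flag_antibiotics(day0, rx("cephalexin", 3, 10), cfg),
                   "none")
  # sub-3-day course does not qualify
  expect_identical(flag_antibiotics(day0, rx("cephalexin", 10, 2), cfg),
                   "none")
  # overlapping/adjacent fills of the same drug merge into one covered run
  two <- rbind(rx("cephalexin", 10, 2), rx("cephalexin", 12, 2))
  expect_identical(flag_antibiotics(day0, two, cfg), "staph_directed")
  # a covered-day gap does not merge
  gap <- rbind(rx("cephalexin", 10, 1), rx("cephalexin", 20, 1))
  expect_identical(flag_antibiotics(day0, gap, cfg), "none")
  # staph-directed wins over non-staph when both qualify
  both <- rbind(rx("cephalexin", 10, 7), rx("azithromycin", 20, 5))
  expect_identical(flag_antibiotics(day0, both, cfg), "staph_directed")
  # unknown drugs are non-antibiotics, logged once
  expect_message(out <- flag_antibiotics(day0, rx("lisinopril", 10, 30), cfg,
                                         quiet = FALSE),
                 "lisinopril")
  expect_identical(out, "none")
})

test_that("ICD flags are prefix-matched on normalized codes in days 0-90", {
  dx <- function(code, day) {
    data.frame(code = code, event_date = day0 + day)
  }
  expect_true(flag_icd(day0, dx("T82.7XXA", 30), cfg)[["icd_cied_infection"]])
  # dotless coding matches the same prefix
  expect_true(flag_icd(day0, dx("T827XXA", 30), cfg)[["icd_cied_infection"]])
  # wound dehiscence counts toward the SSI flag
  f <- flag_icd(day0, dx("T81.31XA", 15), cfg)
  expect_true(f[["icd_ssi"]])
  expect_false(f[["icd_cied_infection"]])
  expect_true(flag_icd(day0, dx("R78.81", 5),
                       cfg)[["icd_unspecified_infection"]])
  # outside the window
  expect_false(flag_icd(day0, dx("T82.7XXA", 91),
                        cfg)[["icd_cied_infection"]])
  expect_false(flag_icd(day0, dx("T82.7XXA", -1),
                        cfg)[["icd_cied_infection"]])
  expect_false(any(flag_icd(day0, NULL, cfg)))
})

test_that("micro flags require positive susceptibility-tested cultures and track organisms", {
  mrec <- function(class, pos, susc, text = "", day = 40) {
    data.frame(order_date = day0 + day, specimen_class = class,
               culture_positive = pos, susceptibility_tested = susc,
               result_text = text)
  }
  f <- flag_micro(day0, mrec("cardiac", TRUE, TRUE), cfg)
  expect_true(f[["micro_cardiac_pos"]])
  expect_true(f[["micro_order_no_staph"]])
  # positive without susceptibility testing does not count
  expect_false(flag_micro(day0, mrec("blood", TRUE, FALSE),
                          cfg)[["micro_blood_pos"]])
  # a negative blood order with empty text: order-without-staph only
  f <- flag_micro(day0, mrec("blood", FALSE, FALSE), cfg)
  expect_false(any(f[c("micro_blood_pos", "micro_cardiac_pos",
                       "micro_misc_pos", "micro_s_aureus", "micro_cons")]))
  expect_true(f[["micro_order_no_staph"]])
  # no orders at all: everything false, including order-without-staph
  expect_false(any(flag_micro(day0, NULL, cfg)))
  # organism text sets the organism flag and clears order-without-staph
  f <- flag_micro(day0, mrec("blood", TRUE, TRUE,
                             "STAPHYLOCOCCUS AUREUS isolated"), cfg)
  expect_true(f[["micro_s_aureus"]])
  expect_false(f[["micro_order_no_staph"]])
})

test_that("note flags respect the pre/post windows", {
  note <- function(text, day, title = "CARDIOLOGY OUTPATIENT NOTE") {
    data.frame(note_id = "N1", note_title = title, note_date = day0 + day,
               text = text, stringsAsFactors = FALSE)
  }
  rs <- default_ruleset()
  f <- flag_notes(day0, note("pocket infection", 20), rs)
  expect_identical(f, c(note_infection_post = TRUE,
                        note_infection_pre = FALSE))
  f <- flag_notes(day0, note("cied infection", -30), rs)
  expect_identical(f, c(note_infection_post = FALSE,
                        note_infection_pre = TRUE))
  # day 1 falls in neither window
  expect_false(any(flag_notes(day0, note("pocket infection", 1), rs)))
  # patient-instruction titles are filtered out
  expect_false(any(flag_notes(day0, note("device infection", 20,
                                         "PATIENT INSTRUCTIONS"), rs)))
})

test_that("build_flag_vectors is pure, windowed and mutually exclusive", {
  cohort <- tiny_cohort()
  flags <- build_flag_vectors(cohort, cfg)
  expect_identical(nrow(flags), 5L)
  expect_identical(flags$procedure_id, sprintf("E%02d", 1:5))
  # passthroughs
  expect_identical(flags$emergent, cohort$procedures$emergent)
  expect_identical(flags$congestive_heart_failure,
                   c(TRUE, FALSE, TRUE, FALSE, FALSE))
  # patient P01: code, staph antibiotic, fever, s. aureus blood, post note
  expect_true(flags$icd_cied_infection[1])
  expect_identical(flags$antibiotic_class[1], "staph_directed")
  expect_true(flags$fever_30d[1])
  expect_true(flags$micro_s_aureus[1])
  expect_true(flags$note_infection_post[1])
  # P04's only note predates its procedure by ~7 weeks: history flag
  expect_true(flags$note_infection_pre[4])
  expect_false(flags$note_infection_post[4])
  # determinism
  expect_identical(build_flag_vectors(cohort, cfg), flags)
  # antibiotic_class is single-valued; organism flags exclude no-staph flag
  expect_true(all(flags$antibiotic_class %in%
                    c("none", "staph_directed", "non_staph")))
  expect_false(any(flags$micro_order_no_staph &
                     (flags$micro_s_aureus | flags$micro_cons)))
  # shifting every event by +200 days zeroes every time-windowed flag
  shifted <- cohort
  for (stream in c("diagnoses", "pharmacy", "micro", "vitals", "notes")) {
    datecol <- switch(stream, diagnoses = "event_date",
                      pharmacy = "fill_date", micro = "order_date",
                      vitals = "measured_at", notes = "note_date")
    shifted[[stream]][[datecol]] <- shifted[[stream]][[datecol]] + 200
  }
  shifted$patients$death_date <- shifted$patients$death_date + 200
  sflags <- build_flag_vectors(shifted, cfg)
  windowed <- c("died_90d", "icd_cied_infection", "icd_ssi",
                "icd_unspecified_infection", "fever_30d", "micro_blood_pos",
                "micro_cardiac_pos", "micro_misc_pos", "micro_s_aureus",
                "micro_cons", "micro_order_no_staph", "note_infection_post",
                "note_infection_pre")
  expect_false(any(unlist(sflags[windowed])))
  expect_true(all(sflags$antibiotic_class == "none"))
})

test_that("a cohort with no events yields only passthrough flags", {
  cohort <- one_proc_cohort(emergent = TRUE)
  flags <- build_flag_vectors(cohort, cfg)
  expect_true(flags$emergent)
  expect_identical(flags$antibiotic_class, "none")
  bools <- setdiff(names(flags)[vapply(flags, is.logical, TRUE)], "emergent")
  expect_false(any(unlist(flags[bools])))
})
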