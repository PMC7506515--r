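#' Load the flag-extraction configuration
#'
#' Reads the YAML configuration controlling flag extraction: ICD-10-CM code
#' prefix lists (CIED infection, SSI/wound-dehiscence, unspecified
#' infection), the Staphylococcus-directed vs other antibiotic lists, all
#' day windows, the fever threshold (38.0 degC) and the minimum consecutive
#' covered antibiotic days (3). With no argument the packaged default
#' configuration is returned.
#'
#' All windows are inclusive day-offset intervals relative to the procedure
#' day, except mortality, which is death strictly before day 90
#' (`[0, 90)`).
#'
#' @param path Optional path to a YAML file with the same structure as the
#'   packaged `extdata/config.yaml`.
#' @return Named list of configuration sections, with the compiled keyword
#'   ruleset attached as `$ruleset`.
#' @export
flag_config <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "config.yaml", package = "ciedtriage",
                        mustWork = TRUE)
  }
  cfg <- yaml::read_yaml(path)
  needed <- c("icd_codes", "antibiotics", "windows")
  missing <- setdiff(needed, names(cfg))
  if (length(missing)) {
    stop("flag config missing section(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  cfg$fever_threshold_c <- cfg$fever_threshold_c %||% 38.0
  cfg$min_consecutive_antibiotic_days <-
    cfg$min_consecutive_antibiotic_days %||% 3L
  if (is.null(cfg$keyword_rules) || identical(cfg$keyword_rules, "default")) {
    cfg$ruleset <- default_ruleset()
  } else {
    rule_path <- cfg$keyword_rules
    if (!file.exists(rule_path)) {
      rule_path <- file.path(dirname(path), cfg$keyword_rules)
    }
    cfg$ruleset <- compile_ruleset(rule_path)
  }
  cfg
}

#' 90-day mortality flag
#'
#' `TRUE` iff the patient has a death date with `0 <= death - procedure < 90`
#' days. A recorded death before the procedure date is treated as a data
#' quality problem: a warning is emitted and the flag is `FALSE`.
#'
#' @param procedure_date Procedure anchor date.
#' @param death_date Death date or `NA`.
#' @param window_days Upper bound (exclusive), default 90.
#' @return Logical scalar.
#' @export
flag_mortality <- function(procedure_date, death_date, window_days = 90L) {
  if (is.na(death_date)) return(FALSE)
  off <- day_offset(death_date, procedure_date)
  if (off < 0L) {
    warning("death_date precedes procedure_date; mortality flag set FALSE",
            call. = FALSE)
    return(FALSE)
  }
  off < window_days
}

#' Postprocedure fever flag
#'
#' `TRUE` iff any temperature at or above the threshold (default 38.0 degC)
#' is recorded with day offset in the fever window (default `[0, 30]`).
#'
#' @param procedure_date Anchor date.
#' @param vitals Data frame with `measure`, `value`, `measured_at` rows for
#'   this patient.
#' @param threshold_c Temperature threshold in degC.
#' @param window Inclusive day-offset interval.
#' @return Logical scalar.
#' @export
flag_fever <- function(procedure_date, vitals, threshold_c = 38.0,
                       window = c(0L, 30L)) {
  if (is.null(vitals) || nrow(vitals) == 0L) return(FALSE)
  temps <- vitals[vitals$measure == "temperature_c", , drop = FALSE]
  if (!nrow(temps)) return(FALSE)
  off <- day_offset(temps$measured_at, procedure_date)
  any(off >= window[1] & off <= window[2] & temps$value >= threshold_c)
}

# merge per-drug covered-day intervals [fill, fill + supply - 1] and return
# the longest run of consecutive covered days
longest_covered_run <- function(start_day, n_days) {
  covered <- sort(unique(unlist(Map(function(s, n) s + seq_len(n) - 1L,
                                    start_day, n_days))))
  if (!length(covered)) return(0L)
  runs <- split(covered, cumsum(c(1L, diff(covered) != 1L)))
  max(lengths(runs))
}

#' Antibiotic course flag
#'
#' Classifies the procedure's postprocedure antibiotic exposure into one of
#' `none`, `staph_directed`, `non_staph` (mutually exclusive). A qualifying
#' course is one or more fills of the same antibiotic whose merged
#' covered-day intervals (`fill_date` through `fill_date + days_supplied -
#' 1`) give at least `min_days` (default 3) consecutive covered days, with
#' every contributing fill date inside the fill window (default `[6, 90]`
#' days postprocedure — the first postprocedure week is excluded so routine
#' periprocedural prophylaxis does not flag). Returns `staph_directed` if
#' any qualifying course uses a Staphylococcus-directed agent, else
#' `non_staph` if any qualifying antibiotic course exists, else `none`.
#' Drug names absent from the configuration are treated as non-antibiotics
#' (logged once per call via `message`).
#'
#' @param procedure_date Anchor date.
#' @param pharmacy Data frame with `drug_name`, `fill_date`, `days_supplied`.
#' @param config A [flag_config()] list (uses `$antibiotics`, `$windows`,
#'   `$min_consecutive_antibiotic_days`).
#' @param quiet Suppress the unknown-drug message.
#' @return One of `"none"`, `"staph_directed"`, `"non_staph"`.
#' @export
flag_antibiotics <- function(procedure_date, pharmacy, config = flag_config(),
                             quiet = FALSE) {
  if (is.null(pharmacy) || nrow(pharmacy) == 0L) return("none")
  staph <- tolower(config$antibiotics$staph_directed)
  other <- tolower(config$antibiotics$other)
  window <- config$windows$antibiotics %||% c(6L, 90L)
  min_days <- config$min_consecutive_antibiotic_days
  drug <- tolower(pharmacy$drug_name)
  is_abx <- drug %in% c(staph, other)
  if (!quiet && any(!is_abx)) {
    unknown <- unique(drug[!is_abx])
    message("flag_antibiotics: treating as non-antibiotic (absent from config): ",
            paste(utils::head(unknown, 8L), collapse = ", "))
  }
  off <- day_offset(pharmacy$fill_date, procedure_date)
  keep <- is_abx & off >= window[1] & off <= window[2]
  if (!any(keep)) return("none")
  ph <- pharmacy[keep, , drop = FALSE]
  ph$off <- off[keep]
  ph$drug <- drug[keep]
  qualifying <- vapply(split(ph, ph$drug), function(d) {
    longest_covered_run(d$off, d$days_supplied) >= min_days
  }, logical(1))
  qdrugs <- names(qualifying)[qualifying]
  if (!length(qdrugs)) return("none")
  if (any(qdrugs %in% staph)) "staph_directed" else "non_staph"
}

#' ICD-10-CM diagnosis flags
#'
#' One flag per configured code list (CIED infection, SSI including wound
#' dehiscence, unspecified infection): `TRUE` iff at least one diagnosis
#' event with day offset in the ICD window (default `[0, 90]`) matches a
#' configured prefix. Matching is prefix-based on normalized codes with
#' dots removed on both sides, so the prefix `T82.7` matches `T82.7XXA` and
#' `T827XXA` alike.
#'
#' @param procedure_date Anchor date.
#' @param diagnoses Data frame with `code`, `event_date`.
#' @param config A [flag_config()] list.
#' @return Named logical vector `c(icd_cied_infection=, icd_ssi=,
#'   icd_unspecified_infection=)`.
#' @export
flag_icd <- function(procedure_date, diagnoses, config = flag_config()) {
  out <- c(icd_cied_infection = FALSE, icd_ssi = FALSE,
           icd_unspecified_infection = FALSE)
  if (is.null(diagnoses) || nrow(diagnoses) == 0L) return(out)
  window <- config$windows$icd %||% c(0L, 90L)
  off <- day_offset(diagnoses$event_date, procedure_date)
  codes <- gsub(".", "", toupper(trimws(diagnoses$code)), fixed = TRUE)
  codes <- codes[off >= window[1] & off <= window[2]]
  if (!length(codes)) return(out)
  hits <- function(prefixes) {
    prefixes <- gsub(".", "", toupper(prefixes), fixed = TRUE)
    any(vapply(prefixes, function(p) any(startsWith(codes, p)), logical(1)))
  }
  out["icd_cied_infection"] <- hits(config$icd_codes$cied)
  out["icd_ssi"] <- hits(config$icd_codes$ssi)
  out["icd_unspecified_infection"] <- hits(config$icd_codes$unspecified)
  out
}

#' Microbiology flags
#'
#' Specimen-class flags (`micro_blood_pos`, `micro_cardiac_pos`,
#' `micro_misc_pos`) are `TRUE` iff a record of that class inside the micro
#' window (default `[0, 90]`) has a positive culture **and** antibiotic
#' susceptibility testing performed. Organism flags (`micro_s_aureus`,
#' `micro_cons`) come from [scan_result_text()] over in-window result text.
#' `micro_order_no_staph` is `TRUE` iff at least one in-window order exists
#' and neither organism flag fired — so with no orders at all every micro
#' flag, including `micro_order_no_staph`, is `FALSE`.
#'
#' @param procedure_date Anchor date.
#' @param micro Data frame with the micro stream columns.
#' @param config A [flag_config()] list (organism rules come from its
#'   `$ruleset`).
#' @return Named logical vector of the six micro flags.
#' @export
flag_micro <- function(procedure_date, micro, config = flag_config()) {
  out <- c(micro_blood_pos = FALSE, micro_cardiac_pos = FALSE,
           micro_misc_pos = FALSE, micro_s_aureus = FALSE, micro_cons = FALSE,
           micro_order_no_staph = FALSE)
  if (is.null(micro) || nrow(micro) == 0L) return(out)
  window <- config$windows$micro %||% c(0L, 90L)
  off <- day_offset(micro$order_date, procedure_date)
  m <- micro[off >= window[1] & off <= window[2], , drop = FALSE]
  if (!nrow(m)) return(out)
  pos <- m$culture_positive & m$susceptibility_tested
  out["micro_blood_pos"] <- any(pos & m$specimen_class == "blood")
  out["micro_cardiac_pos"] <- any(pos & m$specimen_class == "cardiac")
  out["micro_misc_pos"] <- any(pos & m$specimen_class == "miscellaneous")
  organism_rules <- config$ruleset[vapply(config$ruleset,
                                          function(r) r$polarity == "organism",
                                          TRUE)]
  for (txt in m$result_text[nzchar(m$result_text)]) {
    org <- scan_result_text(txt, organism_rules)
    out["micro_s_aureus"] <- out["micro_s_aureus"] || org["s_aureus"]
    out["micro_cons"] <- out["micro_cons"] || org["coag_neg_staph"]
    if (out["micro_s_aureus"] && out["micro_cons"]) break
  }
  out["micro_order_no_staph"] <- !out["micro_s_aureus"] && !out["micro_cons"]
  out
}

#' Clinical-note keyword flags
#'
#' `note_infection_post` is `TRUE` iff any `post_infection` rule matches any
#' of the patient's notes dated 3-90 days after the procedure;
#' `note_infection_pre` iff any `pre_history` rule matches a note dated
#' 3-90 days *before* the procedure. Each rule enforces its own window and
#' note-title filter through [match_rule()].
#'
#' @param procedure_date Anchor date.
#' @param notes Data frame of the patient's notes.
#' @param ruleset A compiled `keyword_ruleset`.
#' @return Named logical vector `c(note_infection_post=,
#'   note_infection_pre=)`.
#' @export
flag_notes <- function(procedure_date, notes, ruleset = default_ruleset()) {
  out <- c(note_infection_post = FALSE, note_infection_pre = FALSE)
  if (is.null(notes) || nrow(notes) == 0L) return(out)
  polarity <- vapply(ruleset, `[[`, "", "polarity")
  for (target in c(post = "post_infection", pre = "pre_history")) {
    flag <- if (target == "post_infection") "note_infection_post" else
      "note_infection_pre"
    for (r in ruleset[polarity == target]) {
      if (out[flag]) break
      for (i in seq_len(nrow(notes))) {
        if (nrow(match_rule(notes[i, ], r, procedure_date))) {
          out[flag] <- TRUE
          break
        }
      }
    }
  }
  out
}

#' Build the per-procedure flag vectors
#'
#' Computes, for every index procedure in the cohort, the full covariate set
#' the triage model consumes: 90-day mortality, emergent indicator, the
#' eight comorbidity passthrough flags, the three ICD flags, 30-day fever,
#' the antibiotic course class, the six microbiology flags and the two
#' clinical-note keyword flags. A pure, deterministic function of
#' `(cohort, config)`.
#'
#' @param cohort An [emr_cohort()].
#' @param config A [flag_config()] list.
#' @param quiet Suppress per-call progress/unknown-drug messages.
#' @return A data frame of class `flag_table`, one row per procedure
#'   (ordered by `procedure_id`), with a `flag_prevalence` attribute holding
#'   the marginal rate of every flag across the cohort.
#' @export
build_flag_vectors <- function(cohort, config = flag_config(), quiet = TRUE) {
  stopifnot(inherits(cohort, "emr_cohort"))
  procs <- cohort$procedures
  pat <- cohort$patients
  pat_idx <- match(procs$patient_id, pat$patient_id)
  by_patient <- function(stream) {
    split(seq_len(nrow(stream)), stream$patient_id)
  }
  dx_idx <- by_patient(cohort$diagnoses)
  rx_idx <- by_patient(cohort$pharmacy)
  mi_idx <- by_patient(cohort$micro)
  vi_idx <- by_patient(cohort$vitals)
  no_idx <- by_patient(cohort$notes)
  # cheap prefilter: notes whose token set cannot contain any first-group
  # variant of any note rule never need the full matcher
  note_rules <- config$ruleset[vapply(config$ruleset, function(r)
    r$polarity %in% c("post_infection", "pre_history"), TRUE)]
  any_variant <- unique(tolower(unlist(lapply(note_rules,
                                              function(r) unlist(r$words)))))
  rows <- vector("list", nrow(procs))
  mort_window <- config$windows$mortality_days %||% 90L
  for (i in seq_len(nrow(procs))) {
    pid <- procs$patient_id[i]
    pdate <- procs$procedure_date[i]
    dx <- cohort$diagnoses[dx_idx[[pid]] %||% integer(0), , drop = FALSE]
    rx <- cohort$pharmacy[rx_idx[[pid]] %||% integer(0), , drop = FALSE]
    mi <- cohort$micro[mi_idx[[pid]] %||% integer(0), , drop = FALSE]
    vi <- cohort$vitals[vi_idx[[pid]] %||% integer(0), , drop = FALSE]
    no <- cohort$notes[no_idx[[pid]] %||% integer(0), , drop = FALSE]
    if (nrow(no)) {
      candidate <- vapply(no$text, function(t)
        any(tokenize(t) %in% any_variant), TRUE, USE.NAMES = FALSE)
      no <- no[candidate, , drop = FALSE]
    }
    icd <- flag_icd(pdate, dx, config)
    mic <- flag_micro(pdate, mi, config)
    nts <- flag_notes(pdate, no, config$ruleset)
    comorb <- as.list(pat[pat_idx[i], comorbidity_names(), drop = FALSE])
    rows[[i]] <- c(
      list(procedure_id = procs$procedure_id[i],
           died_90d = flag_mortality(pdate, pat$death_date[pat_idx[i]],
                                     mort_window),
           emergent = procs$emergent[i]),
      comorb,
      as.list(icd),
      list(fever_30d = flag_fever(pdate, vi, config$fever_threshold_c,
                                  config$windows$fever %||% c(0L, 30L)),
           antibiotic_class = flag_antibiotics(pdate, rx, config,
                                               quiet = quiet)),
      as.list(mic),
      as.list(nts)
    )
  }
  flags <- do.call(rbind, lapply(rows, function(r)
    as.data.frame(r, stringsAsFactors = FALSE)))
  rownames(flags) <- NULL
  class(flags) <- c("flag_table", "data.frame")
  attr(flags, "flag_prevalence") <- flag_prevalence(flags)
  flags
}

#' Marginal flag prevalence summary
#'
#' Rate of every flag across procedures (the antibiotic class reported as
#' one rate per level), in the style of a cohort characteristics table.
#'
#' @param flags A `flag_table` from [build_flag_vectors()].
#' @return Data frame with columns `flag`, `n`, `rate`.
#' @export
flag_prevalence <- function(flags) {
  n <- nrow(flags)
  logical_cols <- names(flags)[vapply(flags, is.logical, TRUE)]
  rows <- lapply(logical_cols, function(col) {
    data.frame(flag = col, n = sum(flags[[col]]),
               rate = if (n) mean(flags[[col]]) else NA_real_)
  })
  for (lev in c("staph_directed", "non_staph")) {
    k <- sum(flags$antibiotic_class == lev)
    rows[[length(rows) + 1L]] <- data.frame(
      flag = paste0("antibiotic_", lev), n = k,
      rate = if (n) k / n else NA_real_)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
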