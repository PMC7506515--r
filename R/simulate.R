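#' Simulation configuration for the synthetic EMR generator
#'
#' Defaults encode the statistical structure the surveillance algorithm
#' assumes in a national CIED cohort: a 0.8% 90-day procedure-related
#' infection prevalence, a further 0.7% of procedures performed on an
#' infection already present at the time of the procedure (revision cases),
#' infection onset approximately normal with mean 35 and SD 21 days
#' truncated to \[3, 90\], and per-flag signal emission probabilities
#' conditional on infection status anchored to observed marginal flag rates
#' (background) and flag rates among confirmed infections (conditional).
#' Copy-forward of historical infection text is planted: most background
#' postprocedure keyword mentions arise from copied preprocedure
#' documentation, which is what makes the preprocedure-history flag a
#' *conditionally* negative predictor even though its marginal rate among
#' true infections is higher than in the cohort.
#'
#' @param n_procedures Number of index procedures (>= 1).
#' @param seed Integer seed; fixes the full output byte-for-byte.
#' @param ... Named overrides of any default component (see the returned
#'   list).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_procedures = 10000L, seed = 1L, ...) {
  cfg <- list(
    n_procedures = as.integer(n_procedures),
    seed = as.integer(seed),
    infection_prevalence = 0.008,
    preexisting_rate = 0.007,
    onset_mean = 35, onset_sd = 21, onset_range = c(3L, 90L),
    type_probs = c(pocket = 0.831, endocarditis_or_lead = 0.149,
                   cellulitis_only = 0.019),
    # P(signal | true procedure-related infection)
    infected = list(
      died_90d = 0.149, icd_cied = 0.787, icd_ssi = 0.085, icd_unspec = 0.043,
      fever = 0.149, abx_staph = 0.638, abx_non_staph = 0.043,
      micro_blood_pos = 0.872, micro_cardiac_pos = 0.447,
      micro_misc_pos = 0.021, micro_s_aureus = 0.149, micro_cons = 0.085,
      micro_neg_order = 0.6, note_post = 0.957, history_doc = 0.213,
      physician_documented = 0.85
    ),
    # background rates among procedures with no device infection
    background = list(
      died_90d = 0.027, late_death = 0.02, icd_cied = 0.0377,
      icd_ssi = 0.0055, icd_unspec = 0.0135, fever = 0.0271,
      abx_staph = 0.1636, abx_non_staph = 0.0321,
      micro_blood_pos = 0.0943, micro_cardiac_pos = 0.0167,
      micro_misc_pos = 0.0961, micro_s_aureus = 0.0058, micro_cons = 0.0045,
      micro_neg_order = 0.02, history_doc = 0.037, note_post_only = 0.045,
      abx_noise = 0.05, prophylaxis = 0.30, nondrug_fill = 0.5,
      instruction_note = 0.10, abstraction_symptoms = 0.05,
      abstraction_abx = 0.08, stitch_abscess = 0.003,
      cellulitis_other_site = 0.003
    ),
    # preexisting (present-at-procedure) infection cases: revision
    # procedures with heavy historical documentation and residual treatment
    preexisting = list(
      pre_note = 0.95, icd_cied = 0.35, abx_staph = 0.45,
      micro_cardiac_pos = 0.20, micro_blood_pos = 0.15, fever = 0.10,
      micro_neg_order = 0.5
    ),
    copy_forward = 0.9,
    comorbidity_prev = c(
      congestive_heart_failure = 0.507, solid_tumor_without_metastasis = 0.082,
      coagulopathy = 0.057, diabetes_uncomplicated = 0.403,
      diabetes_complicated = 0.277, obesity = 0.207,
      pulmonary_circulation_disease = 0.043, renal_failure = 0.256
    ),
    emergent_rate = 0.124,
    age_mean = 72, age_sd = 10.6,
    male_rate = 0.977,
    race_probs = c(white = 0.785, black = 0.155, other = 0.03,
                   unknown = 0.03),
    hispanic_rate = 0.054,
    start_date = as.Date("2016-10-01"), accrual_days = 365L,
    n_facilities = 67L,
    signal_titles = c("CARDIOLOGY OUTPATIENT NOTE",
                      "CARDIOLOGY ATTENDING NOTE",
                      "INFECTIOUS DISEASE CONSULT"),
    filler_titles = c("PRIMARY CARE NOTE", "NURSING NOTE",
                      "TELEPHONE ENCOUNTER", "PHARMACY NOTE"),
    instruction_title = "PATIENT INSTRUCTIONS - DEVICE CARE",
    keyword_phrases = list(c("pocket", "infection"), c("cied", "infection"),
                           c("device", "infection"),
                           c("pacemaker", "infection"), c("endocarditis"),
                           c("pocket", "abscess")),
    filler_vocab = c(
      "patient", "seen", "today", "clinic", "followup", "reports", "denies",
      "chest", "pain", "shortness", "breath", "wound", "site", "healing",
      "well", "continue", "current", "medications", "plan", "return",
      "weeks", "stable", "incision", "clean", "dry", "intact", "vitals",
      "reviewed", "discussed", "history", "presents", "exam", "unremarkable",
      "cardiac", "rhythm", "rate", "controlled", "no", "acute", "distress")
  )
  dots <- list(...)
  for (nm in names(dots)) {
    if (is.list(cfg[[nm]]) && is.list(dots[[nm]])) {
      cfg[[nm]][names(dots[[nm]])] <- dots[[nm]]
    } else {
      cfg[[nm]] <- dots[[nm]]
    }
  }
  stopifnot(cfg$n_procedures >= 1L,
            cfg$infection_prevalence >= 0, cfg$infection_prevalence <= 1,
            cfg$preexisting_rate >= 0, cfg$preexisting_rate <= 1)
  class(cfg) <- "sim_config"
  cfg
}

rtrunc_norm_int <- function(n, mean, sd, range) {
  out <- integer(0)
  while (length(out) < n) {
    draw <- round(stats::rnorm(n - length(out), mean, sd))
    out <- c(out, draw[draw >= range[1] & draw <= range[2]])
  }
  as.integer(out)
}

sim_note_text <- function(phrase, vocab, n_tokens, gapped) {
  filler <- sample(vocab, n_tokens, replace = TRUE)
  if (is.null(phrase)) return(paste(filler, collapse = " "))
  if (gapped && length(phrase) > 1L) {
    phrase <- c(phrase[1], sample(vocab, 1L), phrase[-1])
  }
  pos <- sample.int(n_tokens + 1L, 1L) - 1L
  paste(c(filler[seq_len(pos)], phrase,
          filler[seq_len(n_tokens - pos) + pos]), collapse = " ")
}

#' Simulate a synthetic EMR cohort with planted infections
#'
#' Draws, for every index procedure, an infection status (procedure-related
#' infection, infection present at the procedure, or neither), then emits
#' the documentation signals each status probabilistically generates across
#' all seven EMR streams: keyword phrases embedded in generated note text
#' (sometimes with one intervening token, exercising the gap-matching
#' semantics), ICD-10-CM codes, qualifying antibiotic courses, positive
#' cultures with organism result text, fever, and death dates — plus
#' realistic noise (unrelated medications, periprocedural prophylaxis,
#' sub-3-day courses, normal temperatures, filler notes,
#' keyword-containing patient-instruction notes that the note-title filter
#' must exclude, and copy-forward of historical infection text into
#' postprocedure notes).
#'
#' All randomness flows from `config$seed`; identical configs produce
#' byte-identical cohort files through [write_cohort()].
#'
#' @param config A [sim_config()].
#' @return List of class `sim_result`: `cohort` (an [emr_cohort()]),
#'   `truth` (ground-truth review labels: `procedure_id`, `reviewed`,
#'   `infection`, `infection_type`, `present_on_admission`, `onset_day`)
#'   and `abstractions` (chart-abstraction records consistent with the
#'   truth under [adjudicate()]).
#' @export
simulate_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, simulate_cohort_impl(config))
}

simulate_cohort_impl <- function(cfg) {
  n <- cfg$n_procedures
  pid <- sprintf("P%06d", seq_len(n))
  eid <- sprintf("E%06d", seq_len(n))
  pdate <- cfg$start_date + sample.int(cfg$accrual_days, n, replace = TRUE) - 1L

  status <- sample(c("infected", "preexisting", "background"), n,
                   replace = TRUE,
                   prob = c(cfg$infection_prevalence, cfg$preexisting_rate,
                            1 - cfg$infection_prevalence -
                              cfg$preexisting_rate))
  inf <- status == "infected"
  pre <- status == "preexisting"
  bg <- status == "background"

  onset <- rep(NA_integer_, n)
  onset[inf] <- rtrunc_norm_int(sum(inf), cfg$onset_mean, cfg$onset_sd,
                                cfg$onset_range)
  type <- rep("none", n)
  if (any(inf)) {
    type[inf] <- sample(names(cfg$type_probs), sum(inf), replace = TRUE,
                        prob = cfg$type_probs / sum(cfg$type_probs))
  }

  # ---- patients -----------------------------------------------------------
  patients <- data.frame(
    patient_id = pid,
    age = pmin(100L, pmax(21L,
                          as.integer(round(stats::rnorm(n, cfg$age_mean,
                                                        cfg$age_sd))))),
    sex = ifelse(stats::runif(n) < cfg$male_rate, "male", "female"),
    race = sample(names(cfg$race_probs), n, replace = TRUE,
                  prob = cfg$race_probs),
    ethnicity = ifelse(stats::runif(n) < cfg$hispanic_rate, "hispanic",
                       "non-hispanic"),
    stringsAsFactors = FALSE
  )
  for (cm in comorbidity_names()) {
    patients[[cm]] <- stats::runif(n) < cfg$comorbidity_prev[[cm]]
  }
  p_inf <- cfg$infected
  p_bg <- cfg$background
  p_pre <- cfg$preexisting
  died <- logical(n)
  died[inf] <- stats::runif(sum(inf)) < p_inf$died_90d
  died[!inf] <- stats::runif(sum(!inf)) < p_bg$died_90d
  death_day <- rep(NA_integer_, n)
  death_day[died & inf] <- vapply(which(died & inf), function(i) {
    lo <- min(onset[i], 89L)
    lo + sample.int(90L - lo, 1L) - 1L
  }, 1L)
  if (any(died & !inf)) {
    death_day[died & !inf] <- sample.int(90L, sum(died & !inf),
                                         replace = TRUE) - 1L
  }
  late <- !died & stats::runif(n) < p_bg$late_death
  death_day[late] <- 90L + sample.int(275L, sum(late), replace = TRUE)
  patients$death_date <- pdate + death_day

  procedures <- data.frame(
    patient_id = pid, procedure_id = eid, procedure_date = pdate,
    facility_id = sprintf("F%03d", sample.int(cfg$n_facilities, n,
                                              replace = TRUE)),
    emergent = stats::runif(n) < cfg$emergent_rate,
    stringsAsFactors = FALSE
  )

  # helper accumulators ------------------------------------------------------
  dx_rows <- list(); rx_rows <- list(); mi_rows <- list(); vt_rows <- list()
  nt_rows <- list()
  add <- function(store, df) c(store, list(df))

  draw_for <- function(mask, p) mask & stats::runif(n) < p
  sig_day <- function(i, lo = 0L, hi = 90L) {
    # day near onset for infected cases, uniform in window otherwise
    base <- ifelse(inf[i], pmin(hi, pmax(lo, onset[i])),
                   lo + sample.int(hi - lo + 1L, length(i),
                                   replace = TRUE) - 1L)
    as.integer(base)
  }

  # ---- diagnoses ----------------------------------------------------------
  cied_codes <- c("T82.7XXA", "T82.6XXA")
  ssi_codes <- c("T81.31XA", "T81.4XXA")
  unspec_codes <- c("A49.9", "R78.81")
  emit_dx <- function(mask, codes) {
    idx <- which(mask)
    if (!length(idx)) return()
    dx_rows <<- add(dx_rows, data.frame(
      patient_id = pid[idx],
      code = sample(codes, length(idx), replace = TRUE),
      event_date = pdate[idx] + sig_day(idx),
      stringsAsFactors = FALSE))
  }
  emit_dx(draw_for(inf, p_inf$icd_cied) | draw_for(bg, p_bg$icd_cied) |
            draw_for(pre, p_pre$icd_cied), cied_codes)
  emit_dx(draw_for(inf, p_inf$icd_ssi) | draw_for(bg, p_bg$icd_ssi),
          ssi_codes)
  emit_dx(draw_for(inf, p_inf$icd_unspec) | draw_for(bg, p_bg$icd_unspec),
          unspec_codes)

  # ---- vitals -------------------------------------------------------------
  fever <- draw_for(inf, p_inf$fever) | draw_for(bg, p_bg$fever) |
    draw_for(pre, p_pre$fever)
  fev_idx <- which(fever)
  if (length(fev_idx)) {
    day <- ifelse(inf[fev_idx], pmin(onset[fev_idx], 30L),
                  sample.int(31L, length(fev_idx), replace = TRUE) - 1L)
    vt_rows <- add(vt_rows, data.frame(
      patient_id = pid[fev_idx], measure = "temperature_c",
      value = round(stats::runif(length(fev_idx), 38.0, 39.6), 1),
      measured_at = pdate[fev_idx] + as.integer(day),
      stringsAsFactors = FALSE))
  }
  n_norm <- sample.int(3L, n, replace = TRUE)
  norm_pid <- rep(pid, n_norm)
  norm_anchor <- rep(pdate, n_norm)
  vt_rows <- add(vt_rows, data.frame(
    patient_id = norm_pid, measure = "temperature_c",
    value = round(stats::runif(length(norm_pid), 36.0, 37.5), 1),
    measured_at = norm_anchor + sample.int(61L, length(norm_pid),
                                           replace = TRUE) - 1L,
    stringsAsFactors = FALSE))

  # ---- pharmacy -----------------------------------------------------------
  staph_drugs <- c("cephalexin", "cefazolin", "vancomycin", "doxycycline",
                   "trimethoprim-sulfamethoxazole", "clindamycin")
  other_abx <- c("azithromycin", "ciprofloxacin", "levofloxacin",
                 "amoxicillin")
  nondrugs <- c("lisinopril", "metformin", "atorvastatin", "metoprolol",
                "warfarin")
  emit_rx <- function(mask, drugs, supply_lo = 7L, supply_hi = 14L) {
    idx <- which(mask)
    if (!length(idx)) return()
    day <- ifelse(inf[idx], pmin(90L, pmax(6L, onset[idx])),
                  5L + sample.int(85L, length(idx), replace = TRUE))
    rx_rows <<- add(rx_rows, data.frame(
      patient_id = pid[idx],
      drug_name = sample(drugs, length(idx), replace = TRUE),
      fill_date = pdate[idx] + as.integer(day),
      days_supplied = supply_lo - 1L +
        sample.int(supply_hi - supply_lo + 1L, length(idx), replace = TRUE),
      stringsAsFactors = FALSE))
  }
  abx_u <- stats::runif(n)
  abx_class <- rep("none", n)
  abx_class[inf] <- ifelse(abx_u[inf] < p_inf$abx_staph, "staph",
                           ifelse(abx_u[inf] < p_inf$abx_staph +
                                    p_inf$abx_non_staph, "non", "none"))
  abx_class[bg] <- ifelse(abx_u[bg] < p_bg$abx_staph, "staph",
                          ifelse(abx_u[bg] < p_bg$abx_staph +
                                   p_bg$abx_non_staph, "non", "none"))
  abx_class[pre] <- ifelse(abx_u[pre] < p_pre$abx_staph, "staph", "none")
  emit_rx(abx_class == "staph", staph_drugs)
  emit_rx(abx_class == "non", other_abx)
  # noise: periprocedural prophylaxis (fill before day 6), sub-3-day
  # courses inside the window, and non-antibiotic fills
  prophy <- which(stats::runif(n) < p_bg$prophylaxis)
  if (length(prophy)) {
    rx_rows <- add(rx_rows, data.frame(
      patient_id = pid[prophy], drug_name = "cefazolin",
      fill_date = pdate[prophy] + sample(0:1, length(prophy), replace = TRUE),
      days_supplied = sample(1:3, length(prophy), replace = TRUE),
      stringsAsFactors = FALSE))
  }
  shorties <- which(bg & stats::runif(n) < p_bg$abx_noise)
  if (length(shorties)) {
    rx_rows <- add(rx_rows, data.frame(
      patient_id = pid[shorties],
      drug_name = sample(staph_drugs, length(shorties), replace = TRUE),
      fill_date = pdate[shorties] + 5L +
        sample.int(85L, length(shorties), replace = TRUE),
      days_supplied = sample(1:2, length(shorties), replace = TRUE),
      stringsAsFactors = FALSE))
  }
  nd <- which(stats::runif(n) < p_bg$nondrug_fill)
  if (length(nd)) {
    rx_rows <- add(rx_rows, data.frame(
      patient_id = pid[nd],
      drug_name = sample(nondrugs, length(nd), replace = TRUE),
      fill_date = pdate[nd] + sample.int(90L, length(nd),
                                         replace = TRUE) - 1L,
      days_supplied = sample(c(30L, 90L), length(nd), replace = TRUE),
      stringsAsFactors = FALSE))
  }

  # ---- microbiology -------------------------------------------------------
  sa_text <- c("STAPHYLOCOCCUS AUREUS isolated from culture",
               "MRSA detected on screen")
  cons_text <- c("coagulase negative staphylococcus species isolated",
                 "coag neg staph isolated", "staphylococcus epidermidis")
  pos_text <- c("enterococcus faecalis isolated",
                "gram positive cocci in chains")
  neg_text <- c("no growth after 48 hours", "culture negative to date")
  emit_micro <- function(mask, class, positive, texts) {
    idx <- which(mask)
    if (!length(idx)) return()
    mi_rows <<- add(mi_rows, data.frame(
      patient_id = pid[idx], order_date = pdate[idx] + sig_day(idx),
      specimen_class = class, culture_positive = positive,
      susceptibility_tested = positive,
      result_text = sample(texts, length(idx), replace = TRUE),
      stringsAsFactors = FALSE))
  }
  sa <- draw_for(inf, p_inf$micro_s_aureus) |
    draw_for(bg, p_bg$micro_s_aureus)
  cons <- !sa & (draw_for(inf, p_inf$micro_cons) |
                   draw_for(bg, p_bg$micro_cons))
  blood <- draw_for(inf, p_inf$micro_blood_pos) |
    draw_for(bg, p_bg$micro_blood_pos) | draw_for(pre, p_pre$micro_blood_pos)
  emit_micro(blood & sa, "blood", TRUE, sa_text)
  emit_micro(blood & cons, "blood", TRUE, cons_text)
  emit_micro(blood & !sa & !cons, "blood", TRUE, pos_text)
  # organism found on a non-blood or standalone order
  emit_micro(sa & !blood, "miscellaneous", TRUE, sa_text)
  emit_micro(cons & !blood, "miscellaneous", TRUE, cons_text)
  emit_micro(draw_for(inf, p_inf$micro_cardiac_pos) |
               draw_for(bg, p_bg$micro_cardiac_pos) |
               draw_for(pre, p_pre$micro_cardiac_pos),
             "cardiac", TRUE, pos_text)
  emit_micro(draw_for(inf, p_inf$micro_misc_pos) |
               draw_for(bg, p_bg$micro_misc_pos) & !sa & !cons,
             "miscellaneous", TRUE, pos_text)
  emit_micro(draw_for(inf, p_inf$micro_neg_order) |
               draw_for(bg, p_bg$micro_neg_order) |
               draw_for(pre, p_pre$micro_neg_order),
             "blood", FALSE, neg_text)

  # ---- clinical notes -----------------------------------------------------
  phrase_id <- sample.int(length(cfg$keyword_phrases), n, replace = TRUE)
  note_acc <- new.env(parent = emptyenv())
  note_acc$k <- 0L
  emit_notes <- function(idx, days, titles, with_phrase) {
    if (!length(idx)) return()
    txt <- character(length(idx))
    for (j in seq_along(idx)) {
      phrase <- if (with_phrase[j]) cfg$keyword_phrases[[phrase_id[idx[j]]]]
                else NULL
      txt[j] <- sim_note_text(phrase, cfg$filler_vocab,
                              n_tokens = 7L + sample.int(18L, 1L),
                              gapped = stats::runif(1) < 0.4)
    }
    ids <- sprintf("N%07d", note_acc$k + seq_along(idx))
    note_acc$k <- note_acc$k + length(idx)
    nt_rows <<- add(nt_rows, data.frame(
      note_id = ids, patient_id = pid[idx], note_title = titles,
      note_date = pdate[idx] + as.integer(days), text = txt,
      stringsAsFactors = FALSE))
  }
  # postprocedure infection documentation (infected cases)
  post_doc <- draw_for(inf, p_inf$note_post)
  idx <- which(post_doc)
  if (length(idx)) {
    day <- pmin(90L, pmax(3L, onset[idx] +
                            sample(-2:14, length(idx), replace = TRUE)))
    emit_notes(idx, day,
               sample(cfg$signal_titles, length(idx), replace = TRUE),
               rep(TRUE, length(idx)))
  }
  # preprocedure history documentation, with copy-forward into the
  # postprocedure record (the mechanism the history flag exists to counter)
  hist_doc <- draw_for(inf, p_inf$history_doc) |
    draw_for(bg, p_bg$history_doc) | draw_for(pre, p_pre$pre_note)
  idx <- which(hist_doc)
  if (length(idx)) {
    day <- -(6L + sample.int(55L, length(idx), replace = TRUE))
    emit_notes(idx, day,
               sample(cfg$signal_titles, length(idx), replace = TRUE),
               rep(TRUE, length(idx)))
    copied <- idx[stats::runif(length(idx)) < cfg$copy_forward]
    if (length(copied)) {
      emit_notes(copied, 2L + sample.int(88L, length(copied), replace = TRUE),
                 sample(cfg$signal_titles, length(copied), replace = TRUE),
                 rep(TRUE, length(copied)))
    }
  }
  # independent background postprocedure keyword mention
  idx <- which(draw_for(bg, p_bg$note_post_only))
  if (length(idx)) {
    emit_notes(idx, 2L + sample.int(88L, length(idx), replace = TRUE),
               sample(cfg$signal_titles, length(idx), replace = TRUE),
               rep(TRUE, length(idx)))
  }
  # patient-instruction notes contain the keywords but must be excluded by
  # the note-title filter
  idx <- which(stats::runif(n) < p_bg$instruction_note)
  if (length(idx)) {
    emit_notes(idx, 2L + sample.int(88L, length(idx), replace = TRUE),
               rep(cfg$instruction_title, length(idx)),
               rep(TRUE, length(idx)))
  }
  # filler notes for everyone
  n_filler <- sample.int(2L, n, replace = TRUE)
  idx <- rep(seq_len(n), n_filler)
  emit_notes(idx, sample(-90:90, length(idx), replace = TRUE),
             sample(cfg$filler_titles, length(idx), replace = TRUE),
             rep(FALSE, length(idx)))

  bindr <- function(rows) if (length(rows)) do.call(rbind, rows) else NULL
  cohort <- emr_cohort(
    patients = patients, procedures = procedures,
    diagnoses = bindr(dx_rows), pharmacy = bindr(rx_rows),
    micro = bindr(mi_rows), vitals = bindr(vt_rows), notes = bindr(nt_rows))

  # ---- ground truth and abstractions --------------------------------------
  truth <- data.frame(
    procedure_id = eid, reviewed = TRUE, infection = inf,
    infection_type = type, present_on_admission = pre,
    onset_day = onset, stringsAsFactors = FALSE)

  phys <- logical(n)
  phys[inf] <- stats::runif(sum(inf)) < p_inf$physician_documented
  phys[pre] <- TRUE
  symptoms <- draw_for(bg, p_bg$abstraction_symptoms) |
    (inf & stats::runif(n) < 0.6) | (pre & stats::runif(n) < 0.5)
  lab <- (inf & stats::runif(n) < 0.6) | (pre & stats::runif(n) < 0.5)
  abx_init <- draw_for(bg, p_bg$abstraction_abx) |
    (inf & stats::runif(n) < 0.7) | (pre & stats::runif(n) < 0.5)
  # infections without physician documentation must satisfy >= 2 criteria
  need2 <- inf & !phys
  symptoms[need2] <- TRUE
  lab[need2] <- TRUE
  # uninfected, non-excluded cases never accumulate 2 criteria: stray
  # documentation is limited to a single criterion
  both <- bg & symptoms & abx_init
  symptoms[both] <- FALSE
  stitch <- bg & stats::runif(n) < p_bg$stitch_abscess
  cell_other <- bg & !stitch & stats::runif(n) < p_bg$cellulitis_other_site
  symptoms[stitch | cell_other] <- TRUE
  abx_init[stitch | cell_other] <- TRUE
  abstractions <- data.frame(
    procedure_id = eid,
    physician_documented_infection = phys,
    symptoms_documented = symptoms,
    positive_laboratory = lab,
    antibiotics_initiated = abx_init,
    infection_present_at_procedure = pre,
    superficial_cellulitis_other_site = cell_other,
    stitch_abscess_only = stitch,
    days_postprocedure = onset,
    infection_type = type,
    stringsAsFactors = FALSE)

  structure(list(cohort = cohort, truth = truth,
                 abstractions = abstractions, config = cfg),
            class = "sim_result")
}

#' @export
print.sim_result <- function(x, ...) {
  cat(sprintf("<sim_result> %d procedures, %d infections (%.2f%%), %d present-at-procedure\n",
              nrow(x$truth), sum(x$truth$infection),
              100 * mean(x$truth$infection),
              sum(x$truth$present_on_admission)))
  invisible(x)
}

#' Paired development / validation cohorts
#'
#' Two independent seeded cohorts from one configuration (seeds `seed` and
#' `seed + 1`), for fit-on-development / evaluate-on-validation workflows.
#'
#' @param config A [sim_config()].
#' @return List with `development` and `validation`, each a `sim_result`.
#' @export
end_to_end_fixture <- function(config = sim_config()) {
  dev_cfg <- config
  val_cfg <- config
  val_cfg$seed <- config$seed + 1L
  list(development = simulate_cohort(dev_cfg),
       validation = simulate_cohort(val_cfg))
}
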