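# Independent oracles and shared fixtures for the test suite.

# Brute-force ordered-subsequence matcher: explores every ordered token-index
# assignment of word groups satisfying the gap constraint. Reference
# implementation for the DP matcher, deliberately naive.
brute_force_match <- function(tokens, groups, gap) {
  G <- length(groups)
  n <- length(tokens)
  if (G == 0L || n == 0L) return(FALSE)
  rec <- function(g, prev) {
    lo <- if (g == 1L) 1L else prev + 1L
    hi <- if (g == 1L) n else min(n, prev + 1L + gap)
    if (lo > hi) return(FALSE)
    for (i in lo:hi) {
      if (tokens[i] %in% groups[[g]]) {
        if (g == G || rec(g + 1L, i)) return(TRUE)
      }
    }
    FALSE
  }
  rec(1L, 0L)
}

# Coarse-to-fine grid search maximizing the exact Bernoulli log-likelihood;
# independent of any IRLS machinery.
grid_logistic_fit <- function(X, y, rounds = 9L, pts = 15L, width = 8) {
  Xd <- cbind(1, X)
  p_dim <- ncol(Xd)
  center <- rep(0, p_dim)
  loglik <- function(b) {
    eta <- drop(Xd %*% b)
    sum(y * eta - log1p(exp(eta)))
  }
  for (r in seq_len(rounds)) {
    grids <- lapply(seq_len(p_dim), function(j) {
      seq(center[j] - width, center[j] + width, length.out = pts)
    })
    cand <- as.matrix(expand.grid(grids))
    ll <- apply(cand, 1L, loglik)
    center <- cand[which.max(ll), ]
    width <- width * 2.5 / (pts - 1)
  }
  unname(center)
}

# All-pairs AUC: concordant pairs + half ties over every positive-negative
# pair.
brute_auc <- function(scores, labels) {
  pos <- scores[as.logical(labels)]
  neg <- scores[!as.logical(labels)]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + (p > q) + 0.5 * (p == q)
  }
  tot / (length(pos) * length(neg))
}

# Published review-count summaries used as evaluation inputs: distribution
# of procedures and review yield by predicted-probability band for the
# development and validation samples of the source surveillance study.
dev_band_counts <- function() {
  data.frame(
    lo = c(0, 0.01, 0.03, 0.10, 0.50),
    hi = c(0.01, 0.03, 0.10, 0.50, 1),
    cohort_n = c(8883L, 226L, 221L, 176L, 100L),
    reviewed_n = c(188L, 52L, 42L, 60L, 39L),
    infections_n = c(1L, 2L, 3L, 13L, 28L)
  )
}

val_band_counts <- function() {
  data.frame(
    lo = c(0, 0.01, 0.03, 0.10, 0.50),
    hi = c(0.01, 0.03, 0.10, 0.50, 1),
    cohort_n = c(8883L, 224L, 200L, 193L, 106L),
    reviewed_n = c(68L, 11L, 52L, 126L, 106L),
    infections_n = c(2L, 1L, 3L, 36L, 65L)
  )
}

# Small handbuilt cohort touching every stream.
tiny_cohort <- function() {
  patients <- data.frame(
    patient_id = sprintf("P%02d", 1:5),
    age = c(70L, 65L, 80L, 72L, 68L),
    sex = c("male", "male", "female", "male", "unknown"),
    race = c("white", "black", "white", "unknown", "white"),
    ethnicity = "non-hispanic",
    stringsAsFactors = FALSE
  )
  for (cm in comorbidity_names()) patients[[cm]] <- FALSE
  patients$congestive_heart_failure <- c(TRUE, FALSE, TRUE, FALSE, FALSE)
  patients$death_date <- as.Date(c(NA, NA, "2017-03-01", NA, NA))
  procedures <- data.frame(
    procedure_id = sprintf("E%02d", 1:5),
    patient_id = sprintf("P%02d", 1:5),
    procedure_date = as.Date("2017-01-01") + 0:4,
    facility_id = "F001",
    emergent = c(FALSE, TRUE, FALSE, FALSE, FALSE),
    stringsAsFactors = FALSE
  )
  diagnoses <- data.frame(
    patient_id = c("P01", "P02"),
    code = c("T82.7XXA", "J18.9"),
    event_date = as.Date(c("2017-01-20", "2017-02-01")),
    stringsAsFactors = FALSE
  )
  pharmacy <- data.frame(
    patient_id = c("P01", "P02"),
    drug_name = c("cephalexin", "azithromycin"),
    fill_date = as.Date(c("2017-01-11", "2017-01-22")),
    days_supplied = c(7L, 5L),
    stringsAsFactors = FALSE
  )
  micro <- data.frame(
    patient_id = c("P01", "P03"),
    order_date = as.Date(c("2017-01-15", "2017-02-12")),
    specimen_class = c("blood", "cardiac"),
    culture_positive = c(TRUE, TRUE),
    susceptibility_tested = c(TRUE, TRUE),
    result_text = c("STAPHYLOCOCCUS AUREUS isolated", "gram positive cocci"),
    stringsAsFactors = FALSE
  )
  vitals <- data.frame(
    patient_id = c("P01", "P02"),
    measure = "temperature_c",
    value = c(38.4, 36.8),
    measured_at = as.Date(c("2017-01-10", "2017-01-05")),
    stringsAsFactors = FALSE
  )
  notes <- data.frame(
    note_id = sprintf("N%03d", 1:3),
    patient_id = c("P01", "P02", "P04"),
    note_title = c("CARDIOLOGY OUTPATIENT NOTE", "PRIMARY CARE NOTE",
                   "CARDIOLOGY ATTENDING NOTE"),
    note_date = as.Date(c("2017-01-21", "2017-01-10", "2016-11-15")),
    text = c("patient seen today pocket infection noted at site",
             "routine followup\nno issues",
             "history of cied infection managed previously"),
    stringsAsFactors = FALSE
  )
  emr_cohort(patients, procedures, diagnoses, pharmacy, micro, vitals, notes)
}

# Single-procedure cohort builder for targeted flag tests: supply any subset
# of event streams, anchored at procedure date 2017-01-01 (day 0).
one_proc_cohort <- function(diagnoses = NULL, pharmacy = NULL, micro = NULL,
                            vitals = NULL, notes = NULL, death_date = NA,
                            emergent = FALSE) {
  patients <- data.frame(patient_id = "P01", age = 70L, sex = "male",
                         race = "white", ethnicity = "non-hispanic",
                         stringsAsFactors = FALSE)
  for (cm in comorbidity_names()) patients[[cm]] <- FALSE
  patients$death_date <- as.Date(death_date)
  procedures <- data.frame(procedure_id = "E01", patient_id = "P01",
                           procedure_date = as.Date("2017-01-01"),
                           facility_id = "F001", emergent = emergent,
                           stringsAsFactors = FALSE)
  fill_pid <- function(df) {
    if (!is.null(df) && !"patient_id" %in% names(df)) df$patient_id <- "P01"
    df
  }
  emr_cohort(patients, procedures, fill_pid(diagnoses), fill_pid(pharmacy),
             fill_pid(micro), fill_pid(vitals), fill_pid(notes))
}

day0 <- as.Date("2017-01-01")
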