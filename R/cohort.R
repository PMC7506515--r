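#' EMR cohort container
#'
#' An `emr_cohort` bundles the seven flat EMR streams the surveillance
#' algorithm consumes, keyed on an index CIED procedure (day 0 anchor):
#'
#' * `patients` — one row per patient: `patient_id`, `age`, `sex`
#'   (`male`/`female`/`unknown`), `race`, `ethnicity`, eight comorbidity
#'   booleans (see [comorbidity_names()]) and an optional `death_date`.
#' * `procedures` — the unit of surveillance: `procedure_id`, `patient_id`,
#'   `procedure_date`, `facility_id`, `emergent`.
#' * `diagnoses` — ICD-10-CM events: `patient_id`, `code`, `event_date`.
#'   Codes are normalized to uppercase with surrounding whitespace stripped.
#' * `pharmacy` — outpatient fills: `patient_id`, `drug_name`, `fill_date`,
#'   `days_supplied` (>= 1).
#' * `micro` — microbiology orders/results: `patient_id`, `order_date`,
#'   `specimen_class` (`blood`/`cardiac`/`miscellaneous`/`other`),
#'   `culture_positive`, `susceptibility_tested`, `result_text`.
#' * `vitals` — `patient_id`, `measure` (`temperature_c`), `value` in
#'   degrees Celsius (physiologic range 30-45 enforced), `measured_at`.
#' * `notes` — clinical note text: `note_id`, `patient_id`, `note_title`,
#'   `note_date`, `text`.
#'
#' Every event-stream `patient_id` must resolve to exactly one patient
#' (referential closure); `patient_id`, `procedure_id` and `note_id` are
#' unique within the cohort.
#'
#' @param patients,procedures,diagnoses,pharmacy,micro,vitals,notes
#'   Data frames with the columns described above. Event streams may be
#'   `NULL`, meaning empty.
#' @return A validated object of class `emr_cohort` (a named list of the
#'   seven data frames, canonically sorted).
#' @seealso [read_cohort()], [write_cohort()], [simulate_cohort()]
#' @export
emr_cohort <- function(patients, procedures, diagnoses = NULL, pharmacy = NULL,
                       micro = NULL, vitals = NULL, notes = NULL) {
  streams <- list(
    patients   = normalize_stream(patients,   "patients"),
    procedures = normalize_stream(procedures, "procedures"),
    diagnoses  = normalize_stream(diagnoses,  "diagnoses"),
    pharmacy   = normalize_stream(pharmacy,   "pharmacy"),
    micro      = normalize_stream(micro,      "micro"),
    vitals     = normalize_stream(vitals,     "vitals"),
    notes      = normalize_stream(notes,      "notes")
  )
  cohort <- structure(streams, class = "emr_cohort")
  validate_cohort(cohort)
  canonical_sort(cohort)
}

#' Comorbidity flag names carried on every patient record
#'
#' @return Character vector of the required comorbidity boolean columns.
#' @export
comorbidity_names <- function() {
  c("congestive_heart_failure", "solid_tumor_without_metastasis",
    "coagulopathy", "diabetes_uncomplicated", "diabetes_complicated",
    "obesity", "pulmonary_circulation_disease", "renal_failure")
}

cohort_schemas <- function() {
  list(
    patients = c("patient_id", "age", "sex", "race", "ethnicity",
                 comorbidity_names(), "death_date"),
    procedures = c("procedure_id", "patient_id", "procedure_date",
                   "facility_id", "emergent"),
    diagnoses = c("patient_id", "code", "event_date"),
    pharmacy = c("patient_id", "drug_name", "fill_date", "days_supplied"),
    micro = c("patient_id", "order_date", "specimen_class", "culture_positive",
              "susceptibility_tested", "result_text"),
    vitals = c("patient_id", "measure", "value", "measured_at"),
    notes = c("note_id", "patient_id", "note_title", "note_date", "text")
  )
}

cohort_date_cols <- function() {
  list(patients = "death_date", procedures = "procedure_date",
       diagnoses = "event_date", pharmacy = "fill_date",
       micro = "order_date", vitals = "measured_at", notes = "note_date")
}

cohort_logical_cols <- function() {
  list(patients = comorbidity_names(), procedures = "emergent",
       micro = c("culture_positive", "susceptibility_tested"))
}

normalize_stream <- function(df, name) {
  schema <- cohort_schemas()[[name]]
  if (is.null(df)) {
    df <- as.data.frame(
      stats::setNames(replicate(length(schema), character(0), simplify = FALSE),
                      schema))
  }
  missing <- setdiff(schema, names(df))
  if (length(missing)) {
    stop(sprintf("stream '%s': missing required column(s): %s",
                 name, paste(missing, collapse = ", ")), call. = FALSE)
  }
  df <- df[schema]
  for (col in cohort_date_cols()[[name]]) {
    df[[col]] <- as_date_iso(df[[col]], col, name)
  }
  for (col in cohort_logical_cols()[[name]]) {
    df[[col]] <- parse_logical(df[[col]], col, name)
  }
  char_cols <- setdiff(schema, c(cohort_date_cols()[[name]],
                                 cohort_logical_cols()[[name]],
                                 "age", "days_supplied", "value"))
  for (col in char_cols) df[[col]] <- as.character(df[[col]])
  if ("age" %in% schema) df$age <- as.integer(df$age)
  if ("days_supplied" %in% schema) df$days_supplied <- as.integer(df$days_supplied)
  if ("value" %in% schema) df$value <- as.numeric(df$value)
  if ("code" %in% schema) df$code <- toupper(trimws(df$code))
  rownames(df) <- NULL
  df
}

parse_logical <- function(x, col, name) {
  if (is.logical(x)) return(x)
  u <- toupper(trimws(as.character(x)))
  out <- rep(NA, length(u))
  out[u %in% c("TRUE", "T", "1")] <- TRUE
  out[u %in% c("FALSE", "F", "0")] <- FALSE
  if (any(is.na(out) & !is.na(u) & nzchar(u))) {
    stop(sprintf("stream '%s': column '%s' is not interpretable as logical",
                 name, col), call. = FALSE)
  }
  out
}

validate_cohort <- function(cohort) {
  p <- cohort$patients
  if (anyDuplicated(p$patient_id)) {
    stop("duplicate patient_id: ",
         paste(unique(p$patient_id[duplicated(p$patient_id)]), collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(cohort$procedures$procedure_id)) {
    stop("duplicate procedure_id in procedures", call. = FALSE)
  }
  if (anyDuplicated(cohort$notes$note_id)) {
    stop("duplicate note_id in notes", call. = FALSE)
  }
  if (nrow(p) && any(!is.na(p$age) & p$age < 0)) {
    stop("patients: negative age", call. = FALSE)
  }
  bad_sex <- setdiff(unique(p$sex), c("male", "female", "unknown"))
  if (length(bad_sex)) {
    stop("patients: sex must be male/female/unknown, found: ",
         paste(bad_sex, collapse = ", "), call. = FALSE)
  }
  for (name in c("procedures", "diagnoses", "pharmacy", "micro", "vitals",
                 "notes")) {
    dangling <- setdiff(cohort[[name]]$patient_id, p$patient_id)
    if (length(dangling)) {
      stop(sprintf("stream '%s': dangling patient_id(s): %s", name,
                   paste(utils::head(dangling, 5L), collapse = ", ")),
           call. = FALSE)
    }
  }
  v <- cohort$vitals
  if (nrow(v)) {
    bad_measure <- setdiff(unique(v$measure), "temperature_c")
    if (length(bad_measure)) {
      stop("vitals: unsupported measure(s): ",
           paste(bad_measure, collapse = ", "), call. = FALSE)
    }
    out_of_range <- is.na(v$value) | v$value < 30 | v$value > 45
    if (any(out_of_range)) {
      stop(sprintf("vitals: %d temperature value(s) outside physiologic range 30-45 degC (rows %s)",
                   sum(out_of_range),
                   paste(utils::head(which(out_of_range), 5L), collapse = ", ")),
           call. = FALSE)
    }
  }
  ph <- cohort$pharmacy
  if (nrow(ph) && any(is.na(ph$days_supplied) | ph$days_supplied < 1)) {
    stop("pharmacy: days_supplied must be >= 1", call. = FALSE)
  }
  m <- cohort$micro
  if (nrow(m)) {
    bad <- setdiff(unique(m$specimen_class),
                   c("blood", "cardiac", "miscellaneous", "other"))
    if (length(bad)) {
      stop("micro: unknown specimen_class: ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
  }
  invisible(cohort)
}

canonical_sort <- function(cohort) {
  cohort$patients   <- resort(cohort$patients, "patient_id")
  cohort$procedures <- resort(cohort$procedures, "procedure_id")
  cohort$diagnoses  <- resort(cohort$diagnoses, "patient_id", "event_date", "code")
  cohort$pharmacy   <- resort(cohort$pharmacy, "patient_id", "fill_date", "drug_name")
  cohort$micro      <- resort(cohort$micro, "patient_id", "order_date",
                              "specimen_class", "result_text")
  cohort$vitals     <- resort(cohort$vitals, "patient_id", "measured_at", "value")
  cohort$notes      <- resort(cohort$notes, "note_id")
  cohort
}

resort <- function(df, ...) {
  cols <- lapply(list(...), function(k) {
    x <- df[[k]]
    if (inherits(x, "Date")) as.integer(x) else x
  })
  df <- df[do.call(radix_order, cols), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' @export
print.emr_cohort <- function(x, ...) {
  cat("<emr_cohort>\n")
  for (name in names(x)) {
    cat(sprintf("  %-10s %6d rows\n", name, nrow(x[[name]])))
  }
  invisible(x)
}

#' Read an EMR cohort from a directory of flat files
#'
#' Expects `patients.csv`, `procedures.csv`, `diagnoses.csv`, `pharmacy.csv`,
#' `micro.csv`, `vitals.csv` (CSV, header row, UTF-8) and `notes.jsonl`
#' (one JSON object per line; JSONL is used for notes because free text
#' contains delimiters and newlines). Missing event-stream files are treated
#' as empty streams; `patients.csv` and `procedures.csv` are required.
#'
#' Malformed rows that can be isolated (vitals outside the physiologic
#' temperature range 30-45 degC) are dropped with a line-numbered warning;
#' structural problems (missing columns, dangling `patient_id` references)
#' are errors.
#'
#' @param dir Directory containing the cohort files.
#' @return An [emr_cohort()] object. Row counts per stream are reported via
#'   `message()`.
#' @export
read_cohort <- function(dir) {
  if (!dir.exists(dir)) stop("cohort directory not found: ", dir, call. = FALSE)
  read_stream <- function(name, required = FALSE) {
    path <- file.path(dir, paste0(name, ".csv"))
    if (!file.exists(path)) {
      if (required) stop("required file missing: ", path, call. = FALSE)
      return(NULL)
    }
    utils::read.csv(path, colClasses = "character", na.strings = character(0),
                    fileEncoding = "UTF-8")
  }
  patients <- read_stream("patients", required = TRUE)
  procedures <- read_stream("procedures", required = TRUE)
  vitals <- read_stream("vitals")
  if (!is.null(vitals) && nrow(vitals) && "value" %in% names(vitals)) {
    val <- suppressWarnings(as.numeric(vitals$value))
    bad <- is.na(val) | val < 30 | val > 45
    if (any(bad)) {
      warning(sprintf(
        "vitals.csv: dropped %d row(s) with non-physiologic temperature (file line(s) %s)",
        sum(bad), paste(utils::head(which(bad) + 1L, 10L), collapse = ", ")),
        call. = FALSE)
      vitals <- vitals[!bad, , drop = FALSE]
    }
  }
  notes <- NULL
  notes_path <- file.path(dir, "notes.jsonl")
  if (file.exists(notes_path)) {
    lines <- readLines(notes_path, encoding = "UTF-8")
    lines <- lines[nzchar(lines)]
    if (length(lines)) {
      recs <- lapply(lines, jsonlite::fromJSON)
      notes <- data.frame(
        note_id = vapply(recs, function(r) as.character(r$note_id), ""),
        patient_id = vapply(recs, function(r) as.character(r$patient_id), ""),
        note_title = vapply(recs, function(r) as.character(r$note_title), ""),
        note_date = vapply(recs, function(r) as.character(r$note_date), ""),
        text = vapply(recs, function(r) as.character(r$text %||% ""), ""),
        stringsAsFactors = FALSE
      )
    }
  }
  cohort <- emr_cohort(
    patients = patients, procedures = procedures,
    diagnoses = read_stream("diagnoses"), pharmacy = read_stream("pharmacy"),
    micro = read_stream("micro"), vitals = vitals, notes = notes
  )
  message(sprintf(
    "read_cohort: %d patients, %d procedures, %d diagnoses, %d fills, %d micro, %d vitals, %d notes",
    nrow(cohort$patients), nrow(cohort$procedures), nrow(cohort$diagnoses),
    nrow(cohort$pharmacy), nrow(cohort$micro), nrow(cohort$vitals),
    nrow(cohort$notes)))
  cohort
}

#' Write an EMR cohort to a directory of flat files
#'
#' Inverse of [read_cohort()]. Output is deterministic: fixed column order,
#' rows sorted by primary id, dates as ISO-8601, logicals as `TRUE`/`FALSE`,
#' so identical cohorts produce byte-identical files across runs.
#'
#' @param cohort An [emr_cohort()] object (re-validated before writing;
#'   an unresolvable reference refuses to write).
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "emr_cohort"))
  validate_cohort(cohort)
  cohort <- canonical_sort(cohort)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (name in setdiff(names(cohort), "notes")) {
    df <- cohort[[name]]
    for (col in names(df)) {
      if (inherits(df[[col]], "Date")) {
        df[[col]] <- ifelse(is.na(df[[col]]), "", format(df[[col]], "%Y-%m-%d"))
      } else if (is.logical(df[[col]])) {
        df[[col]] <- ifelse(df[[col]], "TRUE", "FALSE")
      }
    }
    utils::write.csv(df, file.path(dir, paste0(name, ".csv")),
                     row.names = FALSE, quote = TRUE, na = "",
                     fileEncoding = "UTF-8")
  }
  notes <- cohort$notes
  con <- file(file.path(dir, "notes.jsonl"), open = "wb")
  on.exit(close(con))
  if (nrow(notes)) {
    for (i in seq_len(nrow(notes))) {
      rec <- list(note_id = notes$note_id[i], patient_id = notes$patient_id[i],
                  note_title = notes$note_title[i],
                  note_date = format(notes$note_date[i], "%Y-%m-%d"),
                  text = notes$text[i])
      writeLines(as.character(jsonlite::toJSON(rec, auto_unbox = TRUE)), con,
                 useBytes = TRUE)
    }
  }
  invisible(dir)
}
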