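#' Adjudicate a chart abstraction against the reference infection definition
#'
#' Deterministic implementation of the reference-standard 90-day CIED
#' infection definition applied to structured chart-review abstractions. A
#' case is an infection iff
#'
#' * physician documentation of infection is present, **or** at least two of
#'   \{documented symptoms, positive laboratory tests, initiation of
#'   antibiotic treatment\} hold; **and**
#' * none of the exclusions applies: infection already present at the time
#'   of the procedure, superficial cellulitis at another site, or a stitch
#'   abscess only; **and**
#' * onset (`days_postprocedure`), when recorded, is within 90 days.
#'
#' Exclusions take precedence over inclusion criteria.
#'
#' @param abstractions Data frame with logical columns
#'   `physician_documented_infection`, `symptoms_documented`,
#'   `positive_laboratory`, `antibiotics_initiated`,
#'   `infection_present_at_procedure`, `superficial_cellulitis_other_site`,
#'   `stitch_abscess_only`, an integer `days_postprocedure` (`NA` allowed),
#'   a `procedure_id`, and optionally `infection_type` and
#'   `present_on_admission` carried through to the label.
#' @return Data frame of review labels: `procedure_id`, `reviewed` (always
#'   `TRUE` — adjudication implies review), `infection`, `infection_type`
#'   (`"none"` for non-infections), `present_on_admission`, `onset_day`.
#' @export
adjudicate <- function(abstractions) {
  req <- c("procedure_id", "physician_documented_infection",
           "symptoms_documented", "positive_laboratory",
           "antibiotics_initiated", "infection_present_at_procedure",
           "superficial_cellulitis_other_site", "stitch_abscess_only")
  missing <- setdiff(req, names(abstractions))
  if (length(missing)) {
    stop("abstractions missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  a <- abstractions
  days <- if ("days_postprocedure" %in% names(a)) {
    as.integer(a$days_postprocedure)
  } else rep(NA_integer_, nrow(a))
  criteria <- a$symptoms_documented + a$positive_laboratory +
    a$antibiotics_initiated
  included <- a$physician_documented_infection | criteria >= 2L
  excluded <- a$infection_present_at_procedure |
    a$superficial_cellulitis_other_site | a$stitch_abscess_only
  in_window <- is.na(days) | days <= 90L
  infection <- included & !excluded & in_window
  type <- if ("infection_type" %in% names(a)) as.character(a$infection_type)
          else rep("pocket", nrow(a))
  type[!infection] <- "none"
  data.frame(
    procedure_id = a$procedure_id,
    reviewed = TRUE,
    infection = infection,
    infection_type = type,
    present_on_admission = a$infection_present_at_procedure,
    onset_day = ifelse(infection, days, NA_integer_),
    stringsAsFactors = FALSE
  )
}
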