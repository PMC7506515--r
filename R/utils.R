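#' @keywords internal
"_PACKAGE"

#' Day offset between an event date and the procedure anchor
#'
#' All time windows in the package are day-granular: day 0 is the procedure
#' day and the offset is the whole-day difference `event_date - procedure_date`.
#' Time-of-day is ignored everywhere.
#'
#' @param event_date `Date` vector.
#' @param procedure_date `Date` scalar (or vector recycled against
#'   `event_date`).
#' @return Integer vector of day offsets (negative = before the procedure).
#' @export
day_offset <- function(event_date, procedure_date) {
  as.integer(as.Date(event_date) - as.Date(procedure_date))
}

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's stream afterwards so package functions never perturb user RNG.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Locale-independent stable ordering for deterministic file output.
radix_order <- function(...) order(..., method = "radix")

`%||%` <- function(a, b) if (is.null(a)) b else a

as_date_iso <- function(x, field, file = NULL) {
  if (inherits(x, "Date")) return(x)
  x <- as.character(x)
  out <- as.Date(rep(NA_character_, length(x)))
  nonblank <- !is.na(x) & nzchar(trimws(x))
  parsed <- as.Date(x[nonblank], format = "%Y-%m-%d")
  if (anyNA(parsed)) {
    bad <- which(nonblank)[is.na(parsed)]
    stop(sprintf("field '%s'%s: unparseable ISO-8601 date(s) at row(s) %s",
                 field, if (is.null(file)) "" else paste0(" in ", file),
                 paste(utils::head(bad, 5L), collapse = ", ")), call. = FALSE)
  }
  out[nonblank] <- parsed
  out
}
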