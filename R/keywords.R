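#' Tokenize clinical note text
#'
#' Lowercases and splits on any run of non-alphanumeric characters, so
#' punctuation acts as a token boundary. Deterministic; empty or
#' whitespace-only text yields a zero-length vector.
#'
#' @param text Character scalar.
#' @return Character vector of lowercase word tokens.
#' @export
tokenize <- function(text) {
  if (is.null(text) || is.na(text) || !nzchar(text)) return(character(0))
  toks <- strsplit(tolower(text), "[^a-z0-9]+")[[1]]
  toks[nzchar(toks)]
}

#' Construct a keyword matching rule
#'
#' A rule is an ordered sequence of word groups; each group is a set of
#' spelling variants for one word position (e.g. `c("cied", "pacemaker",
#' "device")`). The rule matches a note when the groups appear in order with
#' at most `max_gap_tokens` intervening tokens between consecutive matched
#' words ("1 or 2 spaces" in prose corresponds to the default of at most one
#' intervening word). Matching is case-insensitive on tokens; there is no
#' stemming, fuzzy matching or negation detection — variant lists are
#' curated, and stale "history of infection" mentions are handled by the
#' preprocedure-history flag rather than NLP negation.
#'
#' @param rule_id Unique rule identifier.
#' @param words List of character vectors: one variant set per word position.
#' @param max_gap_tokens Maximum intervening tokens between consecutive
#'   matched words (default 1).
#' @param note_titles Character vector of case-insensitive substring patterns
#'   a note title must contain, or `"any"` (no filtering). Exact EMR note
#'   titles are site-specific, hence substring patterns.
#' @param window_days Integer length-2: allowed note-date offset relative to
#'   the procedure day (inclusive), e.g. `c(3, 90)` post or `c(-90, -3)` pre.
#' @param polarity One of `"post_infection"` (postprocedure infection
#'   documentation), `"pre_history"` (preprocedure device-infection history)
#'   or `"organism"` (microbiology result text).
#' @return A `keyword_rule` object.
#' @export
keyword_rule <- function(rule_id, words, max_gap_tokens = 1,
                         note_titles = "any", window_days = c(3L, 90L),
                         polarity = c("post_infection", "pre_history",
                                      "organism")) {
  polarity <- match.arg(polarity)
  if (!is.character(rule_id) || length(rule_id) != 1L || !nzchar(rule_id)) {
    stop("rule_id must be a non-empty string", call. = FALSE)
  }
  # a bare character vector means one single-variant group per element
  if (is.character(words)) words <- as.list(words)
  if (!is.list(words) || length(words) == 0L) {
    stop(sprintf("rule '%s': words must be a non-empty list of variant sets",
                 rule_id), call. = FALSE)
  }
  words <- lapply(words, function(g) {
    g <- tolower(trimws(as.character(g)))
    g <- g[nzchar(g)]
    if (length(g) == 0L) {
      stop(sprintf("rule '%s': empty word group", rule_id), call. = FALSE)
    }
    g
  })
  max_gap_tokens <- as.integer(max_gap_tokens)
  if (is.na(max_gap_tokens) || max_gap_tokens < 0L) {
    stop(sprintf("rule '%s': max_gap_tokens must be an integer >= 0", rule_id),
         call. = FALSE)
  }
  window_days <- as.integer(window_days)
  if (length(window_days) != 2L || anyNA(window_days) ||
      window_days[1] > window_days[2]) {
    stop(sprintf("rule '%s': window_days must be [lo, hi] with lo <= hi",
                 rule_id), call. = FALSE)
  }
  structure(list(rule_id = rule_id, words = words,
                 max_gap_tokens = max_gap_tokens,
                 note_titles = tolower(as.character(note_titles)),
                 window_days = window_days, polarity = polarity),
            class = "keyword_rule")
}

note_title_ok <- function(title, patterns) {
  if (length(patterns) == 0L || "any" %in% patterns) return(TRUE)
  title <- tolower(title %||% "")
  any(vapply(patterns, function(p) grepl(p, title, fixed = TRUE), logical(1)))
}

# Ordered-subsequence matching with a bounded gap: feas[g, i] is TRUE when
# token i can serve as the match for word group g with the remaining groups
# still matchable downstream. Computed right-to-left, then matches are
# reconstructed earliest-first from every feasible start.
match_tokens <- function(tokens, words, max_gap) {
  n <- length(tokens)
  G <- length(words)
  if (n == 0L || G > n) return(integer(0))
  ok <- vapply(words, function(g) tokens %in% g, logical(n))
  ok <- matrix(ok, nrow = n, ncol = G)
  feas <- matrix(FALSE, nrow = n, ncol = G)
  feas[, G] <- ok[, G]
  if (G > 1L) {
    for (g in (G - 1L):1L) {
      for (i in which(ok[, g])) {
        lo <- i + 1L
        hi <- min(n, i + 1L + max_gap)
        if (lo <= hi && any(feas[lo:hi, g + 1L])) feas[i, g] <- TRUE
      }
    }
  }
  starts <- which(feas[, 1L])
  if (!length(starts)) return(integer(0))
  # reconstruct one span per feasible start (earliest feasible continuation)
  spans <- matrix(0L, nrow = length(starts), ncol = 2L)
  for (k in seq_along(starts)) {
    pos <- starts[k]
    cur <- pos
    if (G > 1L) {
      for (g in 2L:G) {
        lo <- cur + 1L
        hi <- min(n, cur + 1L + max_gap)
        cur <- lo - 1L + which(feas[lo:hi, g])[1L]
      }
    }
    spans[k, ] <- c(pos, cur)
  }
  spans
}

#' Match a keyword rule against a clinical note
#'
#' A match requires (a) the note-date offset from `procedure_date` to lie in
#' the rule's `window_days`, (b) the note title to pass the rule's title
#' filter, and (c) the rule's word groups to appear in token order with at
#' most `max_gap_tokens` intervening tokens between consecutive matched
#' words. Out-of-window or title-filtered notes yield zero matches, never an
#' error.
#'
#' @param note A single-row data frame (or list) with `note_id`,
#'   `note_title`, `note_date`, `text`.
#' @param rule A [keyword_rule()].
#' @param procedure_date The day-0 anchor date.
#' @return Data frame with one row per match: `rule_id`, `note_id`,
#'   `start_token`, `end_token`, `matched_text`.
#' @export
match_rule <- function(note, rule, procedure_date) {
  stopifnot(inherits(rule, "keyword_rule"))
  empty <- data.frame(rule_id = character(0), note_id = character(0),
                      start_token = integer(0), end_token = integer(0),
                      matched_text = character(0), stringsAsFactors = FALSE)
  off <- day_offset(note$note_date, procedure_date)
  if (is.na(off) || off < rule$window_days[1] || off > rule$window_days[2]) {
    return(empty)
  }
  if (!note_title_ok(note$note_title, rule$note_titles)) return(empty)
  tokens <- tokenize(note$text)
  spans <- match_tokens(tokens, rule$words, rule$max_gap_tokens)
  if (!is.matrix(spans) || nrow(spans) == 0L) return(empty)
  data.frame(
    rule_id = rule$rule_id,
    note_id = as.character(note$note_id),
    start_token = spans[, 1L],
    end_token = spans[, 2L],
    matched_text = vapply(seq_len(nrow(spans)), function(k) {
      paste(tokens[spans[k, 1L]:spans[k, 2L]], collapse = " ")
    }, ""),
    stringsAsFactors = FALSE
  )
}

#' Compile a declarative rule configuration into an executable ruleset
#'
#' Accepts either a YAML/JSON file path or an already-parsed list with a
#' top-level `rules` element; each rule entry carries `id`, `words` (list of
#' variant vectors), and optional `max_gap_tokens`, `note_titles`,
#' `window_days`, `polarity`. Evaluation of the compiled ruleset over a note
#' stream is a pure function of `(notes, procedure_date)`.
#'
#' @param config File path or list.
#' @return A `keyword_ruleset`: list of [keyword_rule()] objects with unique
#'   ids.
#' @export
compile_ruleset <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config) || is.null(config$rules)) {
    stop("ruleset config must contain a 'rules' list", call. = FALSE)
  }
  allowed <- c("id", "words", "max_gap_tokens", "note_titles", "window_days",
               "polarity")
  rules <- lapply(config$rules, function(r) {
    unknown <- setdiff(names(r), allowed)
    if (length(unknown)) {
      stop(sprintf("rule '%s': unknown field(s): %s", r$id %||% "<unnamed>",
                   paste(unknown, collapse = ", ")), call. = FALSE)
    }
    keyword_rule(
      rule_id = r$id %||% stop("rule without an id", call. = FALSE),
      words = r$words,
      max_gap_tokens = r$max_gap_tokens %||% 1L,
      note_titles = unlist(r$note_titles %||% "any"),
      window_days = unlist(r$window_days %||% c(3L, 90L)),
      polarity = r$polarity %||% "post_infection"
    )
  })
  ids <- vapply(rules, `[[`, "", "rule_id")
  if (anyDuplicated(ids)) {
    stop("duplicate rule id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  structure(rules, names = ids, class = "keyword_ruleset")
}

#' @export
print.keyword_ruleset <- function(x, ...) {
  cat(sprintf("<keyword_ruleset> %d rule(s)\n", length(x)))
  for (r in x) {
    cat(sprintf("  %-22s %-14s gap<=%d window [%d,%d] %s\n", r$rule_id,
                r$polarity, r$max_gap_tokens, r$window_days[1],
                r$window_days[2],
                paste(vapply(r$words, function(g) g[1], ""), collapse = "+")))
  }
  invisible(x)
}

#' Default shipped keyword ruleset
#'
#' Loads the package's default rule file
#' (`system.file("extdata", "keyword_rules.yaml")`): postprocedure infection
#' phrases (pocket infection, device/CIED/pacemaker + infection,
#' endocarditis, lead infection) restricted to cardiology-type note titles
#' in day window \[+3, +90\], the same phrases as preprocedure-history rules
#' in \[-90, -3\], and organism rules for *Staphylococcus aureus* and
#' coagulase-negative staphylococci. The file is user-replaceable
#' configuration, not code.
#'
#' @return A `keyword_ruleset`.
#' @export
default_ruleset <- function() {
  compile_ruleset(system.file("extdata", "keyword_rules.yaml",
                              package = "ciedtriage", mustWork = TRUE))
}

#' Scan a microbiology result text for organism classes
#'
#' Variant-aware keyword matching of free-text culture results for the two
#' organism classes the algorithm flags: *Staphylococcus aureus* and
#' coagulase-negative staphylococci. Date windows do not apply here; result
#' timing is handled by the microbiology flag extraction.
#'
#' @param result_text Character scalar (possibly empty).
#' @param organism_rules List of `organism`-polarity [keyword_rule()]s, by
#'   default the organism rules of [default_ruleset()]. Rules whose
#'   `rule_id` starts with `"s_aureus"` feed the first flag, `"cons"` the
#'   second.
#' @return Named logical vector `c(s_aureus = , coag_neg_staph = )`.
#' @export
scan_result_text <- function(result_text, organism_rules = NULL) {
  if (is.null(organism_rules)) {
    rs <- default_ruleset()
    organism_rules <- rs[vapply(rs, function(r) r$polarity == "organism",
                                TRUE)]
  }
  out <- c(s_aureus = FALSE, coag_neg_staph = FALSE)
  tokens <- tokenize(result_text)
  if (!length(tokens)) return(out)
  for (r in organism_rules) {
    spans <- match_tokens(tokens, r$words, r$max_gap_tokens)
    if (is.matrix(spans) && nrow(spans)) {
      if (startsWith(r$rule_id, "s_aureus")) out["s_aureus"] <- TRUE
      if (startsWith(r$rule_id, "cons")) out["coag_neg_staph"] <- TRUE
    }
  }
  out
}
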