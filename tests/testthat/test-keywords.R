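test_that("tokenize lowercases, strips punctuation and is deterministic", {
  expect_identical(tokenize(""), character(0))
  expect_identical(tokenize(NA_character_), character(0))
  expect_identical(tokenize("CIED pocket infection."),
                   c("cied", "pocket", "infection"))
  expect_identical(tokenize("peri-device fluid;  r/o infection!"),
                   c("peri", "device", "fluid", "r", "o", "infection"))
  set.seed(5)
  for (i in 1:200) {
    s <- rawToChar(as.raw(sample(32:126, sample(0:60, 1), replace = TRUE)))
    expect_identical(tokenize(s), tokenize(s))
  }
})

test_that("match_rule enforces word order, gap bound, window and title filter", {
  rule <- keyword_rule("cied_inf", list(c("cied"), c("infection")),
                       max_gap_tokens = 1, note_titles = "any",
                       window_days = c(3, 90))
  note <- function(text, day = 20, title = "CARDIOLOGY NOTE") {
    data.frame(note_id = "N1", note_title = title, note_date = day0 + day,
               text = text, stringsAsFactors = FALSE)
  }
  expect_identical(nrow(match_rule(note("cied pocket infection"), rule, day0)),
                   1L)
  m <- match_rule(note("cied pocket infection"), rule, day0)
  expect_identical(m$matched_text, "cied pocket infection")
  # adjacency also matches (gap bound is a maximum)
  expect_identical(nrow(match_rule(note("cied infection"), rule, day0)), 1L)
  # order violated
  expect_identical(nrow(match_rule(note("infection of cied"), rule, day0)), 0L)
  # two intervening tokens exceed the gap bound
  expect_identical(
    nrow(match_rule(note("cied lead tip infection"), rule, day0)), 0L)
  # out-of-window notes never match, whatever the text
  expect_identical(nrow(match_rule(note("cied infection", day = 1), rule,
                                   day0)), 0L)
  expect_identical(nrow(match_rule(note("cied infection", day = 91), rule,
                                   day0)), 0L)
  # title filter is a case-insensitive substring test
  filtered <- keyword_rule("cied_inf2", list(c("cied"), c("infection")),
                           note_titles = "cardiology")
  expect_identical(
    nrow(match_rule(note("cied infection", title = "PATIENT INSTRUCTIONS"),
                    filtered, day0)), 0L)
  expect_identical(
    nrow(match_rule(note("cied infection", title = "Cardiology Attending"),
                    filtered, day0)), 1L)
  # variants are interchangeable within a word group
  var <- keyword_rule("dev_inf", list(c("cied", "pacemaker"),
                                      c("infection")))
  expect_identical(nrow(match_rule(note("pacemaker site infection"), var,
                                   day0)), 1L)
})

test_that("greedy-looking cases need the feasibility lookahead", {
  # earliest first-word match cannot complete; a later one can
  rule <- keyword_rule("abc", list("a", "b", "c"), max_gap_tokens = 0,
                       window_days = c(0, 0))
  note <- data.frame(note_id = "N1", note_title = "x", note_date = day0,
                     text = "a b a b c", stringsAsFactors = FALSE)
  expect_gt(nrow(match_rule(note, rule, day0)), 0L)
  # within one start, the earliest second-word choice dead-ends
  rule2 <- keyword_rule("abc2", list("a", "b", "c"), max_gap_tokens = 1,
                        window_days = c(0, 0))
  note2 <- data.frame(note_id = "N1", note_title = "x", note_date = day0,
                      text = "a b b x c", stringsAsFactors = FALSE)
  expect_gt(nrow(match_rule(note2, rule2, day0)), 0L)
  # and a true dead end on every path is correctly rejected
  note3 <- data.frame(note_id = "N1", note_title = "x", note_date = day0,
                      text = "a b x b c", stringsAsFactors = FALSE)
  expect_identical(nrow(match_rule(note3, rule2, day0)), 0L)
})

test_that("matcher agrees with the brute-force subsequence oracle and is gap-monotone", {
  set.seed(17)
  alphabet <- letters[1:10]
  for (i in 1:500) {
    tokens <- sample(alphabet, sample(1:30, 1), replace = TRUE)
    n_groups <- sample(1:3, 1)
    groups <- replicate(n_groups, sample(alphabet, sample(1:2, 1)),
                        simplify = FALSE)
    gap <- sample(0:3, 1)
    rule <- keyword_rule("r", groups, max_gap_tokens = gap,
                         window_days = c(0, 0))
    note <- data.frame(note_id = "N1", note_title = "t", note_date = day0,
                       text = paste(tokens, collapse = " "),
                       stringsAsFactors = FALSE)
    got <- nrow(match_rule(note, rule, day0)) > 0L
    want <- brute_force_match(tokens, groups, gap)
    expect_identical(got, want,
                     info = sprintf("tokens=%s gap=%d",
                                    paste(tokens, collapse = " "), gap))
    # raising the gap never removes a match
    if (got) {
      wider <- keyword_rule("r", groups, max_gap_tokens = gap + 2L,
                            window_days = c(0, 0))
      expect_gt(nrow(match_rule(note, wider, day0)), 0L)
    }
  }
})

test_that("compile_ruleset validates configs and loads the shipped default", {
  empty <- compile_ruleset(list(rules = list()))
  expect_s3_class(empty, "keyword_ruleset")
  expect_length(empty, 0L)
  expect_error(
    compile_ruleset(list(rules = list(
      list(id = "a", words = list("x")),
      list(id = "a", words = list("y"))))),
    "duplicate rule id")
  expect_error(
    compile_ruleset(list(rules = list(
      list(id = "a", words = list("x"), shazam = 1)))),
    "unknown field")
  expect_error(
    compile_ruleset(list(rules = list(
      list(id = "a", words = list(character(0)))))),
    "empty word group")
  rs <- default_ruleset()
  pol <- vapply(rs, function(r) r$polarity, "")
  expect_gte(sum(pol == "post_infection"), 1L)
  expect_gte(sum(pol == "pre_history"), 1L)
  expect_gte(sum(pol == "organism"), 1L)
})

test_that("scan_result_text flags organism classes from free text", {
  expect_identical(scan_result_text("STAPHYLOCOCCUS AUREUS isolated"),
                   c(s_aureus = TRUE, coag_neg_staph = FALSE))
  expect_identical(scan_result_text("coag negative staph"),
                   c(s_aureus = FALSE, coag_neg_staph = TRUE))
  expect_identical(scan_result_text("coagulase neg staphylococcus species"),
                   c(s_aureus = FALSE, coag_neg_staph = TRUE))
  expect_identical(scan_result_text(""),
                   c(s_aureus = FALSE, coag_neg_staph = FALSE))
  expect_identical(scan_result_text("no growth after 48 hours"),
                   c(s_aureus = FALSE, coag_neg_staph = FALSE))
})
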