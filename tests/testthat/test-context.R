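first_pair <- function(text, lex = mini_lexicon()) {
  s <- one_sentence(text)
  pairs <- pair_candidates(theme_filter(s, lex), change_filter(s, lex))
  list(sentence = s, pair = pairs[1, ], pairs = pairs)
}

test_that("negation triggers kill pairs inside their scope", {
  rules <- mini_rules()
  x <- first_pair("mood did not improve")
  expect_equal(check_negation(x$sentence, x$pair, rules), "fail")

  y <- first_pair("mood improved")
  expect_equal(check_negation(y$sentence, y$pair, rules), "pass")

  # scope terminator: negation before "but" does not reach the second clause
  z <- first_pair("not hungry, but anxiety increased")
  expect_equal(z$pair$theme_phrase, "anxiety")
  expect_equal(check_negation(z$sentence, z$pair, rules), "pass")
  v <- apply_context_filter(z$sentence, z$pairs, rules)
  expect_true(v$accepted[[1]])
})

test_that("experiencer check rejects non-patient subjects", {
  rules <- mini_rules()
  x <- first_pair("Mother reports she herself felt more anxious")
  expect_equal(check_experiencer(x$sentence, x$pair, rules), "fail")

  z <- first_pair("Patient felt more calmness today", lex = lexicon(data.frame(
    phrase = c("calmness", "more"), category = c("theme:symptoms", "change"),
    polarity = c(1, 1)
  )))
  expect_equal(check_experiencer(z$sentence, z$pair, rules), "pass")

  w <- first_pair("Sister's sadness increased", lex = lexicon(data.frame(
    phrase = c("sadness", "increased"), category = c("theme:symptoms", "change"),
    polarity = c(-1, 1)
  )))
  expect_equal(check_experiencer(w$sentence, w$pair, rules), "fail")
})

test_that("temporality check enforces currency and scope windows", {
  rules <- mini_rules()
  x <- first_pair("Years ago anxiety increased sharply")
  expect_equal(check_temporality(x$sentence, x$pair, rules), "fail")

  y <- first_pair("Today, anxiety symptoms increased")
  expect_equal(check_temporality(y$sentence, y$pair, rules), "pass")

  # a windowed trigger whose scope ends before the match leaves it untouched
  narrow <- context_rules(data.frame(
    trigger = "years ago", kind = "non-current", scope = "forward", window = "1"
  ))
  z <- first_pair("Years ago stable, anxiety increased")
  expect_equal(check_temporality(z$sentence, z$pair, narrow), "pass")
})

test_that("hypothetical check rejects conditional contexts", {
  rules <- mini_rules()
  x <- first_pair("if anxiety increases, call us", lex = lexicon(data.frame(
    phrase = c("anxiety", "increases"), category = c("theme:symptoms", "change"),
    polarity = c(-1, 1)
  )))
  expect_equal(check_hypothetical(x$sentence, x$pair, rules), "fail")

  y <- first_pair("anxiety increased")
  expect_equal(check_hypothetical(y$sentence, y$pair, rules), "pass")

  z <- first_pair("anxiety possibly increased")
  expect_equal(check_hypothetical(z$sentence, z$pair, rules), "fail")
})

test_that("linkage check demands a clause-internal dependency path", {
  x <- first_pair("anxiety symptoms increased")
  expect_equal(check_change_concerns_theme(x$sentence, x$pair), "pass")

  y <- first_pair(
    "We increased the medication doses but the patient's anxiety did not respond"
  )
  expect_equal(check_change_concerns_theme(y$sentence, y$pair), "fail")

  z <- first_pair("more anxiety")
  expect_equal(check_change_concerns_theme(z$sentence, z$pair), "pass")
})

test_that("linkage falls back to a token window without dependencies", {
  cfg <- pipeline_config()
  x <- first_pair("anxiety very clearly increased")
  x$sentence$tokens$head <- NA_integer_
  expect_equal(check_change_concerns_theme(x$sentence, x$pair, cfg), "pass")

  # same sentence, window too narrow for the two-token gap
  tight <- pipeline_config(fallback_window = 1L)
  expect_equal(check_change_concerns_theme(x$sentence, x$pair, tight), "fail")

  # clause delimiter followed by a finite verb blocks the fallback link
  y <- first_pair("We increased doses but anxiety did not respond")
  y$sentence$tokens$head <- NA_integer_
  expect_equal(check_change_concerns_theme(y$sentence, y$pair, cfg), "fail")
})

test_that("acceptance is the conjunction of the five checks", {
  combine_checks <- getFromNamespace("combine_checks", "clinchange")
  combos <- expand.grid(
    current = c("pass", "fail"), not_hypothetical = c("pass", "fail"),
    concerns_patient = c("pass", "fail"), not_negated = c("pass", "fail"),
    change_concerns_theme = c("pass", "fail"), stringsAsFactors = FALSE
  )
  expect_equal(nrow(combos), 32L)
  for (i in seq_len(nrow(combos))) {
    checks <- unlist(combos[i, ])
    expect_identical(combine_checks(checks), all(checks == "pass"))
  }

  # integration: one failing check is enough to reject
  rules <- mini_rules()
  x <- first_pair("mood did not improve")
  v <- apply_context_filter(x$sentence, x$pairs, rules)
  expect_false(v$accepted[[1]])
  expect_false(v$not_negated[[1]])
  expect_true(all(v[1, c(
    "current", "not_hypothetical", "concerns_patient", "change_concerns_theme"
  )] == TRUE))

  y <- first_pair("mood improved")
  vy <- apply_context_filter(y$sentence, y$pairs, rules)
  expect_true(vy$accepted[[1]])

  # vacuous case
  empty <- apply_context_filter(y$sentence, y$pairs[0, ], rules)
  expect_equal(nrow(empty), 0L)
  expect_true("accepted" %in% names(empty))
})

test_that("an empty rule set passes every trigger-based check", {
  no_rules <- context_rules()
  texts <- c(
    "mood did not improve", "if anxiety increases, call us",
    "Mother reports more anxiety", "Years ago anxiety increased"
  )
  for (txt in texts) {
    x <- first_pair(txt, lex = mini_lexicon())
    if (!nrow(x$pairs)) next
    v <- apply_context_filter(x$sentence, x$pairs, no_rules)
    expect_true(all(v$current & v$not_hypothetical &
      v$concerns_patient & v$not_negated))
    # only the linkage check can still reject
    expect_identical(v$accepted, v$change_concerns_theme)
  }
})

test_that("verdicts are independent across pairs in a sentence", {
  rules <- mini_rules()
  lex <- mini_lexicon()
  s <- one_sentence("more interaction but mood did not improve")
  pairs <- pair_candidates(theme_filter(s, lex), change_filter(s, lex))
  v <- apply_context_filter(s, pairs, rules)
  for (i in seq_len(nrow(pairs))) {
    vi <- apply_context_filter(s, pairs[i, ], rules)
    expect_identical(vi$accepted, v$accepted[[i]])
  }
})

test_that("rule files parse and validate", {
  rules <- default_fixture_rules()
  expect_s3_class(rules, "clin_context_rules")
  expect_true(all(rules$kind %in% c(
    "negation", "hypothetical", "non-patient-experiencer", "non-current"
  )))
  nl <- read_context_rules(system.file("extdata", "context_rules_nl.tsv",
    package = "clinchange"
  ))
  expect_gt(nrow(nl), 0L)

  expect_error(
    context_rules(data.frame(
      trigger = "x", kind = "bogus", scope = "forward", window = "sentence"
    )),
    "kind"
  )
  expect_error(
    context_rules(data.frame(
      trigger = "x", kind = "negation", scope = "forward", window = "0"
    )),
    "window"
  )
})
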