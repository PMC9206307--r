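score_for <- function(text, lex, theme = NULL, rules = context_rules()) {
  res <- run_pipeline(make_note(text), lex, rules)
  sc <- res$sentence_scores
  if (!is.null(theme)) sc <- sc[sc$theme == theme, ]
  sc$score
}

test_that("sentence scores multiply polarity by direction and add", {
  lex <- mini_lexicon()
  expect_identical(score_for("more anxiety", lex, "symptoms"), -1L)
  expect_identical(score_for("participation improved", lex, "social"), 1L)
  expect_identical(
    score_for("The patient was more anxious and sad", lex, "symptoms"), -2L
  )
  expect_identical(score_for("less energy", lex, "wellbeing"), -1L)
  # no accepted pair -> no score row at all
  expect_length(score_for("anxiety persists unchanged today", lex), 0L)
})

test_that("aggregation takes the mean over passing sentences only", {
  scores <- tibble::tibble(
    patient_id = "P1", trajectory_id = "T1",
    note_id = c("N1", "N2", "N3"), sentence_index = 1L,
    theme = "symptoms", score = c(-2L, 1L, 2L), n_pairs = 1L
  )
  agg <- aggregate_scores(scores, "patient")
  expect_equal(agg$mean_sentiment, 1 / 3)
  expect_equal(agg$n_change_sentences, 3L)

  empty <- aggregate_scores(scores[0, ], "patient")
  expect_equal(nrow(empty), 0L)

  const <- aggregate_scores(
    tibble::tibble(
      patient_id = "P1", trajectory_id = "T1", note_id = c("N1", "N2"),
      sentence_index = 1L, theme = "symptoms", score = c(-1L, -1L),
      n_pairs = 1L
    ),
    "trajectory"
  )
  expect_equal(const$mean_sentiment, -1)

  # undefined means stay missing, never zero
  ts <- tibble::tibble(
    key_id = c("P1", "P2"), theme = "symptoms",
    n_theme_sentences = c(3L, 5L)
  )
  agg2 <- aggregate_scores(scores, "patient", theme_sentences = ts)
  expect_true(is.na(agg2$mean_sentiment[agg2$key_id == "P2"]))
  expect_equal(agg2$n_change_sentences[agg2$key_id == "P2"], 0L)

  # one trajectory shared by two patients is a key error
  bad <- scores
  bad$patient_id <- c("P1", "P2", "P1")
  expect_error(aggregate_scores(bad, "trajectory"), "more than one")
})

test_that("the three-sentence walkthrough traces stage by stage", {
  lex <- mini_lexicon()
  rules <- mini_rules()
  note <- make_note(paste(
    "Patient is still anxious.",
    "Participation improved since admission.",
    "Mood did not improve."
  ))
  res <- run_pipeline(note, lex, rules)
  tr <- res$trace$sentence_trace
  expect_equal(
    tr$stage[tr$sentence_index == 1 & tr$theme == "symptoms"],
    "cancelled_step3"
  )
  expect_equal(
    tr$stage[tr$sentence_index == 3 & tr$theme == "wellbeing"],
    "rejected_step4"
  )
  expect_equal(
    tr$stage[tr$sentence_index == 2 & tr$theme == "social"],
    "scored"
  )
  expect_equal(nrow(res$sentence_scores), 1L)
  expect_equal(res$sentence_scores$score, 1L)
  counts <- res$trace$stage_counts
  expect_equal(counts$n_sentences, rep(3L, length(lexicon_themes(lex))))
  expect_equal(counts$n_scored[counts$theme == "social"], 1L)
  expect_equal(counts$n_change[counts$theme == "symptoms"], 0L)

  # empty input
  empty <- run_pipeline(make_note("placeholder")[0, ], lex, rules)
  expect_equal(nrow(empty$sentence_scores), 0L)
  expect_equal(nrow(empty$summaries), 0L)
})

test_that("scores obey conservation, sign-flip and permutation invariance", {
  lex <- default_fixture_lexicon()
  rules <- default_fixture_rules()
  corpus <- generate_corpus(generator_config(n_patients = 8, seed = 31))
  res <- run_pipeline(corpus$notes, lex, rules)

  # conservation: sum over units of mean * n equals total score, per theme
  for (th in unique(res$sentence_scores$theme)) {
    tot <- sum(res$sentence_scores$score[res$sentence_scores$theme == th])
    sm <- res$summaries[res$summaries$key == "trajectory" &
      res$summaries$theme == th & res$summaries$n_change_sentences > 0, ]
    expect_equal(sum(sm$mean_sentiment * sm$n_change_sentences), tot)
  }

  # sign flip: negating theme polarities negates all scores and means
  flipped_df <- tibble::as_tibble(lex)[, c("phrase", "category", "polarity", "match_mode")]
  flipped_df$polarity <- ifelse(
    flipped_df$category == "change", flipped_df$polarity, -flipped_df$polarity
  )
  res_flip <- run_pipeline(corpus$notes, lexicon(flipped_df), rules)
  a <- res$sentence_scores[order(
    res$sentence_scores$note_id, res$sentence_scores$sentence_index,
    res$sentence_scores$theme
  ), ]
  b <- res_flip$sentence_scores[order(
    res_flip$sentence_scores$note_id, res_flip$sentence_scores$sentence_index,
    res_flip$sentence_scores$theme
  ), ]
  expect_equal(nrow(a), nrow(b))
  expect_identical(a$score, -b$score)
  sa <- res$summaries[order(res$summaries$key, res$summaries$key_id, res$summaries$theme), ]
  sb <- res_flip$summaries[order(res_flip$summaries$key, res_flip$summaries$key_id, res_flip$summaries$theme), ]
  expect_equal(sa$mean_sentiment, -sb$mean_sentiment)

  # permutation invariance: shuffled notes give the same summaries
  withr::with_seed(5, {
    perm <- sample.int(nrow(corpus$notes))
  })
  res_perm <- run_pipeline(corpus$notes[perm, ], lex, rules)
  sp <- res_perm$summaries[order(
    res_perm$summaries$key, res_perm$summaries$key_id, res_perm$summaries$theme
  ), ]
  expect_equal(as.data.frame(sa), as.data.frame(sp))
})

test_that("pipeline scores match the brute-force enumerator on small corpora", {
  lex <- default_fixture_lexicon()
  rules <- default_fixture_rules()
  cfg <- pipeline_config()
  for (seed in 1:20) {
    corpus <- generate_corpus(generator_config(
      n_patients = 2, notes_per_patient = c(1L, 3L),
      sentences_per_note = c(2L, 6L),
      p_theme = 0.4, p_change_given_theme = 0.5, seed = 1000 + seed
    ))
    res <- run_pipeline(corpus$notes, lex, rules, cfg)
    got <- res$sentence_scores[order(
      res$sentence_scores$note_id, res$sentence_scores$sentence_index,
      res$sentence_scores$theme
    ), c("note_id", "sentence_index", "theme", "score")]
    want <- naive_pipeline_scores(corpus$notes, lex, rules, cfg)
    expect_equal(
      as.data.frame(got),
      want[, c("note_id", "sentence_index", "theme", "score")],
      ignore_attr = TRUE
    )
  }
})
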