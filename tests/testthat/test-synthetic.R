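test_that("generation is deterministic in the seed", {
  a <- generate_corpus(generator_config(n_patients = 4, seed = 123))
  b <- generate_corpus(generator_config(n_patients = 4, seed = 123))
  expect_identical(a, b)
  c <- generate_corpus(generator_config(n_patients = 4, seed = 124))
  expect_false(identical(a$notes$text, c$notes$text))
})

test_that("degenerate configurations label every sentence as promised", {
  # no corruptions, theme and change everywhere -> all accept
  cfg <- generator_config(
    n_patients = 3, p_theme = 1, p_change_given_theme = 1,
    p_negation = 0, p_hypothetical = 0, p_nonpatient = 0, p_history = 0,
    p_repetition = 0, seed = 5
  )
  corpus <- generate_corpus(cfg)
  expect_true(all(corpus$truth$label == "accept"))

  # no change cues -> everything rejected
  cfg2 <- generator_config(
    n_patients = 3, p_theme = 1, p_change_given_theme = 0,
    p_repetition = 0, seed = 5
  )
  corpus2 <- generate_corpus(cfg2)
  expect_true(all(corpus2$truth$label == "reject"))
  res2 <- run_pipeline(
    corpus2$notes, default_fixture_lexicon(), default_fixture_rules()
  )
  expect_equal(nrow(res2$sentence_scores), 0L)
  expect_true(all(res2$trace$sentence_trace$stage %in%
    c("no_theme", "cancelled_step3")))

  # invalid configurations are refused
  expect_error(generator_config(p_theme = 1.2), "\\[0, 1\\]")
  expect_error(
    generator_config(p_negation = 0.6, p_hypothetical = 0.6),
    "sum"
  )
  expect_error(generator_config(n_patients = 0), ">= 1")
})

test_that("expected_summaries equals an independent group-by of the truth", {
  corpus <- generate_corpus(generator_config(
    n_patients = 6, p_change_given_theme = 0.4, seed = 88
  ))
  for (key in c("trajectory", "patient")) {
    got <- expected_summaries(corpus$truth, key)
    key_col <- paste0(key, "_id")
    acc <- corpus$truth[corpus$truth$label == "accept", ]
    for (i in seq_len(nrow(got))) {
      kid <- got$key_id[[i]]
      th <- got$theme[[i]]
      sub <- acc[acc[[key_col]] == kid & acc$theme == th, ]
      present <- corpus$truth[corpus$truth[[key_col]] == kid &
        corpus$truth$theme == th & corpus$truth$has_theme, ]
      expect_equal(got$n_theme_sentences[[i]], nrow(present))
      expect_equal(got$n_change_sentences[[i]], nrow(sub))
      if (nrow(sub)) {
        expect_equal(got$mean_sentiment[[i]], mean(sub$expected_score))
      } else {
        expect_true(is.na(got$mean_sentiment[[i]]))
      }
    }
  }

  # the worked three-sentence mean: scores -2, 1, 2 average to 1/3
  truth <- tibble::tibble(
    patient_id = "P1", trajectory_id = "T1", note_id = c("N1", "N2", "N3"),
    sentence_index = 1L, text = "t", theme = "symptoms",
    has_theme = TRUE, has_change = TRUE, corruption = NA_character_,
    label = "accept", expected_score = c(-2L, 1L, 2L)
  )
  expect_equal(expected_summaries(truth, "patient")$mean_sentiment, 1 / 3)
})

test_that("the pipeline recovers the constructed ground truth exactly", {
  lex <- default_fixture_lexicon()
  rules <- default_fixture_rules()
  corpus <- generate_corpus(generator_config(
    n_patients = 12, p_change_given_theme = 0.3, seed = 2024
  ))
  rep_ <- evaluate(corpus$labels, lex, rules)
  expect_true(all(rep_$accuracy == 1))
  expect_true(all(rep_$precision[!is.na(rep_$precision)] == 1))
  expect_true(all(rep_$recall[!is.na(rep_$recall)] == 1))

  # per-stage counts: pipeline rejections equal injected corruption counts
  res <- run_pipeline(corpus$notes, lex, rules)
  tr <- res$trace$sentence_trace
  for (th in lexicon_themes(lex)) {
    truth_th <- corpus$truth[corpus$truth$theme == th, ]
    tr_th <- tr[tr$theme == th, ]
    expect_equal(sum(tr_th$stage != "no_theme"), sum(truth_th$has_theme))
    expect_equal(
      sum(tr_th$stage == "cancelled_step3"),
      sum(truth_th$has_theme & !truth_th$has_change)
    )
    expect_equal(
      sum(tr_th$stage == "rejected_step4"),
      sum(!is.na(truth_th$corruption))
    )
    expect_equal(sum(tr_th$stage == "scored"), sum(truth_th$label == "accept"))
  }

  # summaries equal the analytic oracle
  for (key in c("trajectory", "patient")) {
    want <- expected_summaries(corpus$truth, key)
    got <- res$summaries[res$summaries$key == key, ]
    expect_equal(as.data.frame(got), as.data.frame(want), tolerance = 1e-12)
  }
})

test_that("removing a lexicon entry lowers recall but never precision", {
  lex <- default_fixture_lexicon()
  rules <- default_fixture_rules()
  corpus <- generate_corpus(generator_config(
    n_patients = 12, p_change_given_theme = 0.35, seed = 303
  ))
  # drop one theme word that the corpus actually uses in an accepted sentence
  acc <- corpus$truth[corpus$truth$label == "accept" &
    corpus$truth$theme == "symptoms", ]
  expect_gt(nrow(acc), 0L)
  used <- NULL
  for (w in c("anxiety", "sadness", "anger", "agitation", "calmness")) {
    if (any(grepl(paste0("\\b", w, "\\b"), acc$text))) {
      used <- w
      break
    }
  }
  expect_false(is.null(used))
  df <- tibble::as_tibble(lex)[, c("phrase", "category", "polarity", "match_mode")]
  pruned <- lexicon(df[df$phrase != used, ])
  full_rep <- evaluate(corpus$labels, lex, rules)
  prun_rep <- evaluate(corpus$labels, pruned, rules)
  full_sym <- full_rep[full_rep$theme == "symptoms", ]
  prun_sym <- prun_rep[prun_rep$theme == "symptoms", ]
  expect_lt(prun_sym$recall, full_sym$recall)
  expect_equal(prun_sym$precision, 1)
})

test_that("empirical theme rates converge to p_theme on large corpora", {
  p <- 0.18
  cfg <- generator_config(
    n_patients = 150, notes_per_patient = c(4L, 4L),
    sentences_per_note = c(5L, 5L), p_theme = p, p_repetition = 0, seed = 606
  )
  corpus <- generate_corpus(cfg)
  n_sent <- nrow(corpus$truth) / length(unique(corpus$truth$theme))
  expect_gte(n_sent, 1000)
  for (th in unique(corpus$truth$theme)) {
    sub <- corpus$truth[corpus$truth$theme == th, ]
    rate <- mean(sub$has_theme)
    se <- sqrt(p * (1 - p) / nrow(sub))
    expect_lt(abs(rate - p), 3 * se + 1e-9)
  }
})
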