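#' Configuration for the synthetic corpus generator
#'
#' Controls the statistical structure of generated corpora: how many patients
#' and notes, how often sentences mention a theme, how often a theme mention
#' comes with a change cue, and how often a theme+change sentence is wrapped
#' in a corrupting context (negation, hypothetical, non-patient experiencer,
#' history). The defaults emulate the structure of real inpatient corpora:
#' theme mentions are frequent but change sentences are sparse (an order of
#' magnitude rarer than theme sentences), and repeated status sentences
#' recur across consecutive notes.
#'
#' Corruption probabilities are conditional on a sentence containing both a
#' theme phrase and a change cue; their sum must not exceed 1.
#'
#' @param n_patients Number of patients.
#' @param notes_per_patient Integer range `c(min, max)` of notes per
#'   trajectory.
#' @param sentences_per_note Integer range `c(min, max)` of sentences per
#'   note.
#' @param p_theme Probability that a sentence mentions a given theme
#'   (independently per theme).
#' @param p_change_given_theme Probability that a theme-mentioning sentence
#'   carries a change cue.
#' @param p_negation,p_hypothetical,p_nonpatient,p_history Probabilities of
#'   each context corruption, conditional on theme + change.
#' @param polarity_mix Proportion of injected theme phrases drawn from the
#'   positive-polarity pool.
#' @param p_repetition Probability that a sentence slot repeats the
#'   trajectory's fixed status sentence (a theme mention without change).
#' @param p_two_trajectories Probability that a patient has two admission
#'   trajectories instead of one.
#' @param seed Integer seed; a fixed seed yields a byte-identical corpus.
#' @return A `clin_generator_config` list.
#' @export
generator_config <- function(n_patients = 20L,
                             notes_per_patient = c(2L, 5L),
                             sentences_per_note = c(4L, 10L),
                             p_theme = 0.18,
                             p_change_given_theme = 0.12,
                             p_negation = 0.12,
                             p_hypothetical = 0.05,
                             p_nonpatient = 0.07,
                             p_history = 0.06,
                             polarity_mix = 0.5,
                             p_repetition = 0.10,
                             p_two_trajectories = 0.2,
                             seed = 1L) {
  probs <- c(
    p_theme, p_change_given_theme, p_negation, p_hypothetical,
    p_nonpatient, p_history, polarity_mix, p_repetition, p_two_trajectories
  )
  if (any(probs < 0 | probs > 1)) {
    abort("all generator probabilities must lie in [0, 1]")
  }
  corruption_total <- p_negation + p_hypothetical + p_nonpatient + p_history
  if (corruption_total > 1) {
    abort("corruption probabilities must sum to at most 1")
  }
  if (n_patients < 1L || any(notes_per_patient < 1L) ||
    any(sentences_per_note < 1L)) {
    abort("generator counts must be >= 1")
  }
  structure(
    list(
      n_patients = as.integer(n_patients),
      notes_per_patient = as.integer(notes_per_patient),
      sentences_per_note = as.integer(sentences_per_note),
      p_theme = p_theme,
      p_change_given_theme = p_change_given_theme,
      p_negation = p_negation,
      p_hypothetical = p_hypothetical,
      p_nonpatient = p_nonpatient,
      p_history = p_history,
      polarity_mix = polarity_mix,
      p_repetition = p_repetition,
      p_two_trajectories = p_two_trajectories,
      seed = as.integer(seed)
    ),
    class = "clin_generator_config"
  )
}

# Language-parameterised sentence templates. Wrapper triggers must exist in
# the rule file handed to generate(); comparative cues must be comparatives
# under the profile and absent from the lexicon.
generator_templates <- function(language = "en") {
  if (language != "en") {
    abort("only the English template set ships with the package")
  }
  list(
    comparative_cues = c("stronger", "higher", "clearer"),
    quantifiers = c("more", "less", "fewer"),
    theme_only = c("Patient shows %s.", "Still %s during the day.", "Observed %s on the ward."),
    status = "Patient still shows %s.",
    wrappers = list(
      negation = list(fmt = "No %s.", trigger = "no", kind = "negation"),
      hypothetical = list(fmt = "If %s, call us.", trigger = "if", kind = "hypothetical"),
      nonpatient = list(
        fmt = "Mother reports %s.", trigger = "mother",
        kind = "non-patient-experiencer"
      ),
      history = list(
        fmt = "Years ago %s.", trigger = "years ago",
        kind = "non-current"
      )
    ),
    distractors = c(
      "Routine observations on the ward.",
      "Vital signs recorded.",
      "Medication administered as planned.",
      "Attended the group session.",
      "Ate lunch in the dining room.",
      "Slept through the night."
    )
  )
}

cap_first <- function(x) {
  paste0(toupper(substr(x, 1, 1)), substr(x, 2, nchar(x)))
}

#' Generate a synthetic annotated clinical-note corpus
#'
#' Builds notes from templates whose behaviour under the supplied fixture
#' lexicon, rules and annotator profile is unambiguous: every theme and
#' change phrase used is in the lexicon, every corruption wrapper's trigger
#' is in the rule file, and accepted constructions keep the theme and change
#' cue adjacent inside one clause. Ground truth (per sentence, per theme:
#' accept/reject label, expected score, injected corruption) is computed
#' constructively at generation time — never by running the pipeline — so it
#' can serve as an independent oracle for end-to-end validation.
#'
#' @param config A [generator_config()].
#' @param lex Fixture lexicon; defaults to the English lexicon shipped under
#'   `extdata`.
#' @param rules Fixture context rules; defaults to the shipped English set.
#' @param profile The annotator [language_profile()] the corpus targets.
#' @return A list with elements `notes` (tibble), `truth` (tibble with one
#'   row per sentence x theme: ids, `sentence_index`, `text`, `has_theme`,
#'   `has_change`, `corruption`, `label`, `expected_score`) and `labels`
#'   (the `text`/`theme`/`label` columns of `truth`, ready for
#'   [evaluate()]).
#' @export
#' @examples
#' corpus <- generate_corpus(generator_config(n_patients = 2, seed = 7))
#' head(corpus$truth)
generate_corpus <- function(config = generator_config(),
                            lex = default_fixture_lexicon(),
                            rules = default_fixture_rules(),
                            profile = language_profile("en")) {
  tpl <- generator_templates(profile$language)
  vocab <- generator_vocabulary(lex, rules, tpl, profile)
  withr::with_seed(config$seed, generate_corpus_impl(config, tpl, vocab, lex))
}

generator_vocabulary <- function(lex, rules, tpl, profile) {
  th <- theme_entries(lex)
  th <- th[lengths(th$phrase_tokens) == 1L & th$match_mode == "exact-token", ]
  ch <- change_entries(lex)
  ch <- ch[lengths(ch$phrase_tokens) == 1L & ch$match_mode == "exact-token", ]
  if (!nrow(th) || !nrow(ch)) {
    abort("fixture lexicon must contain single-token theme and change entries")
  }
  if (anyDuplicated(th$phrase)) {
    abort("generator requires theme phrases to be unique across themes")
  }
  static_words <- fold_text(unlist(lapply(
    c(tpl$theme_only, tpl$status, tpl$distractors,
      vapply(tpl$wrappers, function(w) w$fmt, character(1))),
    function(s) tokenize_text(s)$surface
  )))
  clash2 <- intersect(static_words, c(th$phrase, ch$phrase))
  if (length(clash2)) {
    abort(sprintf(
      "template scaffolding words collide with lexicon phrases: %s",
      paste(clash2, collapse = ", ")
    ))
  }
  trigger_words <- unique(unlist(rules$trigger_tokens))
  clash <- intersect(c(th$phrase, ch$phrase), trigger_words)
  if (length(clash)) {
    abort(sprintf(
      "lexicon phrases collide with rule triggers: %s",
      paste(clash, collapse = ", ")
    ))
  }
  ch_pos <- vapply(ch$phrase, pos_tag_one, character(1),
    profile = profile, USE.NAMES = FALSE
  )
  ch$style <- ifelse(
    ch$phrase %in% tpl$quantifiers, "quant",
    ifelse(ch_pos %in% c("VERB", "AUX"), "verb", NA_character_)
  )
  ch <- ch[!is.na(ch$style), ] # only cues the templates can realise
  if (!nrow(ch)) abort("no template-compatible change entries in lexicon")
  comp <- tpl$comparative_cues
  comp_ok <- vapply(comp, function(w) {
    degree_one(w, "ADJ", profile) == "comparative" &&
      !w %in% c(th$phrase, ch$phrase, trigger_words)
  }, logical(1))
  comp <- comp[comp_ok]
  if (!length(comp)) {
    abort("no usable comparative cue under the supplied profile/lexicon")
  }
  for (w in names(tpl$wrappers)) {
    wr <- tpl$wrappers[[w]]
    ok <- any(rules$trigger == wr$trigger & rules$kind == wr$kind)
    if (!ok) {
      abort(sprintf(
        "corruption template '%s' needs rule trigger '%s' (%s)",
        w, wr$trigger, wr$kind
      ))
    }
  }
  list(themes = th, changes = ch, comparatives = comp)
}

generate_corpus_impl <- function(config, tpl, vocab, lex) {
  all_themes <- lexicon_themes(lex)
  th <- vocab$themes
  ch <- vocab$changes
  corr_kinds <- c("negation", "hypothetical", "nonpatient", "history")
  corr_p <- c(
    config$p_negation, config$p_hypothetical,
    config$p_nonpatient, config$p_history
  )
  pick_theme_entry <- function(theme) {
    pool <- th[th$theme == theme, ]
    pos_pool <- pool[pool$polarity == 1L, ]
    neg_pool <- pool[pool$polarity == -1L, ]
    use_pos <- runif(1) < config$polarity_mix
    chosen <- if (use_pos && nrow(pos_pool)) {
      pos_pool
    } else if (!use_pos && nrow(neg_pool)) {
      neg_pool
    } else {
      pool
    }
    chosen[sample.int(nrow(chosen), 1L), ]
  }
  notes_rows <- list()
  truth_rows <- list()
  note_counter <- 0L
  for (p in seq_len(config$n_patients)) {
    patient_id <- sprintf("P%03d", p)
    n_traj <- if (runif(1) < config$p_two_trajectories) 2L else 1L
    date0 <- as.Date("2020-01-01") + (p - 1L) * 30L
    for (tr in seq_len(n_traj)) {
      trajectory_id <- sprintf("%s-T%d", patient_id, tr)
      status_entry <- th[sample.int(nrow(th), 1L), ]
      status_text <- cap_first(sprintf(tpl$status, status_entry$phrase))
      n_notes <- sample.int(
        config$notes_per_patient[2] - config$notes_per_patient[1] + 1L, 1L
      ) + config$notes_per_patient[1] - 1L
      for (nn in seq_len(n_notes)) {
        note_counter <- note_counter + 1L
        note_id <- sprintf("N%05d", note_counter)
        n_sent <- sample.int(
          config$sentences_per_note[2] - config$sentences_per_note[1] + 1L, 1L
        ) + config$sentences_per_note[1] - 1L
        sent_texts <- character(n_sent)
        for (si in seq_len(n_sent)) {
          made <- make_sentence(
            config, tpl, vocab, all_themes, pick_theme_entry,
            status_entry, status_text, corr_kinds, corr_p
          )
          sent_texts[[si]] <- made$text
          tr_row <- made$truth
          tr_row$patient_id <- patient_id
          tr_row$trajectory_id <- trajectory_id
          tr_row$note_id <- note_id
          tr_row$sentence_index <- si
          truth_rows[[length(truth_rows) + 1L]] <- tr_row
        }
        notes_rows[[length(notes_rows) + 1L]] <- tibble::tibble(
          patient_id = patient_id, trajectory_id = trajectory_id,
          note_id = note_id,
          date = date0 + (tr - 1L) * 60L + nn - 1L,
          text = paste(sent_texts, collapse = " ")
        )
      }
    }
  }
  notes <- dplyr::bind_rows(notes_rows)
  truth <- dplyr::bind_rows(truth_rows)
  truth <- truth[, c(
    "patient_id", "trajectory_id", "note_id", "sentence_index", "text",
    "theme", "has_theme", "has_change", "corruption", "label", "expected_score"
  )]
  list(
    notes = notes,
    truth = truth,
    labels = truth[, c("text", "theme", "label")]
  )
}

make_sentence <- function(config, tpl, vocab, all_themes, pick_theme_entry,
                          status_entry, status_text, corr_kinds, corr_p) {
  blank_truth <- function(text, themes_present = character(),
                          has_change = FALSE, corruption = NA_character_,
                          scores = NULL) {
    present <- all_themes %in% themes_present
    changed <- has_change & present
    clean <- is.na(corruption)
    expected <- vapply(all_themes, function(t) {
      if (!is.null(scores) && t %in% names(scores) && clean) {
        scores[[t]]
      } else {
        NA_integer_
      }
    }, integer(1))
    tibble::tibble(
      text = text,
      theme = all_themes,
      has_theme = present,
      has_change = changed,
      corruption = ifelse(changed, corruption, NA_character_),
      label = ifelse(changed & clean, "accept", "reject"),
      expected_score = unname(expected)
    )
  }
  if (runif(1) < config$p_repetition) {
    return(list(
      text = status_text,
      truth = blank_truth(status_text, status_entry$theme)
    ))
  }
  present <- all_themes[runif(length(all_themes)) < config$p_theme]
  if (!length(present)) {
    text <- sample(tpl$distractors, 1L)
    return(list(text = text, truth = blank_truth(text)))
  }
  entries <- lapply(present, pick_theme_entry)
  names(entries) <- present
  has_change <- runif(1) < config$p_change_given_theme
  if (!has_change) {
    frame <- sample(tpl$theme_only, 1L)
    listed <- paste(
      vapply(entries, function(e) e$phrase, character(1)),
      collapse = " and "
    )
    text <- cap_first(sprintf(frame, listed))
    return(list(text = text, truth = blank_truth(text, present)))
  }
  use_comp <- length(present) == 1L && runif(1) < 0.25
  scores <- integer()
  segs <- character()
  for (t in present) {
    e <- entries[[t]]
    if (use_comp) {
      cue <- sample(vocab$comparatives, 1L)
      segs <- c(segs, paste0(e$phrase, " seems ", cue))
      scores[[t]] <- e$polarity * 1L
    } else {
      crow <- vocab$changes[sample.int(nrow(vocab$changes), 1L), ]
      seg <- if (crow$style == "quant") {
        paste(crow$phrase, e$phrase)
      } else {
        paste(e$phrase, crow$phrase)
      }
      segs <- c(segs, seg)
      scores[[t]] <- e$polarity * crow$polarity
    }
  }
  core <- paste(segs, collapse = " and ")
  u <- runif(1)
  cum <- cumsum(corr_p)
  corruption <- NA_character_
  for (k in seq_along(corr_kinds)) {
    if (u < cum[[k]]) {
      corruption <- corr_kinds[[k]]
      break
    }
  }
  text <- if (is.na(corruption)) {
    cap_first(paste0(core, "."))
  } else {
    sprintf(tpl$wrappers[[corruption]]$fmt, core)
  }
  list(
    text = text,
    truth = blank_truth(text, present, TRUE, corruption, scores)
  )
}

#' Analytic summaries from generator ground truth
#'
#' Computes the patient- or trajectory-level theme summaries directly from a
#' generated corpus's ground-truth table — an independent group-by over the
#' constructed labels and expected scores, used to assert that
#' [run_pipeline()] reproduces them.
#'
#' @param truth The `truth` tibble from [generate_corpus()].
#' @param key `"trajectory"` or `"patient"`.
#' @return A tibble shaped like the [aggregate_scores()] output.
#' @export
expected_summaries <- function(truth, key = c("trajectory", "patient")) {
  key <- match.arg(key)
  key_col <- paste0(key, "_id")
  grp <- dplyr::group_by(truth, .data[[key_col]], .data$theme)
  agg <- dplyr::summarise(grp,
    n_theme_sentences = sum(.data$has_theme),
    n_change_sentences = sum(.data$label == "accept"),
    mean_sentiment = ifelse(
      sum(.data$label == "accept") > 0,
      sum(.data$expected_score[.data$label == "accept"]) /
        sum(.data$label == "accept"),
      NA_real_
    ),
    .groups = "drop"
  )
  agg <- agg[agg$n_theme_sentences > 0L | agg$n_change_sentences > 0L, ]
  names(agg)[names(agg) == key_col] <- "key_id"
  out <- tibble::tibble(
    key = key, key_id = agg$key_id, theme = agg$theme,
    n_theme_sentences = as.integer(agg$n_theme_sentences),
    n_change_sentences = as.integer(agg$n_change_sentences),
    mean_sentiment = agg$mean_sentiment
  )
  out[order(out$key_id, out$theme), ]
}

#' Shipped English fixture lexicon and context rules
#'
#' Small English phrase inventories used by the synthetic generator, the
#' examples and the test suite. They are synthetic fixtures written for this
#' package, not a published clinical phrase list.
#'
#' @return A `clin_lexicon` / `clin_context_rules`.
#' @export
default_fixture_lexicon <- function() {
  read_lexicon(system.file("extdata", "lexicon_en.tsv",
    package = "clinchange", mustWork = TRUE
  ))
}

#' @rdname default_fixture_lexicon
#' @export
default_fixture_rules <- function() {
  read_context_rules(system.file("extdata", "context_rules_en.tsv",
    package = "clinchange", mustWork = TRUE
  ))
}
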