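#' Score a sentence from its context verdicts (pipeline step 5)
#'
#' Each accepted pair contributes the product of its theme polarity and its
#' change direction; per theme, the contributions are added. "More anxiety"
#' (-1 x +1) scores -1, "participation improved" (+1 x +1) scores +1, and
#' "The patient was more anxious and sad" (-1 x +1 twice) scores -2. Themes
#' with no accepted pair emit nothing.
#'
#' @param verdicts Output of [apply_context_filter()] for one sentence.
#' @return A tibble with one row per theme holding at least one accepted
#'   pair: `theme`, `score` (integer), `n_pairs`.
#' @export
score_sentence <- function(verdicts) {
  acc <- verdicts[verdicts$accepted, , drop = FALSE]
  if (!nrow(acc)) {
    return(tibble::tibble(
      theme = character(), score = integer(), n_pairs = integer()
    ))
  }
  contrib <- acc$theme_polarity * acc$change_direction
  agg <- tapply(contrib, acc$theme, sum)
  npair <- tapply(contrib, acc$theme, length)
  tibble::tibble(
    theme = names(agg),
    score = as.integer(agg),
    n_pairs = as.integer(npair)
  )
}

#' Aggregate sentence scores to patient or trajectory summaries
#'
#' The summary score for a grouping unit and theme is the mean sentiment over
#' all sentences that passed the filters for that unit: e.g. sentence scores
#' \{-2, 1, 2\} give a mean of 1/3. When no sentence passed, the mean is
#' undefined and reported as `NA` — never coerced to 0, which would fake a
#' neutral observation.
#'
#' @param scores A tibble of sentence scores carrying `patient_id`,
#'   `trajectory_id`, `theme`, `score` columns (as emitted by
#'   [run_pipeline()]).
#' @param key `"trajectory"` or `"patient"`.
#' @param theme_sentences Optional tibble (`key_id`, `theme`,
#'   `n_theme_sentences`) counting sentences containing any phrase of the
#'   theme per unit, used to fill the `n_theme_sentences` column and to emit
#'   undefined-mean rows for units whose theme sentences never passed the
#'   change/context filters.
#' @return A tibble with columns `key`, `key_id`, `theme`,
#'   `n_theme_sentences`, `n_change_sentences`, `mean_sentiment`.
#' @export
aggregate_scores <- function(scores, key = c("trajectory", "patient"),
                             theme_sentences = NULL) {
  key <- match.arg(key)
  key_col <- paste0(key, "_id")
  if (nrow(scores)) {
    if (!key_col %in% names(scores)) {
      abort(sprintf("scores must carry a '%s' column", key_col))
    }
    mixed <- unique(scores[, c("patient_id", "trajectory_id")])
    if (anyDuplicated(mixed$trajectory_id) && key == "trajectory") {
      abort("a trajectory_id maps to more than one patient_id")
    }
    grp <- dplyr::group_by(scores, .data[[key_col]], .data$theme)
    agg <- dplyr::summarise(grp,
      n_change_sentences = dplyr::n(),
      mean_sentiment = sum(.data$score) / dplyr::n(),
      .groups = "drop"
    )
    names(agg)[names(agg) == key_col] <- "key_id"
  } else {
    agg <- tibble::tibble(
      key_id = character(), theme = character(),
      n_change_sentences = integer(), mean_sentiment = double()
    )
  }
  if (!is.null(theme_sentences)) {
    agg <- dplyr::full_join(theme_sentences, agg, by = c("key_id", "theme"))
    agg$n_change_sentences[is.na(agg$n_change_sentences)] <- 0L
    agg$n_theme_sentences[is.na(agg$n_theme_sentences)] <- 0L
  } else {
    agg$n_theme_sentences <- NA_integer_
  }
  out <- tibble::tibble(
    key = key,
    key_id = agg$key_id,
    theme = agg$theme,
    n_theme_sentences = as.integer(agg$n_theme_sentences),
    n_change_sentences = as.integer(agg$n_change_sentences),
    mean_sentiment = agg$mean_sentiment
  )
  out[order(out$key_id, out$theme), ]
}

#' Run the full change-extraction pipeline
#'
#' Applies all five steps to a set of notes: sentence splitting and
#' annotation, theme filter, change filter, context filter, and sentiment
#' scoring, followed by aggregation to trajectory and patient summaries.
#' Deterministic for fixed inputs and configuration.
#'
#' @param notes A data frame of notes with columns `patient_id`,
#'   `trajectory_id`, `note_id`, `date`, `text`.
#' @param lex A `clin_lexicon`.
#' @param rules A `clin_context_rules`; defaults to the permissive empty set.
#' @param config A [pipeline_config()].
#' @param annotator An annotation backend, by default [rule_annotator()].
#' @return A list of class `clin_pipeline_result`:
#'   * `sentence_scores` — tibble (`patient_id`, `trajectory_id`, `note_id`,
#'     `sentence_index`, `theme`, `score`, `n_pairs`);
#'   * `summaries` — trajectory- and patient-level [aggregate_scores()]
#'     output bound together (column `key` distinguishes them);
#'   * `trace` — list with `stage_counts` (per theme: `n_sentences`,
#'     `n_theme`, `n_change`, `n_accepted`, `n_scored`) and
#'     `sentence_trace` (per sentence and theme, the final stage reached:
#'     `"no_theme"`, `"cancelled_step3"`, `"rejected_step4"`, `"scored"`).
#' @export
#' @examples
#' lex <- lexicon(data.frame(
#'   phrase = c("anxiety", "more"),
#'   category = c("theme:symptoms", "change"),
#'   polarity = c(-1, 1)
#' ))
#' notes <- data.frame(
#'   patient_id = "P1", trajectory_id = "T1", note_id = "N1",
#'   date = as.Date("2020-01-01"), text = "More anxiety today."
#' )
#' run_pipeline(notes, lex)$sentence_scores
run_pipeline <- function(notes, lex, rules = context_rules(),
                         config = pipeline_config(),
                         annotator = rule_annotator()) {
  notes <- tibble::as_tibble(notes)
  themes <- lexicon_themes(lex)
  score_rows <- list()
  trace_rows <- list()
  for (nr in seq_len(nrow(notes))) {
    sentences <- segment(notes[nr, ], annotator)
    for (s in sentences) {
      tm <- theme_filter(s, lex)
      present <- unique(tm$theme)
      stage <- setNames(rep("no_theme", length(themes)), themes)
      if (nrow(tm)) {
        cm <- change_filter(s, lex)
        if (!nrow(cm)) {
          stage[present] <- "cancelled_step3"
        } else {
          pairs <- pair_candidates(tm, cm)
          verdicts <- apply_context_filter(s, pairs, rules, config)
          sc <- score_sentence(verdicts)
          stage[present] <- "rejected_step4"
          stage[sc$theme] <- "scored"
          if (nrow(sc)) {
            sc$patient_id <- s$patient_id
            sc$trajectory_id <- s$trajectory_id
            sc$note_id <- s$note_id
            sc$sentence_index <- s$sentence_index
            score_rows[[length(score_rows) + 1L]] <- sc
          }
        }
      }
      trace_rows[[length(trace_rows) + 1L]] <- tibble::tibble(
        patient_id = s$patient_id, trajectory_id = s$trajectory_id,
        note_id = s$note_id, sentence_index = s$sentence_index,
        theme = themes, stage = unname(stage)
      )
    }
  }
  sentence_scores <- if (length(score_rows)) {
    out <- dplyr::bind_rows(score_rows)
    out[, c(
      "patient_id", "trajectory_id", "note_id", "sentence_index",
      "theme", "score", "n_pairs"
    )]
  } else {
    tibble::tibble(
      patient_id = character(), trajectory_id = character(),
      note_id = character(), sentence_index = integer(),
      theme = character(), score = integer(), n_pairs = integer()
    )
  }
  sentence_trace <- if (length(trace_rows)) {
    dplyr::bind_rows(trace_rows)
  } else {
    tibble::tibble(
      patient_id = character(), trajectory_id = character(),
      note_id = character(), sentence_index = integer(),
      theme = character(), stage = character()
    )
  }
  stage_counts <- stage_count_table(sentence_trace, themes)
  summaries <- dplyr::bind_rows(
    aggregate_scores(sentence_scores, "trajectory",
      theme_sentence_counts(sentence_trace, "trajectory")
    ),
    aggregate_scores(sentence_scores, "patient",
      theme_sentence_counts(sentence_trace, "patient")
    )
  )
  structure(
    list(
      sentence_scores = sentence_scores,
      summaries = summaries,
      trace = list(
        stage_counts = stage_counts,
        sentence_trace = sentence_trace
      )
    ),
    class = "clin_pipeline_result"
  )
}

theme_sentence_counts <- function(sentence_trace, key) {
  key_col <- paste0(key, "_id")
  if (!nrow(sentence_trace)) {
    return(tibble::tibble(
      key_id = character(), theme = character(), n_theme_sentences = integer()
    ))
  }
  has_theme <- sentence_trace[sentence_trace$stage != "no_theme", ]
  grp <- dplyr::group_by(has_theme, .data[[key_col]], .data$theme)
  out <- dplyr::summarise(grp, n_theme_sentences = dplyr::n(), .groups = "drop")
  names(out)[names(out) == key_col] <- "key_id"
  out
}

stage_count_table <- function(sentence_trace, themes) {
  out <- lapply(themes, function(th) {
    st <- sentence_trace$stage[sentence_trace$theme == th]
    n_sent <- length(st)
    tibble::tibble(
      theme = th,
      n_sentences = n_sent,
      n_theme = sum(st != "no_theme"),
      n_change = sum(st %in% c("rejected_step4", "scored")),
      n_accepted = sum(st == "scored"),
      n_scored = sum(st == "scored")
    )
  })
  dplyr::bind_rows(out)
}

#' @export
print.clin_pipeline_result <- function(x, ...) {
  cat("<clin_pipeline_result>\n")
  cat("Stage counts per theme:\n")
  print(x$trace$stage_counts)
  cat(sprintf(
    "%d scored sentence-theme rows; %d summary rows\n",
    nrow(x$sentence_scores), nrow(x$summaries)
  ))
  invisible(x)
}
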