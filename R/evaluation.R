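#' F1 score from precision and recall
#'
#' The harmonic mean `2 * p * r / (p + r)`, `NA` when either input is missing
#' or both are zero.
#'
#' @param precision,recall Proportions in \[0, 1\].
#' @return The F1 score, or `NA`.
#' @export
#' @examples
#' f1_score(0.75, 1.0)
f1_score <- function(precision, recall) {
  ifelse(
    is.na(precision) | is.na(recall) | (precision + recall) == 0,
    NA_real_,
    2 * precision * recall / (precision + recall)
  )
}

#' Predict the accept/reject label for an isolated sentence
#'
#' A sentence is labelled `"accept"` for a theme exactly when, run through
#' the full pipeline as a single-sentence note, it yields at least one
#' sentence score for that theme — i.e. it passes the theme, change and
#' context filters. This mirrors how validation sentences are labelled by
#' human annotators.
#'
#' @param text Sentence text.
#' @param theme Theme name.
#' @param lex A `clin_lexicon`.
#' @param rules A `clin_context_rules`.
#' @param config A [pipeline_config()].
#' @param annotator An annotation backend.
#' @return `"accept"` or `"reject"`.
#' @export
predict_label <- function(text, theme, lex, rules = context_rules(),
                          config = pipeline_config(),
                          annotator = rule_annotator()) {
  preds <- predict_labels(
    tibble::tibble(text = text, theme = theme), lex, rules, config, annotator
  )
  preds$predicted[[1L]]
}

# batched prediction: one pipeline run over all sentences as one-sentence notes
predict_labels <- function(sentences, lex, rules, config, annotator) {
  sentences <- tibble::as_tibble(sentences)
  uniq <- unique(sentences$text)
  notes <- tibble::tibble(
    patient_id = "eval", trajectory_id = "eval",
    note_id = paste0("s", seq_along(uniq)),
    date = as.Date("2000-01-01"), text = uniq
  )
  res <- run_pipeline(notes, lex, rules, config, annotator)
  hit <- unique(res$sentence_scores[, c("note_id", "theme")])
  key <- paste(hit$note_id, hit$theme)
  ids <- setNames(paste0("s", seq_along(uniq)), uniq)
  sentences$predicted <- ifelse(
    paste(ids[sentences$text], sentences$theme) %in% key, "accept", "reject"
  )
  sentences
}

#' Evaluate the pipeline against accept/reject annotations
#'
#' Compares human sentence labels with pipeline predictions per theme and
#' derives the confusion counts and classification metrics. `"accept"` is the
#' positive class. Undefined ratios (zero denominators) are reported as `NA`,
#' never as 0 — reporting 0 would silently deflate summary tables.
#'
#' @param labels A data frame with columns `text`, `theme`, `label`
#'   (`"accept"`/`"reject"`).
#' @param lex A `clin_lexicon`.
#' @param rules A `clin_context_rules`.
#' @param config A [pipeline_config()].
#' @param annotator An annotation backend.
#' @return A tibble with one row per theme: `theme`, `n`, `tp`, `fp`, `fn`,
#'   `tn`, `accuracy`, `precision`, `recall`, `f1`.
#' @export
evaluate <- function(labels, lex, rules = context_rules(),
                     config = pipeline_config(),
                     annotator = rule_annotator()) {
  labels <- tibble::as_tibble(labels)
  need <- c("text", "theme", "label")
  miss <- setdiff(need, names(labels))
  if (length(miss)) {
    abort(sprintf("labels missing column(s): %s", paste(miss, collapse = ", ")))
  }
  if (!all(labels$label %in% c("accept", "reject"))) {
    abort("labels must be 'accept' or 'reject'")
  }
  unknown <- setdiff(unique(labels$theme), lexicon_themes(lex))
  if (length(unknown)) {
    abort(sprintf(
      "label theme(s) not in lexicon: %s", paste(unknown, collapse = ", ")
    ))
  }
  preds <- predict_labels(labels, lex, rules, config, annotator)
  out <- lapply(sort(unique(preds$theme)), function(th) {
    sub <- preds[preds$theme == th, ]
    conf <- confusion_metrics(
      sub$label == "accept", sub$predicted == "accept"
    )
    tibble::tibble(theme = th, n = nrow(sub), !!!conf)
  })
  dplyr::bind_rows(out)
}

confusion_metrics <- function(truth, pred) {
  tp <- sum(truth & pred)
  fp <- sum(!truth & pred)
  fn <- sum(truth & !pred)
  tn <- sum(!truth & !pred)
  precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  recall <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  list(
    tp = tp, fp = fp, fn = fn, tn = tn,
    accuracy = (tp + tn) / (tp + fp + fn + tn),
    precision = precision,
    recall = recall,
    f1 = f1_score(precision, recall)
  )
}
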