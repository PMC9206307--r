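#' Theme filter (pipeline step 2)
#'
#' A sentence passes the theme filter when at least one phrase belonging to
#' one of the candidate themes matches. Matching is delegated to
#' [lexicon_lookup()] over the lexicon's theme entries; each theme filters
#' independently, so a phrase listed under two themes fires for both.
#'
#' @param sentence A `clin_sentence` from [segment()].
#' @param lex A `clin_lexicon`.
#' @return A tibble of theme matches (`theme`, `phrase`, `polarity`,
#'   `match_mode`, `start`, `end`, `source = "lexicon"`), ordered by theme
#'   then span start; zero rows means the sentence is rejected at this step.
#' @export
theme_filter <- function(sentence, lex) {
  hits <- lexicon_lookup(theme_entries(lex), sentence$tokens)
  out <- tibble::tibble(
    theme = hits$theme, phrase = hits$phrase, polarity = hits$polarity,
    match_mode = hits$match_mode, start = hits$start, end = hits$end,
    source = rep("lexicon", nrow(hits))
  )
  out[order(out$theme, out$start), ]
}

#' Change filter (pipeline step 3)
#'
#' A sentence passes the change filter when it contains a phrase indicating a
#' moment of change: either a lexicon change entry (carrying its declared
#' direction, +1 increase / -1 decrease) or a token in comparative degree
#' (e.g. "angrier"), which always carries direction +1 — "angrier" means
#' *more* anger; the theme polarity supplies the sign. A comparative token
#' whose span coincides with a lexicon change match is reported once, with
#' the lexicon's declared direction taking precedence. An empty result
#' cancels further analysis of the sentence.
#'
#' @inheritParams theme_filter
#' @return A tibble of change matches (`phrase`, `direction`, `start`, `end`,
#'   `source` in `{"lexicon", "comparative"}`), ordered by span start.
#' @export
change_filter <- function(sentence, lex) {
  tok <- sentence$tokens
  hits <- lexicon_lookup(change_entries(lex), tok)
  lex_part <- tibble::tibble(
    phrase = hits$phrase, direction = hits$polarity,
    start = hits$start, end = hits$end,
    source = rep("lexicon", nrow(hits))
  )
  comp_idx <- which(tok$degree == "comparative")
  comp_part <- tibble::tibble(
    phrase = fold_text(tok$surface[comp_idx]),
    direction = rep(1L, length(comp_idx)),
    start = comp_idx - 1L, end = comp_idx,
    source = rep("comparative", length(comp_idx))
  )
  if (nrow(lex_part) && nrow(comp_part)) {
    covered <- vapply(seq_len(nrow(comp_part)), function(i) {
      any(comp_part$start[[i]] >= lex_part$start &
        comp_part$end[[i]] <= lex_part$end)
    }, logical(1))
    comp_part <- comp_part[!covered, ]
  }
  out <- dplyr::bind_rows(lex_part, comp_part)
  out[order(out$start, out$source), ]
}

#' Pair theme matches with change matches
#'
#' Each theme match is paired with at most one change match: its nearest by
#' token distance, ties resolved to the leftmost change match. One change
#' match may serve several theme matches (so a single "more" licenses both
#' theme words in "more anxious and sad"), but a change match whose token
#' span overlaps the theme match's own span is never used — a token matched
#' as a theme phrase cannot simultaneously act as the change phrase of its
#' own pair.
#'
#' @param theme_matches Output of [theme_filter()].
#' @param change_matches Output of [change_filter()] for the same sentence.
#' @return A tibble of candidate pairs with columns `theme`, `theme_phrase`,
#'   `theme_polarity`, `theme_start`, `theme_end`, `change_phrase`,
#'   `change_direction`, `change_start`, `change_end`, `change_source`.
#' @export
pair_candidates <- function(theme_matches, change_matches) {
  empty <- tibble::tibble(
    theme = character(), theme_phrase = character(),
    theme_polarity = integer(), theme_start = integer(), theme_end = integer(),
    change_phrase = character(), change_direction = integer(),
    change_start = integer(), change_end = integer(), change_source = character()
  )
  if (!nrow(theme_matches) || !nrow(change_matches)) {
    return(empty)
  }
  rows <- vector("list", nrow(theme_matches))
  for (i in seq_len(nrow(theme_matches))) {
    ts <- theme_matches$start[[i]]
    te <- theme_matches$end[[i]]
    overlap <- change_matches$start < te & change_matches$end > ts
    cand <- which(!overlap)
    if (!length(cand)) next
    dist <- ifelse(
      change_matches$end[cand] <= ts,
      ts - change_matches$end[cand],
      change_matches$start[cand] - te
    )
    best <- cand[order(dist, change_matches$start[cand])][[1L]]
    rows[[i]] <- tibble::tibble(
      theme = theme_matches$theme[[i]],
      theme_phrase = theme_matches$phrase[[i]],
      theme_polarity = theme_matches$polarity[[i]],
      theme_start = ts, theme_end = te,
      change_phrase = change_matches$phrase[[best]],
      change_direction = change_matches$direction[[best]],
      change_start = change_matches$start[[best]],
      change_end = change_matches$end[[best]],
      change_source = change_matches$source[[best]]
    )
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) {
    return(empty)
  }
  dplyr::bind_rows(rows)
}
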