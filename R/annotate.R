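#' Rule-based linguistic annotator
#'
#' Builds an annotation backend: a function that takes a sentence string and
#' returns the token table the downstream filters consume. The shipped backend
#' is rule-based — coarse part-of-speech tags from closed-class lists and
#' suffix heuristics, lemmas from an irregular table plus suffix stripping,
#' morphological degree (positive/comparative/superlative) from the profile's
#' suffix and irregular tables, and a clause-oriented dependency sketch in
#' which tokens attach to their clause head and clause heads chain to the
#' sentence root with a `"conj"` relation.
#'
#' Any replacement backend (e.g. one wrapping a statistical tagger/parser)
#' can be supplied wherever an `annotator` argument is accepted, provided it
#' honours the same token contract (see [segment()]); the pipeline never
#' reaches past that contract.
#'
#' @param profile A [language_profile()].
#' @return A function of one sentence string returning a tibble with columns
#'   `surface`, `lemma`, `pos`, `degree`, `head`, `deprel`, `start`, `end`
#'   (character offsets 0-based, half-open, relative to the sentence).
#' @export
#' @examples
#' ann <- rule_annotator()
#' ann("Anxiety symptoms increased")
rule_annotator <- function(profile = language_profile("en")) {
  force(profile)
  f <- function(text) annotate_text(text, profile)
  structure(f, class = c("clin_annotator", "function"), profile = profile)
}

TOKEN_REGEX <- "[\\p{L}\\p{M}]+|\\p{N}+|[^\\p{L}\\p{M}\\p{N}\\s]"

tokenize_text <- function(text) {
  loc <- stringi::stri_locate_all_regex(text, TOKEN_REGEX)[[1L]]
  if (is.na(loc[1L, 1L])) {
    return(list(surface = character(), start = integer(), end = integer()))
  }
  list(
    surface = stringi::stri_sub(text, loc[, 1L], loc[, 2L]),
    start = as.integer(loc[, 1L] - 1L), # to 0-based half-open
    end = as.integer(loc[, 2L])
  )
}

pos_tag_one <- function(folded, profile) {
  if (stringi::stri_detect_regex(folded, "^\\p{N}+$")) {
    return("NUM")
  }
  if (!stringi::stri_detect_regex(folded, "[\\p{L}\\p{M}]")) {
    return("PUNCT")
  }
  if (folded %in% profile$aux) {
    return("AUX")
  }
  if (folded %in% profile$det) {
    return("DET")
  }
  if (folded %in% profile$pron) {
    return("PRON")
  }
  if (folded %in% profile$cconj) {
    return("CCONJ")
  }
  if (folded %in% profile$sconj) {
    return("SCONJ")
  }
  if (folded %in% profile$adp) {
    return("ADP")
  }
  if (folded %in% profile$adjectives ||
    !is.na(comparative_base(folded, profile)) ||
    !is.na(superlative_base(folded, profile))) {
    return("ADJ")
  }
  if (any(vapply(
    profile$adverb_suffixes,
    function(s) endsWith(folded, s) && nchar(folded) > nchar(s) + 2L,
    logical(1)
  ))) {
    return("ADV")
  }
  if (folded %in% profile$verbs) {
    return("VERB")
  }
  if (nchar(folded) > 4L && (endsWith(folded, "ed") || endsWith(folded, "ing"))) {
    return("VERB")
  }
  "NOUN"
}

lemma_one <- function(folded, pos, degree, profile) {
  irr <- profile$irregular_lemmas
  if (folded %in% names(irr)) {
    return(unname(irr[[folded]]))
  }
  if (degree == "comparative") {
    base <- comparative_base(folded, profile)
    if (!is.na(base)) {
      return(base)
    }
  }
  if (degree == "superlative") {
    base <- superlative_base(folded, profile)
    if (!is.na(base)) {
      return(base)
    }
  }
  if (pos == "VERB" && profile$language == "en") {
    for (rule in list(
      c("ies$", "y"), c("sses$", "ss"), c("es$", "e"), c("s$", ""),
      c("ied$", "y"), c("ed$", "e"), c("ed$", ""), c("ing$", "")
    )) {
      if (stringi::stri_detect_regex(folded, rule[[1L]]) && nchar(folded) > 4L) {
        cand <- stringi::stri_replace_first_regex(folded, rule[[1L]], rule[[2L]])
        if (cand %in% profile$verbs) {
          return(cand)
        }
      }
    }
  }
  folded
}

degree_one <- function(folded, pos, profile) {
  if (!pos %in% c("ADJ", "ADV")) {
    return("n/a")
  }
  if (folded %in% names(profile$irregular_superlatives) ||
    !is.na(degree_base(folded, profile$superlative_suffixes, TRUE, profile))) {
    return("superlative")
  }
  if (folded %in% names(profile$irregular_comparatives) ||
    !is.na(degree_base(folded, profile$comparative_suffixes, TRUE, profile))) {
    return("comparative")
  }
  "positive"
}

# Clause-oriented dependency sketch. Clauses are split at coordinating
# conjunctions and at ";"/"," — but only when the material that follows
# contains a finite verb (so "more anxious and sad" stays one clause while
# "..., but the patient did not respond" starts a new one). Tokens attach to
# their clause head (first finite verb, else first content token); clause
# heads after the first attach to the root with deprel "conj", the clause
# boundary the linkage check refuses to cross.
build_dependencies <- function(surface, pos) {
  n <- length(surface)
  head <- integer(n)
  deprel <- character(n)
  if (n == 0L) {
    return(list(head = head, deprel = deprel))
  }
  finite <- pos %in% c("VERB", "AUX")
  delim <- pos == "CCONJ" | surface %in% c(";", ",")
  clause <- cumsum(delim)
  clause[1L] <- max(clause[1L], 0L)
  # merge a chunk into its predecessor when it carries no finite verb
  ids <- unique(clause)
  remap <- setNames(ids, ids)
  for (k in seq_along(ids)) {
    if (k == 1L) next
    idx <- which(clause == ids[[k]])
    body <- idx[!delim[idx]]
    if (!any(finite[body])) {
      remap[[as.character(ids[[k]])]] <- remap[[as.character(ids[[k - 1L]])]]
    }
  }
  clause <- unname(remap[as.character(clause)])
  heads_of_clause <- integer()
  root <- NA_integer_
  for (cid in unique(clause)) {
    idx <- which(clause == cid)
    cand <- idx[finite[idx]]
    if (!length(cand)) cand <- idx[!pos[idx] %in% c("PUNCT", "CCONJ")]
    if (!length(cand)) cand <- idx
    ch <- cand[[1L]]
    if (is.na(root)) {
      root <- ch
      head[ch] <- 0L
      deprel[ch] <- "root"
    } else {
      head[ch] <- root
      deprel[ch] <- "conj"
    }
    for (i in idx) {
      if (i == ch) next
      head[i] <- ch
      deprel[i] <- if (pos[i] == "PUNCT") {
        "punct"
      } else if (pos[i] == "CCONJ") {
        "cc"
      } else {
        "dep"
      }
    }
  }
  list(head = head, deprel = deprel)
}

annotate_text <- function(text, profile) {
  tok <- tokenize_text(text)
  folded <- fold_text(tok$surface)
  pos <- vapply(folded, pos_tag_one, character(1), profile = profile,
    USE.NAMES = FALSE
  )
  degree <- mapply(degree_one, folded, pos,
    MoreArgs = list(profile = profile), USE.NAMES = FALSE
  )
  if (!length(folded)) degree <- character()
  lemma <- mapply(lemma_one, folded, pos, degree,
    MoreArgs = list(profile = profile), USE.NAMES = FALSE
  )
  if (!length(folded)) lemma <- character()
  dep <- build_dependencies(tok$surface, pos)
  tibble::tibble(
    surface = tok$surface,
    lemma = as.character(lemma),
    pos = pos,
    degree = as.character(degree),
    head = dep$head,
    deprel = dep$deprel,
    start = tok$start,
    end = tok$end
  )
}

fold_text <- function(x) {
  stringi::stri_trans_nfc(stringi::stri_trans_tolower(x))
}

#' Split a clinical note into annotated sentences
#'
#' Step 1 of the pipeline. Sentence boundaries are terminal punctuation
#' (`.`, `!`, `?`) followed by whitespace or end of text, plus newlines —
#' nursing notes are often line-structured, so every non-empty line is treated
#' as (at least one) sentence. Splitting is a pure function of the note text.
#' Each sentence is then annotated by the supplied backend; token character
#' offsets are re-based to the note, so `substr`-style extraction from the
#' note text reproduces every surface form.
#'
#' @param note A one-row data frame (or named list) with fields `patient_id`,
#'   `trajectory_id`, `note_id`, `date`, `text`.
#' @param annotator An annotation backend, by default [rule_annotator()].
#' @return A list of `clin_sentence` objects. Each is a list with the note's
#'   ids, `sentence_index` (1-based), `char_span` (0-based half-open character
#'   offsets into the note text), `text`, and a `tokens` tibble with columns
#'   `surface`, `lemma`, `pos`, `degree` (one of `"positive"`,
#'   `"comparative"`, `"superlative"`, `"n/a"`), `head` (row index of the
#'   head token, 0 for the sentence root), `deprel`, `start`, `end`
#'   (character offsets into the note, 0-based half-open).
#' @export
#' @examples
#' note <- list(
#'   patient_id = "P1", trajectory_id = "T1", note_id = "N1",
#'   date = as.Date("2020-01-01"), text = "Anxiety increased. Slept well."
#' )
#' sents <- segment(note)
#' length(sents)
segment <- function(note, annotator = rule_annotator()) {
  note <- as.list(note)
  for (f in c("patient_id", "trajectory_id", "note_id", "text")) {
    if (is.null(note[[f]]) || !nzchar(trimws(as.character(note[[f]])[1]))) {
      abort(sprintf("note field '%s' must be non-empty", f))
    }
  }
  text <- as.character(note$text)[1]
  spans <- sentence_spans(text)
  out <- vector("list", nrow(spans))
  for (i in seq_len(nrow(spans))) {
    s0 <- spans$start[[i]]
    s1 <- spans$end[[i]]
    stext <- stringi::stri_sub(text, s0 + 1L, s1)
    tokens <- tryCatch(
      annotator(stext),
      error = function(e) {
        abort(sprintf(
          "annotation backend failed on note '%s': %s",
          note$note_id, conditionMessage(e)
        ))
      }
    )
    tokens$start <- tokens$start + s0
    tokens$end <- tokens$end + s0
    out[[i]] <- new_clin_sentence(note, i, c(s0, s1), stext, tokens)
  }
  out
}

new_clin_sentence <- function(note, index, char_span, text, tokens) {
  structure(
    list(
      patient_id = as.character(note$patient_id)[1],
      trajectory_id = as.character(note$trajectory_id)[1],
      note_id = as.character(note$note_id)[1],
      date = note$date,
      sentence_index = as.integer(index),
      char_span = as.integer(char_span),
      text = text,
      tokens = tokens
    ),
    class = "clin_sentence"
  )
}

#' @export
print.clin_sentence <- function(x, ...) {
  cat(sprintf(
    "<clin_sentence %s#%d [%d,%d)> %s\n",
    x$note_id, x$sentence_index, x$char_span[1], x$char_span[2], x$text
  ))
  invisible(x)
}

# 0-based half-open sentence spans; trims surrounding whitespace per sentence.
sentence_spans <- function(text) {
  n <- stringi::stri_length(text)
  cuts <- integer()
  term <- stringi::stri_locate_all_regex(text, "[.!?]+(?=\\s|$)")[[1L]]
  if (!is.na(term[1L, 1L])) cuts <- c(cuts, term[, 2L])
  nl <- stringi::stri_locate_all_fixed(text, "\n")[[1L]]
  if (!is.na(nl[1L, 1L])) cuts <- c(cuts, nl[, 1L] - 1L)
  cuts <- sort(unique(c(cuts, n)))
  cuts <- cuts[cuts >= 1L]
  starts <- integer()
  ends <- integer()
  prev <- 0L
  for (cut in cuts) {
    if (cut <= prev) next
    seg <- stringi::stri_sub(text, prev + 1L, cut)
    lead <- stringi::stri_locate_first_regex(seg, "\\S")[1L, 1L]
    if (!is.na(lead)) {
      trail <- stringi::stri_locate_last_regex(seg, "\\S")[1L, 2L]
      starts <- c(starts, prev + lead - 1L)
      ends <- c(ends, prev + trail)
    }
    prev <- cut
  }
  tibble::tibble(start = as.integer(starts), end = as.integer(ends))
}

#' Re-derive morphological degree for a sentence
#'
#' Recomputes the `degree` column of a sentence's tokens from surface form and
#' part-of-speech: adjectives and adverbs receive
#' positive/comparative/superlative via the profile's suffix and irregular
#' tables, all other tokens `"n/a"`. Idempotent; useful when tokens come from
#' an external backend that does not emit degree.
#'
#' @param sentence A `clin_sentence`.
#' @param profile A [language_profile()].
#' @return The sentence with an updated `degree` column.
#' @export
annotate_degree <- function(sentence, profile = language_profile("en")) {
  tok <- sentence$tokens
  folded <- fold_text(tok$surface)
  tok$degree <- mapply(degree_one, folded, tok$pos,
    MoreArgs = list(profile = profile), USE.NAMES = FALSE
  )
  if (!nrow(tok)) tok$degree <- character()
  tok$degree <- as.character(tok$degree)
  sentence$tokens <- tok
  sentence
}

# Contract checks shared by the fallback annotator and any external backend.
validate_sentence <- function(sentence, note_text = NULL) {
  tok <- sentence$tokens
  stopifnot(is.data.frame(tok))
  need <- c("surface", "lemma", "pos", "degree", "head", "deprel", "start", "end")
  if (!all(need %in% names(tok))) {
    abort("token table missing required columns")
  }
  if (nrow(tok)) {
    if (any(tok$head < 0L | tok$head > nrow(tok))) {
      abort("token head index out of range")
    }
    if (sum(tok$head == 0L) != 1L) {
      abort("sentence must have exactly one root token")
    }
    if (any(tok$start < sentence$char_span[1]) ||
      any(tok$end > sentence$char_span[2])) {
      abort("token spans must lie within the sentence span")
    }
    if (!all(tok$degree %in% c("positive", "comparative", "superlative", "n/a"))) {
      abort("invalid degree value")
    }
    if (!is.null(note_text)) {
      got <- stringi::stri_sub(note_text, tok$start + 1L, tok$end)
      if (!identical(got, tok$surface)) {
        abort("token offsets do not round-trip to surfaces")
      }
    }
  }
  invisible(sentence)
}
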