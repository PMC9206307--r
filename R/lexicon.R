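#' Construct a phrase lexicon
#'
#' A lexicon is the inventory of matchable phrases that drives the theme and
#' change filters. Each entry binds a phrase to a category — `"theme:<name>"`
#' for a theme phrase or `"change"` for a change phrase — and a polarity in
#' `{-1, +1}`: for theme entries the connotation (negative phrases such as
#' "anxiety" carry -1, positive phrases such as "joy" carry +1), for change
#' entries the direction (+1 = increase, -1 = decrease). Phrases are
#' normalised on construction: case-folded, Unicode NFC (diacritics
#' preserved), internal whitespace collapsed.
#'
#' @param entries A data frame with columns `phrase`, `category`, `polarity`
#'   and optionally `match_mode` (`"exact-token"`, the default, compares
#'   case-folded surfaces; `"lemma"` compares lemmas).
#' @return A `clin_lexicon`: a tibble of normalised entries with a `theme`
#'   column split out of `category`, plus a `themes` attribute holding the
#'   ordered set of theme names.
#' @export
#' @examples
#' lex <- lexicon(data.frame(
#'   phrase = c("anxiety", "more"),
#'   category = c("theme:symptoms", "change"),
#'   polarity = c(-1, 1)
#' ))
#' lexicon_themes(lex)
lexicon <- function(entries = NULL) {
  if (is.null(entries) || nrow(as.data.frame(entries)) == 0L) {
    out <- tibble::tibble(
      phrase = character(), category = character(), theme = character(),
      polarity = integer(), match_mode = character(),
      phrase_tokens = list()
    )
    return(structure(out, class = c("clin_lexicon", class(out)), themes = character()))
  }
  entries <- tibble::as_tibble(entries)
  need <- c("phrase", "category", "polarity")
  missing_cols <- setdiff(need, names(entries))
  if (length(missing_cols)) {
    abort(sprintf(
      "lexicon is missing required column(s): %s",
      paste(missing_cols, collapse = ", ")
    ))
  }
  if (!"match_mode" %in% names(entries)) entries$match_mode <- "exact-token"
  entries$match_mode[is.na(entries$match_mode) | entries$match_mode == ""] <-
    "exact-token"
  for (i in seq_len(nrow(entries))) {
    row_err <- function(field, msg) {
      abort(sprintf("lexicon row %d, field '%s': %s", i, field, msg))
    }
    ph <- normalise_phrase(entries$phrase[[i]])
    if (is.na(ph) || !nzchar(ph)) row_err("phrase", "empty after normalization")
    entries$phrase[[i]] <- ph
    cat_i <- as.character(entries$category[[i]])
    if (is.na(cat_i) ||
      !(cat_i == "change" || grepl("^theme:.+$", cat_i))) {
      row_err("category", "must be 'change' or 'theme:<name>'")
    }
    pol <- suppressWarnings(as.numeric(entries$polarity[[i]]))
    if (is.na(pol) || !pol %in% c(-1, 1)) {
      row_err("polarity", "must be -1 or +1")
    }
    if (!entries$match_mode[[i]] %in% c("exact-token", "lemma")) {
      row_err("match_mode", "must be 'exact-token' or 'lemma'")
    }
  }
  entries$category <- as.character(entries$category)
  entries$polarity <- as.integer(entries$polarity)
  dup <- duplicated(entries[, c("phrase", "category")])
  if (any(dup)) {
    d <- entries[dup, ]
    abort(sprintf(
      "duplicate (phrase, category) pair(s): %s",
      paste(sprintf("('%s', '%s')", d$phrase, d$category), collapse = ", ")
    ))
  }
  entries$theme <- ifelse(
    entries$category == "change", NA_character_,
    sub("^theme:", "", entries$category)
  )
  entries$phrase_tokens <- lapply(entries$phrase, function(p) {
    tokenize_text(p)$surface
  })
  # canonical order makes construction independent of file row order
  ord <- order(entries$category, entries$phrase, entries$match_mode)
  entries <- entries[ord, c(
    "phrase", "category", "theme", "polarity", "match_mode", "phrase_tokens"
  )]
  themes <- unique(entries$theme[!is.na(entries$theme)])
  structure(entries,
    class = c("clin_lexicon", class(tibble::tibble())),
    themes = sort(themes)
  )
}

normalise_phrase <- function(x) {
  x <- fold_text(as.character(x))
  stringi::stri_trim_both(stringi::stri_replace_all_regex(x, "\\s+", " "))
}

#' @rdname lexicon
#' @param x A `clin_lexicon`.
#' @export
lexicon_themes <- function(x) attr(x, "themes")

#' @export
print.clin_lexicon <- function(x, ...) {
  cat(sprintf(
    "<clin_lexicon: %d entries (%d change), themes: %s>\n",
    nrow(x), sum(x$category == "change"),
    paste(lexicon_themes(x), collapse = ", ")
  ))
  if (nrow(x)) print(tibble::as_tibble(x)[, 1:5])
  invisible(x)
}

theme_entries <- function(lexicon) lexicon[lexicon$category != "change", ]
change_entries <- function(lexicon) lexicon[lexicon$category == "change", ]

#' Read or write a phrase lexicon
#'
#' Lexicon files are UTF-8 TSV with a header (`phrase`, `category`,
#' `polarity`, optional `match_mode`) or a JSON array of objects with the same
#' keys. Reading validates every row and normalises phrases, so the result is
#' independent of row order; writing emits the normalised entries, making
#' read-after-write the identity on the normalised entry set.
#'
#' @param path File path.
#' @param format `"tsv"` or `"json"`; inferred from the file extension by
#'   default.
#' @return `read_lexicon()` returns a `clin_lexicon`; `write_lexicon()`
#'   returns `path` invisibly.
#' @export
read_lexicon <- function(path, format = c("auto", "tsv", "json")) {
  format <- resolve_format(path, match.arg(format))
  if (!file.exists(path)) abort(sprintf("lexicon file not found: %s", path))
  if (file.size(path) == 0L) {
    return(lexicon(NULL))
  }
  raw <- if (format == "tsv") {
    readr::read_tsv(path,
      col_types = readr::cols(.default = readr::col_character()),
      progress = FALSE
    )
  } else {
    out <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
    if (length(out) == 0L) tibble::tibble() else tibble::as_tibble(out)
  }
  lexicon(raw)
}

#' @rdname read_lexicon
#' @param lex A `clin_lexicon`.
#' @export
write_lexicon <- function(lex, path, format = c("auto", "tsv", "json")) {
  format <- resolve_format(path, match.arg(format))
  out <- tibble::as_tibble(lex)[, c("phrase", "category", "polarity", "match_mode")]
  if (format == "tsv") {
    readr::write_tsv(out, path, progress = FALSE)
  } else {
    jsonlite::write_json(out, path, auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(path)
}

resolve_format <- function(path, format) {
  if (format != "auto") {
    return(format)
  }
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tsv", "txt")) {
    return("tsv")
  }
  if (ext == "json") {
    return("json")
  }
  abort(sprintf("cannot infer lexicon format from extension '.%s'", ext))
}

#' Clone a lexicon entry under surface variants
#'
#' Clinical phrase lists gain robustness from listing frequent spelling
#' variants and misspellings alongside the canonical form. This helper clones
#' one entry under each supplied variant, keeping category, polarity and
#' match mode; the base entry itself is unchanged. A variant equal to the base
#' phrase after normalisation is skipped with a warning.
#'
#' @param entry A one-row lexicon entry (a row of a `clin_lexicon`, or a list
#'   with fields `phrase`, `category`, `polarity`, `match_mode`).
#' @param variants Non-empty character vector of variant surface forms.
#' @return A tibble of cloned entries (possibly zero rows if all variants were
#'   skipped), suitable for binding into a new [lexicon()].
#' @export
#' @examples
#' lex <- lexicon(data.frame(
#'   phrase = "anxiety", category = "theme:symptoms", polarity = -1
#' ))
#' expand_variants(lex[1, ], c("anxeity", "anxietyy"))
expand_variants <- function(entry, variants) {
  entry <- as.list(entry)
  if (length(variants) == 0L) {
    abort("variants must be non-empty")
  }
  base <- normalise_phrase(entry$phrase)
  norm <- vapply(variants, normalise_phrase, character(1), USE.NAMES = FALSE)
  keep <- norm != base & nzchar(norm)
  if (any(!keep)) {
    warn(sprintf(
      "skipping variant(s) identical to base phrase '%s'", base
    ))
  }
  norm <- unique(norm[keep])
  tibble::tibble(
    phrase = norm,
    category = entry$category,
    polarity = as.integer(entry$polarity),
    match_mode = entry$match_mode %||% "exact-token"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Find lexicon phrase matches in a token sequence
#'
#' Scans a token sequence for every entry of a lexicon and returns all
#' maximal, per-entry non-overlapping contiguous matches as half-open token
#' spans (0-based). Exact-token entries compare case-folded surfaces; lemma
#' entries compare lemmas. Different entries may match overlapping spans —
#' each contributes its own match.
#'
#' @param lex A `clin_lexicon`.
#' @param tokens A token tibble with columns `surface` and `lemma` (as
#'   produced by [segment()]).
#' @return A tibble with one row per match: `phrase`, `category`, `theme`,
#'   `polarity`, `match_mode`, `start`, `end` (token indices, 0-based
#'   half-open), ordered by `start` then entry phrase.
#' @export
lexicon_lookup <- function(lex, tokens) {
  empty <- tibble::tibble(
    phrase = character(), category = character(), theme = character(),
    polarity = integer(), match_mode = character(),
    start = integer(), end = integer()
  )
  n <- nrow(tokens)
  if (!nrow(lex) || n == 0L) {
    return(empty)
  }
  folded <- fold_text(tokens$surface)
  lemmas <- fold_text(tokens$lemma)
  res <- vector("list", nrow(lex))
  for (e in seq_len(nrow(lex))) {
    target <- lex$phrase_tokens[[e]]
    k <- length(target)
    if (k == 0L || k > n) next
    haystack <- if (lex$match_mode[[e]] == "lemma") lemmas else folded
    starts <- integer()
    i <- 1L
    while (i <= n - k + 1L) {
      if (all(haystack[i:(i + k - 1L)] == target)) {
        starts <- c(starts, i - 1L) # 0-based
        i <- i + k # per-entry matches do not overlap
      } else {
        i <- i + 1L
      }
    }
    if (length(starts)) {
      res[[e]] <- tibble::tibble(
        phrase = lex$phrase[[e]], category = lex$category[[e]],
        theme = lex$theme[[e]], polarity = lex$polarity[[e]],
        match_mode = lex$match_mode[[e]],
        start = starts, end = starts + k
      )
    }
  }
  res <- res[!vapply(res, is.null, logical(1))]
  if (!length(res)) {
    return(empty)
  }
  out <- dplyr::bind_rows(res)
  out[order(out$start, out$phrase), ]
}
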