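#' Construct or read context rules
#'
#' Context rules are trigger phrases with a scope, in the style of the
#' ConText algorithm for clinical text: when a trigger fires, every token
#' inside its scope is considered negated / hypothetical / experienced by
#' someone other than the patient / not current, depending on the rule kind.
#' A scope runs from the trigger in the declared direction up to `window`
#' tokens (or the sentence boundary) and is cut short by a scope terminator
#' (configured in [pipeline_config()], e.g. "but", ";").
#'
#' Rule files are UTF-8 TSV with header columns `trigger`, `kind`, `scope`,
#' `window` (an integer token count or the word `sentence`). Trigger phrases
#' may span multiple tokens and are matched on case-folded surfaces. Minimal
#' English and Dutch starter sets ship with the package (see
#' `system.file("extdata", package = "clinchange")`); trigger inventories are
#' data, not code, and should be tailored per corpus.
#'
#' @param rules A data frame with columns `trigger`, `kind` (one of
#'   `"negation"`, `"hypothetical"`, `"non-patient-experiencer"`,
#'   `"non-current"`), `scope` (`"forward"`, `"backward"`,
#'   `"bidirectional"`), `window` (integer or `"sentence"`). `NULL` gives the
#'   permissive empty rule set under which the four trigger-based checks pass
#'   for every pair.
#' @return A `clin_context_rules` tibble.
#' @export
#' @examples
#' context_rules(data.frame(
#'   trigger = "not", kind = "negation", scope = "forward", window = "sentence"
#' ))
context_rules <- function(rules = NULL) {
  kinds <- c("negation", "hypothetical", "non-patient-experiencer", "non-current")
  if (is.null(rules) || nrow(as.data.frame(rules)) == 0L) {
    out <- tibble::tibble(
      trigger = character(), kind = character(), scope = character(),
      window = character(), trigger_tokens = list()
    )
    return(structure(out, class = c("clin_context_rules", class(out))))
  }
  rules <- tibble::as_tibble(rules)
  need <- c("trigger", "kind", "scope", "window")
  miss <- setdiff(need, names(rules))
  if (length(miss)) {
    abort(sprintf(
      "context rules missing column(s): %s", paste(miss, collapse = ", ")
    ))
  }
  rules$trigger <- vapply(rules$trigger, normalise_phrase, character(1),
    USE.NAMES = FALSE
  )
  if (any(!nzchar(rules$trigger))) abort("context rule trigger must be non-empty")
  if (any(!rules$kind %in% kinds)) {
    abort(sprintf("context rule kind must be one of: %s", paste(kinds, collapse = ", ")))
  }
  if (any(!rules$scope %in% c("forward", "backward", "bidirectional"))) {
    abort("context rule scope must be forward, backward or bidirectional")
  }
  rules$window <- as.character(rules$window)
  win_num <- suppressWarnings(as.integer(rules$window))
  bad <- rules$window != "sentence" & (is.na(win_num) | win_num < 1L)
  if (any(bad)) {
    abort("context rule window must be a positive integer or 'sentence'")
  }
  rules$trigger_tokens <- lapply(rules$trigger, function(p) tokenize_text(p)$surface)
  structure(
    rules[, c("trigger", "kind", "scope", "window", "trigger_tokens")],
    class = c("clin_context_rules", class(tibble::tibble()))
  )
}

#' @rdname context_rules
#' @param path Path to a TSV rule file.
#' @export
read_context_rules <- function(path) {
  if (!file.exists(path)) abort(sprintf("context rule file not found: %s", path))
  if (file.size(path) == 0L) {
    return(context_rules(NULL))
  }
  context_rules(readr::read_tsv(path,
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  ))
}

#' Pipeline configuration
#'
#' Tunable parameters of the context filter and aggregation, all with
#' defaults chosen to reproduce the canonical linkage examples ("anxiety
#' symptoms increased" linked; "We increased the medication doses but the
#' patient's anxiety did not respond" not linked).
#'
#' @param dep_path_bound Maximum dependency-path length (edges) between theme
#'   and change match for the change to be taken as concerning the theme;
#'   default 3.
#' @param fallback_window Maximum token distance used by the linkage check
#'   when dependency annotations are unavailable; default 6.
#' @param scope_terminators Tokens that cut a context trigger's scope short.
#' @param clause_delimiters Tokens that (followed by a finite verb) delimit
#'   clauses for the fallback linkage check.
#' @param group_by Default aggregation key, `"trajectory"` (one admission) or
#'   `"patient"`.
#' @return A `clin_pipeline_config` list.
#' @export
pipeline_config <- function(dep_path_bound = 3L,
                            fallback_window = 6L,
                            scope_terminators = c("but", "however", "although", ";"),
                            clause_delimiters = c("and", "or", "but", ";", ","),
                            group_by = c("trajectory", "patient")) {
  stopifnot(dep_path_bound >= 1L, fallback_window >= 1L)
  structure(
    list(
      dep_path_bound = as.integer(dep_path_bound),
      fallback_window = as.integer(fallback_window),
      scope_terminators = fold_text(scope_terminators),
      clause_delimiters = fold_text(clause_delimiters),
      group_by = match.arg(group_by)
    ),
    class = "clin_pipeline_config"
  )
}

# token index sets (0-based) covered by triggers of one kind
trigger_scope_indices <- function(tokens, rules, kind, config) {
  rules <- rules[rules$kind == kind, , drop = FALSE]
  n <- nrow(tokens)
  covered <- logical(n)
  if (!nrow(rules) || n == 0L) {
    return(covered)
  }
  folded <- fold_text(tokens$surface)
  terminators <- config$scope_terminators
  for (r in seq_len(nrow(rules))) {
    target <- rules$trigger_tokens[[r]]
    k <- length(target)
    if (k == 0L || k > n) next
    win <- rules$window[[r]]
    win_n <- if (win == "sentence") n else as.integer(win)
    for (i in seq_len(n - k + 1L)) {
      if (!all(folded[i:(i + k - 1L)] == target)) next
      s <- i # 1-based trigger start
      e <- i + k - 1L # 1-based trigger end
      if (rules$scope[[r]] %in% c("forward", "bidirectional")) {
        j <- e + 1L
        steps <- 0L
        while (j <= n && steps < win_n) {
          if (folded[[j]] %in% terminators) break
          covered[[j]] <- TRUE
          j <- j + 1L
          steps <- steps + 1L
        }
      }
      if (rules$scope[[r]] %in% c("backward", "bidirectional")) {
        j <- s - 1L
        steps <- 0L
        while (j >= 1L && steps < win_n) {
          if (folded[[j]] %in% terminators) break
          covered[[j]] <- TRUE
          j <- j - 1L
          steps <- steps + 1L
        }
      }
    }
  }
  covered
}

span_covered <- function(covered, start, end) {
  idx <- seq.int(start + 1L, end) # 0-based half-open span -> 1-based rows
  any(covered[idx])
}

check_scope_kind <- function(sentence, pair, rules, kind, config,
                             spans = c("theme", "change")) {
  covered <- trigger_scope_indices(sentence$tokens, rules, kind, config)
  hit <- FALSE
  if ("theme" %in% spans) {
    hit <- hit || span_covered(covered, pair$theme_start, pair$theme_end)
  }
  if ("change" %in% spans) {
    hit <- hit || span_covered(covered, pair$change_start, pair$change_end)
  }
  if (hit) "fail" else "pass"
}

#' The five contextual checks (pipeline step 4)
#'
#' Each check inspects one candidate pair inside its sentence and returns
#' `"pass"` or `"fail"`:
#'
#' * `check_negation()` — fails when a negation trigger's scope covers the
#'   change match *or* the theme match; a negated change word kills the pair.
#' * `check_hypothetical()` — fails when a conditional/possibility trigger
#'   scopes either match.
#' * `check_experiencer()` — fails when a non-patient-experiencer trigger
#'   (family or clinician subject phrases) scopes the theme match; the
#'   patient is the assumed experiencer of clinical notes, so the default is
#'   pass.
#' * `check_temporality()` — the "current" check; fails when a history or
#'   future marker scopes either match.
#' * `check_change_concerns_theme()` — passes when the change match and the
#'   theme match are syntactically linked: dependency path of at most
#'   `dep_path_bound` edges with no clause boundary (`"conj"` relation) on
#'   the path. When tokens carry no dependency annotation, falls back to a
#'   token-distance window with no intervening clause delimiter followed by a
#'   finite verb.
#'
#' @param sentence A `clin_sentence`.
#' @param pair A one-row candidate pair from [pair_candidates()].
#' @param rules A `clin_context_rules`.
#' @param config A [pipeline_config()].
#' @return `"pass"` or `"fail"`.
#' @name context_checks
NULL

#' @rdname context_checks
#' @export
check_negation <- function(sentence, pair, rules, config = pipeline_config()) {
  check_scope_kind(sentence, pair, rules, "negation", config)
}

#' @rdname context_checks
#' @export
check_hypothetical <- function(sentence, pair, rules, config = pipeline_config()) {
  check_scope_kind(sentence, pair, rules, "hypothetical", config)
}

#' @rdname context_checks
#' @export
check_experiencer <- function(sentence, pair, rules, config = pipeline_config()) {
  check_scope_kind(sentence, pair, rules, "non-patient-experiencer", config,
    spans = "theme"
  )
}

#' @rdname context_checks
#' @export
check_temporality <- function(sentence, pair, rules, config = pipeline_config()) {
  check_scope_kind(sentence, pair, rules, "non-current", config)
}

# anchor token (1-based row) of a span: the token whose head lies outside the
# span, else the first token
span_anchor <- function(tokens, start, end) {
  rows <- seq.int(start + 1L, end)
  for (r in rows) {
    h <- tokens$head[[r]]
    if (is.na(h) || h == 0L || h < start + 1L || h > end) {
      return(r)
    }
  }
  rows[[1L]]
}

path_to_root <- function(tokens, i) {
  path <- integer()
  while (!is.na(i) && i != 0L && !(i %in% path)) {
    path <- c(path, i)
    i <- tokens$head[[i]]
  }
  path
}

dep_path <- function(tokens, a, b) {
  pa <- path_to_root(tokens, a)
  pb <- path_to_root(tokens, b)
  common <- intersect(pa, pb)
  if (!length(common)) {
    return(NULL)
  }
  lca <- common[[1L]]
  up_a <- pa[seq_len(which(pa == lca))]
  up_b <- pb[seq_len(which(pb == lca))]
  # nodes a .. lca .. b; edges are (node, head) for every non-lca node
  nodes <- c(up_a, rev(up_b[-length(up_b)]))
  edge_nodes <- setdiff(nodes, lca)
  list(nodes = nodes, n_edges = length(edge_nodes), edge_nodes = edge_nodes)
}

#' @rdname context_checks
#' @export
check_change_concerns_theme <- function(sentence, pair,
                                        config = pipeline_config()) {
  tok <- sentence$tokens
  have_deps <- nrow(tok) > 0L && !anyNA(tok$head)
  if (have_deps) {
    a <- span_anchor(tok, pair$theme_start, pair$theme_end)
    b <- span_anchor(tok, pair$change_start, pair$change_end)
    if (a == b) {
      return("pass")
    }
    p <- dep_path(tok, a, b)
    if (is.null(p)) {
      return("fail")
    }
    crosses_clause <- any(tok$deprel[p$edge_nodes] == "conj")
    if (p$n_edges <= config$dep_path_bound && !crosses_clause) {
      return("pass")
    }
    return("fail")
  }
  # fallback: token window without an intervening clause boundary
  if (pair$change_end <= pair$theme_start) {
    lo <- pair$change_end
    hi <- pair$theme_start
  } else {
    lo <- pair$theme_end
    hi <- pair$change_start
  }
  if (hi - lo > config$fallback_window) {
    return("fail")
  }
  between <- if (hi > lo) seq.int(lo + 1L, hi) else integer() # 1-based rows
  folded <- fold_text(tok$surface)
  finite <- tok$pos %in% c("VERB", "AUX")
  for (j in between) {
    if (folded[[j]] %in% config$clause_delimiters &&
      any(finite[seq.int(j, nrow(tok))])) {
      return("fail")
    }
  }
  "pass"
}

combine_checks <- function(checks) {
  all(unlist(checks) == "pass")
}

#' Apply the context filter to a sentence's candidate pairs
#'
#' Runs the five contextual checks on every candidate pair and returns one
#' verdict per pair, order-preserving. A pair is accepted only when all five
#' checks pass; verdicts are independent across pairs. With an empty rule set
#' the four trigger-based checks pass for every pair, leaving only the
#' syntactic linkage check active.
#'
#' @param sentence A `clin_sentence`.
#' @param pairs Candidate pairs from [pair_candidates()].
#' @param rules A `clin_context_rules`.
#' @param config A [pipeline_config()].
#' @return A tibble with the pair columns plus logical check columns
#'   `current`, `not_hypothetical`, `concerns_patient`, `not_negated`,
#'   `change_concerns_theme` (`TRUE` = pass) and `accepted`.
#' @export
apply_context_filter <- function(sentence, pairs, rules = context_rules(),
                                 config = pipeline_config()) {
  check_cols <- c(
    "current", "not_hypothetical", "concerns_patient", "not_negated",
    "change_concerns_theme"
  )
  if (!nrow(pairs)) {
    out <- pairs
    for (cc in c(check_cols, "accepted")) out[[cc]] <- logical()
    return(out)
  }
  res <- lapply(seq_len(nrow(pairs)), function(i) {
    pair <- pairs[i, ]
    checks <- c(
      current = check_temporality(sentence, pair, rules, config),
      not_hypothetical = check_hypothetical(sentence, pair, rules, config),
      concerns_patient = check_experiencer(sentence, pair, rules, config),
      not_negated = check_negation(sentence, pair, rules, config),
      change_concerns_theme = check_change_concerns_theme(sentence, pair, config)
    )
    checks
  })
  out <- pairs
  for (cc in check_cols) {
    out[[cc]] <- vapply(res, function(x) x[[cc]] == "pass", logical(1))
  }
  out$accepted <- vapply(res, combine_checks, logical(1))
  out
}
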