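# Brute-force reference implementations, deliberately written as plain loops
# so they stay independent of the package's vectorised/tree-walking internals.

# every (entry, start) pair tested directly; per-entry overlaps resolved
# greedily from the left
naive_lookup <- function(lex, tokens) {
  out <- list()
  n <- nrow(tokens)
  surf <- tolower(stringi::stri_trans_nfc(tokens$surface))
  lem <- tolower(stringi::stri_trans_nfc(tokens$lemma))
  for (e in seq_len(nrow(lex))) {
    target <- lex$phrase_tokens[[e]]
    k <- length(target)
    hay <- if (lex$match_mode[[e]] == "lemma") lem else surf
    taken <- rep(FALSE, n)
    for (i in seq_len(max(0L, n - k + 1L))) {
      span <- i:(i + k - 1L)
      if (all(hay[span] == target) && !any(taken[span])) {
        taken[span] <- TRUE
        out[[length(out) + 1L]] <- data.frame(
          phrase = lex$phrase[[e]], category = lex$category[[e]],
          theme = lex$theme[[e]], polarity = lex$polarity[[e]],
          start = i - 1L, end = i - 1L + k,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  if (!length(out)) {
    return(data.frame(
      phrase = character(), category = character(), theme = character(),
      polarity = integer(), start = integer(), end = integer(),
      stringsAsFactors = FALSE
    ))
  }
  do.call(rbind, out)
}

naive_trigger_cover <- function(tokens, rules, kind, terminators) {
  n <- nrow(tokens)
  surf <- tolower(stringi::stri_trans_nfc(tokens$surface))
  covered <- rep(FALSE, n)
  sel <- which(rules$kind == kind)
  for (r in sel) {
    trig <- rules$trigger_tokens[[r]]
    k <- length(trig)
    win <- rules$window[[r]]
    wn <- if (win == "sentence") n else as.integer(win)
    for (i in seq_len(max(0L, n - k + 1L))) {
      if (!all(surf[i:(i + k - 1L)] == trig)) next
      if (rules$scope[[r]] %in% c("forward", "bidirectional")) {
        j <- i + k
        cnt <- 0L
        while (j <= n && cnt < wn && !(surf[j] %in% terminators)) {
          covered[j] <- TRUE
          j <- j + 1L
          cnt <- cnt + 1L
        }
      }
      if (rules$scope[[r]] %in% c("backward", "bidirectional")) {
        j <- i - 1L
        cnt <- 0L
        while (j >= 1L && cnt < wn && !(surf[j] %in% terminators)) {
          covered[j] <- TRUE
          j <- j - 1L
          cnt <- cnt + 1L
        }
      }
    }
  }
  covered
}

# shortest undirected path in the dependency graph by breadth-first search
naive_dep_path <- function(tokens, a, b) {
  n <- nrow(tokens)
  adj <- vector("list", n)
  lab <- list()
  for (i in seq_len(n)) {
    h <- tokens$head[[i]]
    if (!is.na(h) && h >= 1L && h <= n) {
      adj[[i]] <- c(adj[[i]], h)
      adj[[h]] <- c(adj[[h]], i)
      lab[[paste(min(i, h), max(i, h))]] <- tokens$deprel[[i]]
    }
  }
  prev <- rep(NA_integer_, n)
  seen <- rep(FALSE, n)
  queue <- a
  seen[a] <- TRUE
  while (length(queue)) {
    cur <- queue[[1L]]
    queue <- queue[-1L]
    if (cur == b) break
    for (nb in adj[[cur]]) {
      if (!seen[nb]) {
        seen[nb] <- TRUE
        prev[nb] <- cur
        queue <- c(queue, nb)
      }
    }
  }
  if (!seen[b]) {
    return(NULL)
  }
  path <- b
  while (path[[1L]] != a) path <- c(prev[path[[1L]]], path)
  labels <- character()
  for (k in seq_len(length(path) - 1L)) {
    key <- paste(min(path[k], path[k + 1L]), max(path[k], path[k + 1L]))
    labels <- c(labels, lab[[key]])
  }
  list(n_edges = length(path) - 1L, labels = labels)
}

naive_anchor <- function(tokens, start, end) {
  rows <- (start + 1L):end
  for (r in rows) {
    h <- tokens$head[[r]]
    if (is.na(h) || h == 0L || h < start + 1L || h > end) {
      return(r)
    }
  }
  rows[[1L]]
}

# full per-sentence re-derivation: enumerate all (theme match, change match,
# context) combinations with plain loops and return per-theme scores
naive_sentence_scores <- function(sentence, lex, rules, config) {
  tok <- sentence$tokens
  th_lex <- lex[lex$category != "change", ]
  ch_lex <- lex[lex$category == "change", ]
  th <- naive_lookup(th_lex, tok)
  if (!nrow(th)) {
    return(data.frame(theme = character(), score = integer()))
  }
  ch <- naive_lookup(ch_lex, tok)
  ch <- data.frame(
    direction = ch$polarity, start = ch$start, end = ch$end,
    stringsAsFactors = FALSE
  )
  for (i in seq_len(nrow(tok))) {
    if (tok$degree[[i]] == "comparative") {
      inside_lex <- FALSE
      if (nrow(ch)) {
        inside_lex <- any(ch$start <= i - 1L & ch$end >= i)
      }
      if (!inside_lex) {
        ch <- rbind(ch, data.frame(direction = 1L, start = i - 1L, end = i))
      }
    }
  }
  if (!nrow(ch)) {
    return(data.frame(theme = character(), score = integer()))
  }
  cov <- list(
    negation = naive_trigger_cover(tok, rules, "negation", config$scope_terminators),
    hypothetical = naive_trigger_cover(tok, rules, "hypothetical", config$scope_terminators),
    experiencer = naive_trigger_cover(tok, rules, "non-patient-experiencer", config$scope_terminators),
    current = naive_trigger_cover(tok, rules, "non-current", config$scope_terminators)
  )
  hits <- function(covered, s, e) any(covered[(s + 1L):e])
  scores <- list()
  for (i in seq_len(nrow(th))) {
    best <- NA_integer_
    best_d <- Inf
    for (j in seq_len(nrow(ch))) {
      if (ch$start[[j]] < th$end[[i]] && ch$end[[j]] > th$start[[i]]) next
      d <- if (ch$end[[j]] <= th$start[[i]]) {
        th$start[[i]] - ch$end[[j]]
      } else {
        ch$start[[j]] - th$end[[i]]
      }
      if (d < best_d || (d == best_d && ch$start[[j]] < ch$start[[best]])) {
        best <- j
        best_d <- d
      }
    }
    if (is.na(best)) next
    j <- best
    bad <- hits(cov$negation, th$start[[i]], th$end[[i]]) ||
      hits(cov$negation, ch$start[[j]], ch$end[[j]]) ||
      hits(cov$hypothetical, th$start[[i]], th$end[[i]]) ||
      hits(cov$hypothetical, ch$start[[j]], ch$end[[j]]) ||
      hits(cov$experiencer, th$start[[i]], th$end[[i]]) ||
      hits(cov$current, th$start[[i]], th$end[[i]]) ||
      hits(cov$current, ch$start[[j]], ch$end[[j]])
    if (bad) next
    a <- naive_anchor(tok, th$start[[i]], th$end[[i]])
    b <- naive_anchor(tok, ch$start[[j]], ch$end[[j]])
    if (a != b) {
      p <- naive_dep_path(tok, a, b)
      if (is.null(p) || p$n_edges > config$dep_path_bound ||
        any(p$labels == "conj")) {
        next
      }
    }
    t <- th$theme[[i]]
    scores[[t]] <- (scores[[t]] %||% 0L) + th$polarity[[i]] * ch$direction[[j]]
  }
  if (!length(scores)) {
    return(data.frame(theme = character(), score = integer()))
  }
  data.frame(
    theme = names(scores), score = unlist(scores),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

naive_pipeline_scores <- function(notes, lex, rules = context_rules(),
                                  config = pipeline_config()) {
  rows <- list()
  for (i in seq_len(nrow(notes))) {
    for (s in segment(notes[i, ])) {
      sc <- naive_sentence_scores(s, lex, rules, config)
      if (nrow(sc)) {
        sc$note_id <- s$note_id
        sc$sentence_index <- s$sentence_index
        rows[[length(rows) + 1L]] <- sc
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(
      theme = character(), score = integer(), note_id = character(),
      sentence_index = integer(), stringsAsFactors = FALSE
    ))
  }
  out <- do.call(rbind, rows)
  out[order(out$note_id, out$sentence_index, out$theme), ]
}

# confusion metrics recomputed from first principles
naive_metrics <- function(truth, pred) {
  tab <- c(
    tp = sum(truth == "accept" & pred == "accept"),
    fp = sum(truth == "reject" & pred == "accept"),
    fn = sum(truth == "accept" & pred == "reject"),
    tn = sum(truth == "reject" & pred == "reject")
  )
  p <- if (tab[["tp"]] + tab[["fp"]] > 0) {
    tab[["tp"]] / (tab[["tp"]] + tab[["fp"]])
  } else {
    NA_real_
  }
  r <- if (tab[["tp"]] + tab[["fn"]] > 0) {
    tab[["tp"]] / (tab[["tp"]] + tab[["fn"]])
  } else {
    NA_real_
  }
  f <- if (!is.na(p) && !is.na(r) && p + r > 0) 2 * p * r / (p + r) else NA_real_
  list(
    counts = tab, accuracy = (tab[["tp"]] + tab[["tn"]]) / sum(tab),
    precision = p, recall = r, f1 = f
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
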