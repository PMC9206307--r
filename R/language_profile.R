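#' Language profile for the rule-based annotator
#'
#' A language profile bundles the word lists and suffix tables the rule-based
#' annotator needs: closed-class inventories for coarse part-of-speech tagging,
#' an open adjective list plus comparative/superlative suffix rules for degree
#' detection, verb inventories for finite-verb (and hence clause) detection,
#' and an irregular-lemma table. Profiles are plain lists so users can extend
#' any field for their own corpus vocabulary.
#'
#' The shipped `"en"` profile covers common clinical-note vocabulary and the
#' fixture corpus; the `"nl"` profile is a minimal Dutch starter set. Degree
#' suffix rules are language-configurable because comparative morphology
#' (English *-er/-ier*, Dutch *-er/-der*) differs across languages.
#'
#' Quantifiers such as "more"/"less" are deliberately absent from the
#' irregular-comparative table: they are change *phrases* carrying their own
#' direction in a lexicon, and listing them as comparatives would override a
#' lexicon-declared decrease direction (e.g. "less" = -1) with the fixed +1 of
#' comparative matches.
#'
#' @param language `"en"` or `"nl"`.
#' @param ... Named fields overriding or extending the defaults; character
#'   vector fields are unioned with the defaults.
#'
#' @return An object of class `clin_language_profile`: a named list with
#'   fields `language`, `adjectives`, `irregular_comparatives`,
#'   `irregular_superlatives`, `comparative_suffixes`, `superlative_suffixes`,
#'   `adverb_suffixes`, `verbs`, `aux`, `det`, `pron`, `cconj`, `sconj`,
#'   `adp`, `irregular_lemmas`.
#' @export
#' @examples
#' prof <- language_profile("en", adjectives = "cheerful")
#' "cheerful" %in% prof$adjectives
language_profile <- function(language = c("en", "nl"), ...) {
  language <- match.arg(language)
  base <- if (language == "en") profile_en() else profile_nl()
  extra <- list(...)
  for (nm in names(extra)) {
    if (!nm %in% names(base)) {
      abort(sprintf("unknown language profile field '%s'", nm))
    }
    if (is.character(base[[nm]]) && is.null(names(base[[nm]]))) {
      base[[nm]] <- unique(c(base[[nm]], extra[[nm]]))
    } else {
      base[[nm]] <- extra[[nm]]
    }
  }
  structure(base, class = "clin_language_profile")
}

profile_en <- function() {
  list(
    language = "en",
    adjectives = c(
      "angry", "anxious", "sad", "calm", "happy", "drowsy", "strong", "weak",
      "clear", "good", "bad", "big", "small", "quiet", "restless", "tired",
      "alert", "high", "low", "stable", "friendly", "hungry", "energetic",
      "depressed", "agitated", "cheerful", "close", "nice", "well", "sleepy",
      "irritable", "tense"
    ),
    irregular_comparatives = c(better = "good", worse = "bad"),
    irregular_superlatives = c(best = "good", worst = "bad"),
    comparative_suffixes = c("er", "ier"),
    superlative_suffixes = c("est", "iest"),
    adverb_suffixes = c("ly"),
    verbs = c(
      "increase", "increases", "increased", "decrease", "decreases",
      "decreased", "improve", "improves", "improved", "worsen", "worsens",
      "worsened", "report", "reports", "reported", "sleep", "slept", "feel",
      "feels", "felt", "respond", "responds", "responded", "call", "calls",
      "called", "seem", "seems", "seemed", "appear", "appears", "appeared",
      "show", "shows", "showed", "say", "says", "said", "go", "goes", "went",
      "note", "noted", "notes", "deny", "denies", "denied", "lack", "lacks",
      "lacked", "eat", "ate", "attend", "attended", "administer",
      "administered", "record", "recorded", "take", "took", "remain",
      "remains", "remained"
    ),
    aux = c(
      "is", "was", "are", "were", "am", "be", "been", "being", "did", "does",
      "do", "will", "would", "can", "could", "may", "might", "must", "should",
      "shall", "has", "had", "have"
    ),
    det = c(
      "the", "a", "an", "this", "that", "these", "those", "no", "some",
      "any", "each", "every", "his", "her", "their", "its", "our", "your", "my"
    ),
    pron = c(
      "he", "she", "it", "they", "we", "i", "you", "him", "them", "us",
      "me", "herself", "himself", "themselves", "who", "which"
    ),
    cconj = c("and", "or", "but", "nor"),
    sconj = c(
      "if", "because", "although", "while", "when", "since", "unless",
      "whether", "that"
    ),
    adp = c(
      "in", "on", "at", "of", "to", "with", "from", "for", "than", "by",
      "over", "during", "about", "after", "before", "into", "as"
    ),
    irregular_lemmas = c(
      slept = "sleep", felt = "feel", went = "go", said = "say", ate = "eat",
      took = "take", was = "be", were = "be", been = "be", is = "be",
      are = "be", am = "be", did = "do", does = "do", has = "have",
      had = "have", denies = "deny", denied = "deny"
    )
  )
}

profile_nl <- function() {
  list(
    language = "nl",
    adjectives = c(
      "boos", "angstig", "somber", "rustig", "blij", "moe", "druk", "goed",
      "slecht", "sterk", "zwak", "onrustig", "helder", "gespannen"
    ),
    irregular_comparatives = c(beter = "goed", slechter = "slecht"),
    irregular_superlatives = c(best = "goed", slechtst = "slecht"),
    comparative_suffixes = c("er", "der"),
    superlative_suffixes = c("st", "ste"),
    adverb_suffixes = character(),
    verbs = c(
      "toegenomen", "afgenomen", "verbeterd", "verslechterd", "slaapt",
      "sliep", "voelt", "voelde", "meldt", "meldde", "neemt", "nam", "toont",
      "toonde", "lijkt", "leek", "gaat", "ging", "zegt", "zei"
    ),
    aux = c(
      "is", "was", "zijn", "waren", "wordt", "werd", "worden", "werden",
      "heeft", "had", "hebben", "hadden", "kan", "kon", "zal", "zou", "moet",
      "mag", "ben", "bent"
    ),
    det = c(
      "de", "het", "een", "dit", "dat", "deze", "die", "geen", "zijn",
      "haar", "hun", "ons", "onze", "elke", "iedere"
    ),
    pron = c(
      "hij", "zij", "ze", "het", "wij", "we", "ik", "jij", "u", "hem",
      "haar", "hen", "zich", "zichzelf", "wie"
    ),
    cconj = c("en", "of", "maar", "noch"),
    sconj = c("als", "omdat", "hoewel", "terwijl", "wanneer", "tenzij", "dat"),
    adp = c(
      "in", "op", "aan", "van", "naar", "met", "uit", "voor", "dan", "door",
      "over", "tijdens", "na", "bij", "tot"
    ),
    irregular_lemmas = c(
      sliep = "slapen", voelde = "voelen", ging = "gaan", zei = "zeggen",
      was = "zijn", waren = "zijn", is = "zijn", had = "hebben",
      hadden = "hebben", werd = "worden", werden = "worden"
    )
  )
}

# Candidate base forms for a comparative/superlative surface, given suffixes:
# strip "ier"->"y" style endings first, then plain suffix, undouble a doubled
# final consonant, and restore a final "e" (nicer -> nice).
degree_base <- function(word, suffixes, y_restore, profile) {
  cands <- character()
  for (suf in suffixes) {
    if (!endsWith(word, suf) || nchar(word) <= nchar(suf) + 1) next
    stem <- substr(word, 1L, nchar(word) - nchar(suf))
    if (y_restore && startsWith(suf, "i")) {
      cands <- c(cands, paste0(stem, "y"))
      next
    }
    cands <- c(cands, stem)
    n <- nchar(stem)
    if (n >= 2 && substr(stem, n, n) == substr(stem, n - 1L, n - 1L)) {
      cands <- c(cands, substr(stem, 1L, n - 1L)) # bigger -> big
    }
    cands <- c(cands, paste0(stem, "e")) # nicer -> nice
  }
  hit <- cands[cands %in% profile$adjectives]
  if (length(hit)) hit[[1L]] else NA_character_
}

comparative_base <- function(word, profile) {
  irr <- profile$irregular_comparatives
  if (word %in% names(irr)) {
    return(unname(irr[[word]]))
  }
  degree_base(word, profile$comparative_suffixes, TRUE, profile)
}

superlative_base <- function(word, profile) {
  irr <- profile$irregular_superlatives
  if (word %in% names(irr)) {
    return(unname(irr[[word]]))
  }
  degree_base(word, profile$superlative_suffixes, TRUE, profile)
}

#' @export
print.clin_language_profile <- function(x, ...) {
  cat(sprintf(
    "<clin_language_profile '%s': %d adjectives, %d verbs>\n",
    x$language, length(x$adjectives), length(x$verbs)
  ))
  invisible(x)
}
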