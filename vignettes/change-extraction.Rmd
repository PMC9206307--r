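---
title: "Extracting moments of change from clinical notes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Extracting moments of change from clinical notes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Psychiatric treatment outcomes are poorly captured by structured fields in
electronic health records. Diagnosis-specific rating scales are sparse
outside trial settings, while the information clinicians actually care about
— symptom reduction, social functioning, general well-being, the patient's
own experience — lives in free-text doctors' and nurses' notes. Those notes
are highly repetitive: daily entries restate an unchanged status over and
over. The sentences worth extracting are the ones that describe a *change*
in the patient's state.

`clinchange` implements a semi-rule-based pipeline for exactly that task. It
is lexicon-driven: every phrase inventory (theme phrases, change phrases,
context triggers) is data supplied by the user, so the same code runs on any
language or corpus for which such lists exist. The package ships small
English fixtures and a Dutch starter rule set; they are synthetic
demonstration inventories, not a validated clinical phrase list, and any
serious application must supply corpus-tailored lists.

## The pipeline

The unit of analysis is the sentence. Five steps:

1. **Segmentation and annotation.** Notes are split into sentences
   (terminal punctuation plus newlines: nursing notes are line-structured,
   so every non-empty line is a sentence boundary). Tokens carry surface,
   lemma, coarse part of speech, morphological degree, and a dependency
   head/relation. The annotation backend is pluggable; the shipped backend
   is rule-based (closed-class word lists, suffix heuristics, an
   irregular-form table, and a clause-oriented dependency sketch). Nothing
   downstream reaches past the token contract, so a statistical tagger can
   be substituted without touching the filters.
2. **Theme filter.** A sentence survives only if at least one lexicon
   phrase for some theme matches. Themes filter independently; a phrase
   listed under two themes fires for both.
3. **Change filter.** A surviving sentence must also contain a change cue:
   a lexicon change phrase carrying a direction (+1 increase, −1 decrease),
   or a token in comparative degree ("angrier"), which always carries
   direction +1 — "angrier" is *more* anger; the sign comes from the theme
   polarity. Without a cue the sentence is cancelled.
4. **Context filter.** Each candidate (theme match, change match) pair must
   pass five checks: the phrases are current, not hypothetical, concern the
   patient, are not negated, and the change grammatically concerns the
   theme. The first four are trigger/scope rules in the style of the
   ConText algorithm: a trigger phrase projects a scope forward, backward
   or both, up to a token window or the sentence boundary, cut short by
   scope terminators ("but", ";", …). A pair dies if a negation or
   hypothetical trigger scopes either member, if a non-patient-experiencer
   trigger scopes the theme match, or if a history/future trigger scopes
   either member. The fifth check is syntactic: the dependency path between
   the two matches must have at most `dep_path_bound` edges and must not
   cross a clause boundary (a `"conj"` edge). This accepts "anxiety
   symptoms increased" and rejects "We increased the medication doses but
   the patient's anxiety did not respond", where the change verb sits in a
   different clause than the theme word.
5. **Scoring.** Each accepted pair contributes
   `polarity(theme) x direction(change)` in `{-1, +1}`; per theme,
   contributions add. "More anxiety" scores −1, "participation improved"
   +1, "the patient was more anxious and sad" −2 (one shared "more", two
   theme words). Per patient or per admission trajectory, the summary is
   the mean sentence score over sentences that passed — scores {−2, 1, 2}
   give 1/3.

## Design decisions the task left open

* **Pairing rule.** Nothing in the scoring definition fixes *which* change
  cue licenses which theme phrase when several of each occur. We pair each
  theme match with its nearest change match by token distance (ties to the
  leftmost), and allow one change match to serve several theme matches.
  This is the weakest rule that makes the additive two-theme example work
  (a single "more" licensing both "anxious" and "sad"), and it is
  deterministic. A theme match never pairs with a change match overlapping
  its own span, which prevents a comparative theme word from licensing
  itself.
* **Comparatives are always +1.** A comparative states that some quality
  is present to a higher degree; whether that is good or bad is the theme
  phrase's job. Treating "less" as a comparative would wrongly override its
  lexicon direction (−1), so quantifiers are deliberately excluded from the
  irregular-comparative table and handled as lexicon change entries.
* **Undefined means stay missing.** For a patient with no accepted sentence
  for a theme, the mean is `NA`, never 0: not every patient has a recorded
  change on every theme, and 0 would fabricate a neutral observation.
* **Aggregation key.** Trajectory (one inpatient admission) is the primary
  reporting unit; patient-level aggregation is needed when comparing
  against per-patient instruments. `run_pipeline()` emits both.
* **Match mode.** Exact-token matching of case-folded surfaces is the
  default. A `lemma` match mode is available per entry because inflectional
  morphology (verb conjugation, in particular) is a known recall killer for
  surface lists; it is opt-in so that behaviour with a surface-only list is
  the reference behaviour.
* **Evaluation convention.** `"accept"` is the positive class. Undefined
  precision/recall (empty denominators) are reported as `NA`, not 0 or 1.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `dep_path_bound` | 3 edges | maximum dependency-path length for the linkage check |
| `fallback_window` | 6 tokens | token-distance bound when no dependencies are available |
| `scope_terminators` | but, however, although, ";" | tokens that end a trigger scope |
| `clause_delimiters` | and, or, but, ";", "," | candidate clause boundaries (effective only when followed by a finite verb) |
| rule `window` | per rule | trigger scope extent, a token count or sentence-bounded |

The defaults reproduce the canonical linkage examples above; all are config
keys, because trigger inventories and scope conventions are corpus-specific
and no published inventory was available to copy.

## The rule-based annotator

The shipped backend trades coverage for transparency. Part of speech comes
from closed-class lists plus suffixes (`-ly` adverbs, `-ed`/`-ing` verbs),
defaulting to noun. Degree detection strips comparative/superlative
suffixes (`-er`/`-ier`, `-est`), undoubles final consonants, restores final
`e`, and consults an irregular table (better, worse, …); a candidate is a
comparative only if the recovered stem is a known adjective, which keeps
"mother", "never" and "anger" out. The dependency sketch segments a
sentence into clauses at coordinating conjunctions and at `;`/`,` — but
only when the following material contains a finite verb, so "more anxious
and sad" stays one clause — attaches tokens to their clause head, and
chains clause heads to the root with `"conj"` edges. This is not a parser;
it is the minimal structure the linkage check needs, and the contract tests
run identically against it and against any substituted backend.

## The synthetic corpus generator

Real psychiatric notes cannot be shared, so the test corpus is generated.
`generate_corpus()` emulates the statistical skeleton the pipeline assumes:

* theme mentions are common but change sentences are sparse — the default
  `p_change_given_theme = 0.12` keeps accepted change sentences roughly an
  order of magnitude rarer than theme sentences, the regime reported for
  real inpatient trajectories (on the order of a hundred theme sentences
  but fewer than ten change sentences per admission);
* a sentence that does carry a change is corrupted with probability
  0.12/0.05/0.07/0.06 (negation / hypothetical / non-patient experiencer /
  history), drawn once per sentence;
* `polarity_mix = 0.5` balances positive and negative theme phrases;
* repeated status sentences recur across a trajectory's notes
  (`p_repetition = 0.1`), mimicking the repetitiveness that motivates
  change filtering in the first place.

Ground truth is constructed at generation time from the template algebra —
never by running the pipeline — so end-to-end tests are non-circular.
Templates keep accepted theme/change pairs adjacent within one clause and
put every corruption trigger in sentence-initial position with
sentence-bounded scope, so the intended verdict is unambiguous under the
fixture rules.

What the generator does **not** emulate: real clinical language (free word
order, ellipsis, abbreviations, misspellings), Dutch morphology beyond the
starter suffix table, ambiguous triggers, or annotator disagreement.
Perfect precision/recall on generated corpora therefore demonstrates
internal consistency of the five stages — that the implementation does
exactly what the rules say — not performance on real notes, where published
rule-based systems of this type show high accuracy but markedly imperfect
recall.

## Numerical and degenerate-input choices

Sentence scores are integers; summary means are doubles (tests compare at
tolerance 1e-12). Matching is greedy left-to-right per entry with maximal
non-overlapping spans; different entries may overlap. Character and token
spans are 0-based half-open; sentence indices are 1-based. Empty notes are
an error; an empty note *list*, an empty lexicon and an empty rule set are
valid degenerate inputs (the empty rule set makes the four trigger-based
checks pass everywhere, leaving the linkage check active). Lexicon
construction is canonically ordered, so file row order never matters.

## Validation problem sizes

The test suite validates the pipeline against independent brute-force
re-derivations (all-pairs phrase scans, breadth-first dependency paths,
first-principles confusion counts): 200 random corpora of up to ~60
sentences for the enumeration oracle, one corpus of roughly 10,000
sentences for end-to-end ground-truth recovery, 1,000 random confusion
matrices for the metric identities, and exhaustive enumeration for the
32-way check conjunction and the structured-source antisymmetry. These
sizes were chosen to exercise every code path many times while keeping the
default `R CMD check` run comfortably interactive.

## Known limitations

* Recall is bounded by the phrase lists; inflectional variants must be
  listed or matched in lemma mode.
* The five checks are sentence-bounded; cross-sentence context ("see
  yesterday's note") is invisible by design.
* The severity orderings shipped for juridical status and dismissal
  destination are placeholders and must be declared per institution.
* The regression of theme scores against an external instrument (e.g. a
  depression rating scale) is deliberately out of scope: it is routine
  modelling on top of this package's outputs, not part of the extraction
  method.
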