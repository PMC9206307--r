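# clinchange

Lexicon-driven extraction and sentiment scoring of *moments of change* in
clinical free text.

Psychiatric EHR notes record treatment outcomes — symptom reduction, social
functioning, general well-being, patient experience — almost exclusively as
free text, and they do so repetitively: most daily entries restate an
unchanged status. `clinchange` finds the sentences that describe a change
in the patient's state on such transdiagnostic outcome themes, scores each
one, and aggregates the scores per patient or admission trajectory. It is
aimed at clinical-NLP researchers and health-informatics teams who have (or
can author) phrase lists for their own corpus and language: every
inventory the pipeline uses is a data file, not code.

## The method

The unit of analysis is the sentence. For each sentence:

1. **Annotate** — split notes into sentences, tag tokens (lemma, POS,
   morphological degree, dependency head); the backend is pluggable and a
   rule-based annotator ships with the package.
2. **Theme filter** — keep sentences containing a theme phrase from the
   lexicon; each theme phrase carries a polarity *p* ∈ {−1, +1}
   ("anxiety" −1, "joy" +1).
3. **Change filter** — keep sentences containing a change cue with
   direction *d* ∈ {−1, +1}: a change phrase ("improvement" +1, "less" −1)
   or a comparative adjective form ("angrier", always +1).
4. **Context filter** — pair each theme match with its nearest change cue
   and apply five checks: current, not hypothetical, concerns the patient,
   not negated (trigger/scope rules in the ConText style), and the change
   grammatically concerns the theme (clause-internal dependency path).
5. **Score** — every accepted pair contributes *p × d*; per theme the
   contributions add. "More anxiety" → −1; "participation improved" → +1;
   "the patient was more anxious and sad" → (−1·1) + (−1·1) = −2. The
   summary score per patient/trajectory and theme is the mean over scored
   sentences: scores {−2, 1, 2} → 1/3. No scored sentence → the mean is
   missing, never 0.

An evaluation harness compares pipeline accept/reject decisions against
human sentence annotations (accuracy, precision, recall, F1), a synthetic
corpus generator with constructive ground truth makes every stage testable
without clinical data, and structured EHR fields (prescription counts,
juridical status, dismissal destination) can be encoded as
worsened/unchanged/improved categories and merged with the text scores.

## Worked example

```r
library(clinchange)

lex   <- default_fixture_lexicon()   # shipped demo lexicon (TSV under extdata)
rules <- default_fixture_rules()     # shipped demo context triggers

notes <- data.frame(
  patient_id = "P1", trajectory_id = "T1", note_id = "N1",
  date = as.Date("2020-03-02"),
  text = paste(
    "Patient is still anxious.",
    "More interaction with the group today.",
    "Mood did not improve."
  )
)

res <- run_pipeline(notes, lex, rules)
res$sentence_scores
#> # A tibble: 1 × 7
#>   patient_id trajectory_id note_id sentence_index theme  score n_pairs
#>   <chr>      <chr>         <chr>            <int> <chr>  <int>   <int>
#> 1 P1         T1            N1                   2 social     1       1
```

Sentence 1 mentions a theme ("anxious") but no change cue, so it is
cancelled at step 3; sentence 3 has both ("mood", "improve") but the change
word is negated, so its pair is rejected by the context filter; only
sentence 2 is scored: "interaction" (+1) × "more" (+1) = +1 on the social
functioning theme. The trace records this per stage:

```r
res$trace$stage_counts
#> # A tibble: 4 × 6
#>   theme      n_sentences n_theme n_change n_accepted n_scored
#>   <chr>            <int>   <int>    <int>      <int>    <int>
#> 1 experience           3       0        0          0        0
#> 2 social               3       1        1          1        1
#> 3 symptoms             3       1        0          0        0
#> 4 wellbeing            3       1        1          0        0
```

and the trajectory summary keeps undefined means missing:

```r
subset(res$summaries, key == "trajectory" & n_theme_sentences > 0)
#> # A tibble: 3 × 6
#>   key        key_id theme    n_theme_sentences n_change_sentences mean_sentiment
#>   <chr>      <chr>  <chr>                <int>              <int>          <dbl>
#> 1 trajectory T1     social                   1                  1              1
#> 2 trajectory T1     symptoms                 1                  0             NA
#> 3 trajectory T1     wellbei…                 1                  0             NA
```

A command-line wrapper for batch use (`run`, `evaluate`, `generate`
subcommands) is in `inst/cli/clinchange.R`.

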