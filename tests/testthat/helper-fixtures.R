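# Small in-code fixtures shared across tests.

mini_lexicon <- function() {
  lexicon(data.frame(
    phrase = c(
      "anxiety", "anxious", "sad", "mood", "participation", "interaction",
      "energy", "contact",
      "more", "less", "improved", "improve", "improvement", "increased"
    ),
    category = c(
      "theme:symptoms", "theme:symptoms", "theme:symptoms", "theme:wellbeing",
      "theme:social", "theme:social", "theme:wellbeing", "theme:social",
      rep("change", 6)
    ),
    polarity = c(-1, -1, -1, 1, 1, 1, 1, 1, 1, -1, 1, 1, 1, 1)
  ))
}

mini_rules <- function() {
  context_rules(data.frame(
    trigger = c("not", "no", "if", "possibly", "mother", "sister", "years ago"),
    kind = c(
      "negation", "negation", "hypothetical", "hypothetical",
      "non-patient-experiencer", "non-patient-experiencer", "non-current"
    ),
    scope = "forward",
    window = "sentence"
  ))
}

make_note <- function(text, patient_id = "P1", trajectory_id = "T1",
                      note_id = "N1", date = as.Date("2020-01-01")) {
  tibble::tibble(
    patient_id = patient_id, trajectory_id = trajectory_id,
    note_id = note_id, date = date, text = text
  )
}

one_sentence <- function(text, annotator = rule_annotator()) {
  segment(make_note(text), annotator)[[1]]
}
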