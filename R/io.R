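#' Read clinical notes
#'
#' Notes are one record per line of JSONL (keys `patient_id`,
#' `trajectory_id`, `note_id`, `date` ISO-8601, `text`) or a CSV with the
#' same columns.
#'
#' @param path File path.
#' @param format `"auto"` (by extension), `"jsonl"` or `"csv"`.
#' @return A tibble of notes.
#' @export
read_notes <- function(path, format = c("auto", "jsonl", "csv")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("jsonl", "ndjson", "json")) "jsonl" else "csv"
  }
  notes <- if (format == "jsonl") {
    read_jsonl(path)
  } else {
    readr::read_csv(path,
      col_types = readr::cols(.default = readr::col_character()),
      progress = FALSE
    )
  }
  need <- c("patient_id", "trajectory_id", "note_id", "date", "text")
  miss <- setdiff(need, names(notes))
  if (length(miss)) {
    abort(sprintf("notes missing column(s): %s", paste(miss, collapse = ", ")))
  }
  notes$date <- as.Date(notes$date)
  tibble::as_tibble(notes)[, need]
}

#' @rdname read_notes
#' @param notes A notes tibble.
#' @export
write_notes_jsonl <- function(notes, path) {
  write_jsonl(notes, path)
}

read_jsonl <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  rows <- lapply(lines, function(l) {
    tibble::as_tibble(jsonlite::fromJSON(l, simplifyVector = TRUE))
  })
  dplyr::bind_rows(rows)
}

write_jsonl <- function(df, path) {
  df <- as.data.frame(df)
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  for (i in seq_len(nrow(df))) {
    writeLines(
      jsonlite::toJSON(as.list(df[i, , drop = FALSE]),
        auto_unbox = TRUE, null = "null", na = "null"
      ),
      con
    )
  }
  invisible(path)
}

#' Read accept/reject sentence annotations
#'
#' Two dialects are supported: the span-annotation-tool JSONL export (objects
#' with keys `text`, `label` holding the theme name, and `answer` holding
#' `"accept"`/`"reject"`) and a plain CSV with columns `text`, `theme`,
#' `label`.
#'
#' @param path File path.
#' @param format `"auto"` (by extension), `"jsonl"` or `"csv"`.
#' @return A tibble with columns `text`, `theme`, `label`.
#' @export
read_labels <- function(path, format = c("auto", "jsonl", "csv")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("jsonl", "ndjson", "json")) "jsonl" else "csv"
  }
  if (format == "jsonl") {
    raw <- read_jsonl(path)
    need <- c("text", "label", "answer")
    miss <- setdiff(need, names(raw))
    if (length(miss)) {
      abort(sprintf(
        "annotation JSONL missing key(s): %s", paste(miss, collapse = ", ")
      ))
    }
    out <- tibble::tibble(text = raw$text, theme = raw$label, label = raw$answer)
  } else {
    out <- readr::read_csv(path,
      col_types = readr::cols(.default = readr::col_character()),
      progress = FALSE
    )
    miss <- setdiff(c("text", "theme", "label"), names(out))
    if (length(miss)) {
      abort(sprintf(
        "annotation CSV missing column(s): %s", paste(miss, collapse = ", ")
      ))
    }
    out <- tibble::as_tibble(out)[, c("text", "theme", "label")]
  }
  if (!all(out$label %in% c("accept", "reject"))) {
    abort("annotation labels must be 'accept' or 'reject'")
  }
  out
}

#' Write pipeline outputs
#'
#' `write_scores_jsonl()` writes sentence-level scores as JSONL;
#' `write_summaries_csv()` writes patient/trajectory summaries as CSV with
#' undefined means as empty fields; `write_report_csv()` writes an
#' [evaluate()] report; `write_trace_jsonl()` writes the per-sentence stage
#' trace for error analysis.
#'
#' @param result A `clin_pipeline_result` from [run_pipeline()], or the
#'   corresponding tibble for the report writer.
#' @param path Output file path.
#' @name pipeline_io
NULL

#' @rdname pipeline_io
#' @export
write_scores_jsonl <- function(result, path) {
  write_jsonl(result$sentence_scores, path)
}

#' @rdname pipeline_io
#' @export
write_summaries_csv <- function(result, path) {
  readr::write_csv(result$summaries, path, na = "", progress = FALSE)
}

#' @rdname pipeline_io
#' @param report An [evaluate()] report tibble.
#' @export
write_report_csv <- function(report, path) {
  readr::write_csv(report, path, na = "", progress = FALSE)
}

#' @rdname pipeline_io
#' @export
write_trace_jsonl <- function(result, path) {
  write_jsonl(result$trace$sentence_trace, path)
}
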