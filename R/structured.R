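#' Default orderings for structured EHR sources
#'
#' Each structured source needs a declared direction in which larger values
#' mean a worse state before start/end values can be compared. Counts
#' (prescriptions) are compared numerically; ordinal sources are compared via
#' an explicit severity ranking. The shipped rankings for juridical status
#' and dismissal destination are configurable placeholders — institutions
#' should declare their own.
#'
#' @return A named list; each element has fields `type` (`"count"` or
#'   `"ordinal"`), `larger_is` (`"worse"` or `"better"`), and for ordinals
#'   `levels` ordered from least to most severe.
#' @export
default_source_orderings <- function() {
  list(
    benzodiazepine_prescriptions = list(type = "count", larger_is = "worse"),
    other_psychiatric_medication = list(type = "count", larger_is = "worse"),
    juridical_status = list(
      type = "ordinal", larger_is = "worse",
      levels = c("voluntary", "conditional", "involuntary")
    ),
    destination = list(
      type = "ordinal", larger_is = "worse",
      levels = c(
        "independent_home", "home_with_support", "sheltered_housing",
        "clinical_facility"
      )
    )
  )
}

#' Encode start/end observations as three-level change categories
#'
#' Structured EHR fields enter the joint outcome table as categorical
#' changes: `worsened` when the end-of-admission value is worse than the
#' start value under the source's declared ordering (e.g. more
#' benzodiazepine prescriptions at the end than at the start), `unchanged`
#' when equal, `improved` otherwise.
#'
#' @param obs A data frame with columns `patient_id`, `source`,
#'   `value_at_start`, `value_at_end`.
#' @param orderings A list like [default_source_orderings()]; must contain
#'   every source present in `obs`.
#' @return A tibble `patient_id`, `source`, `category` (factor with levels
#'   `worsened`, `unchanged`, `improved`).
#' @export
#' @examples
#' encode_change(data.frame(
#'   patient_id = "P1", source = "benzodiazepine_prescriptions",
#'   value_at_start = 1, value_at_end = 3
#' ))
encode_change <- function(obs, orderings = default_source_orderings()) {
  obs <- tibble::as_tibble(obs)
  need <- c("patient_id", "source", "value_at_start", "value_at_end")
  miss <- setdiff(need, names(obs))
  if (length(miss)) {
    abort(sprintf(
      "structured observations missing column(s): %s",
      paste(miss, collapse = ", ")
    ))
  }
  if (anyDuplicated(obs[, c("patient_id", "source")])) {
    abort("duplicate (patient_id, source) observation")
  }
  severity <- function(value, source) {
    ord <- orderings[[source]]
    if (is.null(ord)) {
      abort(sprintf("no ordering declared for source '%s'", source))
    }
    v <- if (ord$type == "count") {
      num <- suppressWarnings(as.numeric(value))
      if (is.na(num)) {
        abort(sprintf("non-numeric count for source '%s'", source))
      }
      num
    } else {
      idx <- match(as.character(value), ord$levels)
      if (is.na(idx)) {
        abort(sprintf(
          "value '%s' not comparable under source '%s' ordering",
          value, source
        ))
      }
      idx
    }
    if (ord$larger_is == "worse") v else -v
  }
  category <- character(nrow(obs))
  for (i in seq_len(nrow(obs))) {
    s0 <- severity(obs$value_at_start[[i]], obs$source[[i]])
    s1 <- severity(obs$value_at_end[[i]], obs$source[[i]])
    category[[i]] <- if (s1 > s0) {
      "worsened"
    } else if (s1 == s0) {
      "unchanged"
    } else {
      "improved"
    }
  }
  tibble::tibble(
    patient_id = as.character(obs$patient_id),
    source = as.character(obs$source),
    category = factor(category, levels = c("worsened", "unchanged", "improved"))
  )
}

#' Merge text-derived theme summaries with structured change categories
#'
#' Assembles one row per patient: the per-theme mean sentiment columns
#' (`mean_<theme>`, missing means stay missing) next to one categorical
#' column per structured source (factor with `worsened` as the reference
#' level, ready for one-hot contrasts). Lossless: every summary and category
#' appears exactly once; the output is sorted by patient id, so input order
#' does not matter.
#'
#' @param summaries Patient-level rows of a [run_pipeline()] summary table
#'   (`key == "patient"`), or any tibble with `key_id`, `theme`,
#'   `mean_sentiment`.
#' @param categories Output of [encode_change()].
#' @return A tibble with one row per patient.
#' @export
merge_outcomes <- function(summaries, categories) {
  summaries <- tibble::as_tibble(summaries)
  if ("key" %in% names(summaries)) {
    summaries <- summaries[summaries$key == "patient", ]
  }
  if (anyDuplicated(summaries[, c("key_id", "theme")])) {
    abort("duplicate (patient, theme) summary")
  }
  if (anyDuplicated(categories[, c("patient_id", "source")])) {
    abort("duplicate (patient_id, source) category")
  }
  wide_s <- tidyr::pivot_wider(
    summaries[, c("key_id", "theme", "mean_sentiment")],
    names_from = "theme", values_from = "mean_sentiment",
    names_prefix = "mean_"
  )
  names(wide_s)[names(wide_s) == "key_id"] <- "patient_id"
  wide_c <- tidyr::pivot_wider(
    dplyr::mutate(categories,
      category = as.character(.data$category)
    ),
    names_from = "source", values_from = "category"
  )
  out <- dplyr::full_join(wide_s, wide_c, by = "patient_id")
  src_cols <- setdiff(names(wide_c), "patient_id")
  for (src in src_cols) {
    out[[src]] <- factor(out[[src]],
      levels = c("worsened", "unchanged", "improved")
    )
  }
  # deterministic row and column order regardless of input order
  mean_cols <- setdiff(names(wide_s), "patient_id")
  out <- out[order(out$patient_id),
    c("patient_id", sort(mean_cols), sort(src_cols))
  ]
  out
}
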