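write_jsonl <- function(records, path) {
  lines <- vapply(records, function(r) {
    jsonlite::toJSON(r, auto_unbox = TRUE, digits = NA, null = "null")
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

read_jsonl <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lapply(lines[nzchar(lines)], jsonlite::fromJSON)
}

#' Write a corpus (and its ground truth) as JSONL
#'
#' The corpus file carries one object per report with `report_id`, `text`
#' and `category`; the ground truth goes to a separate file keyed by
#' `report_id`, simulating the blinded setting in which the answer
#' pipeline sees only the narratives.
#'
#' @param corpus An `mqa_corpus`.
#' @param path Corpus JSONL path.
#' @param truth_path Optional ground-truth JSONL path.
#' @return `path`, invisibly.
#' @export
write_corpus_jsonl <- function(corpus, path, truth_path = NULL) {
  stopifnot(inherits(corpus, "mqa_corpus"))
  recs <- lapply(seq_len(nrow(corpus$reports)), function(i) {
    list(report_id = corpus$reports$report_id[i],
         text = corpus$reports$text[i],
         category = corpus$reports$category[i])
  })
  write_jsonl(recs, path)
  if (!is.null(truth_path)) {
    t_recs <- lapply(seq_len(nrow(corpus$truth)), function(i) {
      row <- as.list(corpus$truth[i, ])
      row[vapply(row, function(v) length(v) == 1 && is.na(v), logical(1))] <- NULL
      row
    })
    write_jsonl(t_recs, truth_path)
  }
  invisible(path)
}

#' Read a JSONL corpus written by [write_corpus_jsonl()]
#'
#' @param path Corpus JSONL path.
#' @return Tibble with `report_id`, `text`, `category`.
#' @export
read_corpus_jsonl <- function(path) {
  recs <- read_jsonl(path)
  tibble::tibble(
    report_id = vapply(recs, `[[`, character(1), "report_id"),
    text = vapply(recs, `[[`, character(1), "text"),
    category = vapply(recs, function(r) r$category %||% NA_character_,
                      character(1)))
}

#' Write an answer set as JSONL
#'
#' One object per (report, question) with the backend id, the raw
#' free-text answer and the canonical value.
#'
#' @param answers Answer tibble from [run_mqa()] or [truth_answers()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_answers_jsonl <- function(answers, path) {
  recs <- lapply(seq_len(nrow(answers)), function(i) {
    list(report_id = answers$report_id[i],
         question_id = answers$question_id[i],
         backend_id = answers$source_id[i] %||% NA_character_,
         raw_text = if ("raw_text" %in% names(answers))
           answers$raw_text[i] else NA_character_,
         canonical_value = answers$value[i])
  })
  write_jsonl(recs, path)
  invisible(path)
}

#' Read an answer set written by [write_answers_jsonl()]
#'
#' @param path Answers JSONL path.
#' @return Tibble with `report_id`, `question_id`, `source_id`,
#'   `raw_text`, `value`.
#' @export
read_answers_jsonl <- function(path) {
  recs <- read_jsonl(path)
  grab <- function(field) {
    vapply(recs, function(r) {
      v <- r[[field]]
      if (is.null(v)) NA_character_ else as.character(v)
    }, character(1))
  }
  tibble::tibble(report_id = grab("report_id"),
                 question_id = grab("question_id"),
                 source_id = grab("backend_id"),
                 raw_text = grab("raw_text"),
                 value = grab("canonical_value"))
}

#' Write a concordance table as CSV
#'
#' Columns: `question_id`, `pair`, `concordant`, `total`, `rate`.
#'
#' @param table A `concordance_table` from [per_question_rates()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_concordance_csv <- function(table, path) {
  stopifnot(inherits(table, "concordance_table"))
  utils::write.csv(as.data.frame(table$per_question), path,
                   row.names = FALSE)
  invisible(path)
}
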