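#' Answer every question for every report in a corpus
#'
#' Runs the full MQA pipeline over the malignant reports of a corpus: for
#' each report the token budget decides between full-text context and
#' segment retrieval ([select_context()]); each question's context is
#' passed to the answer backend and the free-text answer is normalized to
#' a canonical value. Segment embeddings are computed once per report and
#' reused across the 12 questions.
#'
#' @param corpus An `mqa_corpus`, or a tibble of reports with `report_id`
#'   and `text` columns.
#' @param questions Question tibble, see [load_questions()].
#' @param backend Answer backend, see [reference_backend()].
#' @param embedder Embedder for retrieval scoring.
#' @param k Segments to retrieve (default 3).
#' @param token_limit Token budget (default 2048).
#' @param segment_length Segment length in characters (default 1200).
#' @param token_counter Function text -> token count.
#' @return Tibble with one row per (report, question):
#'   `report_id`, `question_id`, `source_id`, `used_full_text`,
#'   `raw_text`, `value`.
#' @export
run_mqa <- function(corpus, questions = load_questions(),
                    backend = reference_backend(),
                    embedder = hashed_tf_embedder(), k = 3L,
                    token_limit = 2048L, segment_length = 1200L,
                    token_counter = count_tokens) {
  reports <- if (inherits(corpus, "mqa_corpus")) {
    corpus$reports[corpus$reports$category == "thyroid_malignant", ,
                   drop = FALSE]
  } else {
    corpus
  }
  q_vecs <- lapply(questions$text, embed_text, embedder = embedder)
  out <- vector("list", nrow(reports))
  for (i in seq_len(nrow(reports))) {
    text <- reports$text[i]
    split_needed <- needs_splitting(text, token_limit, token_counter)
    segs <- NULL
    seg_vecs <- NULL
    if (split_needed) {
      segs <- segment_text(text, segment_length)
      seg_vecs <- lapply(segs$text, embed_text, embedder = embedder)
    }
    raw_texts <- character(nrow(questions))
    values <- character(nrow(questions))
    for (j in seq_len(nrow(questions))) {
      question <- questions[j, ]
      context <- if (split_needed) {
        scores <- vapply(seg_vecs, cosine_similarity, numeric(1),
                         b = q_vecs[[j]])
        select_from_scores(segs, scores, k)$context_text
      } else {
        text
      }
      raw <- answer_question(context, question, backend)
      raw_texts[j] <- raw$text
      values[j] <- normalize_answer(raw$text, question)
    }
    out[[i]] <- tibble::tibble(
      report_id = reports$report_id[i],
      question_id = questions$question_id,
      source_id = backend$id,
      used_full_text = !split_needed,
      raw_text = raw_texts,
      value = values)
  }
  resolve_conditionals(do.call(rbind, out), questions)
}

# Conditional items: when the triggering question's answer is negative the
# canonical value is not_applicable (e.g. positive-node count without
# nodes, second-cancer histology without a second cancer).
resolve_conditionals <- function(answers, questions) {
  cond <- questions[!is.na(questions$depends_on_id), , drop = FALSE]
  for (i in seq_len(nrow(cond))) {
    trigger_value <- if (cond$depends_on_value[i]) "yes" else "no"
    trig <- answers[answers$question_id == cond$depends_on_id[i], ]
    inactive <- trig$report_id[trig$value != trigger_value &
                                 trig$value != "not_stated"]
    idx <- answers$question_id == cond$question_id[i] &
      answers$report_id %in% inactive
    answers$value[idx] <- "not_applicable"
  }
  answers
}

#' Ground-truth answer set for a corpus
#'
#' Maps each malignant report's truth record to the canonical answer of
#' every question in the schema, giving the gold-standard answer set the
#' pipeline is evaluated against. Conditional items get `not_applicable`
#' when their trigger is negative.
#'
#' @param corpus An `mqa_corpus`.
#' @param questions Question tibble.
#' @return Tibble with `report_id`, `question_id`, `source_id` (`TRUTH`),
#'   `value`.
#' @export
truth_answers <- function(corpus, questions = load_questions()) {
  stopifnot(inherits(corpus, "mqa_corpus"))
  truth <- corpus$truth[corpus$truth$category == "thyroid_malignant", ,
                        drop = FALSE]
  yn <- function(x) ifelse(x, "yes", "no")
  rows <- lapply(seq_len(nrow(truth)), function(i) {
    t <- truth[i, ]
    vals <- c(
      q1 = format(t$tumor_size_cm, trim = TRUE),
      q2 = yn(t$gross_ete),
      q3 = t$location,
      q4 = yn(t$nodes_examined > 0),
      q5 = if (t$nodes_examined == 0) "not_applicable" else
        as.character(t$nodes_positive),
      q6 = t$t_category,
      q7 = yn(t$vascular_invasion),
      q8 = yn(t$lymphatic_invasion),
      q9 = t$histology,
      q10 = t$aggressive_variant,
      q11 = yn(t$second_cancer),
      q12 = if (!t$second_cancer) "not_applicable" else
        t$second_cancer_histology)
    missing_q <- setdiff(questions$question_id, names(vals))
    if (length(missing_q)) {
      stop("no ground-truth mapping for question(s): ",
           paste(missing_q, collapse = ", "), call. = FALSE)
    }
    tibble::tibble(report_id = t$report_id,
                   question_id = questions$question_id,
                   source_id = "TRUTH",
                   value = unname(vals[questions$question_id]))
  })
  do.call(rbind, rows)
}

#' Retrieval hit rate over a corpus
#'
#' For every (long report, question) pair that goes through segmentation,
#' checks whether the assembled top-k context contains the answer-bearing
#' sentence verbatim. Reports within the token budget are skipped (the
#' full text trivially contains every sentence).
#'
#' @inheritParams run_mqa
#' @return List with `hits`, `total` and `rate` (percent; `NaN` when no
#'   report required splitting).
#' @export
retrieval_hit_rate <- function(corpus, questions = load_questions(),
                               embedder = hashed_tf_embedder(), k = 3L,
                               token_limit = 2048L, segment_length = 1200L,
                               token_counter = count_tokens) {
  stopifnot(inherits(corpus, "mqa_corpus"))
  reports <- corpus$reports[corpus$reports$category == "thyroid_malignant", ,
                            drop = FALSE]
  q_vecs <- lapply(questions$text, embed_text, embedder = embedder)
  hits <- 0L
  total <- 0L
  for (i in seq_len(nrow(reports))) {
    text <- reports$text[i]
    if (!needs_splitting(text, token_limit, token_counter)) next
    key <- reports$key_sentences[[i]]
    segs <- segment_text(text, segment_length)
    seg_vecs <- lapply(segs$text, embed_text, embedder = embedder)
    for (j in seq_len(nrow(questions))) {
      qid <- questions$question_id[j]
      if (!qid %in% names(key)) next
      scores <- vapply(seg_vecs, cosine_similarity, numeric(1),
                       b = q_vecs[[j]])
      ctx <- select_from_scores(segs, scores, k)$context_text
      total <- total + 1L
      if (grepl(key[[qid]], ctx, fixed = TRUE)) hits <- hits + 1L
    }
  }
  list(hits = hits, total = total, rate = 100 * hits / total)
}
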