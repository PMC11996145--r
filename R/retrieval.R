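#' Build the retrieval context for one question against one report
#'
#' Implements the context-construction procedure of the pipeline. Reports
#' within the token budget are used whole (`used_full_text = TRUE`).
#' Longer reports are split into fixed-length segments
#' ([segment_text()]), each segment and the bare question text are
#' embedded, segments are scored by cosine similarity against the
#' question, and the `k` highest-scoring segments are kept (ties broken
#' toward the lower segment index). Selected segments are assembled in
#' document order; adjacent segments — which tile the original text — are
#' concatenated seamlessly so that a sentence cut by a segment boundary is
#' restored verbatim, and a single newline marks each gap between
#' non-adjacent runs.
#'
#' @param question_text The bare question (the question, not the full
#'   prompt, is what gets embedded for scoring).
#' @param report_text The report narrative; must be nonempty.
#' @param k Number of segments to retrieve (default 3).
#' @param embedder Embedder object, see [hashed_tf_embedder()].
#' @param token_limit Token budget triggering segmentation (default 2048).
#' @param segment_length Segment length in characters (default 1200).
#' @param token_counter Function text -> token count.
#' @return An object of class `retrieval_context`: a list with
#'   `used_full_text`, `selected` (0-based segment indices in document
#'   order), `scores` (cosine similarities aligned with `selected`),
#'   `score_order` (indices ranked best-first) and `context_text`.
#' @export
select_context <- function(question_text, report_text, k = 3L,
                           embedder = hashed_tf_embedder(),
                           token_limit = 2048L, segment_length = 1200L,
                           token_counter = count_tokens) {
  stopifnot(is.character(report_text), length(report_text) == 1L,
            nzchar(report_text), k >= 1)
  if (!needs_splitting(report_text, token_limit, token_counter)) {
    return(structure(
      list(used_full_text = TRUE, selected = integer(), scores = numeric(),
           score_order = integer(), context_text = report_text),
      class = "retrieval_context"))
  }
  segs <- segment_text(report_text, segment_length)
  seg_embeddings <- lapply(segs$text, embed_text, embedder = embedder)
  q_vec <- embed_text(question_text, embedder)
  scores <- vapply(seg_embeddings, cosine_similarity, numeric(1), b = q_vec)
  select_from_scores(segs, scores, k)
}

# Core selection/assembly shared by select_context() and the batch pipeline
# (which precomputes segment embeddings once per report).
select_from_scores <- function(segs, scores, k) {
  k_eff <- min(as.integer(k), nrow(segs))
  ranked <- order(-scores, segs$index)[seq_len(k_eff)]
  sel <- sort(segs$index[ranked])
  pos <- match(sel, segs$index)
  # runs of consecutive indices are concatenated seamlessly; "\n" marks gaps
  run_id <- cumsum(c(1L, diff(sel) != 1L))
  run_texts <- vapply(split(segs$text[pos], run_id), paste0,
                      character(1), collapse = "")
  structure(
    list(used_full_text = FALSE,
         selected = sel,
         scores = scores[pos],
         score_order = segs$index[ranked],
         context_text = paste(run_texts, collapse = "\n")),
    class = "retrieval_context")
}

#' @export
print.retrieval_context <- function(x, ...) {
  if (x$used_full_text) {
    cat("<retrieval_context> full report text (",
        nchar(x$context_text), " chars)\n", sep = "")
  } else {
    cat("<retrieval_context> segments [",
        paste(x$selected, collapse = ", "), "] scores [",
        paste(sprintf("%.3f", x$scores), collapse = ", "), "]\n", sep = "")
  }
  invisible(x)
}
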