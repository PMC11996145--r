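#' Count whitespace tokens
#'
#' Default token counter for the token-budget check: the number of
#' whitespace-delimited tokens. A real language-model backend may plug in
#' its own tokenizer through the `token_counter` arguments; the default is
#' backend-agnostic and deterministic.
#'
#' @param text A single character string.
#' @return Nonnegative integer token count.
#' @export
count_tokens <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  if (is.na(text) || !nzchar(trimws(text))) return(0L)
  toks <- strsplit(trimws(text), "[[:space:]]+")[[1]]
  length(toks)
}

#' Does a report exceed the model's token budget?
#'
#' Reports within the budget are passed to the answer backend whole;
#' longer reports go through segmentation and similarity-based retrieval.
#'
#' @param text Report narrative.
#' @param token_limit Context budget in tokens (default 2048, the budget of
#'   a small locally deployable instruction-tuned model).
#' @param token_counter Function text -> token count.
#' @return `TRUE` iff the token count strictly exceeds `token_limit`.
#' @export
needs_splitting <- function(text, token_limit = 2048L,
                            token_counter = count_tokens) {
  stopifnot(token_limit >= 1)
  token_counter(text) > token_limit
}

#' Split a report into fixed-length character segments
#'
#' Segments tile the text exactly: segment i+1 begins where segment i ends,
#' with no overlap and no gap, and every segment except possibly the last
#' has length exactly `segment_length`. Offsets are 0-based half-open, so
#' `substr(text, start + 1, end)` recovers each segment and concatenating
#' all segment texts reconstructs the input byte-for-byte. Splitting at raw
#' character boundaries may cut words; retrieval assembly compensates by
#' joining adjacent selected segments seamlessly (see [select_context()]).
#'
#' @param text A single string.
#' @param segment_length Segment length in characters (default 1200).
#' @return A tibble with columns `index` (0-based), `start`, `end`
#'   (0-based half-open offsets) and `text`. Empty input gives zero rows.
#' @export
segment_text <- function(text, segment_length = 1200L) {
  stopifnot(is.character(text), length(text) == 1L, segment_length >= 1)
  n <- nchar(text)
  if (is.na(text) || n == 0L) {
    return(tibble::tibble(index = integer(), start = integer(),
                          end = integer(), text = character()))
  }
  starts <- seq.int(0L, n - 1L, by = segment_length)
  ends <- pmin(starts + segment_length, n)
  tibble::tibble(
    index = seq_along(starts) - 1L,
    start = as.integer(starts),
    end = as.integer(ends),
    text = substring(text, starts + 1L, ends)
  )
}
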