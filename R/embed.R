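#' Deterministic hashed term-frequency embedder
#'
#' The default embedder behind the retrieval step. Text is lowercased,
#' non-alphanumeric characters become separators, and each word token is
#' hashed (31-polynomial rolling hash) into one of `dimension` buckets.
#' Bucket weights are sublinear term frequencies, `1 + log(tf)`, and the
#' vector is unit-normalized, so the dot product of two embeddings is their
#' cosine similarity. The embedder is fully deterministic: identical text
#' always produces identical vectors, which keeps the whole retrieval
#' pipeline reproducible without any model download.
#'
#' Any object implementing the same contract — a list with elements
#' `embed` (function text -> numeric vector of fixed length), `dimension`
#' and `id` — can replace it, e.g. an adapter around a sentence-embedding
#' model.
#'
#' @param dimension Number of hash buckets (default 512).
#' @return An object of class `mqa_embedder`.
#' @export
hashed_tf_embedder <- function(dimension = 512L) {
  stopifnot(dimension >= 2)
  dimension <- as.integer(dimension)
  hash_cache <- new.env(parent = emptyenv())
  hash_token <- function(token) {
    h <- hash_cache[[token]]
    if (!is.null(h)) return(h)
    v <- 0L
    for (code in utf8ToInt(token)) v <- (v * 31L + code) %% dimension
    h <- v + 1L
    hash_cache[[token]] <- h
    h
  }
  embed <- function(text) {
    toks <- tokenize_words(text)
    vec <- numeric(dimension)
    if (length(toks) == 0L) {
      attr(vec, "empty_text") <- TRUE
      return(vec)
    }
    idx <- vapply(toks, hash_token, integer(1), USE.NAMES = FALSE)
    tf <- tabulate(idx, nbins = dimension)
    nz <- tf > 0L
    vec[nz] <- 1 + log(tf[nz])
    vec / sqrt(sum(vec^2))
  }
  structure(list(embed = embed, dimension = dimension, id = "hashed-tf"),
            class = "mqa_embedder")
}

tokenize_words <- function(text) {
  if (is.na(text) || !nzchar(text)) return(character())
  cleaned <- gsub("[^a-z0-9]+", " ", tolower(text))
  toks <- strsplit(trimws(cleaned), " ", fixed = TRUE)[[1]]
  toks[nzchar(toks)]
}

#' Embed a text span
#'
#' @param text A single string.
#' @param embedder An embedder object (see [hashed_tf_embedder()]).
#' @return Numeric vector of length `embedder$dimension`; the zero vector,
#'   flagged with attribute `empty_text`, for empty input (similarity
#'   against it is defined as 0).
#' @export
embed_text <- function(text, embedder = hashed_tf_embedder()) {
  stopifnot(inherits(embedder, "mqa_embedder"))
  embedder$embed(text)
}

#' Cosine similarity between two embedding vectors
#'
#' `dot(a, b) / (||a|| ||b||)`: symmetric and invariant to positive
#' rescaling of either argument. If either vector is zero (the designated
#' empty-text embedding), the similarity is defined as 0.
#'
#' @param a,b Numeric vectors of equal length.
#' @return A number in `[-1, 1]`.
#' @export
cosine_similarity <- function(a, b) {
  if (length(a) != length(b)) {
    stop("embedding dimension mismatch: ", length(a), " vs ", length(b),
         call. = FALSE)
  }
  na <- sqrt(sum(a^2))
  nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) return(0)
  min(1, max(-1, sum(a * b) / (na * nb)))
}
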