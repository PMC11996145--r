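`%||%` <- function(x, y) if (is.null(x)) y else x

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# random stream.
with_seed <- function(seed, code) {
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Split a narrative into sentence-like units: hard breaks at newlines
# (synoptic lines), then at a period followed by whitespace. Decimal points
# ("4.2 x 3.0 cm") are not followed by whitespace and survive intact.
split_sentences <- function(text) {
  lines <- unlist(strsplit(text, "\n", fixed = TRUE), use.names = FALSE)
  out <- unlist(strsplit(lines, "(?<=\\.)\\s+", perl = TRUE), use.names = FALSE)
  out <- trimws(out)
  out[nzchar(out)]
}

.number_words <- c(
  none = 0L, zero = 0L, one = 1L, two = 2L, three = 3L, four = 4L,
  five = 5L, six = 6L, seven = 7L, eight = 8L, nine = 9L, ten = 10L,
  eleven = 11L, twelve = 12L, thirteen = 13L, fourteen = 14L,
  fifteen = 15L, sixteen = 16L, seventeen = 17L, eighteen = 18L,
  nineteen = 19L, twenty = 20L
)

# "three" -> 3, "None" -> 0, "7" -> 7; NA when unparseable.
parse_count_token <- function(token) {
  token <- tolower(trimws(token))
  if (grepl("^[0-9]+$", token)) return(as.integer(token))
  if (token %in% names(.number_words)) return(unname(.number_words[[token]]))
  NA_integer_
}

count_to_word <- function(n) {
  stopifnot(n >= 0, n <= 20)
  w <- names(.number_words)[match(n, .number_words)]
  # match() finds "none" first for 0; prefer "zero" never -- reports say "None"
  w
}

pkg_file <- function(...) {
  system.file(..., package = "thyromqa", mustWork = TRUE)
}
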