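#' Normalize a free-text answer to a canonical typed value
#'
#' Maps a backend's free-text answer to the canonical value used for
#' concordance, according to the question's answer type: unit-aware size
#' parsing (mm are converted to cm), yes/no and negation mapping for
#' booleans, laterality keywords for location, digit or number-word
#' parsing for counts, pT-token canonicalization for TNM stage
#' (`"pT3a"` becomes `"T3a"`), and controlled-vocabulary scans for
#' histology and variants. Unparseable answers become `"not_stated"`;
#' explicit not-applicable phrasings become `"not_applicable"`. The
#' function is total (never errors on text) and idempotent on
#' already-canonical values.
#'
#' @param raw_text Free-text answer (or an already-canonical value).
#' @param question One row of a question tibble (see [load_questions()]).
#' @return A single character canonical value: a number rendered as text
#'   for sizes and counts, `"yes"`/`"no"` for booleans,
#'   `"right_lobe"`/`"left_lobe"`/`"isthmus"`, a bare T token such as
#'   `"T3a"`, a histology or variant token, `"not_stated"` or
#'   `"not_applicable"`.
#' @export
normalize_answer <- function(raw_text, question) {
  stopifnot(is.character(raw_text), length(raw_text) == 1L)
  s <- trimws(raw_text)
  if (!nzchar(s)) return("not_stated")
  if (grepl("not[ _]applicable", s, ignore.case = TRUE)) {
    return("not_applicable")
  }
  not_stated <- grepl(
    "not[ _]stated|cannot be determined|does not state|no mention|unknown",
    s, ignore.case = TRUE)
  if (not_stated) return("not_stated")
  switch(question$answer_type,
    size_cm = normalize_size(s),
    boolean = normalize_boolean(s),
    location = normalize_location(s),
    count = normalize_count(s),
    tnm_stage = normalize_tnm(s),
    histology = normalize_histology(s),
    variant = normalize_variant(s),
    "not_stated")
}

normalize_size <- function(s) {
  m <- regmatches(s, regexec("([0-9]+(?:\\.[0-9]+)?)\\s*(cm|mm)\\b", s,
                             ignore.case = TRUE))[[1]]
  if (length(m) == 3L) {
    val <- as.numeric(m[2])
    if (tolower(m[3]) == "mm") val <- val / 10
    return(format(val, trim = TRUE))
  }
  bare <- regmatches(s, regexec("^([0-9]+(?:\\.[0-9]+)?)$", s))[[1]]
  if (length(bare) == 2L) return(format(as.numeric(bare[2]), trim = TRUE))
  "not_stated"
}

normalize_boolean <- function(s) {
  if (grepl("^(yes|true)\\b", s, ignore.case = TRUE)) return("yes")
  if (grepl("^(no|false)\\b", s, ignore.case = TRUE)) return("no")
  if (is_negated(s)) return("no")
  if (grepl("\\b(present|yes|identified|seen)\\b", s, ignore.case = TRUE)) {
    return("yes")
  }
  "not_stated"
}

normalize_location <- function(s) {
  s <- tolower(s)
  if (grepl("right[ _](thyroid[ _])?lobe", s)) return("right_lobe")
  if (grepl("left[ _](thyroid[ _])?lobe", s)) return("left_lobe")
  if (grepl("\\bisthmus\\b", s)) return("isthmus")
  "not_stated"
}

normalize_count <- function(s) {
  toks <- strsplit(gsub("[^A-Za-z0-9]+", " ", s), " ", fixed = TRUE)[[1]]
  for (tok in toks[nzchar(toks)]) {
    n <- parse_count_token(tok)
    if (!is.na(n)) return(as.character(n))
  }
  "not_stated"
}

normalize_tnm <- function(s) {
  m <- regmatches(s, regexpr("\\bp?T[0-9][abAB]?\\b", s, ignore.case = TRUE))
  if (length(m) == 0L) return("not_stated")
  tok <- sub("^p", "", m[1], ignore.case = TRUE)
  paste0("T", substring(tok, 2, 2), tolower(substring(tok, 3)))
}

normalize_histology <- function(s) {
  m <- regmatches(s, regexpr(.histology_re, s, ignore.case = TRUE))
  if (length(m) == 0L) return("not_stated")
  tolower(m[1])
}

normalize_variant <- function(s) {
  if (grepl("^none$", trimws(s), ignore.case = TRUE)) return("none")
  if (is_negated(s)) return("none")
  sl <- tolower(s)
  if (grepl("tall[ _]cell", sl)) return("tall_cell")
  if (grepl("hobnail", sl)) return("hobnail")
  if (grepl("columnar", sl)) return("columnar")
  "not_stated"
}
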