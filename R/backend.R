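.negation_re <- "\\b(no|not|without|absent|none|negative)\\b"

is_negated <- function(sentence) {
  grepl(.negation_re, sentence, ignore.case = TRUE)
}

.measure_re <- "([0-9]+(?:\\.[0-9]+)?)\\s*(cm|mm)\\b"
.tumor_word_re <- "\\b(tumor|tumour|carcinoma|neoplasm|lesion|nodule)\\b"
.specimen_word_re <- "\\b(lobe|specimen|gland|isthmusectomy|weighs|aggregate)\\b"

#' Deterministic rule-based reference answer backend
#'
#' A pattern-based extractor that answers the 12-question schema from a
#' report excerpt. It stands in for a language model: it conforms to the
#' same backend contract (context + question in, one free-text sentence
#' out) but is fully deterministic, so pipeline behavior — segmentation,
#' retrieval, normalization, concordance — can be tested end to end
#' without model weights. Its rules encode known failure modes the
#' pipeline must avoid, in particular preferring a dimension stated for
#' the tumor itself over specimen dimensions such as the overall lobe, and
#' reading node sections labeled by neck level or compartment even when
#' the word "cervical" never appears.
#'
#' @return An object of class `mqa_backend` with elements `id` and
#'   `answer` (function `(context_text, question) -> free text`).
#' @export
reference_backend <- function() {
  structure(list(id = "reference", answer = reference_extract),
            class = "mqa_backend")
}

#' Run one question through an answer backend
#'
#' The backend contract: given a context (full report or assembled
#' retrieval context) and one question row, return one free-text answer.
#' A backend failure is caught and recorded as a not-stated answer so a
#' batch run continues.
#'
#' @param context_text Nonempty context string.
#' @param question One row of a question tibble.
#' @param backend An `mqa_backend` object.
#' @return A list with `text` (free-text answer) and `backend_id`.
#' @export
answer_question <- function(context_text, question,
                            backend = reference_backend()) {
  stopifnot(inherits(backend, "mqa_backend"),
            is.character(context_text), length(context_text) == 1L,
            nzchar(context_text))
  text <- tryCatch(
    backend$answer(context_text, question),
    error = function(e) {
      warning("backend '", backend$id, "' failed on ", question$question_id,
              ": ", conditionMessage(e), call. = FALSE)
      "The answer is not stated in the report."
    })
  list(text = text, backend_id = backend$id)
}

#' Rule-based extraction for one question
#'
#' The reference backend's core. See [reference_backend()] for scope; the
#' per-question logic is: tumor size from a sentence naming the tumor
#' (specimen/lobe dimensions are rejected as distractors); negation-aware
#' keyword polarity for capsular extension and lymphovascular invasion;
#' "<x> of <y> lymph nodes" patterns (digits or number words) for nodal
#' counts; laterality keywords for location; pT token scan for stage; and
#' controlled-vocabulary scans for histology and aggressive variants,
#' excluding second-cancer sentences when reading the primary histology.
#'
#' @param context_text Report excerpt.
#' @param question One row of a question tibble.
#' @return One free-text answer sentence (a not-stated phrasing when no
#'   pattern fires).
#' @export
reference_extract <- function(context_text, question) {
  sents <- split_sentences(context_text)
  switch(question$question_id,
    q1 = extract_tumor_size(sents),
    q2 = extract_capsular_extension(sents),
    q3 = extract_location(sents),
    q4 = extract_nodes(sents)$q4,
    q5 = extract_nodes(sents)$q5,
    q6 = extract_tnm(sents),
    q7 = extract_invasion(sents, "vascular"),
    q8 = extract_invasion(sents, "lymphatic"),
    q9 = extract_primary_histology(sents),
    q10 = extract_variant(sents),
    q11 = extract_second_cancer(sents)$q11,
    q12 = extract_second_cancer(sents)$q12,
    extract_generic(sents, question)
  )
}

extract_tumor_size <- function(sents) {
  has_measure <- grepl(.measure_re, sents, ignore.case = TRUE)
  has_tumor <- grepl(.tumor_word_re, sents, ignore.case = TRUE)
  is_specimen <- grepl(.specimen_word_re, sents, ignore.case = TRUE)
  # a dimension is trusted only when the sentence names the tumor and is
  # not a specimen/lobe measurement (the classic distractor)
  cand <- sents[has_measure & has_tumor & !is_specimen]
  if (length(cand) == 0L) {
    return("The size of the primary tumor is not stated in the report.")
  }
  m <- regmatches(cand[1], regexec(.measure_re, cand[1], ignore.case = TRUE))[[1]]
  sprintf("The size of the primary tumor was %s %s.", m[2], tolower(m[3]))
}

extract_capsular_extension <- function(sents) {
  ete_re <- paste0("extrathyroidal extension|beyond the (thyroid )?capsule|",
                   "strap muscle|confined to the thyroid")
  cand <- sents[grepl(ete_re, sents, ignore.case = TRUE)]
  if (length(cand) == 0L) {
    return("Extension beyond the thyroid capsule is not stated in the report.")
  }
  s <- cand[1]
  negative <- grepl("confined to the thyroid", s, ignore.case = TRUE) ||
    is_negated(s)
  if (negative) {
    "No, the tumor does not extend beyond the capsule of the thyroid."
  } else {
    "Yes, the tumor extends beyond the capsule of the thyroid."
  }
}

extract_location <- function(sents) {
  anchor <- grepl("\\b(tumor|tumour|cancer|carcinoma|site)\\b", sents,
                  ignore.case = TRUE)
  loc_re <- "right (thyroid )?lobe|left (thyroid )?lobe|\\bisthmus\\b"
  cand <- sents[anchor & grepl(loc_re, sents, ignore.case = TRUE)]
  if (length(cand) == 0L) {
    return("The location of the primary cancer is not stated in the report.")
  }
  s <- tolower(cand[1])
  loc <- if (grepl("right (thyroid )?lobe", s)) "right thyroid lobe"
    else if (grepl("left (thyroid )?lobe", s)) "left thyroid lobe"
    else "isthmus"
  sprintf("The primary cancer is located in the %s.", loc)
}

extract_nodes <- function(sents) {
  cand <- sents[grepl("lymph node", sents, ignore.case = TRUE)]
  if (length(cand) == 0L) {
    return(list(q4 = "The presence of cervical lymph nodes is not stated in the report.",
                q5 = "The number of positive lymph nodes is not stated in the report."))
  }
  # scan every "<x> of <y>" pattern across node sentences and accept the
  # first whose count token parses ("Three of seven", "2 of 5", "None of
  # the four"); other "of" phrases (e.g. "aggregate of level VI") skip
  for (s in cand) {
    ms <- regmatches(s, gregexec(
      "\\b([A-Za-z0-9]+)\\s+of\\s+(?:the\\s+)?([A-Za-z0-9]+)\\b", s))[[1]]
    if (length(ms)) {
      for (j in seq_len(ncol(ms))) {
        pos <- parse_count_token(ms[2, j])
        if (!is.na(pos)) {
          return(list(
            q4 = "Yes, cervical lymph nodes were present.",
            q5 = sprintf("%d lymph nodes were positive for malignancy.", pos)))
        }
      }
    }
  }
  s <- cand[1]
  if (is_negated(s)) {
    return(list(
      q4 = "No, cervical lymph nodes were not present.",
      q5 = "Not applicable; no cervical lymph nodes were present."))
  }
  list(q4 = "Yes, cervical lymph nodes were present.",
       q5 = "The number of positive lymph nodes is not stated in the report.")
}

extract_tnm <- function(sents) {
  cand <- sents[grepl("\\bpT[0-9]", sents)]
  if (length(cand) == 0L) {
    return("The final pathology TNM stage is not stated in the report.")
  }
  t_tok <- regmatches(cand[1], regexpr("\\bpT[0-9][abAB]?\\b", cand[1]))
  n_tok <- regmatches(cand[1], regexpr("\\bpN[0-9xX][abAB]?\\b", cand[1]))
  stage <- paste(c(t_tok, n_tok), collapse = " ")
  sprintf("The final pathology TNM stage of the thyroid cancer is %s.", stage)
}

extract_invasion <- function(sents, kind) {
  re <- paste0("\\b", kind, " invasion\\b")
  cand <- sents[grepl(re, sents, ignore.case = TRUE) &
                  !grepl("lymphovascular", sents, ignore.case = TRUE)]
  if (length(cand) == 0L) {
    kind_cap <- paste0(toupper(substring(kind, 1, 1)), substring(kind, 2))
    return(sprintf("%s invasion is not stated in the report.", kind_cap))
  }
  if (is_negated(cand[1])) {
    sprintf("No, %s invasion is not present.", kind)
  } else {
    sprintf("Yes, %s invasion is present.", kind)
  }
}

.histology_re <- "\\b(papillary|follicular|medullary)\\b"
.second_re <- "\\b(second|incidental|additional)\\b"

extract_primary_histology <- function(sents) {
  cand <- sents[grepl(.histology_re, sents, ignore.case = TRUE) &
                  !grepl(.second_re, sents, ignore.case = TRUE)]
  if (length(cand) == 0L) {
    return("The histology of the primary cancer is not stated in the report.")
  }
  h <- tolower(regmatches(cand[1],
                          regexpr(.histology_re, cand[1], ignore.case = TRUE)))
  sprintf("The histology of the primary thyroid cancer was %s carcinoma.", h)
}

extract_variant <- function(sents) {
  re <- "tall cell|hobnail|columnar"
  cand <- sents[grepl(paste0(re, "|\\bvariant\\b"), sents,
                      ignore.case = TRUE)]
  if (length(cand) == 0L) {
    return("The presence of an aggressive variant is not stated in the report.")
  }
  s <- cand[1]
  if (is_negated(s)) {
    return(paste0("No, a variant of thyroid cancer such as tall cell, ",
                  "hobnail variant, or columnar cell variant was not present."))
  }
  v <- tolower(regmatches(s, regexpr(re, s, ignore.case = TRUE)))
  sprintf("Yes, a %s variant was present, indicative of a more aggressive histology.", v)
}

extract_second_cancer <- function(sents) {
  cand <- sents[grepl(.second_re, sents, ignore.case = TRUE) &
                  grepl("carcinoma|cancer|focus", sents, ignore.case = TRUE)]
  if (length(cand) == 0L) {
    return(list(q11 = "The presence of a second thyroid cancer is not stated in the report.",
                q12 = "The histology of a second thyroid cancer is not stated in the report."))
  }
  s <- cand[1]
  if (is_negated(s)) {
    return(list(q11 = "No, there was no second thyroid cancer present.",
                q12 = "Not applicable; there was no second thyroid cancer present."))
  }
  h <- regmatches(s, regexpr(.histology_re, s, ignore.case = TRUE))
  q12 <- if (length(h) == 1L) {
    sprintf("The histology of the second thyroid cancer was %s carcinoma.",
            tolower(h))
  } else {
    "The histology of the second thyroid cancer is not stated in the report."
  }
  list(q11 = "Yes, there was a second thyroid cancer present.", q12 = q12)
}

# fallback for custom question sets: keyword-overlap sentence lookup
extract_generic <- function(sents, question) {
  q_toks <- setdiff(tokenize_words(question$text),
                    c("the", "a", "an", "of", "is", "was", "were", "there",
                      "what", "where", "how", "any", "in", "or", "to"))
  if (length(sents) == 0L || length(q_toks) == 0L) {
    return("The answer is not stated in the report.")
  }
  overlap <- vapply(sents, function(s) {
    length(intersect(tokenize_words(s), q_toks))
  }, integer(1))
  if (max(overlap) == 0L) return("The answer is not stated in the report.")
  sents[which.max(overlap)]
}
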