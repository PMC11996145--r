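.answer_types <- c("size_cm", "boolean", "location", "count", "tnm_stage",
                   "histology", "variant")

#' Load a question set
#'
#' With no argument, returns the default 12-question thyroid cancer
#' staging and recurrence-risk extraction schema shipped with the package
#' (tumor size, capsular extension, location, nodal status and counts,
#' final pathologic TNM stage, lymphovascular invasion, histology,
#' aggressive variants, second cancers). A custom YAML file with the same
#' layout may be supplied instead.
#'
#' Two items are conditional: the positive-node count (q5) applies only
#' when cervical lymph nodes were present (q4), and the second-cancer
#' histology (q12) only when a second cancer was present (q11). When the
#' trigger is negative their canonical answer is `not_applicable`.
#'
#' @param path Optional path to a YAML question file; `NULL` loads the
#'   default schema.
#' @return A tibble with columns `question_id`, `text`, `answer_type`,
#'   `group`, `depends_on_id`, `depends_on_value`.
#' @export
load_questions <- function(path = NULL) {
  use_default <- is.null(path)
  if (use_default && !is.null(.thyromqa_cache$questions)) {
    return(.thyromqa_cache$questions)
  }
  if (use_default) path <- pkg_file("extdata", "questions.yaml")
  raw <- yaml::read_yaml(path)
  items <- raw$questions
  if (is.null(items) || length(items) == 0L) {
    stop("question file has no `questions` entries", call. = FALSE)
  }
  qs <- tibble::tibble(
    question_id = vapply(items, function(q) as.character(q$id), character(1)),
    text = vapply(items, function(q) as.character(q$text), character(1)),
    answer_type = vapply(items, function(q) as.character(q$answer_type),
                         character(1)),
    group = vapply(items, function(q) as.character(q$group %||% ""),
                   character(1)),
    depends_on_id = vapply(items, function(q) {
      if (is.null(q$depends_on)) NA_character_ else as.character(q$depends_on$id)
    }, character(1)),
    depends_on_value = vapply(items, function(q) {
      if (is.null(q$depends_on)) NA else isTRUE(q$depends_on$value)
    }, logical(1))
  )
  if (anyDuplicated(qs$question_id)) {
    stop("duplicate question ids in question set", call. = FALSE)
  }
  bad <- setdiff(qs$answer_type, .answer_types)
  if (length(bad)) {
    stop("unknown answer_type(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  missing_dep <- setdiff(qs$depends_on_id[!is.na(qs$depends_on_id)],
                         qs$question_id)
  if (length(missing_dep)) {
    stop("depends_on refers to unknown question(s): ",
         paste(missing_dep, collapse = ", "), call. = FALSE)
  }
  if (use_default) .thyromqa_cache$questions <- qs
  qs
}

#' Default prompt template
#'
#' An instruction-style template with one `{context}` and one `{question}`
#' placeholder. Prompt construction is pure placeholder substitution; the
#' wording itself is configuration, not pipeline logic, so alternative
#' templates can be passed to [build_prompt()] unchanged.
#'
#' @return A single template string.
#' @export
default_prompt_template <- function() {
  paste0(
    "Use only the following surgical pathology report excerpt to answer ",
    "the question. If the excerpt does not state the answer, say so.\n\n",
    "Report excerpt:\n{context}\n\nQuestion: {question}\nAnswer:")
}

#' Build a prompt from a template, a context and a question
#'
#' @param template Template string containing `{context}` and `{question}`
#'   exactly once each.
#' @param context_text Nonempty retrieval context or full report text.
#' @param question One row of a question tibble (see [load_questions()]),
#'   or a question string.
#' @return The prompt string; deterministic pure substitution.
#' @export
build_prompt <- function(template = default_prompt_template(), context_text,
                         question) {
  stopifnot(is.character(context_text), length(context_text) == 1L,
            nzchar(context_text))
  q_text <- if (is.character(question)) question else question$text
  stopifnot(length(q_text) == 1L, nzchar(q_text))
  for (ph in c("{context}", "{question}")) {
    n_ph <- lengths(regmatches(template, gregexpr(ph, template, fixed = TRUE)))
    if (n_ph != 1L) {
      stop("template must contain the placeholder ", ph, " exactly once",
           call. = FALSE)
    }
  }
  # substitute the question first so report text containing a literal
  # "{question}" can never be rewritten
  out <- sub("{question}", q_text, template, fixed = TRUE)
  sub("{context}", context_text, out, fixed = TRUE)
}
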