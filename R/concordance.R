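#' Concordance adjudication policy
#'
#' Controls how two canonical answers are judged concordant: sizes are
#' compared after rounding to 0.1 cm, and for boolean questions a
#' `not_stated` answer may be equated with `"no"` (an unmentioned finding
#' is read as absent, the usual convention when reviewers record absent
#' findings). Enum, count and TNM comparisons are exact (the TNM
#' comparison is case-insensitive on the T token).
#'
#' @param size_decimal Decimal places for size rounding (default 1).
#' @param not_stated_as_absent Logical; treat `not_stated` as `"no"` for
#'   boolean questions (default `TRUE`).
#' @return A policy list.
#' @export
default_policy <- function(size_decimal = 1L, not_stated_as_absent = TRUE) {
  list(size_decimal = size_decimal,
       not_stated_as_absent = not_stated_as_absent)
}

#' Are two canonical answers concordant?
#'
#' Type-aware equality for one (report, question) cell. Both answers must
#' be canonical values as produced by [normalize_answer()].
#'
#' @param a,b Canonical answer values (character scalars).
#' @param answer_type The question's answer type.
#' @param policy See [default_policy()].
#' @return `TRUE` or `FALSE`.
#' @export
is_concordant <- function(a, b, answer_type, policy = default_policy()) {
  stopifnot(is.character(a), is.character(b),
            length(a) == 1L, length(b) == 1L)
  special <- c("not_stated", "not_applicable")
  if (answer_type == "boolean" && isTRUE(policy$not_stated_as_absent)) {
    if (a == "not_stated") a <- "no"
    if (b == "not_stated") b <- "no"
  }
  if (a %in% special || b %in% special) return(identical(a, b))
  switch(answer_type,
    size_cm = {
      av <- suppressWarnings(as.numeric(a))
      bv <- suppressWarnings(as.numeric(b))
      if (is.na(av) || is.na(bv)) return(identical(a, b))
      round(av, policy$size_decimal) == round(bv, policy$size_decimal)
    },
    tnm_stage = {
      ta <- regmatches(a, regexpr("T[0-9][ab]?", a, ignore.case = TRUE))
      tb <- regmatches(b, regexpr("T[0-9][ab]?", b, ignore.case = TRUE))
      length(ta) == 1L && length(tb) == 1L && tolower(ta) == tolower(tb)
    },
    identical(a, b))
}

validate_answer_set <- function(x, label) {
  needed <- c("report_id", "question_id", "value")
  missing_cols <- setdiff(needed, names(x))
  if (length(missing_cols)) {
    stop("answer set ", label, " lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  key <- paste(x$report_id, x$question_id)
  if (anyDuplicated(key)) {
    stop("answer set ", label, " has duplicated (report, question) cells",
         call. = FALSE)
  }
  invisible(x)
}

answer_source <- function(x, default) {
  if ("source_id" %in% names(x) && length(unique(x$source_id)) == 1L) {
    unique(x$source_id)
  } else {
    default
  }
}

#' Per-question pairwise concordance rates
#'
#' For two complete answer sets over the same report-by-question grid,
#' computes for every question the number of concordant answers over the
#' number of answers (the concordance rate, in percent), then aggregates:
#' the mean and SD of the per-question rates (sample convention headline,
#' population convention alongside) and the pooled counts and pooled rate
#' (total concordant cells over total cells). Mean-of-rates and pooled
#' rate differ in general; both framings are reported and labeled.
#'
#' @param set_a,set_b Tibbles with columns `report_id`, `question_id`,
#'   `value` (canonical answers; an optional `source_id` column labels the
#'   pair).
#' @param questions Question tibble defining the grid and answer types.
#' @param policy See [default_policy()].
#' @return An object of class `concordance_table`: list with
#'   `per_question` (tibble: `question_id`, `pair`, `concordant`, `total`,
#'   `rate`) and `overall` (list: `mean_rate`, `sd_rate`,
#'   `sd_rate_population`, `pooled_concordant`, `pooled_total`,
#'   `pooled_rate`).
#' @export
per_question_rates <- function(set_a, set_b, questions = load_questions(),
                               policy = default_policy()) {
  validate_answer_set(set_a, "A")
  validate_answer_set(set_b, "B")
  key_a <- paste(set_a$report_id, set_a$question_id)
  key_b <- paste(set_b$report_id, set_b$question_id)
  if (!setequal(key_a, key_b)) {
    diff_cells <- c(setdiff(key_a, key_b), setdiff(key_b, key_a))
    stop("answer sets cover different grids; mismatched cells: ",
         paste(utils::head(diff_cells, 10), collapse = "; "),
         if (length(diff_cells) > 10) " ...", call. = FALSE)
  }
  reports <- unique(set_a$report_id)
  expected <- as.vector(outer(reports, questions$question_id, paste))
  missing_cells <- setdiff(expected, key_a)
  if (length(missing_cells)) {
    stop("incomplete grid; missing cells: ",
         paste(utils::head(missing_cells, 10), collapse = "; "),
         if (length(missing_cells) > 10) " ...", call. = FALSE)
  }
  extra <- setdiff(key_a, expected)
  if (length(extra)) {
    stop("answers outside the report x question grid: ",
         paste(utils::head(extra, 10), collapse = "; "), call. = FALSE)
  }
  b_vals <- set_b$value[match(key_a, key_b)]
  type_of <- stats::setNames(questions$answer_type, questions$question_id)
  agree <- vapply(seq_along(key_a), function(i) {
    is_concordant(set_a$value[i], b_vals[i],
                  type_of[[set_a$question_id[i]]], policy)
  }, logical(1))
  pair <- paste(answer_source(set_a, "A"), answer_source(set_b, "B"),
                sep = "-")
  per_q <- tibble::tibble(
    question_id = questions$question_id,
    pair = pair,
    concordant = vapply(questions$question_id, function(q) {
      sum(agree[set_a$question_id == q])
    }, integer(1), USE.NAMES = FALSE),
    total = vapply(questions$question_id, function(q) {
      sum(set_a$question_id == q)
    }, integer(1), USE.NAMES = FALSE))
  per_q$rate <- 100 * per_q$concordant / per_q$total
  overall <- summarize_rates(per_q$rate)
  overall$pooled_concordant <- sum(per_q$concordant)
  overall$pooled_total <- sum(per_q$total)
  overall$pooled_rate <- 100 * overall$pooled_concordant / overall$pooled_total
  structure(list(per_question = per_q,
                 overall = c(list(mean_rate = overall$mean,
                                  sd_rate = overall$sd,
                                  sd_rate_population = overall$sd_population),
                             overall[c("pooled_concordant", "pooled_total",
                                       "pooled_rate")])),
            class = "concordance_table")
}

#' Mean and SD of per-question concordance rates
#'
#' Arithmetic mean with the sample (n-1) SD as the headline convention;
#' the population (n) SD is reported alongside.
#'
#' @param rates Nonempty numeric vector of rates (percent).
#' @return List with `mean`, `sd` (sample), `sd_sample`, `sd_population`.
#' @export
summarize_rates <- function(rates) {
  if (length(rates) == 0L || !is.numeric(rates)) {
    stop("`rates` must be a nonempty numeric vector", call. = FALSE)
  }
  m <- mean(rates)
  sd_sample <- if (length(rates) > 1L) stats::sd(rates) else NA_real_
  sd_pop <- sqrt(mean((rates - m)^2))
  list(mean = m, sd = sd_sample, sd_sample = sd_sample,
       sd_population = sd_pop)
}

#' Two-sided t test between two pairings' per-question rates
#'
#' Compares two aligned vectors of per-question concordance rates (one per
#' pairwise comparison) with a two-sided t test. The default is a paired
#' test — the same questions underlie both vectors — with Welch's unpaired
#' test available by flag. Degenerate inputs with zero variance in the
#' test statistic's denominator (e.g. identical vectors) return t = 0,
#' p = 1.
#'
#' @param rates_a,rates_b Equal-length, question-aligned numeric vectors
#'   of rates (percent).
#' @param mode `"paired"` (default) or `"welch"`.
#' @return List with `t_statistic`, `p_value`, `df`, `mode_used`.
#' @export
compare_pairings <- function(rates_a, rates_b,
                             mode = c("paired", "welch")) {
  mode <- match.arg(mode)
  if (length(rates_a) != length(rates_b)) {
    stop("rate vectors must be question-aligned and of equal length",
         call. = FALSE)
  }
  if (length(rates_a) < 2L) {
    stop("need at least two questions to compare pairings", call. = FALSE)
  }
  degenerate <- if (mode == "paired") {
    stats::sd(rates_a - rates_b) == 0
  } else {
    stats::sd(rates_a) == 0 && stats::sd(rates_b) == 0
  }
  if (degenerate) {
    df <- if (mode == "paired") length(rates_a) - 1L else NA_real_
    return(list(t_statistic = 0, p_value = 1, df = df, mode_used = mode))
  }
  fit <- if (mode == "paired") {
    stats::t.test(rates_a, rates_b, paired = TRUE,
                  alternative = "two.sided")
  } else {
    stats::t.test(rates_a, rates_b, paired = FALSE, var.equal = FALSE,
                  alternative = "two.sided")
  }
  list(t_statistic = unname(fit$statistic), p_value = fit$p.value,
       df = unname(fit$parameter), mode_used = mode)
}

#' @export
print.concordance_table <- function(x, ...) {
  cat("<concordance_table> pair ", x$per_question$pair[1], "\n", sep = "")
  print(x$per_question, n = nrow(x$per_question))
  ov <- x$overall
  cat(sprintf(
    "mean %.2f%% (SD %.2f sample / %.2f population); pooled %d/%d = %.2f%%\n",
    ov$mean_rate, ov$sd_rate, ov$sd_rate_population,
    ov$pooled_concordant, ov$pooled_total, ov$pooled_rate))
  invisible(x)
}
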