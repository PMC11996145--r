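#' Reported per-question concordance rates from a published evaluation
#'
#' Per-question pairwise concordance rates (percent) from a published
#' evaluation of this pipeline design, in which two clinician reviewers
#' and a locally deployed instruction-tuned language model each answered
#' the 12-question schema on 84 thyroid cancer surgical pathology reports
#' (1008 answers per pairing). The underlying reports are protected
#' patient data and are not redistributable; only these printed summary
#' rates are shipped. They serve as worked-example input for the
#' aggregation functions ([summarize_rates()], [compare_pairings()]) —
#' e.g. the reviewer-reviewer column averages to 99 with SD 1, and the
#' reviewer-model columns average to about 89.
#'
#' @return Tibble with columns `question_id`, `r1_llm`, `r2_llm`, `r1_r2`,
#'   `all_three` (rates in percent).
#' @export
reported_concordance <- function() {
  path <- pkg_file("extdata", "reported_concordance.csv")
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}
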