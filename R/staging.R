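#' Staging rule thresholds
#'
#' Reads the versioned YAML file of guideline constants shipped with the
#' package (AJCC-TNM 8th edition tumor-size cut points, simplified). Keeping
#' the thresholds in a data file makes them auditable and versionable
#' independently of the code.
#'
#' @return A list with elements `version`, `t1a_max_cm`, `t1b_max_cm`,
#'   `t2_max_cm`.
#' @export
staging_thresholds <- function() {
  cached <- .thyromqa_cache$staging
  if (!is.null(cached)) return(cached)
  th <- yaml::read_yaml(pkg_file("extdata", "staging_rules.yaml"))
  .thyromqa_cache$staging <- th
  th
}

.thyromqa_cache <- new.env(parent = emptyenv())

#' Derive the pathologic T category of a differentiated thyroid carcinoma
#'
#' Implements the simplified AJCC-TNM 8th edition tumor (T) classification
#' used by the 12-question extraction schema: T category is a function of
#' tumor size and gross extrathyroidal extension (ETE) only. Gross ETE into
#' the strap muscles overrides size and yields T3b; otherwise size cut
#' points at 1, 2 and 4 cm (upper bound inclusive) give T1a/T1b/T2/T3a.
#' T4 disease, the N1a/N1b split and microscopic ETE nuance are outside the
#' schema and deliberately not modeled.
#'
#' @param size_cm Tumor greatest dimension in cm; must be positive.
#' @param gross_ete Logical; gross extrathyroidal extension into strap
#'   muscles.
#' @return Character vector of T categories among
#'   `"T1a","T1b","T2","T3a","T3b"`.
#' @examples
#' derive_t_category(5.5, FALSE)  # "T3a"
#' derive_t_category(2.5, TRUE)   # "T3b" (gross ETE overrides size)
#' @export
derive_t_category <- function(size_cm, gross_ete) {
  if (any(!is.finite(size_cm)) || any(size_cm <= 0)) {
    stop("`size_cm` must be positive and finite for staging", call. = FALSE)
  }
  stopifnot(is.logical(gross_ete))
  th <- staging_thresholds()
  n <- max(length(size_cm), length(gross_ete))
  size_cm <- rep_len(size_cm, n)
  gross_ete <- rep_len(gross_ete, n)
  out <- ifelse(size_cm <= th$t1a_max_cm, "T1a",
         ifelse(size_cm <= th$t1b_max_cm, "T1b",
         ifelse(size_cm <= th$t2_max_cm, "T2", "T3a")))
  out[gross_ete] <- "T3b"
  out
}

#' Derive the simplified N category from positive node count
#'
#' Any nodal metastasis is N1; the N1a/N1b compartment split is not part of
#' the extraction schema.
#'
#' @param nodes_positive Nonnegative integer count of nodes positive for
#'   malignancy.
#' @return `"N0"` or `"N1"`.
#' @export
derive_n_category <- function(nodes_positive) {
  if (any(!is.finite(nodes_positive)) || any(nodes_positive < 0)) {
    stop("`nodes_positive` must be a nonnegative count", call. = FALSE)
  }
  ifelse(nodes_positive > 0, "N1", "N0")
}

#' Simplified ATA recurrence-risk tier
#'
#' Maps pathology features to a low/intermediate/high structural-recurrence
#' risk tier following the American Thyroid Association stratification in
#' simplified form: gross extrathyroidal extension is high risk; vascular
#' invasion, an aggressive papillary variant (tall cell, hobnail, columnar
#' cell) or any positive node is intermediate; otherwise low. Microscopic
#' lymphatic invasion alone does not raise the tier in this subset.
#'
#' @param gross_ete Logical.
#' @param vascular_invasion Logical.
#' @param nodes_positive Nonnegative integer.
#' @param aggressive_variant One of `"none","tall_cell","hobnail","columnar"`.
#' @return `"low"`, `"intermediate"` or `"high"`.
#' @export
recurrence_risk_tier <- function(gross_ete, vascular_invasion, nodes_positive,
                                 aggressive_variant = "none") {
  stopifnot(is.logical(gross_ete), is.logical(vascular_invasion))
  if (any(nodes_positive < 0)) {
    stop("`nodes_positive` must be a nonnegative count", call. = FALSE)
  }
  n <- max(length(gross_ete), length(vascular_invasion),
           length(nodes_positive), length(aggressive_variant))
  gross_ete <- rep_len(gross_ete, n)
  vascular_invasion <- rep_len(vascular_invasion, n)
  nodes_positive <- rep_len(nodes_positive, n)
  aggressive_variant <- rep_len(aggressive_variant, n)
  intermediate <- vascular_invasion | aggressive_variant != "none" |
    nodes_positive > 0
  out <- ifelse(gross_ete, "high", ifelse(intermediate, "intermediate", "low"))
  out
}
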