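.report_categories <- c("thyroid_malignant", "other_organ", "benign",
                        "cytopathology", "outside_review")
.excluded_categories <- setdiff(.report_categories, "thyroid_malignant")

#' Generator settings for the synthetic report corpus
#'
#' Defaults emulate the composition of the study-scale corpus the pipeline
#' is designed for: 102 accessioned cases of which 84 are malignant
#' thyroid surgical pathology reports and the rest fall into the four
#' exclusion categories (other organ site 10, benign 2, cytopathology 5,
#' outside review 1). `long_fraction` controls how many reports are padded
#' past the 2048-token budget and therefore forced through segmentation
#' and retrieval; `mm_fraction` renders that share of tumor sizes in mm to
#' exercise unit normalization; `cervical_prob` is the probability that a
#' node section uses the word "cervical" rather than a neck-level or
#' compartment label (most real reports label nodes by level, a documented
#' retrieval pitfall); `distractor_dims` adds specimen dimensions (lobe
#' measurements, weights) that are not the tumor size.
#'
#' @param category_proportions Named proportions over the five report
#'   categories; must sum to 1.
#' @param long_fraction Fraction of reports exceeding the token budget.
#' @param mm_fraction Fraction of tumor sizes rendered in mm.
#' @param cervical_prob Probability a node section says "cervical".
#' @param distractor_dims Logical; include specimen-dimension distractors.
#' @param style_weights Named sampling weights over report styles
#'   `prose`, `synoptic`, `mixed`.
#' @param token_limit Token budget the long reports must exceed.
#' @return A list of generator settings.
#' @export
default_style_config <- function(category_proportions = c(
                                   thyroid_malignant = 84, other_organ = 10,
                                   benign = 2, cytopathology = 5,
                                   outside_review = 1) / 102,
                                 long_fraction = 0.3,
                                 mm_fraction = 0.2,
                                 cervical_prob = 0.15,
                                 distractor_dims = TRUE,
                                 style_weights = c(prose = 0.4,
                                                   synoptic = 0.35,
                                                   mixed = 0.25),
                                 token_limit = 2048L) {
  list(category_proportions = category_proportions,
       long_fraction = long_fraction, mm_fraction = mm_fraction,
       cervical_prob = cervical_prob, distractor_dims = distractor_dims,
       style_weights = style_weights, token_limit = token_limit)
}

validate_style_config <- function(config) {
  p <- config$category_proportions
  if (is.null(names(p)) || !all(names(p) %in% .report_categories)) {
    stop("configuration error: category_proportions must be named with ",
         paste(.report_categories, collapse = ", "), call. = FALSE)
  }
  if (abs(sum(p) - 1) > 1e-6 || any(p < 0)) {
    stop("configuration error: category_proportions must be nonnegative ",
         "and sum to 1", call. = FALSE)
  }
  stopifnot(config$long_fraction >= 0, config$long_fraction <= 1,
            config$mm_fraction >= 0, config$mm_fraction <= 1)
  invisible(config)
}

# Deterministic largest-remainder apportionment of n among proportions.
apportion_counts <- function(n, proportions) {
  raw <- n * proportions
  counts <- floor(raw)
  rem <- n - sum(counts)
  if (rem > 0) {
    frac_order <- order(-(raw - counts), seq_along(raw))
    counts[frac_order[seq_len(rem)]] <- counts[frac_order[seq_len(rem)]] + 1
  }
  stats::setNames(as.integer(counts), names(proportions))
}

#' Generate a seeded synthetic corpus of thyroid pathology reports
#'
#' Produces `n` synthetic surgical pathology reports with complete ground
#' truth. Malignant reports carry a full truth record (size, location,
#' extrathyroidal extension, node counts, lymphovascular invasion,
#' histology, aggressive variant, second cancer, derived T category) and a
#' narrative in which every ground-truth fact appears as a literal
#' sentence; excluded-category reports get plausible non-thyroid or benign
#' boilerplate and are never questioned downstream. Generation is fully
#' deterministic for a given `(n, seed, config)`.
#'
#' @param n Number of reports (>= 1).
#' @param seed Integer seed.
#' @param config Generator settings, see [default_style_config()].
#' @return An object of class `mqa_corpus`: list with tibbles `reports`
#'   (`report_id`, `category`, `style`, `long`, `text`, list-columns
#'   `key_sentences` and `distractor_dims_cm`) and `truth` (one row per
#'   report; tumor fields are `NA` outside `thyroid_malignant`).
#' @export
generate_corpus <- function(n, seed, config = default_style_config()) {
  stopifnot(n >= 1)
  validate_style_config(config)
  counts <- apportion_counts(n, config$category_proportions)
  with_seed(seed, {
    categories <- sample(rep(names(counts), counts))
    styles <- sample(names(config$style_weights), n, replace = TRUE,
                     prob = config$style_weights)
    long <- stats::runif(n) < config$long_fraction
    report_ids <- sprintf("SP-%04d", seq_len(n))
    truth_rows <- vector("list", n)
    texts <- character(n)
    key_sentences <- vector("list", n)
    distractor_dims <- vector("list", n)
    for (i in seq_len(n)) {
      truth <- if (categories[i] == "thyroid_malignant") {
        sample_truth(report_ids[i])
      } else {
        empty_truth(report_ids[i], categories[i])
      }
      render_seed <- sample.int(2147483646L, 1)
      rendered <- render_report(truth, style = styles[i], seed = render_seed,
                                config = config, long = long[i])
      truth_rows[[i]] <- truth
      texts[i] <- as.character(rendered)
      key_sentences[[i]] <- attr(rendered, "key_sentences")
      distractor_dims[[i]] <- attr(rendered, "distractor_dims_cm")
    }
    reports <- tibble::tibble(
      report_id = report_ids, category = categories, style = styles,
      long = long, text = texts, key_sentences = key_sentences,
      distractor_dims_cm = distractor_dims)
    truth_df <- tibble::as_tibble(do.call(rbind, lapply(truth_rows, function(t) {
      as.data.frame(t, stringsAsFactors = FALSE)
    })))
    structure(list(reports = reports, truth = truth_df, config = config),
              class = "mqa_corpus")
  })
}

sample_truth <- function(report_id) {
  size <- round(stats::runif(1, 0.4, 6.0), 1)
  if (size <= 0) size <- 0.1
  histology <- sample(c("papillary", "follicular", "medullary"), 1,
                      prob = c(0.80, 0.12, 0.08))
  variant <- if (histology == "papillary") {
    sample(c("none", "tall_cell", "hobnail", "columnar"), 1,
           prob = c(0.80, 0.08, 0.06, 0.06))
  } else "none"
  gross_ete <- stats::runif(1) < 0.15
  nodes_examined <- if (stats::runif(1) < 0.35) 0L else sample(1:12, 1)
  nodes_positive <- if (nodes_examined > 0) {
    stats::rbinom(1, nodes_examined, 0.3)
  } else 0L
  second <- stats::runif(1) < 0.15
  list(report_id = report_id, category = "thyroid_malignant",
       tumor_size_cm = size,
       location = sample(c("right_lobe", "left_lobe", "isthmus"), 1,
                         prob = c(0.45, 0.45, 0.10)),
       gross_ete = gross_ete,
       nodes_examined = as.integer(nodes_examined),
       nodes_positive = as.integer(nodes_positive),
       vascular_invasion = stats::runif(1) < 0.20,
       lymphatic_invasion = stats::runif(1) < 0.25,
       histology = histology, aggressive_variant = variant,
       second_cancer = second,
       second_cancer_histology = if (second) {
         sample(c("papillary", "follicular"), 1, prob = c(0.85, 0.15))
       } else NA_character_,
       t_category = derive_t_category(size, gross_ete))
}

empty_truth <- function(report_id, category) {
  list(report_id = report_id, category = category,
       tumor_size_cm = NA_real_, location = NA_character_, gross_ete = NA,
       nodes_examined = NA_integer_, nodes_positive = NA_integer_,
       vascular_invasion = NA, lymphatic_invasion = NA,
       histology = NA_character_, aggressive_variant = NA_character_,
       second_cancer = NA, second_cancer_histology = NA_character_,
       t_category = NA_character_)
}

cap_first <- function(s) {
  paste0(toupper(substring(s, 1, 1)), substring(s, 2))
}

.location_text <- c(right_lobe = "right thyroid lobe",
                    left_lobe = "left thyroid lobe",
                    isthmus = "isthmus")
.histology_text <- c(papillary = "papillary thyroid carcinoma",
                     follicular = "follicular carcinoma",
                     medullary = "medullary carcinoma")
.variant_text <- c(tall_cell = "tall cell", hobnail = "hobnail",
                   columnar = "columnar cell")

#' Render one synthetic report narrative
#'
#' Deterministically turns a ground-truth record into a report narrative
#' in `prose`, `synoptic` (labeled field/value lines) or `mixed` style.
#' Every ground-truth fact appears as a literal sentence; specimen
#' dimensions that are not the tumor size are included as distractors;
#' node sections are labeled by neck level or compartment and use the word
#' "cervical" only with configurable probability; and `long = TRUE` pads
#' the report with administrative boilerplate until it exceeds the token
#' budget, forcing the retrieval path.
#'
#' @param truth A truth record (named list or one-row data frame) as
#'   produced inside [generate_corpus()].
#' @param style `"prose"`, `"synoptic"` or `"mixed"`.
#' @param seed Integer seed; identical `(truth, style, seed)` give
#'   identical text.
#' @param config Generator settings, see [default_style_config()].
#' @param long Pad beyond the token budget?
#' @return The narrative string, with attributes `key_sentences` (named by
#'   question id; the literal answer-bearing sentence for each item) and
#'   `distractor_dims_cm`.
#' @export
render_report <- function(truth, style = "prose", seed = 1L,
                          config = default_style_config(), long = FALSE) {
  truth <- as.list(truth)
  stopifnot(style %in% c("prose", "synoptic", "mixed"))
  with_seed(seed, {
    if (identical(truth$category, "thyroid_malignant")) {
      render_malignant(truth, style, config, long)
    } else {
      render_excluded(truth, config, long)
    }
  })
}

# decide per-item form: prose/synoptic, resolving "mixed" by coin flip
item_style <- function(style) {
  if (style == "mixed") sample(c("prose", "synoptic"), 1) else style
}

render_malignant <- function(truth, style, config, long) {
  pick <- function(x) if (length(x) == 1L) x else sample(x, 1)
  key <- character()
  loc_txt <- .location_text[[truth$location]]

  # -- tumor size (cm, or mm for a configurable fraction)
  use_mm <- stats::runif(1) < config$mm_fraction
  unit_str <- if (use_mm) {
    sprintf("%d mm", as.integer(round(truth$tumor_size_cm * 10)))
  } else {
    sprintf("%s cm", format(truth$tumor_size_cm))
  }
  key["q1"] <- if (item_style(style) == "synoptic") {
    sprintf("Tumor size: %s.", unit_str)
  } else {
    pick(c(sprintf("The size of the primary tumor is %s.", unit_str),
           sprintf("The primary tumor measures %s in greatest dimension.",
                   unit_str)))
  }

  # -- location
  key["q3"] <- if (item_style(style) == "synoptic") {
    sprintf("Tumor site: %s.", loc_txt)
  } else {
    pick(c(sprintf("The primary cancer is located in the %s.", loc_txt),
           sprintf("The tumor is centered in the %s.", loc_txt)))
  }

  # -- extrathyroidal extension
  key["q2"] <- if (item_style(style) == "synoptic") {
    if (truth$gross_ete) {
      "Extrathyroidal extension: present, with involvement of the strap muscles."
    } else {
      "Extrathyroidal extension: not identified."
    }
  } else if (truth$gross_ete) {
    pick(c(paste0("The tumor extends beyond the thyroid capsule with gross ",
                  "invasion into the strap muscles."),
           "Gross extrathyroidal extension into the strap muscles is present."))
  } else {
    pick(c(paste0("The tumor is confined to the thyroid; no extrathyroidal ",
                  "extension is identified."),
           "No extrathyroidal extension is present."))
  }

  # -- lymph nodes; most reports label nodes by level or compartment,
  #    "cervical" appears only with configurable probability
  node_label <- if (stats::runif(1) < config$cervical_prob) {
    "cervical lymph nodes"
  } else {
    pick(c("level VI lymph nodes", "central compartment lymph nodes",
           "perithyroidal lymph nodes"))
  }
  node_sentence <- if (truth$nodes_examined > 0) {
    use_words <- stats::runif(1) < 0.5
    pos_str <- if (truth$nodes_positive == 0) {
      "None"
    } else if (use_words) {
      cap_first(count_to_word(truth$nodes_positive))
    } else {
      as.character(truth$nodes_positive)
    }
    exam_str <- if (use_words) count_to_word(truth$nodes_examined) else
      as.character(truth$nodes_examined)
    if (item_style(style) == "synoptic") {
      sprintf("Lymph nodes: %s of %s positive for malignancy.",
              pos_str, exam_str)
    } else {
      sprintf("%s of %s %s are positive for malignancy.",
              pos_str, exam_str, node_label)
    }
  } else {
    if (item_style(style) == "synoptic") {
      "Lymph nodes: none identified."
    } else {
      "No lymph nodes are identified in the specimen."
    }
  }
  key["q4"] <- node_sentence
  key["q5"] <- node_sentence

  # -- TNM stage line
  pt <- paste0("p", truth$t_category)
  pn <- if (truth$nodes_examined == 0) "pNX" else
    paste0("p", derive_n_category(truth$nodes_positive))
  key["q6"] <- if (item_style(style) == "synoptic") {
    sprintf("Final pathology TNM stage: %s %s.", pt, pn)
  } else {
    sprintf("The final pathology TNM stage of the thyroid cancer is %s %s.",
            pt, pn)
  }

  # -- lymphovascular invasion
  key["q7"] <- render_invasion("vascular", truth$vascular_invasion,
                               item_style(style), pick)
  key["q8"] <- render_invasion("lymphatic", truth$lymphatic_invasion,
                               item_style(style), pick)

  # -- histology
  hist_txt <- .histology_text[[truth$histology]]
  key["q9"] <- if (item_style(style) == "synoptic") {
    sprintf("Histologic type: %s.", hist_txt)
  } else {
    pick(c(sprintf("The histology of the primary cancer is %s.", hist_txt),
           sprintf("Sections show %s.", hist_txt)))
  }

  # -- aggressive variant
  key["q10"] <- if (truth$aggressive_variant != "none") {
    vtxt <- .variant_text[[truth$aggressive_variant]]
    if (item_style(style) == "synoptic") {
      sprintf("Aggressive variant: %s.", vtxt)
    } else {
      sprintf("%s variant features are present, indicative of a more aggressive histology.",
              cap_first(vtxt))
    }
  } else {
    if (item_style(style) == "synoptic") {
      "Aggressive variant: none identified."
    } else {
      "No tall cell, hobnail, or columnar cell variant is identified."
    }
  }

  # -- second cancer
  second_sentence <- if (truth$second_cancer) {
    hist2_txt <- .histology_text[[truth$second_cancer_histology]]
    if (item_style(style) == "synoptic") {
      sprintf("Second carcinoma: present, %s.", hist2_txt)
    } else {
      sprintf("An incidental second focus of %s is also identified.", hist2_txt)
    }
  } else {
    if (item_style(style) == "synoptic") {
      "Second carcinoma: not identified."
    } else {
      "No second thyroid cancer is identified."
    }
  }
  key["q11"] <- second_sentence
  key["q12"] <- second_sentence

  # -- gross description with specimen-dimension distractors
  procedure <- if (truth$location == "isthmus") "total thyroidectomy" else
    pick(c("total thyroidectomy", "total thyroidectomy",
           sprintf("%s hemithyroidectomy",
                   if (truth$location == "right_lobe") "right" else "left")))
  distractors <- numeric()
  gross <- sprintf(
    "Received in formalin labeled with the patient name is a %s specimen.",
    procedure)
  if (isTRUE(config$distractor_dims)) {
    sides <- if (grepl("hemithyroidectomy", procedure)) {
      sub(" hemithyroidectomy", "", procedure)
    } else {
      c("right", "left")
    }
    for (side in sides) {
      dims <- round(sort(stats::runif(3, 0.8, 6.5), decreasing = TRUE), 1)
      distractors <- c(distractors, dims)
      gross <- c(gross, sprintf("The %s lobe measures %.1f x %.1f x %.1f cm.",
                                side, dims[1], dims[2], dims[3]))
    }
    gross <- c(gross, sprintf("The specimen weighs %.1f g.",
                              round(stats::runif(1, 8, 60), 1)))
  }
  gross <- c(gross,
             "The parenchyma is tan-red and vaguely nodular on sectioning.")

  diag_order <- c("q9", "q10", "q3", "q1", "q2", "q7", "q8", "q4", "q6")
  diag_sentences <- c(unname(key[diag_order]), second_sentence)

  text <- paste(c(
    "SURGICAL PATHOLOGY REPORT",
    sprintf("Accession: %s", truth$report_id),
    "",
    sprintf("CLINICAL HISTORY: %s, surgical resection.",
            pick(c("Thyroid mass", "Thyroid nodule"))),
    "",
    sprintf("SPECIMEN: %s.", cap_first(procedure)),
    "",
    paste(c("GROSS DESCRIPTION:", gross), collapse = " "),
    "",
    "MICROSCOPIC DESCRIPTION AND DIAGNOSIS:",
    if (style == "prose") paste(diag_sentences, collapse = " ") else
      paste(diag_sentences, collapse = "\n")
  ), collapse = "\n")

  if (long) text <- pad_with_boilerplate(text, config$token_limit)

  structure(text, key_sentences = key, distractor_dims_cm = distractors)
}

render_invasion <- function(kind, present, form, pick) {
  if (form == "synoptic") {
    sprintf("%s invasion: %s.", cap_first(kind),
            if (present) "present" else "absent")
  } else if (present) {
    sprintf("%s invasion is present.", cap_first(kind))
  } else {
    pick(c(sprintf("%s invasion is not identified.", cap_first(kind)),
           sprintf("No %s invasion is seen.", kind)))
  }
}

.boilerplate_pool <- c(
  "Formalin fixation time was within recommended laboratory guidelines.",
  "All immunohistochemical controls performed appropriately.",
  "Gross photographs are archived in the laboratory imaging system.",
  "Intraoperative consultation was not requested for this case.",
  "Electronic signature is on file and results were verified by the attending pathologist.",
  "Specimen identification and labeling were confirmed at accessioning.",
  "This case was presented at the departmental quality assurance conference.",
  "Portions of this report were generated from structured laboratory templates.",
  "Clinical correlation is recommended.",
  "Billing codes were assigned according to institutional policy.",
  "Decalcification was not required for this material.",
  "Tissue was handled according to standard operating procedure.",
  "Turnaround time targets were met for this accession.",
  "The requisition form accompanied the specimen container.",
  "Quality control review of the slides showed adequate staining.",
  "Archival material will be retained per laboratory retention policy.")

# Pad a report with administrative boilerplate until it exceeds the token
# budget (plus headroom), forcing it through the retrieval path.
pad_with_boilerplate <- function(text, token_limit) {
  target <- token_limit + 200L
  comment <- c("", "COMMENT:")
  sentences <- character()
  counter <- 0L
  current <- count_tokens(text)
  while (current < target) {
    counter <- counter + 1L
    s <- sample(.boilerplate_pool, 1)
    s <- sprintf("Cassette %s%d was reviewed. %s", sample(LETTERS[1:6], 1),
                 counter, s)
    sentences <- c(sentences, s)
    current <- current + count_tokens(s)
  }
  paras <- split(sentences, ceiling(seq_along(sentences) / 6))
  body <- vapply(paras, paste, character(1), collapse = " ")
  paste(c(text, comment, paste(body, collapse = "\n")), collapse = "\n")
}

render_excluded <- function(truth, config, long) {
  body <- switch(truth$category,
    other_organ = {
      organ <- sample(c("breast, lumpectomy", "colon, segmental resection",
                        "skin of the back, excision",
                        "lung, wedge resection"), 1)
      diagnosis <- sample(c("invasive carcinoma, see synoptic report",
                            "fibroadipose tissue with reactive changes",
                            "carcinoma, further classified in the addendum"), 1)
      sprintf("SPECIMEN: %s.\n\nDIAGNOSIS: %s.", cap_first(organ), diagnosis)
    },
    benign = paste0(
      "SPECIMEN: Thyroid, total thyroidectomy.\n\nDIAGNOSIS: Benign ",
      "multinodular goiter with adenomatoid change. No malignancy is ",
      "identified."),
    cytopathology = paste0(
      "CYTOPATHOLOGY REPORT\n\nSPECIMEN: Thyroid, fine needle aspiration.",
      "\n\nINTERPRETATION: Benign follicular cells and colloid, consistent ",
      "with a benign follicular process (Bethesda category II)."),
    outside_review = paste0(
      "OUTSIDE CASE REVIEW\n\nSlides and blocks received in consultation ",
      "from an outside institution. See the original outside report for ",
      "the complete diagnosis."),
    stop("unknown report category: ", truth$category, call. = FALSE))
  text <- paste(c("SURGICAL PATHOLOGY REPORT",
                  sprintf("Accession: %s", truth$report_id), "", body),
                collapse = "\n")
  if (long) text <- pad_with_boilerplate(text, config$token_limit)
  structure(text, key_sentences = character(), distractor_dims_cm = numeric())
}

#' Apply the study inclusion filter to a corpus
#'
#' Partitions a corpus into the malignant thyroid surgical pathology
#' reports retained for analysis and a tally of excluded reports by
#' category (other organ site, benign, cytopathology, outside review).
#' No report is lost or duplicated: the included count plus the tally sum
#' equals the corpus size.
#'
#' @param corpus An `mqa_corpus` from [generate_corpus()].
#' @return A list with `included` (an `mqa_corpus` restricted to
#'   `thyroid_malignant` reports) and `exclusion_tally` (named integer
#'   vector over the four exclusion categories).
#' @export
filter_corpus <- function(corpus) {
  stopifnot(inherits(corpus, "mqa_corpus"))
  keep <- corpus$reports$category == "thyroid_malignant"
  tally <- vapply(.excluded_categories, function(cat) {
    sum(corpus$reports$category == cat)
  }, integer(1))
  included <- structure(
    list(reports = corpus$reports[keep, , drop = FALSE],
         truth = corpus$truth[corpus$truth$report_id %in%
                                corpus$reports$report_id[keep], , drop = FALSE],
         config = corpus$config),
    class = "mqa_corpus")
  list(included = included, exclusion_tally = tally)
}

#' @export
print.mqa_corpus <- function(x, ...) {
  cat("<mqa_corpus> ", nrow(x$reports), " reports (",
      sum(x$reports$category == "thyroid_malignant"), " thyroid_malignant, ",
      sum(x$reports$long), " over the token budget)\n", sep = "")
  invisible(x)
}
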