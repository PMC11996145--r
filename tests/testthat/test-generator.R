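test_that("generation is byte-identical under a fixed seed", {
  a <- generate_corpus(1, seed = 7)
  b <- generate_corpus(1, seed = 7)
  expect_identical(a, b)
  c <- generate_corpus(1, seed = 8)
  expect_false(identical(a$reports$text, c$reports$text))
})

test_that("default proportions yield the study-scale category counts at n = 102", {
  co <- study_corpus()
  counts <- table(co$reports$category)
  expect_equal(unname(counts["thyroid_malignant"]), 84L, ignore_attr = TRUE)
  expect_equal(unname(counts["other_organ"]), 10L, ignore_attr = TRUE)
  expect_equal(unname(counts["benign"]), 2L, ignore_attr = TRUE)
  expect_equal(unname(counts["cytopathology"]), 5L, ignore_attr = TRUE)
  expect_equal(unname(counts["outside_review"]), 1L, ignore_attr = TRUE)
})

test_that("invalid category proportions are a configuration error", {
  cfg <- default_style_config()
  cfg$category_proportions["benign"] <- 0.5
  expect_error(generate_corpus(10, seed = 1, config = cfg),
               "configuration error")
})

test_that("every generated truth satisfies its invariants", {
  co <- generate_corpus(50, seed = 3)
  truth <- co$truth[co$truth$category == "thyroid_malignant", ]
  expect_true(all(truth$nodes_positive <= truth$nodes_examined))
  expect_true(all(truth$tumor_size_cm > 0))
  expect_true(all(truth$histology[truth$aggressive_variant != "none"] ==
                    "papillary"))
  expect_true(all(is.na(truth$second_cancer_histology) == !truth$second_cancer))
  expect_equal(truth$t_category,
               derive_t_category(truth$tumor_size_cm, truth$gross_ete))
  # only malignant records carry tumor fields
  excluded <- co$truth[co$truth$category != "thyroid_malignant", ]
  expect_true(all(is.na(excluded$tumor_size_cm)))
  expect_true(all(is.na(excluded$t_category)))
})

test_that("rendering realizes the ground truth and its documented pitfalls", {
  truth <- list(report_id = "SP-TEST", category = "thyroid_malignant",
                tumor_size_cm = 5.5, location = "right_lobe",
                gross_ete = FALSE, nodes_examined = 7L, nodes_positive = 3L,
                vascular_invasion = TRUE, lymphatic_invasion = FALSE,
                histology = "papillary", aggressive_variant = "none",
                second_cancer = FALSE,
                second_cancer_histology = NA_character_,
                t_category = "T3a")
  cfg <- default_style_config(mm_fraction = 0, cervical_prob = 0)
  text <- render_report(truth, style = "prose", seed = 5, config = cfg)
  expect_match(text, "5.5 cm", fixed = TRUE)
  expect_match(text, "right thyroid lobe")
  expect_match(text, "of (seven|7) ")
  expect_match(text, "pT3a", fixed = TRUE)
  # negated lymphatic invasion statement literally present
  expect_match(text, "(Lymphatic invasion is not identified|No lymphatic invasion is seen)")
  # node section avoids the word "cervical" when cervical_prob = 0
  expect_false(grepl("cervical", text, ignore.case = TRUE))
  # specimen-dimension distractors present and distinct from tumor size
  dims <- attr(text, "distractor_dims_cm")
  expect_gte(length(dims), 3L)
  # determinism of the renderer
  expect_identical(as.character(text),
                   as.character(render_report(truth, style = "prose",
                                              seed = 5, config = cfg)))
  # every key sentence is literally present in the narrative
  key <- attr(text, "key_sentences")
  expect_setequal(names(key), paste0("q", 1:12))
  for (s in unique(key)) expect_true(grepl(s, text, fixed = TRUE))
})

test_that("filter_corpus partitions the corpus without loss", {
  co <- study_corpus()
  fc <- filter_corpus(co)
  expect_equal(nrow(fc$included$reports), 84L)
  expect_equal(fc$exclusion_tally,
               c(other_organ = 10L, benign = 2L, cytopathology = 5L,
                 outside_review = 1L))
  expect_equal(nrow(fc$included$reports) + sum(fc$exclusion_tally),
               nrow(co$reports))
  expect_true(all(fc$included$reports$category == "thyroid_malignant"))

  # degenerate corpora
  empty_cfg <- default_style_config(category_proportions = c(
    thyroid_malignant = 0, other_organ = 0, benign = 1, cytopathology = 0,
    outside_review = 0))
  benign_only <- generate_corpus(4, seed = 1, config = empty_cfg)
  fb <- filter_corpus(benign_only)
  expect_equal(nrow(fb$included$reports), 0L)
  expect_equal(fb$exclusion_tally[["benign"]], 4L)
  expect_equal(sum(fb$exclusion_tally), 4L)
})

test_that("the long-report fraction is under binomial control", {
  cfg <- default_style_config(long_fraction = 0.3)
  co <- generate_corpus(120, seed = 9, config = cfg)
  n_long <- sum(vapply(co$reports$text, needs_splitting, logical(1)))
  # flagged reports and only flagged reports exceed the budget
  expect_equal(n_long, sum(co$reports$long))
  bounds <- qbinom(c(0.005, 0.995), 120, 0.3)
  expect_gte(n_long, bounds[1])
  expect_lte(n_long, bounds[2])
})

test_that("a configurable fraction of sizes is rendered in mm", {
  cfg <- default_style_config(mm_fraction = 1)
  co <- generate_corpus(20, seed = 21, config = cfg)
  mal <- co$reports$category == "thyroid_malignant"
  q1_sentences <- vapply(co$reports$key_sentences[mal],
                         function(k) k[["q1"]], character(1))
  expect_true(all(grepl("[0-9]+ mm", q1_sentences)))
})

test_that("corpus JSONL round-trips", {
  co <- generate_corpus(6, seed = 2)
  path <- withr::local_tempfile(fileext = ".jsonl")
  truth_path <- withr::local_tempfile(fileext = ".jsonl")
  write_corpus_jsonl(co, path, truth_path)
  back <- read_corpus_jsonl(path)
  expect_equal(back$report_id, co$reports$report_id)
  expect_equal(back$text, co$reports$text)
  expect_equal(back$category, co$reports$category)
  expect_equal(length(readLines(truth_path)), 6L)
})
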