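ctx_size <- paste(
  "The right lobe measures 4.2 x 3.0 x 2.1 cm.",
  "The size of the primary tumor is 5.5 cm.",
  "The primary cancer is located in the right thyroid lobe.")

test_that("the reference backend reads tumor size past specimen distractors", {
  q1 <- question_row("q1")
  raw <- answer_question(ctx_size, q1)
  expect_match(raw$text, "5.5 cm", fixed = TRUE)
  expect_equal(normalize_answer(raw$text, q1), "5.5")

  # only a lobe dimension present: the distractor must be rejected
  distractor_only <- paste(
    "The right lobe measures 4.2 x 3.0 x 2.1 cm and weighs 12 g.",
    "Sections show papillary thyroid carcinoma.")
  raw2 <- answer_question(distractor_only, q1)
  expect_equal(normalize_answer(raw2$text, q1), "not_stated")
})

test_that("location, histology and variant extraction use controlled vocabulary", {
  q3 <- question_row("q3")
  expect_equal(normalize_answer(reference_extract(ctx_size, q3), q3),
               "right_lobe")
  iso <- "The tumor is centered in the isthmus."
  expect_equal(normalize_answer(reference_extract(iso, q3), q3), "isthmus")

  q9 <- question_row("q9")
  two_foci <- paste(
    "An incidental second focus of follicular carcinoma is also identified.",
    "The histology of the primary cancer is papillary thyroid carcinoma.")
  expect_equal(normalize_answer(reference_extract(two_foci, q9), q9),
               "papillary")

  q10 <- question_row("q10")
  neg <- "No tall cell, hobnail, or columnar cell variant is identified."
  expect_equal(normalize_answer(reference_extract(neg, q10), q10), "none")
  pos <- "Hobnail variant features are present."
  expect_equal(normalize_answer(reference_extract(pos, q10), q10), "hobnail")
})

test_that("node counts parse number words and digits", {
  q4 <- question_row("q4")
  q5 <- question_row("q5")
  s <- "Three of seven lymph nodes positive for malignancy."
  expect_equal(normalize_answer(reference_extract(s, q4), q4), "yes")
  expect_equal(normalize_answer(reference_extract(s, q5), q5), "3")

  s2 <- "Lymph nodes: 2 of 5 positive for malignancy."
  expect_equal(normalize_answer(reference_extract(s2, q5), q5), "2")

  s3 <- "None of the four level VI lymph nodes are positive for malignancy."
  expect_equal(normalize_answer(reference_extract(s3, q5), q5), "0")
  expect_equal(normalize_answer(reference_extract(s3, q4), q4), "yes")

  s4 <- "No lymph nodes are identified in the specimen."
  expect_equal(normalize_answer(reference_extract(s4, q4), q4), "no")
  expect_equal(normalize_answer(reference_extract(s4, q5), q5),
               "not_applicable")
})

test_that("negation-aware booleans and absent findings", {
  q7 <- question_row("q7")
  q8 <- question_row("q8")
  expect_equal(normalize_answer(
    reference_extract("Vascular invasion is present.", q7), q7), "yes")
  expect_equal(normalize_answer(
    reference_extract("No vascular invasion is seen.", q7), q7), "no")
  expect_equal(normalize_answer(
    reference_extract("Lymphatic invasion: absent.", q8), q8), "no")
  # no invasion language at all -> not stated
  expect_equal(normalize_answer(
    reference_extract("Sections show benign tissue.", q7), q7), "not_stated")
})

test_that("TNM tokens are scanned and canonicalized", {
  q6 <- question_row("q6")
  raw <- reference_extract(
    "The final pathology TNM stage of the thyroid cancer is pT3a pN1.", q6)
  expect_match(raw, "pT3a")
  expect_equal(normalize_answer(raw, q6), "T3a")
  expect_equal(normalize_answer("pT1B", q6), "T1b")
})

test_that("normalization converts units and is idempotent on canonicals", {
  q1 <- question_row("q1")
  expect_equal(normalize_answer("The size of the primary tumor was 5.5 cm.",
                                q1), "5.5")
  expect_equal(normalize_answer("12 mm", q1), "1.2")
  q8 <- question_row("q8")
  expect_equal(normalize_answer("No, lymphatic invasion is not present.",
                                q8), "no")
  # idempotence: canonical values map to themselves
  cases <- list(q1 = "5.5", q2 = "no", q3 = "right_lobe", q5 = "3",
                q6 = "T3a", q9 = "papillary", q10 = "tall_cell",
                q11 = "yes", q12 = "not_applicable", q4 = "not_stated")
  for (qid in names(cases)) {
    q <- question_row(qid)
    expect_identical(normalize_answer(cases[[qid]], q), cases[[qid]])
  }
})

test_that("backend failures degrade to a not-stated answer", {
  broken <- structure(list(id = "broken",
                           answer = function(context_text, question) {
                             stop("boom")
                           }),
                      class = "mqa_backend")
  q1 <- question_row("q1")
  expect_warning(raw <- answer_question("some context", q1, broken), "boom")
  expect_equal(normalize_answer(raw$text, q1), "not_stated")
})

test_that("identical inputs give identical reference answers", {
  q7 <- question_row("q7")
  a <- answer_question(ctx_size, q7)
  b <- answer_question(ctx_size, q7)
  expect_identical(a, b)
})
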