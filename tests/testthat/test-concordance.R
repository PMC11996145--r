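# small fully-crossed answer grid built in code
toy_answers <- function(n_reports = 4, source = "A",
                        questions = load_questions()) {
  reports <- sprintf("R%02d", seq_len(n_reports))
  base <- c(q1 = "2.5", q2 = "no", q3 = "left_lobe", q4 = "yes", q5 = "1",
            q6 = "T2", q7 = "no", q8 = "no", q9 = "papillary", q10 = "none",
            q11 = "no", q12 = "not_applicable")
  tibble::tibble(
    report_id = rep(reports, each = nrow(questions)),
    question_id = rep(questions$question_id, n_reports),
    source_id = source,
    value = rep(unname(base[questions$question_id]), n_reports))
}

test_that("type-aware cell concordance", {
  pol <- default_policy()
  expect_true(is_concordant("5.5", "5.5", "size_cm", pol))
  expect_false(is_concordant("5.5", "4.2", "size_cm", pol))
  expect_true(is_concordant("5.5", "5.54", "size_cm", pol))  # 0.1 cm rounding
  expect_true(is_concordant("T3a", "t3A", "tnm_stage", pol))
  expect_true(is_concordant("pT3a", "T3a", "tnm_stage", pol))
  expect_false(is_concordant("T3a", "T3b", "tnm_stage", pol))
  expect_true(is_concordant("not_applicable", "not_applicable", "histology",
                            pol))
  expect_false(is_concordant("not_applicable", "not_stated", "histology",
                             pol))
  # boolean policy: an unmentioned finding counts as absent
  expect_true(is_concordant("not_stated", "no", "boolean", pol))
  expect_false(is_concordant("not_stated", "yes", "boolean", pol))
  strict <- default_policy(not_stated_as_absent = FALSE)
  expect_false(is_concordant("not_stated", "no", "boolean", strict))
})

test_that("identical sets are everywhere 100% concordant", {
  a <- toy_answers(5, "A")
  ct <- per_question_rates(a, toy_answers(5, "B"))
  expect_true(all(ct$per_question$rate == 100))
  expect_equal(ct$overall$mean_rate, 100)
  expect_equal(ct$overall$sd_rate, 0)
  expect_equal(ct$overall$pooled_rate, 100)
  expect_equal(ct$per_question$pair[1], "A-B")
})

test_that("rates are symmetric in the two answer sets and pool correctly", {
  a <- toy_answers(6, "A")
  b <- toy_answers(6, "B")
  b$value[b$question_id == "q7"][1:2] <- "yes"
  b$value[b$question_id == "q1"][1] <- "9.9"
  ab <- per_question_rates(a, b)
  ba <- per_question_rates(b, a)
  expect_equal(ab$per_question$concordant, ba$per_question$concordant)
  expect_equal(ab$overall$pooled_rate, ba$overall$pooled_rate)
  expect_equal(ab$overall$pooled_concordant,
               sum(ab$per_question$concordant))
  expect_equal(ab$overall$pooled_total, 6 * 12)
  expect_equal(ab$per_question$rate[ab$per_question$question_id == "q7"],
               100 * 4 / 6)
})

test_that("incomplete or mismatched grids are rejected with cell listings", {
  a <- toy_answers(3, "A")
  b <- toy_answers(3, "B")
  expect_error(per_question_rates(a[-5, ], b[-5, ]), "missing cells")
  expect_error(per_question_rates(a[-5, ], b), "different grids")
  dup <- rbind(a, a[1, ])
  expect_error(per_question_rates(dup, b), "duplicated")
})

test_that("mean/SD aggregation reproduces the published worked example", {
  rates_r1_r2 <- c(98, 97, 99, 99, 100, 100, 100, 100, 100, 97, 99, 99)
  s <- summarize_rates(rates_r1_r2)
  expect_equal(s$mean, 99)
  expect_equal(round(s$sd), 1)          # sample convention
  expect_equal(round(s$sd_population), 1)
  expect_equal(summarize_rates(c(42))$mean, 42)
  expect_equal(summarize_rates(c(42))$sd_population, 0)
  expect_error(summarize_rates(numeric()), "nonempty")
})

test_that("nine discordant cells out of 1008 give the published pooled rate", {
  a <- toy_answers(84, "R1")
  b <- toy_answers(84, "R2")
  stopifnot(nrow(a) == 1008)
  flip <- which(b$question_id == "q2")[1:9]
  b$value[flip] <- "yes"
  ct <- per_question_rates(a, b)
  expect_equal(ct$overall$pooled_concordant, 999)
  expect_equal(ct$overall$pooled_total, 1008)
  expect_equal(round(ct$overall$pooled_rate, 1), 99.1)
  expect_equal(ct$overall$pooled_total - ct$overall$pooled_concordant, 9)
})

test_that("the published per-question columns average as printed", {
  tab <- reported_concordance()
  expect_equal(mean(tab$r1_llm), 88.75)
  expect_equal(round(mean(tab$r1_llm)), 89)
  expect_equal(mean(tab$r1_r2), 99)
  expect_equal(round(sd(tab$r1_r2)), 1)
  expect_equal(round(sd(tab$r1_llm)), 7)
})

# independent textbook t machinery: density integrated numerically
t_density <- function(x, v) {
  gamma((v + 1) / 2) / (sqrt(v * pi) * gamma(v / 2)) *
    (1 + x^2 / v)^(-(v + 1) / 2)
}
t_two_sided_p <- function(t_stat, v) {
  upper <- stats::integrate(t_density, abs(t_stat), Inf, v = v,
                            rel.tol = 1e-12)$value
  2 * upper
}

test_that("pairwise t tests agree with an independent t computation", {
  expect_equal(compare_pairings(c(99, 98, 97), c(99, 98, 97))$p_value, 1)
  expect_equal(compare_pairings(c(99, 98, 97), c(99, 98, 97))$t_statistic, 0)

  a <- c(90, 80, 70)
  b <- c(85, 78, 60)
  res <- compare_pairings(a, b, mode = "paired")
  d <- a - b
  t_hand <- mean(d) / (sd(d) / sqrt(length(d)))
  expect_equal(res$t_statistic, t_hand, tolerance = 1e-12)
  expect_equal(res$p_value, t_two_sided_p(t_hand, length(d) - 1),
               tolerance = 1e-9)

  tab <- reported_concordance()
  res2 <- compare_pairings(tab$r1_llm, tab$r1_r2, mode = "paired")
  d2 <- tab$r1_llm - tab$r1_r2
  t2 <- mean(d2) / (sd(d2) / sqrt(length(d2)))
  expect_equal(res2$t_statistic, t2, tolerance = 1e-12)
  expect_equal(res2$p_value, t_two_sided_p(t2, length(d2) - 1),
               tolerance = 1e-9)
  expect_lt(res2$p_value, 0.001)  # model clearly below the reviewer pairing

  w <- compare_pairings(tab$r1_llm, tab$r2_llm, mode = "welch")
  expect_equal(w$mode_used, "welch")
  expect_gte(w$p_value, 0)
  expect_lte(w$p_value, 1)
  expect_error(compare_pairings(1:3, 1:4), "equal length")
})

test_that("concordance tables export to CSV", {
  ct <- per_question_rates(toy_answers(3, "A"), toy_answers(3, "B"))
  path <- withr::local_tempfile(fileext = ".csv")
  write_concordance_csv(ct, path)
  back <- utils::read.csv(path)
  expect_equal(names(back),
               c("question_id", "pair", "concordant", "total", "rate"))
  expect_equal(nrow(back), 12L)
})
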