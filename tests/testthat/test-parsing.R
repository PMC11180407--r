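test_that("answers that map unambiguously to one in-range score are valid", {
  p <- parse_score("The relevance of the publication is 3.", 5)
  expect_true(p$valid)
  expect_equal(p$score, 3L)

  expect_equal(parse_score("3", 5)$score, 3L)
  expect_equal(parse_score("  4 \n", 5)$score, 4L)
  expect_equal(parse_score("Score: 2 (well below the midpoint)", 5)$score, 2L)
})

test_that("out-of-range, absent and ambiguous integers are tagged invalid", {
  p <- parse_score("7", 5)
  expect_false(p$valid)
  expect_equal(p$invalid_reason, "out_of_range")

  expect_equal(parse_score("no score given", 5)$invalid_reason, "no_integer")
  expect_equal(parse_score("I would say 2, or maybe 4.", 5)$invalid_reason,
               "ambiguous")
  # an out-of-range integer before the unique in-range one could itself be
  # the intended rating
  expect_equal(parse_score("90 percent confident: 3", 5)$invalid_reason,
               "ambiguous")
  # ... but trailing context numbers do not spoil the assignment
  expect_equal(parse_score("3 (confidence 90)", 5)$score, 3L)
  expect_equal(parse_score(NA, 5)$invalid_reason, "response_missing")
})

test_that("digits embedded in words are not score candidates", {
  expect_equal(parse_score("Mistral7B says nothing", 5)$invalid_reason,
               "no_integer")
  expect_equal(parse_score("Mistral7B rates it 4", 5)$score, 4L)
})

test_that("'x out of y' is accepted exactly when y is the scale maximum", {
  expect_equal(parse_score("4 out of 5", 5)$score, 4L)
  expect_equal(parse_score("I rate it 4 out of 5.", 5)$score, 4L)
  # toggled off, both integers compete and the answer is ambiguous
  expect_equal(parse_score("4 out of 5", 5,
                           allow_x_out_of_y = FALSE)$invalid_reason,
               "ambiguous")
  # y != scale_max falls back to the general rule
  expect_equal(parse_score("4 out of 10", 5)$invalid_reason, "ambiguous")
  # slash forms stay strict
  expect_equal(parse_score("3/5", 5)$invalid_reason, "ambiguous")
})

test_that("parse_score is total over fuzzed text", {
  alphabet <- c(letters, 0:9, " ", ".", ",", "/", "-", "(", ")", "%", "\n")
  withr::with_seed(99, {
    for (i in 1:300) {
      txt <- paste(sample(alphabet, sample(0:40, 1), replace = TRUE),
                   collapse = "")
      p <- parse_score(txt, 5)
      expect_s3_class(p, "parsed_score")
      expect_identical(p$valid, is.na(p$invalid_reason))
      expect_identical(p$valid, !is.na(p$score))
      if (p$valid) expect_true(p$score >= 1 && p$score <= 5)
    }
  })
})

test_that("mock answers always parse back to the mock rule score", {
  spec <- synthetic_spec(n = 80, prevalence = 0.25, q_rel = 0.7,
                         q_irr = 0.3, seed = 13)
  recs <- generate_corpus(spec, crit5)
  cfg <- prompt_config(crit5)
  bk <- backend_mock(5)
  tab <- screen_corpus(recs, cfg, bk)
  parsed <- parse_scores(tab, 5)
  expect_true(all(parsed$valid))
  for (i in seq_len(nrow(recs))) {
    p <- build_prompt(cfg, recs[i, ])
    expect_equal(parsed$score[parsed$record_id == recs$id[i]],
                 tiabscreen:::mock_rule_score(bk, p$text))
  }
})

test_that("validity accounting reproduces the printed near-complete percentages", {
  mk_parsed <- function(n, n_valid) {
    structure(data.frame(
      record_id = sprintf("p%05d", seq_len(n)),
      raw_text = "x",
      score = c(rep(3L, n_valid), rep(NA_integer_, n - n_valid)),
      valid = c(rep(TRUE, n_valid), rep(FALSE, n - n_valid)),
      invalid_reason = c(rep(NA_character_, n_valid),
                         rep("no_integer", n - n_valid)),
      stringsAsFactors = FALSE), class = c("scores_table", "data.frame"))
  }
  expect_equal(validity_report(mk_parsed(44055, 44052))$valid_pct, 99.993)
  expect_equal(validity_report(mk_parsed(44055, 44026))$valid_pct, 99.93)
  expect_equal(validity_report(mk_parsed(44055, 44054))$valid_pct, 99.998)

  all_ok <- validity_report(mk_parsed(500, 500))
  expect_equal(all_ok$valid_pct, 100)
  expect_equal(all_ok$n_invalid, 0)

  # conservation and the invalid-relevant count under labels
  parsed <- mk_parsed(100, 97)
  labels <- stats::setNames(rep(c("relevant", "irrelevant"), c(50, 50)),
                            parsed$record_id)
  rep <- validity_report(parsed, labels)
  expect_equal(rep$n_valid + rep$n_invalid, rep$n_total)
  expect_equal(rep$n_invalid_relevant, 0)  # invalid rows are p00098..p00100
  labels2 <- stats::setNames(rep("relevant", 100), parsed$record_id)
  expect_equal(validity_report(parsed, labels2)$n_invalid_relevant, 3)
  expect_error(validity_report(parsed[0, ]),
               class = "tiab_validation_error")
})
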