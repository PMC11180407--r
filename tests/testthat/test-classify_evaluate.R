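test_that("the k+ classifier includes exactly the scores at or above k", {
  expect_equal(classify(3, k = 3, scale_max = 5), "relevant")
  expect_equal(classify(2, k = 3, scale_max = 5), "irrelevant")
  expect_equal(classify(5, k = 6, scale_max = 10), "irrelevant")
  expect_equal(classify(c(1, 2, 3, 4, 5), 3, 5),
               c("irrelevant", "irrelevant", "relevant", "relevant",
                 "relevant"))
  expect_error(classify(6, 3, 5), class = "tiab_validation_error")
  expect_error(classify(NA, 3, 5), class = "tiab_validation_error")
  expect_error(classify(3, 7, 5), class = "tiab_validation_error")
})

test_that("confusion counts match the published worked case and a brute-force oracle", {
  # 19 relevant all scored >= 3; 4410 of 5019 irrelevant scored <= 2
  scores <- c(rep(4L, 19), rep(2L, 4410), rep(3L, 609))
  gold <- rep(c("relevant", "irrelevant"), c(19, 5019))
  ids <- sprintf("w%04d", seq_along(scores))
  pred <- stats::setNames(classify(scores, 3, 5), ids)
  gold <- stats::setNames(gold, ids)
  cc <- confusion(pred, gold)
  expect_equal(cc$TP, 19)
  expect_equal(cc$FN, 0)
  expect_equal(cc$TN, 4410)
  expect_equal(cc$FP, 609)

  # random instances against the per-record counting loop
  for (seed in 1:5) {
    gold_r <- withr::with_seed(seed, sample(c("relevant", "irrelevant"),
                                            200, replace = TRUE))
    pred_r <- withr::with_seed(seed + 50,
                               sample(c("relevant", "irrelevant"), 200,
                                      replace = TRUE))
    ids <- sprintf("r%03d", 1:200)
    names(gold_r) <- names(pred_r) <- ids
    expect_equal(unclass(confusion(pred_r, gold_r))[c("TP", "FP", "TN", "FN")],
                 brute_confusion(pred_r, gold_r))
  }

  # perfect predictions
  cc0 <- confusion(gold_r, gold_r)
  expect_equal(cc0$FP + cc0$FN, 0)

  # id mismatch names the difference
  expect_error(confusion(pred_r[-1], gold_r), "r001",
               class = "tiab_validation_error")
})

test_that("the five measures reproduce the published worked values", {
  m_spec <- metrics(list(TP = 19, FP = 609, TN = 4410, FN = 0))
  expect_equal(round_half_up(m_spec$specificity, 2), 87.87)
  expect_equal(m_spec$sensitivity, 100)

  m_sens <- metrics(list(TP = 23, FP = 10, TN = 100, FN = 73))
  expect_equal(round_half_up(m_sens$sensitivity, 2), 23.96)

  m_und <- metrics(list(TP = 0, FP = 0, TN = 10, FN = 5))
  expect_true(is.na(m_und$precision))
  expect_true("precision" %in% m_und$undefined)
  expect_true(is.na(m_und$f1))
})

test_that("accuracy is the prevalence-weighted mix of sensitivity and specificity", {
  for (seed in 1:10) {
    cc <- withr::with_seed(seed, list(TP = sample(1:50, 1), FP = sample(1:50, 1),
                                      TN = sample(1:50, 1), FN = sample(1:50, 1)))
    m <- metrics(cc)
    n <- cc$TP + cc$FP + cc$TN + cc$FN
    prev <- (cc$TP + cc$FN) / n
    expect_equal(m$accuracy, prev * m$sensitivity + (1 - prev) * m$specificity)
    # F1 is the harmonic mean of precision and recall
    expect_equal(m$f1, 2 / (1 / m$precision + 1 / m$sensitivity))
  }
})

mk_scores_table <- function(ids, scores) {
  structure(data.frame(record_id = ids, raw_text = as.character(scores),
                       score = as.integer(scores), valid = TRUE,
                       invalid_reason = NA_character_,
                       stringsAsFactors = FALSE),
            class = c("scores_table", "data.frame"))
}

test_that("ROC endpoints, monotonicity and degenerate cases behave", {
  ids <- sprintf("r%03d", 1:40)
  gold <- stats::setNames(rep(c("relevant", "irrelevant"), c(10, 30)), ids)

  # perfect separation
  sep <- mk_scores_table(ids, rep(c(5L, 1L), c(10, 30)))
  roc <- roc_curve(sep, gold, 5)
  expect_equal(nrow(roc$points), 6)
  expect_equal(roc$points$k, 6:1)
  expect_true(any(roc$points$sensitivity == 100 &
                    roc$points$specificity == 100))
  expect_equal(roc$auc, 1)

  # all records share one score: every k is all-in or all-out
  flat <- mk_scores_table(ids, rep(3L, 40))
  roc_f <- roc_curve(flat, gold, 5)
  expect_true(all(roc_f$points$sensitivity %in% c(0, 100)))
  expect_true(all(roc_f$points$sensitivity + roc_f$points$specificity == 100))
  expect_equal(roc_f$auc, 0.5)

  # k = 1 includes everything
  expect_equal(roc$points$sensitivity[roc$points$k == 1], 100)
  expect_equal(roc$points$specificity[roc$points$k == 1], 0)

  # single-class input is refused
  expect_error(roc_curve(sep, stats::setNames(rep("relevant", 40), ids), 5),
               class = "tiab_validation_error")
})

test_that("ROC curves are monotone on random instances", {
  for (seed in 1:20) {
    n <- 150
    ids <- sprintf("r%03d", 1:n)
    sc <- withr::with_seed(seed, sample(1:5, n, replace = TRUE))
    gold <- withr::with_seed(seed + 1000,
                             sample(c("relevant", "irrelevant"), n,
                                    replace = TRUE, prob = c(0.3, 0.7)))
    if (length(unique(gold)) < 2) next
    roc <- roc_curve(mk_scores_table(ids, sc),
                     stats::setNames(gold, ids), 5)
    expect_true(all(diff(roc$points$sensitivity) >= 0))
    expect_true(all(diff(roc$points$specificity) <= 0))
  }
})

test_that("labels independent of scores give AUC near one half", {
  n <- 10000
  ids <- sprintf("r%05d", 1:n)
  sc <- withr::with_seed(4, sample(1:5, n, replace = TRUE))
  gold <- withr::with_seed(5, sample(c("relevant", "irrelevant"), n,
                                     replace = TRUE, prob = c(0.3, 0.7)))
  roc <- roc_curve(mk_scores_table(ids, sc), stats::setNames(gold, ids), 5)
  expect_lt(abs(roc$auc - 0.5), 0.02)
})

test_that("threshold-swept AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  n <- 400
  ids <- sprintf("r%03d", 1:n)
  sc <- withr::with_seed(21, sample(1:5, n, replace = TRUE,
                                    prob = c(0.3, 0.25, 0.2, 0.15, 0.1)))
  gold <- withr::with_seed(22, ifelse(stats::runif(n) < sc / 6,
                                      "relevant", "irrelevant"))
  roc <- roc_curve(mk_scores_table(ids, sc), stats::setNames(gold, ids), 5)
  ref <- pROC::roc(response = gold, predictor = sc, levels = c("irrelevant", "relevant"),
                   direction = "<", quiet = TRUE)
  expect_equal(roc$auc, as.numeric(ref$auc), tolerance = 1e-10)
})

test_that("run reports bundle metrics, validity, ROC and score distributions", {
  spec <- synthetic_spec(n = 200, prevalence = 0.15, q_rel = 1, q_irr = 0,
                         seed = 31)
  recs <- generate_corpus(spec, crit8)
  cfg <- prompt_config(crit8)
  scores <- parse_scores(screen_corpus(recs, cfg, backend_mock(5)), 5)
  rep <- evaluate_run(scores, recs, k = 3, scale_max = 5)
  # fully separable by construction
  expect_equal(rep$metrics$sensitivity, 100)
  expect_equal(rep$metrics$specificity, 100)
  expect_equal(rep$roc$auc, 1)

  # per-class means equal an independent loop
  sc <- stats::setNames(scores$score, scores$record_id)
  lab <- stats::setNames(recs$label, recs$id)
  tot <- 0; cnt <- 0
  for (id in names(sc)) {
    if (lab[[id]] == "relevant") { tot <- tot + sc[[id]]; cnt <- cnt + 1 }
  }
  expect_equal(rep$mean_score_relevant, tot / cnt)
  expect_equal(rep$mean_score_overall, mean(sc))

  # frequencies over score values sum to n_valid
  expect_equal(sum(rep$score_frequencies), rep$validity$n_valid)
})
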