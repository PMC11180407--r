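# Threshold ("k+") classification of Likert scores and the full
# evaluation machinery: confusion counts, the five performance measures,
# threshold-swept ROC curves and bundled run reports. The positive class
# is fixed as "relevant" throughout; there is deliberately no option to
# invert it.

#' Threshold classification of Likert scores
#'
#' The `k+` classifier labels a publication relevant iff its score is at
#' least `k` (e.g. the 3+ classifier on a 1-5 scale includes scores 3-5).
#'
#' @param score integer vector of valid scores in `[1, scale_max]`.
#' @param k threshold, in `[1, scale_max + 1]` (with `k = scale_max + 1`
#'   nothing is included).
#' @param scale_max Likert scale maximum.
#' @return character vector in `c("relevant", "irrelevant")`.
#' @export
classify <- function(score, k, scale_max = 5) {
  if (k < 1 || k > scale_max + 1) {
    abort_validation("threshold k = %s outside [1, scale_max + 1]", k)
  }
  bad <- is.na(score) | score < 1 | score > scale_max
  if (any(bad)) {
    abort_validation("score(s) outside [1, %d]: %s (invalid scores must be excluded before classification)",
                     scale_max,
                     paste(utils::head(score[bad], 5), collapse = ", "))
  }
  ifelse(score >= k, "relevant", "irrelevant")
}

#' Cross-tabulate predictions against gold labels
#'
#' @param predictions named character vector (names = record ids) or data
#'   frame with `record_id`/`id` and `prediction`/`label` columns.
#' @param gold_labels labeled corpus or named label vector over the same
#'   ids.
#' @return list of class `confusion_counts`: `TP`, `FP`, `TN`, `FN`.
#' @export
confusion <- function(predictions, gold_labels) {
  pred <- as_prediction_vector(predictions)
  gold <- as_label_vector(gold_labels)
  only_pred <- setdiff(names(pred), names(gold))
  only_gold <- setdiff(names(gold), names(pred))
  if (length(only_pred) > 0L || length(only_gold) > 0L) {
    abort_validation(
      "prediction/label id mismatch; only in predictions: [%s], only in labels: [%s]",
      paste(utils::head(only_pred, 10), collapse = ", "),
      paste(utils::head(only_gold, 10), collapse = ", "))
  }
  gold <- gold[names(pred)]
  if (any(is.na(gold))) {
    abort_validation("unlabeled record(s): %s",
                     paste(utils::head(names(pred)[is.na(gold)], 10),
                           collapse = ", "))
  }
  structure(list(
    TP = sum(pred == "relevant" & gold == "relevant"),
    FP = sum(pred == "relevant" & gold == "irrelevant"),
    TN = sum(pred == "irrelevant" & gold == "irrelevant"),
    FN = sum(pred == "irrelevant" & gold == "relevant")),
    class = "confusion_counts")
}

as_prediction_vector <- function(predictions) {
  if (is.data.frame(predictions)) {
    idcol <- if (!is.null(predictions$record_id)) "record_id" else "id"
    labcol <- if (!is.null(predictions$prediction)) "prediction" else "label"
    stats::setNames(normalize_labels(predictions[[labcol]]),
                    predictions[[idcol]])
  } else if (!is.null(names(predictions))) {
    normalize_labels_keep_names(predictions)
  } else {
    abort_validation("predictions must be a data frame or named vector")
  }
}

#' Performance measures from confusion counts
#'
#' Sensitivity (recall), specificity, accuracy, precision and F1, all on
#' the percentage scale. A measure with a zero denominator is reported as
#' `NA` and listed in `undefined` — never silently set to 0.
#'
#' @param counts a [confusion()] result (or list with `TP`, `FP`, `TN`,
#'   `FN`).
#' @return list of class `metric_set`.
#' @export
metrics <- function(counts) {
  TP <- counts$TP; FP <- counts$FP; TN <- counts$TN; FN <- counts$FN
  if (any(c(TP, FP, TN, FN) < 0)) abort_validation("negative counts")
  ratio <- function(num, den) if (den == 0) NA_real_ else 100 * num / den
  sens <- ratio(TP, TP + FN)
  spec <- ratio(TN, TN + FP)
  acc <- ratio(TP + TN, TP + FP + TN + FN)
  prec <- ratio(TP, TP + FP)
  f1 <- if (is.na(prec) || is.na(sens) || prec + sens == 0) NA_real_ else
    2 * prec * sens / (prec + sens)
  out <- list(sensitivity = sens, specificity = spec, accuracy = acc,
              precision = prec, f1 = f1)
  out$undefined <- names(out)[vapply(out[1:5], is.na, NA)]
  class(out) <- "metric_set"
  out
}

#' @export
print.metric_set <- function(x, digits = 2, ...) {
  for (nm in c("sensitivity", "specificity", "accuracy", "precision", "f1")) {
    v <- x[[nm]]
    cat(sprintf("%-12s %s\n", nm,
                if (is.na(v)) "undefined" else
                  sprintf("%.*f%%", digits, round_half_up(v, digits))))
  }
  invisible(x)
}

#' Threshold-swept ROC curve
#'
#' One (sensitivity, specificity) point per `k+` classifier, for `k` from
#' `scale_max + 1` (nothing included) down to 1 (everything included:
#' sensitivity 100% over valid-scored records). The area under the curve
#' is the trapezoid over (1 - specificity, sensitivity).
#'
#' @param scores a `scores_table` from [parse_scores()] (invalid rows are
#'   dropped) or a named integer vector of valid scores.
#' @param gold_labels labeled corpus or named label vector.
#' @param scale_max Likert scale maximum.
#' @return list of class `roc_curve`: `points` (data frame `k`,
#'   `sensitivity`, `specificity`), `auc`.
#' @export
roc_curve <- function(scores, gold_labels, scale_max = 5) {
  sc <- as_score_vector(scores)
  gold <- as_label_vector(gold_labels)
  gold <- gold[names(sc)]
  if (any(is.na(gold))) abort_validation("labels missing for scored record(s)")
  n_rel <- sum(gold == "relevant")
  n_irr <- sum(gold == "irrelevant")
  if (n_rel == 0L || n_irr == 0L) {
    abort_validation("ROC needs at least one relevant and one irrelevant valid-scored record (got %d / %d)",
                     n_rel, n_irr)
  }
  ks <- seq(scale_max + 1L, 1L)
  pts <- lapply(ks, function(k) {
    inc <- sc >= k
    data.frame(k = k,
               sensitivity = 100 * sum(inc & gold == "relevant") / n_rel,
               specificity = 100 * sum(!inc & gold == "irrelevant") / n_irr)
  })
  pts <- do.call(rbind, pts)
  x <- (100 - pts$specificity) / 100
  y <- pts$sensitivity / 100
  auc <- sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
  structure(list(points = pts, auc = auc, n_relevant = n_rel,
                 n_irrelevant = n_irr),
            class = "roc_curve")
}

as_score_vector <- function(scores) {
  if (is.data.frame(scores)) {
    ok <- scores$valid & !is.na(scores$score)
    stats::setNames(scores$score[ok], scores$record_id[ok])
  } else if (!is.null(names(scores))) {
    scores
  } else {
    abort_validation("scores must be a scores table or named vector")
  }
}

#' Plot a ROC curve
#'
#' @param x a [roc_curve()] object.
#' @param ... passed to [graphics::plot()].
#' @export
plot.roc_curve <- function(x, ...) {
  pts <- x$points
  graphics::plot(100 - pts$specificity, pts$sensitivity, type = "b",
                 xlim = c(0, 100), ylim = c(0, 100),
                 xlab = "100 - specificity (%)", ylab = "sensitivity (%)",
                 ...)
  graphics::abline(0, 1, lty = 2, col = "grey")
  graphics::text(100 - pts$specificity, pts$sensitivity,
                 labels = paste0(pts$k, "+"), pos = 4, cex = 0.8)
  invisible(x)
}

#' Evaluate a screening run
#'
#' Bundles, for one scores table and gold labeling: the confusion counts
#' and five measures of the `k+` classifier, the full ROC with AUC, the
#' invalid-response accounting, per-class mean scores and per-score-value
#' frequencies. Metrics are computed over valid-scored records only; the
#' report always carries `n_invalid` and `n_invalid_relevant` alongside so
#' the exclusion is never silent.
#'
#' @param scores a `scores_table` from [parse_scores()].
#' @param gold_labels labeled corpus or named label vector.
#' @param k classifier threshold.
#' @param scale_max Likert scale maximum.
#' @return list of class `screen_report`.
#' @export
evaluate_run <- function(scores, gold_labels, k = 3, scale_max = 5) {
  gold <- as_label_vector(gold_labels)
  sc <- as_score_vector(scores)
  preds <- stats::setNames(classify(sc, k, scale_max), names(sc))
  counts <- confusion(preds, gold[names(sc)])
  roc <- roc_curve(scores, gold_labels, scale_max)
  validity <- validity_report(scores, gold_labels)
  cls <- gold[names(sc)]
  freq <- table(factor(sc, levels = 1:scale_max), cls)
  structure(list(
    k = k, scale_max = scale_max,
    confusion = counts,
    metrics = metrics(counts),
    roc = roc,
    validity = validity,
    mean_score_relevant = mean(sc[cls == "relevant"]),
    mean_score_overall = mean(sc),
    score_frequencies = freq),
    class = "screen_report")
}

#' @export
print.screen_report <- function(x, ...) {
  cat(sprintf("%d+ classifier on a 1-%d scale\n", x$k, x$scale_max))
  cat(sprintf("valid responses: %d/%d (%s%%), invalid relevant: %s\n",
              x$validity$n_valid, x$validity$n_total,
              format(x$validity$valid_pct),
              format(x$validity$n_invalid_relevant)))
  print(x$metrics)
  cat(sprintf("AUC %.3f; mean score relevant %.2f vs overall %.2f\n",
              x$roc$auc, x$mean_score_relevant, x$mean_score_overall))
  invisible(x)
}
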