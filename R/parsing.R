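# Extraction of a Likert score from a backend answer. The answer usually
# is just a digit, but any text that can be unambiguously assigned to one
# in-range score is accepted; everything else is tagged invalid.

#' Parse one backend answer into a Likert score
#'
#' All positive integer tokens (at word boundaries, so digits embedded in
#' words are ignored) are extracted from the text. The answer is valid
#' when exactly one distinct in-range value occurs and no out-of-range
#' positive integer precedes it (an earlier stray number could plausibly
#' be the rating); otherwise it is invalid with reason `no_integer`,
#' `out_of_range` or `ambiguous`. A missing answer (`NA`) gives reason
#' `response_missing`. The phrase `"x out of y"` with `y` equal to
#' `scale_max` is accepted as score `x` when `allow_x_out_of_y` is `TRUE`
#' (default), since it is unambiguous to a human reader; slash forms like
#' `"3/5"` are still treated as ambiguous.
#'
#' Total and pure: every input maps to a `parsed_score`, none raises.
#'
#' @param raw_text one backend answer (or `NA` for a missing response).
#' @param scale_max Likert scale maximum.
#' @param allow_x_out_of_y accept the `"x out of scale_max"` phrasing.
#' @param record_id optional id carried through to the result.
#' @return list of class `parsed_score`: `record_id`, `raw_text`, `score`
#'   (integer or `NA`), `valid`, `invalid_reason` (`NA` when valid).
#' @export
parse_score <- function(raw_text, scale_max = 5, allow_x_out_of_y = TRUE,
                        record_id = NA_character_) {
  mk <- function(score, reason) {
    structure(list(record_id = record_id, raw_text = raw_text,
                   score = score, valid = is.na(reason),
                   invalid_reason = reason),
              class = "parsed_score")
  }
  if (length(raw_text) != 1L) abort_validation("raw_text must be length 1")
  if (is.na(raw_text)) return(mk(NA_integer_, "response_missing"))
  raw_text <- as.character(raw_text)

  if (allow_x_out_of_y) {
    m <- regmatches(raw_text,
                    regexec("(?<![[:alnum:]])([0-9]+)[[:space:]]+out[[:space:]]+of[[:space:]]+([0-9]+)(?![[:alnum:]])",
                            raw_text, perl = TRUE, ignore.case = TRUE))[[1]]
    if (length(m) == 3L) {
      x <- suppressWarnings(as.integer(m[2]))
      y <- suppressWarnings(as.integer(m[3]))
      if (!is.na(x) && !is.na(y) && y >= 2L) {
        if (y == scale_max && x >= 1L && x <= scale_max) {
          return(mk(x, NA_character_))
        }
        # the phrase names a different scale; no unambiguous assignment
        return(mk(NA_integer_, "ambiguous"))
      }
    }
  }

  m <- gregexpr("(?<![[:alnum:]])[0-9]+(?![[:alnum:]])", raw_text,
                perl = TRUE)[[1]]
  toks <- if (m[1] < 0) character() else regmatches(raw_text, list(m))[[1]]
  vals <- suppressWarnings(as.integer(toks))
  keep <- !is.na(vals) & vals > 0L
  vals <- vals[keep]
  pos <- as.integer(m)[keep]
  if (length(vals) == 0L) return(mk(NA_integer_, "no_integer"))

  in_range <- vals >= 1L & vals <= scale_max
  distinct_in <- unique(vals[in_range])
  if (length(distinct_in) == 0L) return(mk(NA_integer_, "out_of_range"))
  if (length(distinct_in) > 1L) return(mk(NA_integer_, "ambiguous"))
  first_in <- min(pos[in_range])
  if (any(!in_range & pos < first_in)) return(mk(NA_integer_, "ambiguous"))
  mk(distinct_in, NA_character_)
}

#' Parse a whole response table
#'
#' Applies [parse_score()] to every response; rows flagged
#' `response_missing` by [screen_corpus()] stay invalid with that reason.
#'
#' @param responses a `response_table` (or data frame with `record_id`,
#'   `raw_text`).
#' @param scale_max Likert scale maximum.
#' @param allow_x_out_of_y see [parse_score()].
#' @return data frame (class `scores_table`): `record_id`, `raw_text`,
#'   `score`, `valid`, `invalid_reason`.
#' @export
parse_scores <- function(responses, scale_max = 5, allow_x_out_of_y = TRUE) {
  parsed <- lapply(seq_len(nrow(responses)), function(i) {
    parse_score(responses$raw_text[i], scale_max,
                allow_x_out_of_y = allow_x_out_of_y,
                record_id = responses$record_id[i])
  })
  out <- data.frame(
    record_id = vapply(parsed, `[[`, "", "record_id"),
    raw_text = vapply(parsed, function(p) as.character(p$raw_text),
                      NA_character_),
    score = vapply(parsed, `[[`, NA_integer_, "score"),
    valid = vapply(parsed, `[[`, NA, "valid"),
    invalid_reason = vapply(parsed, `[[`, NA_character_, "invalid_reason"),
    stringsAsFactors = FALSE)
  class(out) <- c("scores_table", "data.frame")
  out
}

#' Invalid-response accounting
#'
#' Reports how many answers could be assigned a score and, when gold
#' labels are supplied, how many of the invalid-response publications
#' would have been relevant (invalid answers are excluded from metric
#' computation downstream, so this quantifies what that exclusion hides).
#'
#' `valid_pct` follows the printed-precision convention for
#' near-complete validity: `100 - signif(invalid_pct, 1)` (e.g. 3 invalid
#' out of 44,055 prints 99.993; 29 invalid prints 99.93); the unrounded
#' value is returned as `valid_pct_raw`.
#'
#' @param parsed a `scores_table` from [parse_scores()].
#' @param labels optional labeled corpus (`screening_records` with
#'   labels) or named character vector of labels keyed by record id.
#' @return list: `n_total`, `n_valid`, `n_invalid`, `valid_pct`,
#'   `valid_pct_raw`, `invalid_reasons` (table), and
#'   `n_invalid_relevant` when labels are supplied.
#' @export
validity_report <- function(parsed, labels = NULL) {
  if (nrow(parsed) == 0L) abort_validation("empty scores table")
  n_total <- nrow(parsed)
  n_valid <- sum(parsed$valid)
  n_invalid <- n_total - n_valid
  invalid_pct <- 100 * n_invalid / n_total
  valid_pct <- if (n_invalid == 0L) 100 else 100 - signif(invalid_pct, 1)
  out <- list(n_total = n_total, n_valid = n_valid, n_invalid = n_invalid,
              valid_pct = valid_pct,
              valid_pct_raw = 100 * n_valid / n_total,
              invalid_reasons = table(parsed$invalid_reason[!parsed$valid]))
  if (!is.null(labels)) {
    lab <- as_label_vector(labels)
    inv_ids <- parsed$record_id[!parsed$valid]
    out$n_invalid_relevant <- sum(lab[inv_ids] == "relevant", na.rm = TRUE)
  } else {
    out$n_invalid_relevant <- NA_integer_
  }
  out
}

# Coerce a labeled corpus or named vector to a named label vector.
as_label_vector <- function(labels) {
  if (is.data.frame(labels)) {
    if (is.null(labels$label)) abort_validation("corpus has no label column")
    stats::setNames(labels$label, labels$id)
  } else if (!is.null(names(labels))) {
    normalize_labels_keep_names(labels)
  } else {
    abort_validation("labels must be a labeled corpus or a named vector")
  }
}

normalize_labels_keep_names <- function(x) {
  stats::setNames(normalize_labels(x), names(x))
}
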