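# Synthetic labeled citation corpora with controllable prevalence and a
# plantable lexical signal: criteria keywords appear in relevant abstracts
# with probability q_rel and in irrelevant ones with probability q_irr, so
# the mock backend's overlap score separates the classes by a known,
# analytically predictable margin.

#' Specification of a synthetic screening corpus
#'
#' The defaults emulate a mid-sized biomedical screening dataset: 1000
#' records at 5% prevalence (published screening corpora range from under
#' 0.2% to about 11% relevant), with a strong but imperfect lexical
#' signal (`q_rel` = 0.9, `q_irr` = 0.1).
#'
#' @param n corpus size (>= 2).
#' @param prevalence fraction of relevant records in (0, 1); the corpus
#'   contains exactly `round(n * prevalence)` relevant records (>= 1).
#' @param q_rel probability a criteria keyword appears in a relevant
#'   abstract.
#' @param q_irr same for irrelevant abstracts; `0 <= q_irr <= q_rel <= 1`.
#' @param vocab_size background vocabulary size.
#' @param seed integer RNG seed; corpora are byte-identical per seed.
#' @param abstract_len number of background tokens per abstract.
#' @param title_len number of background tokens per title.
#' @param title_signal titles carry the keyword signal at this fraction of
#'   the abstract strength (keyword planted in the title with probability
#'   `title_signal * q`).
#' @return list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n = 1000, prevalence = 0.05, q_rel = 0.9,
                           q_irr = 0.1, vocab_size = 500, seed = 1,
                           abstract_len = 30, title_len = 8,
                           title_signal = 0.5) {
  if (n < 2) abort_validation("n must be >= 2")
  if (prevalence <= 0 || prevalence >= 1) {
    abort_validation("prevalence must be in (0, 1)")
  }
  if (round(n * prevalence) < 1) {
    abort_validation("round(n * prevalence) must be >= 1")
  }
  if (!(q_irr >= 0 && q_irr <= q_rel && q_rel <= 1)) {
    abort_validation("need 0 <= q_irr <= q_rel <= 1")
  }
  if (title_signal < 0 || title_signal > 1) {
    abort_validation("title_signal must be in [0, 1]")
  }
  structure(list(n = as.integer(n), prevalence = prevalence, q_rel = q_rel,
                 q_irr = q_irr, vocab_size = as.integer(vocab_size),
                 seed = as.integer(seed),
                 abstract_len = as.integer(abstract_len),
                 title_len = as.integer(title_len),
                 title_signal = title_signal),
            class = "synthetic_spec")
}

# Deterministic pseudo-word background vocabulary: the first `size` words
# of the fixed consonant-vowel syllable product, three syllables each.
# Pseudo-words cannot collide with real criteria keywords or stopwords.
make_background_vocab <- function(size, exclude = character()) {
  cons <- c("b", "d", "f", "g", "k", "l", "m", "n", "p", "r", "s", "t", "v", "z")
  vows <- c("a", "e", "i", "o", "u")
  syll <- as.vector(outer(cons, vows, paste0))  # 70 syllables, fixed order
  ns <- length(syll)
  need <- size + length(exclude)
  idx <- seq_len(need) - 1L
  words <- paste0(syll[(idx %/% (ns * ns)) %% ns + 1L],
                  syll[(idx %/% ns) %% ns + 1L],
                  syll[idx %% ns + 1L])
  words <- setdiff(words, exclude)
  utils::head(words, size)
}

#' Generate a labeled synthetic corpus
#'
#' Each abstract is `abstract_len` background pseudo-word tokens plus each
#' distinct content word of `criteria_text` included independently with
#' probability `q_rel` (relevant records) or `q_irr` (irrelevant
#' records); titles carry the same signal at `title_signal` strength.
#' Exactly `round(n * prevalence)` records are labeled relevant, at
#' shuffled positions. Deterministic per `spec$seed`.
#'
#' @param spec a [synthetic_spec()].
#' @param criteria_text criteria string; must yield at least 3 content
#'   words, which become the planted keywords.
#' @param stopwords stopword list defining content words.
#' @return labeled `screening_records` with attribute `"keywords"`.
#' @export
generate_corpus <- function(spec, criteria_text,
                            stopwords = default_stopwords()) {
  stopifnot(inherits(spec, "synthetic_spec"))
  keywords <- content_words(criteria_text, stopwords)
  if (length(keywords) < 3L) {
    abort_validation("criteria_text must yield >= 3 content words (got %d)",
                     length(keywords))
  }
  n <- spec$n
  m <- length(keywords)
  vocab <- make_background_vocab(spec$vocab_size, exclude = keywords)
  with_seed(spec$seed, {
    n_rel <- as.integer(round(n * spec$prevalence))
    label <- rep("irrelevant", n)
    label[sample.int(n, n_rel)] <- "relevant"
    q <- ifelse(label == "relevant", spec$q_rel, spec$q_irr)

    # matrices are column-major, so comparing against q recycles it down
    # each column, i.e. per record as required
    inc_abs <- matrix(stats::runif(n * m), nrow = n) < q
    inc_tit <- matrix(stats::runif(n * m), nrow = n) < (q * spec$title_signal)

    mk_text <- function(i, len, inc) {
      toks <- c(vocab[sample.int(length(vocab), len, replace = TRUE)],
                keywords[inc[i, ]])
      paste(sample(toks), collapse = " ")
    }
    abstract <- vapply(seq_len(n), function(i)
      mk_text(i, spec$abstract_len, inc_abs), "")
    title <- vapply(seq_len(n), function(i)
      mk_text(i, spec$title_len, inc_tit), "")

    recs <- screening_records(sprintf("rec%05d", seq_len(n)),
                              title, abstract, label)
    attr(recs, "keywords") <- keywords
    recs
  })
}

#' Expected mock-backend metrics, in closed form
#'
#' Under the mock rule the score of a record is `1 + min(scale_max - 1,
#' S)` where `S` counts the planted keywords present in title or
#' abstract; with the generator's independent inclusions, `S` is
#' binomial with `m` trials and per-keyword presence probability
#' `1 - (1 - q) * (1 - title_signal * q)`. This gives closed-form
#' expected sensitivity and specificity of the `k+` classifier, and —
#' combined with the exact class prevalence — expected accuracy,
#' precision and F1. Serves as the analytic oracle for the end-to-end
#' pipeline test.
#'
#' @param spec a [synthetic_spec()].
#' @param criteria_text criteria string (defines `m` via its content
#'   words).
#' @param scale_max Likert scale maximum of the mock backend.
#' @param k classifier threshold.
#' @param stopwords stopword list defining content words.
#' @return list of class `metric_set` with expected percentages.
#' @export
expected_mock_metrics <- function(spec, criteria_text, scale_max = 5, k = 3,
                                  stopwords = default_stopwords()) {
  stopifnot(inherits(spec, "synthetic_spec"))
  m <- length(content_words(criteria_text, stopwords))
  p_eff <- function(q) 1 - (1 - q) * (1 - spec$title_signal * q)
  # P(score >= k) = P(S >= k - 1); the cap at scale_max - 1 cannot push a
  # score across any threshold k <= scale_max.
  p_ge <- function(q) {
    if (k > scale_max) return(0)
    if (k <= 1) return(1)
    stats::pbinom(k - 2, m, p_eff(q), lower.tail = FALSE)
  }
  sens <- p_ge(spec$q_rel)
  fpr <- p_ge(spec$q_irr)
  prev <- round(spec$n * spec$prevalence) / spec$n
  acc <- prev * sens + (1 - prev) * (1 - fpr)
  pos <- prev * sens + (1 - prev) * fpr
  prec <- if (pos == 0) NA_real_ else prev * sens / pos
  f1 <- if (is.na(prec) || prec + sens == 0) NA_real_ else
    2 * prec * sens / (prec + sens)
  out <- list(sensitivity = 100 * sens, specificity = 100 * (1 - fpr),
              accuracy = 100 * acc, precision = 100 * prec, f1 = 100 * f1)
  out$undefined <- names(out)[vapply(out[1:5], is.na, NA)]
  class(out) <- "metric_set"
  out
}
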