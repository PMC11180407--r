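# Keyword-driven unsupervised baseline screener: derive keywords from the
# search query, then screen by clustering documents and flagging the
# keyword-associated clusters.

#' Derive screening keywords from a search query
#'
#' Splits the query into individual words and removes stop words,
#' duplicates and punctuation; Boolean operators (AND, OR, NOT) are always
#' stripped, even if absent from the stopword list. Tokens are case-folded
#' and returned in order of first occurrence.
#'
#' @param query_text the search query, e.g. a PubMed query string.
#' @param stopwords stopword list (default: the bundled list).
#' @return list of class `keyword_set` with `keywords` and `source_query`.
#' @export
derive_keywords <- function(query_text, stopwords = default_stopwords()) {
  if (!is.character(query_text) || length(query_text) != 1L ||
      !nzchar(trimws(query_text))) {
    abort_validation("query_text must be a non-empty string")
  }
  toks <- tokenize_words(query_text)
  toks <- toks[!toks %in% c("and", "or", "not")]
  toks <- toks[!toks %in% stopwords]
  toks <- unique(toks)
  if (length(toks) == 0L) {
    abort_validation("empty keyword set: nothing left after removing stop words and operators")
  }
  structure(list(keywords = toks, source_query = query_text),
            class = "keyword_set")
}

#' Unsupervised keyword baseline screener
#'
#' A simple topic-model stand-in for keyword-driven screening: documents
#' (title + abstract) are embedded as TF-IDF vectors and grouped into
#' `n_topics` clusters with k-means; a cluster counts as
#' keyword-associated when at least a fraction `min_overlap` of its
#' `n_top_terms` highest-weight terms are keywords. A record is predicted
#' relevant iff its cluster is keyword-associated. Deterministic for a
#' fixed seed.
#'
#' @param records a `screening_records` corpus (at least 2 records and at
#'   least `n_topics`).
#' @param keywords a [derive_keywords()] result (or character vector).
#' @param n_topics number of clusters/topics (default 2:
#'   on-topic vs off-topic).
#' @param seed integer RNG seed for the clustering.
#' @param n_top_terms number of top terms characterising a topic.
#' @param min_overlap minimal keyword fraction among the top terms for a
#'   topic to count as keyword-associated.
#' @param stopwords stopword list used when tokenising documents.
#' @return data frame: `record_id`, `prediction`
#'   (`"relevant"`/`"irrelevant"`).
#' @export
baseline_screen <- function(records, keywords, n_topics = 2, seed = 1,
                            n_top_terms = 10, min_overlap = 0.1,
                            stopwords = default_stopwords()) {
  records <- validate_records(as.data.frame(records))
  kws <- if (inherits(keywords, "keyword_set")) keywords$keywords else
    as.character(keywords)
  if (length(kws) == 0L) abort_validation("empty keyword set")
  if (nrow(records) < 2L) abort_validation("need at least 2 records")
  if (nrow(records) < n_topics) {
    abort_validation("corpus (%d records) smaller than n_topics = %d",
                     nrow(records), n_topics)
  }
  docs <- paste(records$title, records$abstract)
  tok <- lapply(docs, function(d) {
    t <- tokenize_words(d)
    t[!t %in% stopwords]
  })
  vocab <- sort(unique(unlist(tok)))
  if (length(vocab) == 0L) abort_validation("no content tokens in corpus")
  n <- length(tok)
  dtm <- matrix(0, nrow = n, ncol = length(vocab),
                dimnames = list(records$id, vocab))
  for (i in seq_len(n)) {
    cnt <- table(tok[[i]])
    dtm[i, names(cnt)] <- as.numeric(cnt)
  }
  tf <- dtm / pmax(rowSums(dtm), 1)
  df <- colSums(dtm > 0)
  idf <- log((1 + n) / (1 + df)) + 1
  tfidf <- sweep(tf, 2, idf, `*`)

  km <- with_seed(seed, stats::kmeans(tfidf, centers = n_topics,
                                      nstart = 5, iter.max = 50))
  associated <- vapply(seq_len(n_topics), function(j) {
    w <- km$centers[j, ]
    top <- names(sort(w[w > 0], decreasing = TRUE))
    top <- utils::head(top, n_top_terms)
    if (length(top) == 0L) return(FALSE)
    length(intersect(top, kws)) / length(top) >= min_overlap
  }, NA)
  data.frame(record_id = records$id,
             prediction = ifelse(associated[km$cluster],
                                 "relevant", "irrelevant"),
             stringsAsFactors = FALSE)
}
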