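# Fixtures and fake backends, all built in code at test time.

# A labeled corpus with arbitrary text, n_rel relevant records.
mk_labeled_corpus <- function(n, n_rel, seed = 1) {
  withr::with_seed(seed, {
    label <- rep("irrelevant", n)
    label[sample.int(n, n_rel)] <- "relevant"
    screening_records(
      id = sprintf("id%04d", seq_len(n)),
      title = replicate(n, paste(sample(letters, 6), collapse = "")),
      abstract = replicate(n, paste(sample(letters, 12), collapse = " ")),
      label = label)
  })
}

# Three-entry RIS fixture; the frozen expectations in test-corpus_io.R
# come from parsing these lines by hand.
ris_fixture_lines <- c(
  "TY  - JOUR",
  "ID  - r1",
  "TI  - Deep learning for dose prediction",
  "AB  - We present a model",
  "      for dose prediction.",
  "ER  - ",
  "TY  - JOUR",
  "AN  - a2",
  "TI  - Survey of decision support",
  "ER  - ",
  "TY  - JOUR",
  "TI  - Third entry title",
  "AB  - Abstract three.",
  "ER  - ")

write_ris_fixture <- function(path = withr::local_tempfile(fileext = ".ris",
                                                           .local_envir = parent.frame())) {
  writeLines(ris_fixture_lines, path)
  path
}

# Backend that answers a fixed text and counts how often it is queried.
make_counting_backend <- function(answer = "3") {
  env <- new.env()
  env$calls <- character()
  structure(list(id = "counting", answer = answer, env = env),
            class = c("counting_backend", "screen_backend"))
}

complete.counting_backend <- function(backend, prompt, settings = NULL) {
  backend$env$calls <- c(backend$env$calls, prompt$record_id)
  structure(list(raw_text = backend$answer, backend_id = backend$id),
            class = "backend_response")
}

# Backend that always fails for the given record ids.
make_flaky_backend <- function(fail_ids, answer = "4") {
  structure(list(id = "flaky", fail_ids = fail_ids, answer = answer),
            class = c("flaky_backend", "screen_backend"))
}

complete.flaky_backend <- function(backend, prompt, settings = NULL) {
  if (prompt$record_id %in% backend$fail_ids) {
    tiabscreen:::abort_backend("simulated outage for %s", prompt$record_id)
  }
  structure(list(raw_text = backend$answer, backend_id = backend$id),
            class = "backend_response")
}

registerS3method("complete", "counting_backend", complete.counting_backend,
                 envir = asNamespace("tiabscreen"))
registerS3method("complete", "flaky_backend", complete.flaky_backend,
                 envir = asNamespace("tiabscreen"))

# Criteria strings used across tests; content words are the planted
# keywords of the synthetic corpora.
crit5 <- "randomized radiotherapy dosimetry outcomes toxicity"
crit8 <- paste("Publications about clinical decision support systems",
               "in radiotherapy and radiation oncology")

# Brute-force confusion oracle: per-record counting loop, independent of
# the vectorised implementation.
brute_confusion <- function(pred, gold) {
  tp <- fp <- tn <- fn <- 0L
  for (id in names(pred)) {
    p <- pred[[id]]; g <- gold[[id]]
    if (p == "relevant" && g == "relevant") tp <- tp + 1L
    if (p == "relevant" && g == "irrelevant") fp <- fp + 1L
    if (p == "irrelevant" && g == "irrelevant") tn <- tn + 1L
    if (p == "irrelevant" && g == "relevant") fn <- fn + 1L
  }
  list(TP = tp, FP = fp, TN = tn, FN = fn)
}
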