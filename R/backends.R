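# Text-generation backend contract plus a deterministic mock backend so
# the whole screening pipeline runs offline.

#' Generation settings for a screening run
#'
#' Reproducible screening requires deterministic generation: with
#' `reproducible = TRUE` (the default) a temperature above 0 is rejected,
#' since positive temperatures add a random element to the output.
#'
#' @param temperature non-negative sampling temperature.
#' @param max_new_tokens positive integer generation budget.
#' @param seed optional integer seed forwarded to backends that accept one.
#' @param reproducible flag marking the run as reproducible.
#' @return object of class `generation_settings`.
#' @export
generation_settings <- function(temperature = 0, max_new_tokens = 64,
                                seed = NULL, reproducible = TRUE) {
  if (temperature < 0) abort_validation("temperature must be >= 0")
  if (reproducible && temperature > 0) {
    abort_validation(
      "temperature %.2f > 0 is incompatible with a reproducible run",
      temperature)
  }
  if (max_new_tokens < 1) abort_validation("max_new_tokens must be >= 1")
  structure(list(temperature = temperature,
                 max_new_tokens = as.integer(max_new_tokens),
                 seed = seed, reproducible = reproducible),
            class = "generation_settings")
}

#' Deterministic mock backend
#'
#' Scores a prompt by lexical overlap: the answer is
#' `1 + min(scale_max - 1, s)` where `s` is the number of distinct
#' case-folded content words (non-stopword tokens) shared between the
#' criteria text and the title plus abstract, all recovered from the
#' prompt text itself via [split_prompt()]. The score is therefore a pure
#' function of (prompt text, scale_max), which makes every downstream
#' stage testable without a language model.
#'
#' @param scale_max Likert scale maximum the mock answers on.
#' @param criteria_prefix prefix used to locate the criteria block.
#' @param template `sprintf` template turning the integer score into the
#'   raw answer text (default: the bare digit).
#' @param stopwords stopword list defining content words.
#' @return backend object usable with [complete()] and [screen_corpus()].
#' @export
backend_mock <- function(scale_max = 5,
                         criteria_prefix = ", Relevant criteria:",
                         template = "%d",
                         stopwords = default_stopwords()) {
  structure(list(id = "mock", scale_max = as.integer(scale_max),
                 criteria_prefix = criteria_prefix,
                 template = template, stopwords = stopwords),
            class = c("mock_backend", "screen_backend"))
}

#' Backend running an external command
#'
#' Writes the prompt to the command's standard input and takes its
#' standard output, verbatim, as the answer. This is the generic adapter
#' for locally hosted models exposed as executables.
#'
#' @param command executable to run.
#' @param args character vector of arguments.
#' @return backend object.
#' @export
backend_command <- function(command, args = character()) {
  structure(list(id = paste0("command:", command),
                 command = command, args = args),
            class = c("command_backend", "screen_backend"))
}

#' Backend calling an HTTP completion endpoint
#'
#' Posts `{"prompt": ..., "temperature": ..., "max_new_tokens": ...}` as
#' JSON to `url` through the system `curl` binary and extracts the answer
#' at `response_field` of the JSON reply.
#'
#' @param url endpoint URL.
#' @param response_field name of the reply field holding the answer text.
#' @param headers named character vector of extra HTTP headers.
#' @return backend object.
#' @export
backend_http <- function(url, response_field = "text",
                         headers = character()) {
  structure(list(id = paste0("http:", url), url = url,
                 response_field = response_field, headers = headers),
            class = c("http_backend", "screen_backend"))
}

#' Request a completion from a backend
#'
#' @param backend a `screen_backend` object.
#' @param prompt a [build_prompt()] result.
#' @param settings a [generation_settings()] object.
#' @return list of class `backend_response` with `raw_text` (verbatim,
#'   never pre-trimmed) and `backend_id`.
#' @export
complete <- function(backend, prompt, settings = generation_settings()) {
  UseMethod("complete")
}

mock_rule_score <- function(backend, prompt_text) {
  parts <- split_prompt(prompt_text, backend$criteria_prefix)
  shared <- intersect(content_words(parts$criteria, backend$stopwords),
                      content_words(paste(parts$title, parts$abstract),
                                    backend$stopwords))
  1L + min(backend$scale_max - 1L, length(shared))
}

#' @export
complete.mock_backend <- function(backend, prompt,
                                  settings = generation_settings()) {
  score <- mock_rule_score(backend, prompt$text)
  structure(list(raw_text = sprintf(backend$template, score),
                 backend_id = backend$id),
            class = "backend_response")
}

#' @export
complete.command_backend <- function(backend, prompt,
                                     settings = generation_settings()) {
  tmp <- tempfile("prompt_")
  on.exit(unlink(tmp))
  writeLines(prompt$text, tmp)
  out <- tryCatch(
    suppressWarnings(system2(backend$command, backend$args,
                             stdout = TRUE, stdin = tmp)),
    error = function(e) abort_backend("command backend failed: %s",
                                      conditionMessage(e)))
  status <- attr(out, "status")
  if (!is.null(status) && status != 0) {
    abort_backend("command backend exited with status %d", status)
  }
  structure(list(raw_text = paste(out, collapse = "\n"),
                 backend_id = backend$id),
            class = "backend_response")
}

#' @export
complete.http_backend <- function(backend, prompt,
                                  settings = generation_settings()) {
  body <- jsonlite::toJSON(list(prompt = prompt$text,
                                temperature = settings$temperature,
                                max_new_tokens = settings$max_new_tokens),
                           auto_unbox = TRUE)
  hdr <- c("-H", "Content-Type: application/json")
  for (nm in names(backend$headers)) {
    hdr <- c(hdr, "-H", paste0(nm, ": ", backend$headers[[nm]]))
  }
  out <- tryCatch(
    suppressWarnings(system2("curl", c("-s", "-S", "--fail-with-body", hdr,
                                       "-d", shQuote(body), backend$url),
                             stdout = TRUE, stderr = TRUE)),
    error = function(e) abort_backend("http backend failed: %s",
                                      conditionMessage(e)))
  status <- attr(out, "status")
  if (!is.null(status) && status != 0) {
    abort_backend("http backend request failed: %s",
                  paste(out, collapse = " "))
  }
  reply <- tryCatch(jsonlite::fromJSON(paste(out, collapse = "")),
                    error = function(e) abort_backend(
                      "http backend returned non-JSON reply"))
  txt <- reply[[backend$response_field]]
  if (is.null(txt)) {
    abort_backend("http reply lacks field '%s'", backend$response_field)
  }
  structure(list(raw_text = as.character(txt), backend_id = backend$id),
            class = "backend_response")
}

#' Build a backend from a configuration block
#'
#' @param block list as read from the `backend` block of a screening
#'   config (see [read_screen_config()]).
#' @param config the run's [prompt_config()]; supplies scale and criteria
#'   prefix to the mock backend.
#' @return a `screen_backend` object.
#' @export
backend_from_config <- function(block, config) {
  type <- block$type %||% "mock"
  switch(type,
    mock = backend_mock(scale_max = config$scale_max,
                        criteria_prefix = config$criteria_prefix),
    command = backend_command(block$command,
                              as.character(block$args %||% character())),
    http = backend_http(block$url,
                        response_field = block$response_field %||% "text"),
    abort_validation("unknown backend type '%s'", type))
}

#' Screen a corpus through a backend
#'
#' Builds one prompt per record, requests one completion per record
#' (retrying transient backend failures), and returns the raw responses
#' keyed by record id. Records still failing after `retries` attempts are
#' marked `response_missing` — distinct from an invalid parse — and the
#' run continues. With a `checkpoint` path, completed responses are
#' persisted periodically and a re-run resumes without re-querying them.
#'
#' @param records a `screening_records` corpus.
#' @param config a [prompt_config()].
#' @param backend a `screen_backend`.
#' @param settings a [generation_settings()].
#' @param checkpoint optional CSV path for resumable partial results.
#' @param retries attempts per record before giving up.
#' @param backoff base pause in seconds, doubled per retry.
#' @param audit optional JSON-lines path logging
#'   (record_id, prompt, raw_text) for reproducibility review.
#' @param checkpoint_every flush the checkpoint after this many new
#'   responses.
#' @return data frame (class `response_table`): `record_id`, `raw_text`,
#'   `backend_id`, `response_missing`.
#' @export
screen_corpus <- function(records, config, backend,
                          settings = generation_settings(),
                          checkpoint = NULL, retries = 3, backoff = 0.1,
                          audit = NULL, checkpoint_every = 100L) {
  records <- validate_records(as.data.frame(records))
  done <- NULL
  if (!is.null(checkpoint) && file.exists(checkpoint)) {
    done <- utils::read.csv(checkpoint, colClasses = "character")
    done$response_missing <- done$response_missing == "TRUE"
    done <- done[done$record_id %in% records$id, , drop = FALSE]
  }
  todo <- if (is.null(done)) records else
    records[!records$id %in% done$record_id, , drop = FALSE]

  rows <- vector("list", nrow(todo))
  n_new <- 0L
  flush_checkpoint <- function() {
    if (is.null(checkpoint)) return(invisible())
    part <- rbind(done, do.call(rbind, rows[seq_len(n_new)]))
    utils::write.csv(part, checkpoint, row.names = FALSE)
  }
  for (i in seq_len(nrow(todo))) {
    rec <- todo[i, ]
    prompt <- build_prompt(config, rec)
    resp <- NULL
    for (attempt in seq_len(retries)) {
      resp <- tryCatch(complete(backend, prompt, settings),
                       tiab_backend_error = function(e) e)
      if (!inherits(resp, "error")) break
      if (attempt < retries) Sys.sleep(backoff * 2^(attempt - 1L))
    }
    missing <- inherits(resp, "error")
    rows[[i]] <- data.frame(
      record_id = rec$id,
      raw_text = if (missing) NA_character_ else resp$raw_text,
      backend_id = if (missing) backend$id else resp$backend_id,
      response_missing = missing,
      stringsAsFactors = FALSE)
    n_new <- i
    if (!is.null(audit) && !missing) {
      cat(jsonlite::toJSON(list(record_id = rec$id, prompt = prompt$text,
                                raw_text = resp$raw_text),
                           auto_unbox = TRUE),
          "\n", sep = "", file = audit, append = TRUE)
    }
    if (!is.null(checkpoint) && (i %% checkpoint_every == 0L)) {
      flush_checkpoint()
    }
  }
  out <- rbind(done, do.call(rbind, rows))
  if (is.null(out)) out <- data.frame(record_id = character(),
                                      raw_text = character(),
                                      backend_id = character(),
                                      response_missing = logical())
  # restore corpus order
  out <- out[match(records$id, out$record_id), , drop = FALSE]
  rownames(out) <- NULL
  if (!is.null(checkpoint)) {
    utils::write.csv(out, checkpoint, row.names = FALSE)
  }
  class(out) <- c("response_table", "data.frame")
  out
}
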