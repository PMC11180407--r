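# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Round half away from zero
#'
#' Rounds to `digits` decimal places with ties going away from zero
#' (the "round half up" convention used for all printed percentages in
#' this package), unlike [base::round()] which rounds half to even.
#'
#' @param x numeric vector.
#' @param digits integer number of decimal places.
#' @return numeric vector of the same length as `x`.
#' @examples
#' round_half_up(87.865, 2)  # 87.87
#' round_half_up(0.745, 2)   # 0.75
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Lower-cased word tokens; splits on any non-alphanumeric run.
tokenize_words <- function(text) {
  toks <- unlist(strsplit(tolower(text), "[^[:alnum:]]+"))
  toks[nzchar(toks)]
}

# Distinct non-stopword tokens of a text, order of first occurrence.
content_words <- function(text, stopwords = default_stopwords()) {
  toks <- unique(tokenize_words(text))
  setdiff(toks, stopwords)
}

.tiab_env <- new.env(parent = emptyenv())

#' Bundled English stopword list
#'
#' The fixed stopword list shipped with the package, used by the mock
#' backend's shared-content-word rule and by [derive_keywords()]. Bundling
#' the list (rather than depending on an external resource) freezes the
#' preprocessing so results are reproducible across installations.
#'
#' @return character vector of lower-case stopwords.
#' @export
default_stopwords <- function() {
  if (is.null(.tiab_env$stopwords)) {
    path <- system.file("extdata", "stopwords_en.txt", package = "tiabscreen")
    .tiab_env$stopwords <- readLines(path, encoding = "UTF-8", warn = FALSE)
  }
  .tiab_env$stopwords
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Error conditions carrying the package's exit-code semantics:
# validation errors exit 2, backend errors exit 3 at the CLI.
abort_validation <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("tiab_validation_error", "tiab_error")))
}

abort_backend <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("tiab_backend_error", "tiab_error")))
}
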