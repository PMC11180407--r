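# Prompt assembly: instruction + title block + abstract block + criteria
# block, merged in that fixed order for every record.

.standard_instruction <- paste0(
  "On a scale from 1 (very low probability) to %d (very high probability), ",
  "how would you rate the relevance of the following scientific publication ",
  "to be included in a systematic literature review based on the relevant ",
  "criteria and based on title and abstract?")

.adapted_note <- paste0(
  "(Note: Give a low score if not all criteria are fulfilled. ",
  "Give only a high score if all or almost all criteria are fulfilled.)")

#' Instantiate the instruction string
#'
#' Returns the standard relevance-rating instruction with the Likert scale
#' maximum substituted in. The `adapted` variant appends a note telling the
#' model to give high scores only when all or almost all criteria are met.
#'
#' @param variant `"standard"` or `"adapted"`.
#' @param scale_max integer Likert scale maximum, at least 2.
#' @return the instruction string.
#' @export
instantiate_instruction <- function(variant = c("standard", "adapted"),
                                    scale_max = 5) {
  variant <- match.arg(variant)
  if (!is.numeric(scale_max) || length(scale_max) != 1L ||
      scale_max != as.integer(scale_max) || scale_max < 2) {
    abort_validation("scale_max must be a single integer >= 2 (got %s)",
                     paste(scale_max, collapse = ","))
  }
  text <- sprintf(.standard_instruction, as.integer(scale_max))
  if (variant == "adapted") text <- paste(text, .adapted_note)
  text
}

#' Screening prompt configuration
#'
#' Bundles everything that determines the prompt for a record: the
#' instruction variant, the Likert scale maximum and the relevant-criteria
#' text. The criteria text stays identical across all records of a run;
#' only title and abstract vary.
#'
#' @param criteria_text free-text inclusion/exclusion criteria appended to
#'   every prompt.
#' @param instruction_variant `"standard"` or `"adapted"`.
#' @param scale_max integer Likert scale maximum (default 5).
#' @param criteria_prefix string introducing the criteria block.
#' @return an object of class `prompt_config`.
#' @export
prompt_config <- function(criteria_text,
                          instruction_variant = c("standard", "adapted"),
                          scale_max = 5,
                          criteria_prefix = ", Relevant criteria:") {
  instruction_variant <- match.arg(instruction_variant)
  if (!is.character(criteria_text) || length(criteria_text) != 1L ||
      !nzchar(trimws(criteria_text))) {
    abort_validation("criteria_text must be a non-empty string")
  }
  instruction <- instantiate_instruction(instruction_variant, scale_max)
  structure(list(instruction_variant = instruction_variant,
                 scale_max = as.integer(scale_max),
                 criteria_text = criteria_text,
                 criteria_prefix = criteria_prefix,
                 instruction = instruction),
            class = "prompt_config")
}

#' Build the screening prompt for one record
#'
#' Concatenates, in order: the instruction, `"Title:"` plus the title,
#' `", Abstract:"` plus the abstract, and the criteria block. Title and
#' abstract are embedded verbatim — no truncation, no re-casing — so the
#' prompt is a pure function of (config, record).
#'
#' @param config a [prompt_config()].
#' @param record a single record: list or one-row data frame with `id`,
#'   `title`, `abstract`.
#' @return list of class `screen_prompt` with `text` and `record_id`.
#' @export
build_prompt <- function(config, record) {
  stopifnot(inherits(config, "prompt_config"))
  abstract <- record$abstract %||% ""
  if (is.na(abstract)) abstract <- ""
  text <- paste0(config$instruction,
                 " Title:", record$title,
                 ", Abstract:", abstract,
                 config$criteria_prefix, " ", config$criteria_text)
  structure(list(text = text, record_id = as.character(record$id)),
            class = "screen_prompt")
}

#' Split a prompt back into its parts
#'
#' Inverse of [build_prompt()] for payloads that do not themselves contain
#' the `"Title:"` / `", Abstract:"` marker strings: recovers title,
#' abstract and criteria text exactly.
#'
#' @param text full prompt text.
#' @param criteria_prefix the criteria prefix used when building.
#' @return list with `title`, `abstract`, `criteria`.
#' @export
split_prompt <- function(text, criteria_prefix = ", Relevant criteria:") {
  t_at <- regexpr("Title:", text, fixed = TRUE)
  if (t_at < 0) abort_validation("prompt lacks a 'Title:' marker")
  rest <- substring(text, t_at + nchar("Title:"))
  a_at <- regexpr(", Abstract:", rest, fixed = TRUE)
  if (a_at < 0) abort_validation("prompt lacks an ', Abstract:' marker")
  title <- substring(rest, 1L, a_at - 1L)
  rest <- substring(rest, a_at + nchar(", Abstract:"))
  c_at <- regexpr(criteria_prefix, rest, fixed = TRUE)
  if (c_at < 0) abort_validation("prompt lacks the criteria prefix %s",
                                 dQuote(criteria_prefix))
  abstract <- substring(rest, 1L, c_at - 1L)
  criteria <- sub("^ ", "", substring(rest, c_at + nchar(criteria_prefix)))
  list(title = title, abstract = abstract, criteria = criteria)
}

#' Read a screening configuration file
#'
#' YAML (or JSON, which YAML subsumes) with keys `criteria_text`,
#' `instruction_variant`, `scale_max`, `criteria_prefix`, `threshold` and
#' an optional `backend` block (`type: mock | command | http` plus
#' type-specific fields and generation `settings`).
#'
#' @param path configuration file.
#' @return list with `prompt` (a [prompt_config()]), `threshold`, and
#'   `backend` (the raw backend block, possibly `NULL`).
#' @export
read_screen_config <- function(path) {
  if (!file.exists(path)) abort_validation("config file not found: %s", path)
  raw <- tryCatch(yaml::read_yaml(path),
                  error = function(e) abort_validation(
                    "cannot parse config %s: %s", path, conditionMessage(e)))
  if (is.null(raw$criteria_text)) {
    abort_validation("config %s lacks 'criteria_text'", path)
  }
  cfg <- prompt_config(
    criteria_text = raw$criteria_text,
    instruction_variant = raw$instruction_variant %||% "standard",
    scale_max = raw$scale_max %||% 5,
    criteria_prefix = raw$criteria_prefix %||% ", Relevant criteria:")
  threshold <- as.integer(raw$threshold %||% 3L)
  if (threshold < 1L || threshold > cfg$scale_max + 1L) {
    abort_validation("threshold %d outside [1, scale_max + 1]", threshold)
  }
  list(prompt = cfg, threshold = threshold, backend = raw$backend)
}
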