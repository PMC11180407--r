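#' Construct a validated corpus of screening records
#'
#' A screening corpus is a plain `data.frame` with one row per publication
#' and columns `id`, `title`, `abstract` and (optionally) `label`. Labels
#' use the canonical values `"relevant"` / `"irrelevant"`; `NA` marks an
#' unlabeled record.
#'
#' @param id character vector of unique record identifiers.
#' @param title character vector of titles; must be non-empty after
#'   whitespace normalisation.
#' @param abstract character vector of abstracts; `NA` becomes `""`.
#' @param label optional character vector in
#'   `c("relevant", "irrelevant", NA)`.
#' @return a `data.frame` of class `screening_records`.
#' @export
screening_records <- function(id, title, abstract = "", label = NULL) {
  if (length(abstract) == 1L && length(id) != 1L) {
    abstract <- rep(abstract, length(id))
  }
  df <- data.frame(id = as.character(id),
                   title = as.character(title),
                   abstract = as.character(abstract),
                   stringsAsFactors = FALSE)
  df$abstract[is.na(df$abstract)] <- ""
  if (!is.null(label)) df$label <- normalize_labels(label)
  validate_records(df)
}

validate_records <- function(df) {
  dup <- df$id[duplicated(df$id)]
  if (length(dup) > 0L) {
    abort_validation("duplicate record id(s): %s",
                     paste(unique(dup), collapse = ", "))
  }
  bad_title <- which(!nzchar(trimws(df$title)) | is.na(df$title))
  if (length(bad_title) > 0L) {
    abort_validation("missing or empty title at row(s): %s",
                     paste(bad_title, collapse = ", "))
  }
  class(df) <- c("screening_records", "data.frame")
  df
}

# Accepts 0/1 and relevant/irrelevant (case-insensitive); emits canonical
# values. Anything else is a validation error.
normalize_labels <- function(x) {
  x <- tolower(trimws(as.character(x)))
  out <- rep(NA_character_, length(x))
  out[x %in% c("1", "relevant", "true", "yes")] <- "relevant"
  out[x %in% c("0", "irrelevant", "false", "no")] <- "irrelevant"
  unknown <- !is.na(x) & nzchar(x) & is.na(out)
  if (any(unknown)) {
    abort_validation("unrecognised label value(s): %s",
                     paste(unique(x[unknown]), collapse = ", "))
  }
  out
}

#' Read a citation corpus from CSV or RIS
#'
#' CSV files need a header row; the column mapping is configurable so no
#' single on-disk layout is hard-wired. RIS records use `TI` (or `T1`) for
#' the title, `AB` for the abstract and `ID`/`AN` for the identifier;
#' records lacking an identifier tag get a sequential `ris_<n>` id.
#'
#' A load report (list with `n_records`, `n_missing_abstract`, `format`)
#' is attached as attribute `"load_report"`.
#'
#' @param path file to read.
#' @param format `"csv"` or `"ris"`; default guessed from the extension.
#' @param col_map named list mapping the canonical fields `id`, `title`,
#'   `abstract`, `label` to column names in the CSV header.
#' @return a `screening_records` data frame in file order.
#' @export
read_records <- function(path,
                         format = c("auto", "csv", "ris"),
                         col_map = list(id = "id", title = "title",
                                        abstract = "abstract",
                                        label = "label")) {
  format <- match.arg(format)
  if (!file.exists(path)) abort_validation("file not found: %s", path)
  if (format == "auto") {
    format <- if (grepl("\\.ris$", path, ignore.case = TRUE)) "ris" else "csv"
  }
  if (format == "csv") read_records_csv(path, col_map) else read_records_ris(path)
}

read_records_csv <- function(path, col_map) {
  raw <- tryCatch(
    utils::read.csv(path, colClasses = "character", check.names = FALSE,
                    fileEncoding = "UTF-8"),
    error = function(e) abort_validation("cannot parse CSV %s: %s",
                                         path, conditionMessage(e)))
  for (field in c("id", "title")) {
    if (!col_map[[field]] %in% names(raw)) {
      abort_validation("CSV %s lacks required column '%s'", path,
                       col_map[[field]])
    }
  }
  abstract <- if (col_map$abstract %in% names(raw)) {
    raw[[col_map$abstract]]
  } else {
    rep("", nrow(raw))
  }
  missing_abs <- sum(is.na(abstract) | !nzchar(trimws(abstract)))
  label <- if (!is.null(col_map$label) && col_map$label %in% names(raw)) {
    raw[[col_map$label]]
  } else {
    NULL
  }
  recs <- screening_records(raw[[col_map$id]], raw[[col_map$title]],
                            abstract, label)
  attr(recs, "load_report") <- list(n_records = nrow(recs),
                                    n_missing_abstract = missing_abs,
                                    format = "csv")
  recs
}

# Minimal RIS tag parser: "XX  - value" lines, continuation lines are
# appended to the last seen tag, "ER" closes a record.
read_records_ris <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  entries <- list()
  current <- list()
  last_tag <- NULL
  flush <- function(entry) {
    if (length(entry) == 0L) return(NULL)
    get1 <- function(tags) {
      for (tg in tags) if (!is.null(entry[[tg]])) return(paste(entry[[tg]], collapse = " "))
      NA_character_
    }
    list(id = get1(c("ID", "AN")) , title = get1(c("TI", "T1")),
         abstract = get1("AB"))
  }
  for (ln in lines) {
    m <- regmatches(ln, regexec("^([A-Z][A-Z0-9])  - ?(.*)$", ln))[[1]]
    if (length(m) == 3L) {
      tag <- m[2]; val <- m[3]
      if (tag == "ER") {
        entries[[length(entries) + 1L]] <- flush(current)
        current <- list(); last_tag <- NULL
      } else {
        current[[tag]] <- c(current[[tag]], val)
        last_tag <- tag
      }
    } else if (!is.null(last_tag) && nzchar(trimws(ln))) {
      current[[last_tag]] <- c(current[[last_tag]],
                               sub("^\\s+", "", ln))
    }
  }
  if (length(current) > 0L) entries[[length(entries) + 1L]] <- flush(current)
  entries <- Filter(Negate(is.null), entries)
  if (length(entries) == 0L) abort_validation("no RIS records found in %s", path)
  id <- vapply(entries, `[[`, "", "id")
  need_id <- is.na(id)
  id[need_id] <- sprintf("ris_%d", which(need_id))
  title <- vapply(entries, `[[`, "", "title")
  if (any(is.na(title))) {
    abort_validation("RIS record(s) without TI tag at position(s): %s",
                     paste(which(is.na(title)), collapse = ", "))
  }
  abstract <- vapply(entries, `[[`, "", "abstract")
  missing_abs <- sum(is.na(abstract))
  recs <- screening_records(id, title, abstract)
  attr(recs, "load_report") <- list(n_records = nrow(recs),
                                    n_missing_abstract = missing_abs,
                                    format = "ris")
  recs
}

#' Write a corpus to CSV
#'
#' Labels are emitted as `1` (relevant) / `0` (irrelevant), the convention
#' of the public screening datasets; the label column is omitted for a
#' fully unlabeled corpus.
#'
#' @param records a `screening_records` data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_records <- function(records, path) {
  out <- data.frame(id = records$id, title = records$title,
                    abstract = records$abstract, stringsAsFactors = FALSE)
  if (!is.null(records$label) && any(!is.na(records$label))) {
    out$label <- ifelse(is.na(records$label), "",
                        ifelse(records$label == "relevant", "1", "0"))
  }
  utils::write.csv(out, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Summarise a labeled corpus
#'
#' Computes the record count, relevant count and prevalence percentage
#' (rounded half-up to 2 decimals), i.e. the per-dataset quantities a
#' screening study tabulates.
#'
#' @param records a fully labeled `screening_records` data frame.
#' @return list with `n_total`, `n_relevant`, `prevalence_pct`.
#' @export
summarize_dataset <- function(records) {
  if (nrow(records) == 0L) abort_validation("empty corpus")
  if (is.null(records$label)) abort_validation("corpus has no label column")
  unl <- records$id[is.na(records$label)]
  if (length(unl) > 0L) {
    abort_validation("unlabeled record(s): %s", paste(unl, collapse = ", "))
  }
  n_total <- nrow(records)
  n_relevant <- sum(records$label == "relevant")
  structure(list(n_total = n_total,
                 n_relevant = n_relevant,
                 prevalence_pct = round_half_up(100 * n_relevant / n_total, 2)),
            class = "dataset_summary")
}

#' @export
print.dataset_summary <- function(x, ...) {
  cat(sprintf("%d records, %d relevant (%.2f%%)\n",
              x$n_total, x$n_relevant, x$prevalence_pct))
  invisible(x)
}
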