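#' Biomarker classification tasks
#'
#' The four report-level classification tasks: estrogen receptor (ER),
#' progesterone receptor (PR), HER2 protein expression by
#' immunohistochemistry (HER2_IHC) and HER2 gene amplification by in-situ
#' hybridization (HER2_ISH).
#'
#' @return character vector of the four task identifiers.
#' @export
biomarker_tasks <- function() c("ER", "PR", "HER2_IHC", "HER2_ISH")

.label_schemas <- list(
  ER       = c("Unknown", "Negative", "Positive"),
  PR       = c("Unknown", "Negative", "Positive"),
  HER2_IHC = c("Unknown", "0", "1+", "2+", "3+"),
  HER2_ISH = c("Unknown", "CarriedOutNoResult", "Negative", "Equivocal",
               "Positive")
)

#' Label schema of a task
#'
#' ER and PR have three ordered categories; HER2 IHC has the five
#' semi-quantitative staining categories and HER2 ISH the five amplification
#' categories ("CarriedOutNoResult" records that a test was performed but no
#' result was transmitted).
#'
#' @param task one of [biomarker_tasks()].
#' @return ordered character vector of valid labels.
#' @export
label_schema <- function(task) {
  task <- match.arg(task, biomarker_tasks())
  .label_schemas[[task]]
}

#' Construct a report record
#'
#' @param report_id unique identifier string.
#' @param text UTF-8 free text, non-empty after whitespace stripping.
#' @param language_hint one of "nl", "fr", "mixed", "unknown".
#' @param labels named list/character, names in [biomarker_tasks()], values in
#'   the corresponding [label_schema()]. Tasks may be absent.
#' @param train_only logical; force this record into the training partition
#'   (used for supplementary annotated reports).
#' @return a `receptex_report` list.
#' @export
report <- function(report_id, text, language_hint = "unknown",
                   labels = list(), train_only = FALSE) {
  if (!is.character(report_id) || length(report_id) != 1L || !nzchar(report_id))
    stopf("report_id must be a non-empty string")
  if (!is.character(text) || length(text) != 1L ||
      !nzchar(trimws(text)))
    stopf("report '%s': text must be non-empty", report_id)
  language_hint <- match.arg(language_hint, c("nl", "fr", "mixed", "unknown"))
  labels <- as.list(labels)
  if (length(labels)) {
    bad <- setdiff(names(labels), biomarker_tasks())
    if (length(bad)) stopf("report '%s': unknown task(s) %s", report_id,
                           paste(bad, collapse = ", "))
    for (task in names(labels)) {
      if (!labels[[task]] %in% label_schema(task))
        stopf("report '%s': label '%s' not in %s schema", report_id,
              labels[[task]], task)
    }
  }
  structure(list(report_id = report_id, text = text,
                 language_hint = language_hint, labels = labels,
                 train_only = isTRUE(train_only)),
            class = "receptex_report")
}

#' @export
print.receptex_report <- function(x, ...) {
  cat(sprintf("<report %s> [%s] %d chars, labels: %s\n", x$report_id,
              x$language_hint, nchar(x$text),
              if (length(x$labels))
                paste(names(x$labels), unlist(x$labels), sep = "=",
                      collapse = ", ")
              else "none"))
  invisible(x)
}

validate_corpus <- function(reports) {
  ids <- vapply(reports, `[[`, "", "report_id")
  dup <- ids[duplicated(ids)]
  if (length(dup)) stopf("duplicate report_id(s): %s",
                         paste(unique(dup), collapse = ", "))
  invisible(reports)
}

#' Read a corpus from a JSONL file
#'
#' One JSON object per line with fields `report_id`, `text`, optional
#' `language_hint`, `labels` (object keyed by task) and `train_only`.
#'
#' @param path file path.
#' @return list of report records.
#' @export
read_corpus <- function(path) {
  if (!file.exists(path)) stopf("corpus file not found: %s", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  reports <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    rec <- tryCatch(jsonlite::fromJSON(lines[[i]], simplifyVector = TRUE),
                    error = function(e)
                      stopf("parse error at line %d: %s", i, conditionMessage(e)))
    if (is.null(rec$report_id) || is.null(rec$text))
      stopf("parse error at line %d: missing report_id or text", i)
    reports[[i]] <- report(
      report_id = as.character(rec$report_id),
      text = as.character(rec$text),
      language_hint = rec$language_hint %||% "unknown",
      labels = rec$labels %||% list(),
      train_only = isTRUE(rec$train_only)
    )
  }
  validate_corpus(reports)
}

#' Write a corpus to a JSONL file
#'
#' Inverse of [read_corpus()]; round-trips exactly (UTF-8 preserved).
#'
#' @param reports list of report records.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_corpus <- function(reports, path) {
  validate_corpus(reports)
  lines <- vapply(reports, function(r) {
    rec <- list(report_id = r$report_id, text = r$text,
                language_hint = r$language_hint)
    if (length(r$labels)) rec$labels <- r$labels
    if (isTRUE(r$train_only)) rec$train_only <- TRUE
    jsonlite::toJSON(rec, auto_unbox = TRUE)
  }, "")
  con <- file(path, open = "wb")
  on.exit(close(con))
  if (length(lines)) writeLines(lines, con, useBytes = FALSE)
  invisible(path)
}

#' Export labels as a flat CSV
#'
#' @param reports list of report records.
#' @param path output CSV path (columns report_id, task, label).
#' @return `path`, invisibly.
#' @export
write_labels_csv <- function(reports, path) {
  rows <- do.call(rbind, lapply(reports, function(r) {
    if (!length(r$labels)) return(NULL)
    data.frame(report_id = r$report_id, task = names(r$labels),
               label = unlist(r$labels, use.names = FALSE),
               stringsAsFactors = FALSE)
  }))
  if (is.null(rows))
    rows <- data.frame(report_id = character(), task = character(),
                       label = character())
  write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

corpus_labels <- function(reports, task) {
  vapply(reports, function(r) r$labels[[task]] %||% NA_character_, "")
}

# Largest-remainder allocation of `target` units across strata with sizes n.
allocate_largest_remainder <- function(n, target) {
  if (target <= 0) return(integer(length(n)))
  quota <- n / sum(n) * target
  base <- floor(quota)
  rem <- target - sum(base)
  if (rem > 0) {
    ord <- order(quota - base, n, decreasing = TRUE)
    base[ord[seq_len(rem)]] <- base[ord[seq_len(rem)]] + 1
  }
  pmin(as.integer(base), n)
}

#' Split a labeled corpus into training, validation and test sets
#'
#' Random 60/20/20 split, stratified by the task's label:
#' `|train| = round(0.6 N)`, `|validation| = round(0.2 N)`, test takes the
#' remainder (`N` = reports carrying a label for `task`, excluding
#' `train_only` records, which are always appended to the training
#' partition). Deterministic given `seed`.
#'
#' @param reports list of report records.
#' @param task one of [biomarker_tasks()].
#' @param seed integer seed.
#' @return list with `train_ids`, `validation_ids`, `test_ids`, `seed`, `task`.
#' @export
split_dataset <- function(reports, task, seed) {
  task <- match.arg(task, biomarker_tasks())
  labels <- corpus_labels(reports, task)
  ids <- vapply(reports, `[[`, "", "report_id")
  train_only <- vapply(reports, function(r) isTRUE(r$train_only), TRUE)
  keep <- !is.na(labels)
  forced <- ids[keep & train_only]
  ids <- ids[keep & !train_only]
  labels <- labels[keep & !train_only]
  n <- length(ids)
  if (n < 5L) stopf("need at least 5 labeled reports for task %s, got %d",
                    task, n)

  n_train <- as.integer(round(0.6 * n))
  n_val <- as.integer(round(0.2 * n))

  set.seed(derive_seed(seed, "split"))
  ord <- sample.int(n)
  ids <- ids[ord]; labels <- labels[ord]

  strata <- split(ids, factor(labels, levels = label_schema(task)))
  strata <- strata[lengths(strata) > 0]
  sizes <- lengths(strata)
  a_train <- allocate_largest_remainder(sizes, n_train)
  # leftover capacity per stratum feeds the validation allocation
  a_val <- allocate_largest_remainder(sizes - a_train, n_val)
  train <- character(); val <- character(); test <- character()
  for (k in seq_along(strata)) {
    s <- strata[[k]]
    train <- c(train, s[seq_len(a_train[k])])
    val <- c(val, s[seq_len(a_val[k]) + a_train[k]])
    if (a_train[k] + a_val[k] < length(s))
      test <- c(test, s[(a_train[k] + a_val[k] + 1L):length(s)])
  }
  # largest-remainder rounding can leave train/val one short of the global
  # target when a stratum saturates; top up deterministically from test
  short_train <- n_train - length(train)
  if (short_train > 0) { train <- c(train, test[seq_len(short_train)]); test <- test[-seq_len(short_train)] }
  short_val <- n_val - length(val)
  if (short_val > 0) { val <- c(val, test[seq_len(short_val)]); test <- test[-seq_len(short_val)] }

  list(task = task, seed = seed,
       train_ids = sort(c(train, forced)),
       validation_ids = sort(val),
       test_ids = sort(test))
}
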