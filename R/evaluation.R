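#' Confusion matrix
#'
#' @param gold,predicted equal-length label vectors, all in `schema`.
#' @param schema ordered label set, see [label_schema()].
#' @return square integer table (rows = gold, columns = predicted), class
#'   `receptex_confusion`.
#' @export
confusion_matrix <- function(gold, predicted, schema) {
  gold <- as.character(gold); predicted <- as.character(predicted)
  if (length(gold) != length(predicted))
    stopf("gold and predicted must have equal length (%d vs %d)",
          length(gold), length(predicted))
  bad <- setdiff(unique(c(gold, predicted)), schema)
  if (length(bad)) stopf("label(s) not in schema: %s",
                         paste(bad, collapse = ", "))
  tab <- table(gold = factor(gold, levels = schema),
               predicted = factor(predicted, levels = schema))
  class(tab) <- c("receptex_confusion", class(tab))
  tab
}

#' Macro-averaged F1 score
#'
#' For each class: precision = TP/(TP+FP), recall = TP/(TP+FN) and
#' F1 = 2PR/(P+R), with the 0-when-undefined convention for zero
#' denominators. The macro average is the arithmetic mean of F1 over classes
#' with gold support > 0, so every label is penalized equally regardless of
#' prevalence: 1 corresponds to a perfect classifier and 0 to one that is
#' systematically wrong.
#'
#' @param cm a [confusion_matrix()].
#' @return a number in \[0, 1\].
#' @export
macro_f1 <- function(cm) {
  cm <- unclass(cm)
  if (sum(cm) == 0L) stopf("empty confusion matrix")
  tp <- diag(cm)
  support <- rowSums(cm)
  predicted <- colSums(cm)
  precision <- ifelse(predicted > 0, tp / predicted, 0)
  recall <- ifelse(support > 0, tp / support, 0)
  f1 <- ifelse(precision + recall > 0,
               2 * precision * recall / (precision + recall), 0)
  mean(f1[support > 0])
}

per_class_metrics <- function(cm) {
  cm <- unclass(cm)
  tp <- diag(cm)
  support <- rowSums(cm)
  predicted <- colSums(cm)
  precision <- ifelse(predicted > 0, tp / predicted, 0)
  recall <- ifelse(support > 0, tp / support, 0)
  f1 <- ifelse(precision + recall > 0,
               2 * precision * recall / (precision + recall), 0)
  data.frame(label = rownames(cm), support = as.integer(support),
             precision = precision, recall = recall, f1 = f1,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Evaluate predictions against gold labels
#'
#' @param gold,predicted label vectors.
#' @param schema the task's label schema.
#' @param split name of the evaluated split (bookkeeping only).
#' @return a `receptex_eval` list: per-class precision/recall/F1, `macro_f1`,
#'   `n_reports`, `split` and the confusion matrix.
#' @export
evaluate_predictions <- function(gold, predicted, schema, split = "test") {
  if (!length(gold)) stopf("empty evaluation split")
  cm <- confusion_matrix(gold, predicted, schema)
  structure(list(per_class = per_class_metrics(cm), macro_f1 = macro_f1(cm),
                 n_reports = length(gold), split = split,
                 confusion = cm),
            class = "receptex_eval")
}

#' @export
print.receptex_eval <- function(x, ...) {
  cat(sprintf("<evaluation: %s> macro-F1 = %.3f (N = %d)\n", x$split,
              x$macro_f1, x$n_reports))
  print(x$per_class, digits = 3)
  invisible(x)
}

#' Rule-based baseline classifier
#'
#' Labels a report from the lexicon's label-linked patterns alone: if the
#' report contains a match for a pattern linked to a label of `task`, it is
#' given that label; no match yields "Unknown"; when several conflicting
#' patterns match, the label of the match occurring last in the report wins
#' (decisive information tends to sit at the end).
#'
#' @param reports list of report records (or a single one).
#' @param task one of [biomarker_tasks()].
#' @param lexicon a lexicon with label-linked patterns.
#' @param structures optional precomputed report structures.
#' @return character vector of labels, one per report.
#' @export
rule_based_classify <- function(reports, task,
                                lexicon = default_lexicon(),
                                structures = NULL) {
  if (inherits(reports, "receptex_report")) reports <- list(reports)
  task <- match.arg(task, biomarker_tasks())
  lex <- lexicon[lexicon$task == task, , drop = FALSE]
  if (!nrow(lex)) stopf("lexicon has no label-linked patterns for %s", task)
  if (is.null(structures))
    structures <- lapply(reports, report_structure)
  matches <- match_concepts_corpus(structures, lex)
  vapply(matches, function(m) {
    if (!nrow(m)) return("Unknown")
    # last match wins; on a tie of start, the longer match, then rule order
    m <- m[order(m$start, m$end), , drop = FALSE]
    m$label[nrow(m)]
  }, "")
}

#' Write an evaluation result to JSON (+ confusion CSV)
#'
#' @param eval a `receptex_eval`.
#' @param path output JSON path; the confusion matrix is written next to it
#'   with suffix `_confusion.csv`.
#' @return `path`, invisibly.
#' @export
write_eval_json <- function(eval, path) {
  out <- list(split = eval$split, n_reports = eval$n_reports,
              macro_f1 = eval$macro_f1, per_class = eval$per_class)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  write.csv(as.data.frame.matrix(unclass(eval$confusion)),
            sub("\\.json$", "_confusion.csv", path))
  invisible(path)
}
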