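subset_reports <- function(reports, ids) {
  all_ids <- vapply(reports, `[[`, "", "report_id")
  reports[match(ids, all_ids)]
}

pipeline_options <- function(grid = default_grid(), selection_folds = 10L,
                             self_training = FALSE, min_df = 3L,
                             max_vocabulary = 2000L,
                             lexicon = default_lexicon(),
                             references = reference_sentences(),
                             combos = read_combos(),
                             abbreviations = default_abbreviations()) {
  list(grid = grid, selection_folds = selection_folds,
       self_training = self_training, min_df = min_df,
       max_vocabulary = max_vocabulary, lexicon = lexicon,
       references = references, combos = combos,
       abbreviations = abbreviations)
}

# Featurize reports with fitted artifacts (vocabulary, meta, normalization).
pipeline_features <- function(reports, artifacts, structures = NULL) {
  cfg <- artifacts$feature_config
  cfg$vocabulary <- artifacts$vocabulary
  mat <- build_feature_matrix(reports, cfg, structures = structures)
  if (length(artifacts$meta_specs)) {
    meta <- t(apply(mat, 1, meta_logistic_features,
                    specs = artifacts$meta_specs))
    colnames(meta) <- vapply(artifacts$meta_specs, `[[`, "", "name")
    mat <- cbind(mat, meta)
  }
  apply_normalization(mat, artifacts$normalization)
}

#' Fit all training-stage artifacts and candidate models for one task
#'
#' Everything fitted here — vocabulary, meta-model specs, normalization
#' constants, feature selection and the candidate classifiers — depends on
#' the training partition only, never on validation or test reports.
#'
#' @param reports labeled corpus (list of [report()] records).
#' @param split a [split_dataset()] result for the same task.
#' @param task one of [biomarker_tasks()].
#' @param seed integer seed.
#' @param options see arguments of [run_pipeline()].
#' @return list with `artifacts` (vocabulary, meta_specs, normalization,
#'   ranking, feature_config), `models`, `train_x`, `train_y`.
#' @export
fit_task_models <- function(reports, split, task, seed,
                            options = pipeline_options()) {
  train_reports <- subset_reports(reports, split$train_ids)
  y <- corpus_labels(train_reports, task)
  stopifnot(!anyNA(y))
  cfg <- feature_config(lexicon = options$lexicon,
                        references = options$references,
                        combos = options$combos,
                        abbreviations = options$abbreviations)
  structures <- lapply(train_reports, report_structure,
                       abbreviations = cfg$abbreviations)
  vocabulary <- build_vocabulary(structures, min_df = options$min_df,
                                 max_size = options$max_vocabulary)
  cfg$vocabulary <- vocabulary
  base <- build_feature_matrix(train_reports, cfg, structures = structures)
  meta_specs <- fit_meta_models(base, y, task)
  if (length(meta_specs)) {
    meta <- t(apply(base, 1, meta_logistic_features, specs = meta_specs))
    colnames(meta) <- vapply(meta_specs, `[[`, "", "name")
    base <- cbind(base, meta)
  }
  normalization <- fit_normalization(base)
  train_x <- apply_normalization(base, normalization)
  ranking <- rank_and_select(train_x, y, folds = options$selection_folds,
                             seed = seed)
  ranking$cv <- NULL
  models <- train_candidates(train_x[, ranking$selected, drop = FALSE],
                             y, grid = options$grid, seed = seed)
  cfg$vocabulary <- NULL
  list(artifacts = list(task = task, seed = seed,
                        feature_config = cfg, vocabulary = vocabulary,
                        meta_specs = meta_specs,
                        normalization = normalization, ranking = ranking),
       models = models, train_x = train_x, train_y = y)
}

#' Run the full extraction pipeline
#'
#' Per task: split the labeled corpus 60/20/20, fit all training-stage
#' artifacts and the classifier grid on the training set, optionally
#' self-train on unlabeled reports (the self-trained model is retained only
#' if it improves validation macro-F1), select the best candidate by
#' validation macro-F1, and evaluate the selected model — once — on the
#' held-out test set, alongside the rule-based baseline.
#'
#' @param reports labeled corpus.
#' @param seed root integer seed; all stage seeds derive from it.
#' @param tasks tasks to run (default all four).
#' @param unlabeled optional list of unlabeled reports for self-training.
#' @param exclude_ids report ids dropped from the corpus before splitting
#'   (e.g. flagged multi-tumor reports, which a registry discards).
#' @param grid,selection_folds,self_training,min_df,max_vocabulary,lexicon,references,combos,abbreviations
#'   pipeline settings, see `pipeline_options()`.
#' @return a `receptex_pipeline` list, one element per task: `model`,
#'   `artifacts`, `split`, `validation`, `test`, `baseline_test`, `scores`.
#' @export
run_pipeline <- function(reports, seed = 1L, tasks = biomarker_tasks(),
                         unlabeled = NULL, exclude_ids = NULL,
                         grid = default_grid(), selection_folds = 10L,
                         self_training = FALSE, min_df = 3L,
                         max_vocabulary = 2000L,
                         lexicon = default_lexicon(),
                         references = reference_sentences(),
                         combos = read_combos(),
                         abbreviations = default_abbreviations()) {
  options <- pipeline_options(grid, selection_folds, self_training, min_df,
                              max_vocabulary, lexicon, references, combos,
                              abbreviations)
  if (length(exclude_ids))
    reports <- reports[!vapply(reports, `[[`, "", "report_id") %in%
                         exclude_ids]
  out <- list()
  for (task in tasks) {
    schema <- label_schema(task)
    labeled <- reports[!is.na(corpus_labels(reports, task))]
    split <- split_dataset(labeled, task, seed)
    fitted <- fit_task_models(labeled, split, task, seed, options)

    val_reports <- subset_reports(labeled, split$validation_ids)
    y_val <- corpus_labels(val_reports, task)
    x_val <- pipeline_features(val_reports, fitted$artifacts)
    best <- select_best_model(fitted$models, x_val, y_val, schema)

    if (isTRUE(self_training) && length(unlabeled)) {
      x_unl <- pipeline_features(unlabeled, fitted$artifacts)
      st <- self_train(best$model,
                       x_unl[, best$model$feature_names, drop = FALSE],
                       fitted$train_x[, best$model$feature_names,
                                      drop = FALSE],
                       fitted$train_y)
      st_f1 <- macro_f1(confusion_matrix(y_val, predict_model(st, x_val),
                                         schema))
      if (st_f1 > best$eval$macro_f1) {
        best$model <- st
        best$eval <- evaluate_predictions(y_val, predict_model(st, x_val),
                                          schema, split = "validation")
      }
    }

    test_reports <- subset_reports(labeled, split$test_ids)
    y_test <- corpus_labels(test_reports, task)
    x_test <- pipeline_features(test_reports, fitted$artifacts)
    pred_test <- predict_model(best$model, x_test)
    test_eval <- evaluate_predictions(y_test, pred_test, schema,
                                      split = "test")
    baseline <- rule_based_classify(test_reports, task,
                                    lexicon = options$lexicon)
    baseline_eval <- evaluate_predictions(y_test, baseline, schema,
                                          split = "test (rule-based)")
    out[[task]] <- list(task = task, model = best$model,
                        artifacts = fitted$artifacts, split = split,
                        validation = best$eval, test = test_eval,
                        baseline_test = baseline_eval,
                        scores = best$scores)
  }
  structure(out, class = "receptex_pipeline")
}

#' @export
print.receptex_pipeline <- function(x, ...) {
  cat("<receptex pipeline>\n")
  for (task in names(x)) {
    r <- x[[task]]
    cat(sprintf("  %-8s best = %s | validation F1 = %.3f | test F1 = %.3f | rule-based F1 = %.3f\n",
                task,
                paste0(r$model$family,
                       if (isTRUE(r$model$self_trained)) " (self-trained)" else ""),
                r$validation$macro_f1, r$test$macro_f1,
                r$baseline_test$macro_f1))
  }
  invisible(x)
}

#' Predict biomarker labels for new reports
#'
#' Featurizes the reports with the task result's fitted artifacts and
#' applies its selected model. A report with empty text is labeled
#' "Unknown" with a warning.
#'
#' @param task_result one element of a [run_pipeline()] result.
#' @param reports list of report records.
#' @return named character vector (report_id -> label).
#' @export
predict_labels <- function(task_result, reports) {
  if (inherits(reports, "receptex_report")) reports <- list(reports)
  ids <- vapply(reports, `[[`, "", "report_id")
  texts <- vapply(reports, `[[`, "", "text")
  empty <- !nzchar(trimws(texts))
  out <- setNames(rep("Unknown", length(reports)), ids)
  if (any(empty))
    warnf("%d report(s) with empty text labeled 'Unknown'", sum(empty))
  if (any(!empty)) {
    x <- pipeline_features(reports[!empty], task_result$artifacts)
    out[!empty] <- predict_model(task_result$model, x)
  }
  out
}

#' Save a trained task model as a bundle directory
#'
#' The fitted model and artifacts are serialized, with a JSON sidecar
#' recording task, classifier spec, selected features, normalization
#' constants and seeds.
#'
#' @param task_result one element of a [run_pipeline()] result.
#' @param dir output directory (created).
#' @return `dir`, invisibly.
#' @export
save_model_bundle <- function(task_result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  saveRDS(task_result[c("task", "model", "artifacts")],
          file.path(dir, "model.rds"))
  sidecar <- list(
    task = task_result$task,
    family = task_result$model$family,
    hyperparameters = task_result$model$params,
    self_trained = task_result$model$self_trained,
    selected_features = task_result$model$feature_names,
    normalization = list(
      center = as.list(task_result$artifacts$normalization$center),
      scale = as.list(task_result$artifacts$normalization$scale)),
    seed = task_result$artifacts$seed)
  jsonlite::write_json(sidecar, file.path(dir, "model.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Load a saved model bundle
#'
#' @param dir directory written by [save_model_bundle()].
#' @return a task-result list usable with [predict_labels()].
#' @export
load_model_bundle <- function(dir) {
  readRDS(file.path(dir, "model.rds"))
}
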