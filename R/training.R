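.family_order <- c("random_forest", "svm", "multinomial_logistic",
                   "decision_tree", "knn")

#' Default classifier grid
#'
#' The classifier families compared on each task: random forests with a
#' varying number of trees, support vector machines with linear, radial,
#' polynomial and sigmoid kernels over penalty/kernel-parameter grids,
#' regularized multinomial logistic regression along a 20-point lambda path,
#' classification trees with maximum depth 2 to 10, and k-nearest neighbors
#' with k = 1, 3, 5, 9, 15, 30, 45.
#'
#' @param families optional subset of families to keep.
#' @return list of classifier specs (`family` plus hyperparameters).
#' @export
default_grid <- function(families = .family_order) {
  grid <- list()
  add <- function(family, ...) grid[[length(grid) + 1L]] <<-
      c(list(family = family), list(...))
  for (nt in c(100L, 300L, 500L)) add("random_forest", n_trees = nt)
  for (C in c(0.1, 1, 10)) add("svm", kernel = "linear", cost = C)
  for (C in c(0.1, 1, 10)) for (g in c(0.01, 0.1))
    add("svm", kernel = "radial", cost = C, gamma = g)
  for (C in c(0.1, 1, 10)) for (d in 2:3)
    add("svm", kernel = "polynomial", cost = C, degree = d)
  for (C in c(0.1, 1, 10)) add("svm", kernel = "sigmoid", cost = C)
  add("multinomial_logistic", nlambda = 20L)
  for (d in 2:10) add("decision_tree", max_depth = d)
  for (k in c(1L, 3L, 5L, 9L, 15L, 30L, 45L)) add("knn", k = k)
  grid[vapply(grid, function(g) g$family %in% families, TRUE)]
}

spec_id <- function(spec) {
  hp <- spec[setdiff(names(spec), "family")]
  paste0(spec$family, "(",
         paste(names(hp), unlist(hp), sep = "=", collapse = ","), ")")
}

new_model <- function(family, params, fit, classes, feature_names, seed,
                      extra = list()) {
  structure(c(list(family = family, params = params, fit = fit,
                   classes = classes, feature_names = feature_names,
                   seed = seed, self_trained = FALSE), extra),
            class = "receptex_classifier")
}

#' @export
print.receptex_classifier <- function(x, ...) {
  cat(sprintf("<classifier> %s on %d features, classes: %s%s\n",
              spec_id(c(list(family = x$family), x$params)),
              length(x$feature_names), paste(x$classes, collapse = "/"),
              if (isTRUE(x$self_trained)) " (self-trained)" else ""))
  invisible(x)
}

fit_one <- function(spec, x, y, seed) {
  classes <- levels(droplevels(y))
  y <- droplevels(y)
  params <- spec[setdiff(names(spec), "family")]
  set.seed(derive_seed(seed, spec_id(spec)))
  fit <- switch(spec$family,
    random_forest = randomForest::randomForest(
      x = x, y = y, ntree = spec$n_trees),
    svm = do.call(e1071::svm, c(list(x = x, y = y, kernel = spec$kernel,
                                     cost = spec$cost, scale = FALSE),
      if (!is.null(spec$gamma)) list(gamma = spec$gamma),
      if (!is.null(spec$degree)) list(degree = spec$degree))),
    multinomial_logistic = glmnet::glmnet(
      x, y, family = "multinomial", alpha = 1,
      nlambda = spec$nlambda %||% 20L),
    decision_tree = {
      df <- data.frame(x, check.names = FALSE)
      df$.label <- y
      fit <- rpart::rpart(.label ~ ., data = df, method = "class",
                          control = rpart::rpart.control(
                            maxdepth = spec$max_depth, cp = 0, xval = 0,
                            minsplit = 5))
      # keep the fitted object self-contained (no captured environment)
      environment(fit$terms) <- baseenv()
      fit
    },
    knn = list(train = x, cl = y),
    stopf("unknown classifier family: %s", spec$family))
  new_model(spec$family, params, fit, classes,
            colnames(x), seed,
            extra = if (spec$family == "multinomial_logistic")
              list(lambda = spec$lambda) else list())
}

predict_model <- function(model, x) {
  x <- x[, model$feature_names, drop = FALSE]
  out <- switch(model$family,
    random_forest = as.character(predict(model$fit, x)),
    svm = as.character(predict(model$fit, x)),
    multinomial_logistic = as.character(predict(
      model$fit, x, s = model$lambda, type = "class")),
    decision_tree = {
      df <- data.frame(x, check.names = FALSE)
      as.character(predict(model$fit, df, type = "class"))
    },
    knn = {
      set.seed(derive_seed(model$seed, "knn_predict"))
      as.character(class::knn(model$fit$train, x, model$fit$cl,
                              k = min(model$params$k,
                                      nrow(model$fit$train))))
    })
  out
}

#' Train all candidate classifiers in a grid
#'
#' One fitted model per grid spec (the multinomial-logistic path spec
#' expands to one candidate per lambda on its path, sharing a single fit).
#' Individual spec failures are recorded as warnings, not fatal; an error is
#' raised only if every spec fails.
#'
#' @param x training feature matrix (selected features, normalized).
#' @param y training labels (character or factor).
#' @param grid list of classifier specs, see [default_grid()].
#' @param seed integer seed (each fit gets a named substream).
#' @return list of `receptex_classifier` models.
#' @export
train_candidates <- function(x, y, grid = default_grid(), seed = 1L) {
  stopifnot(length(grid) > 0)
  y <- factor(as.character(y))
  models <- list(); failures <- character()
  for (spec in grid) {
    res <- tryCatch(fit_one(spec, x, y, seed), error = function(e) e)
    if (inherits(res, "error")) {
      failures <- c(failures, sprintf("%s: %s", spec_id(spec),
                                      conditionMessage(res)))
      next
    }
    if (spec$family == "multinomial_logistic") {
      for (s in res$fit$lambda) {
        m <- res
        m$lambda <- s
        m$params <- list(lambda = signif(s, 6))
        models[[length(models) + 1L]] <- m
      }
    } else {
      models[[length(models) + 1L]] <- res
    }
  }
  if (!length(models))
    stopf("all classifier specs failed:\n%s", paste(failures, collapse = "\n"))
  if (length(failures))
    warnf("%d classifier spec(s) failed: %s", length(failures),
          paste(failures, collapse = "; "))
  models
}

#' Select the best model by validation macro-F1
#'
#' Returns the model with the highest macro-averaged F1 on the validation
#' set. Ties break deterministically: fewer features, then fixed family
#' order (random forest, SVM, logistic, tree, kNN), then lexicographic
#' hyperparameters.
#'
#' @param models list of fitted models.
#' @param x_val,y_val validation features and labels.
#' @param schema label schema of the task.
#' @return list with `model`, `eval` (validation [evaluate_predictions()]
#'   result) and `scores` (per-candidate macro-F1).
#' @export
select_best_model <- function(models, x_val, y_val, schema) {
  stopifnot(length(models) > 0, length(y_val) > 0)
  scores <- vapply(models, function(m) {
    pred <- predict_model(m, x_val)
    macro_f1(confusion_matrix(y_val, pred, schema))
  }, 0)
  nfeat <- vapply(models, function(m) length(m$feature_names), 0L)
  fam <- match(vapply(models, `[[`, "", "family"), .family_order)
  hp <- vapply(models, function(m)
    paste(names(m$params), unlist(m$params), sep = "=", collapse = ","), "")
  ord <- order(-scores, nfeat, fam, hp)
  best <- models[[ord[1]]]
  pred <- predict_model(best, x_val)
  list(model = best,
       eval = evaluate_predictions(y_val, pred, schema, split = "validation"),
       scores = data.frame(
         family = vapply(models, `[[`, "", "family"),
         hyperparameters = hp, macro_f1 = scores,
         stringsAsFactors = FALSE))
}

#' Self-training on unlabeled reports
#'
#' Uses the base classifier to pseudo-label unlabeled data, then refits the
#' same spec on the union of the labeled and pseudo-labeled sets. With an
#' empty unlabeled set the base model is returned unchanged. Whether the
#' self-trained model should be retained is decided downstream, by comparing
#' validation macro-F1 (see [run_pipeline()]).
#'
#' @param base fitted `receptex_classifier`.
#' @param x_unlabeled feature matrix of unlabeled reports (same features and
#'   normalization constants as the base model's training data).
#' @param x_train,y_train the original labeled training data.
#' @return refitted model flagged `self_trained`, or `base` if no unlabeled
#'   data.
#' @export
self_train <- function(base, x_unlabeled, x_train, y_train) {
  if (is.null(x_unlabeled) || nrow(x_unlabeled) == 0L) return(base)
  pseudo <- predict_model(base, x_unlabeled)
  x_all <- rbind(x_train[, base$feature_names, drop = FALSE],
                 x_unlabeled[, base$feature_names, drop = FALSE])
  y_all <- factor(c(as.character(y_train), pseudo))
  spec <- c(list(family = base$family), base$params)
  if (base$family == "multinomial_logistic") {
    spec <- list(family = "multinomial_logistic", nlambda = 20L)
    m <- fit_one(spec, x_all, y_all, base$seed)
    # keep the base model's operating point on the refit path
    m$lambda <- base$lambda
    m$params <- base$params
  } else {
    m <- fit_one(spec, x_all, y_all, base$seed)
  }
  m$self_trained <- TRUE
  m
}
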