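stratified_folds <- function(labels, folds, seed) {
  set.seed(derive_seed(seed, "cvfolds"))
  foldid <- integer(length(labels))
  for (lab in unique(labels)) {
    idx <- which(labels == lab)
    idx <- idx[sample.int(length(idx))]
    foldid[idx] <- rep_len(seq_len(folds), length(idx))
  }
  foldid
}

#' Rank and select features with an L1-regularized multinomial model
#'
#' Fits an L1-penalized multinomial logistic regression over a regularization
#' path with stratified k-fold cross-validation on the training partition.
#' The importance of a feature is the maximum absolute coefficient across
#' classes at the selected strength (the largest lambda within one standard
#' error of the minimum deviance, a parsimonious choice aimed at avoiding
#' overfitting); selected features are those with non-zero importance. If the
#' selection is empty, the top 10 features by importance at the
#' minimum-deviance strength are kept instead, with a warning.
#'
#' @param matrix normalized training feature matrix.
#' @param labels training labels (character), at least two classes.
#' @param folds number of CV folds (default 10).
#' @param seed integer seed (folds are seeded deterministically).
#' @return a `receptex_ranking` list with `ranked` (data.frame feature_name,
#'   importance), `selected`, `regularization_strength`, `folds`, `seed`.
#' @export
rank_and_select <- function(matrix, labels, folds = 10L, seed = 1L) {
  labels <- as.character(labels)
  if (length(unique(labels)) < 2L)
    stopf("feature selection needs at least 2 classes in the training labels")
  if (folds > length(labels)) stopf("more folds than samples")
  foldid <- stratified_folds(labels, folds, seed)
  set.seed(derive_seed(seed, "cvglmnet"))
  cv <- glmnet::cv.glmnet(matrix, factor(labels), family = "multinomial",
                          alpha = 1, foldid = foldid, standardize = FALSE)
  importance_at <- function(s) {
    beta <- coef(cv, s = s)
    imp <- Reduce(pmax, lapply(beta, function(b) abs(as.numeric(b[-1, 1]))))
    names(imp) <- rownames(beta[[1]])[-1]
    imp
  }
  imp <- importance_at(cv$lambda.1se)
  selected <- names(imp)[imp > 0]
  strength <- cv$lambda.1se
  if (!length(selected)) {
    warnf("no informative features at lambda.1se; falling back to top-10 at lambda.min")
    imp <- importance_at(cv$lambda.min)
    strength <- cv$lambda.min
    selected <- names(sort(imp, decreasing = TRUE))[seq_len(min(10L, length(imp)))]
  }
  ord <- order(-imp, names(imp))
  structure(list(
    ranked = data.frame(feature_name = names(imp)[ord],
                        importance = unname(imp[ord]),
                        stringsAsFactors = FALSE),
    selected = selected,
    regularization_strength = strength,
    folds = folds, seed = seed, cv = cv),
    class = "receptex_ranking")
}

#' @export
print.receptex_ranking <- function(x, ...) {
  cat(sprintf("<feature ranking> %d features, %d selected (lambda = %.4g)\n",
              nrow(x$ranked), length(x$selected),
              x$regularization_strength))
  print(head(x$ranked, 10))
  invisible(x)
}

#' Export a feature ranking as CSV
#'
#' @param ranking a `receptex_ranking`.
#' @param path output path (columns feature_name, importance, selected).
#' @return `path`, invisibly.
#' @export
write_ranking_csv <- function(ranking, path) {
  out <- ranking$ranked
  out$selected <- out$feature_name %in% ranking$selected
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}
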