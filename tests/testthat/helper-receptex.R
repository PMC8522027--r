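# Independent brute-force macro-F1 oracle: per-class tallies straight from
# the definition, no shared code with macro_f1().
oracle_macro_f1 <- function(cm) {
  cm <- unclass(cm)
  classes <- rownames(cm)
  f1s <- c()
  for (cl in classes) {
    support <- sum(cm[cl, ])
    if (support == 0) next
    tp <- cm[cl, cl]
    fp <- sum(cm[, cl]) - tp
    fn <- support - tp
    p <- if (tp + fp > 0) tp / (tp + fp) else 0
    r <- tp / (tp + fn)
    f1 <- if (p + r > 0) 2 * p * r / (p + r) else 0
    f1s <- c(f1s, f1)
  }
  mean(f1s)
}

random_confusion <- function(k) {
  m <- matrix(rpois(k * k, lambda = sample(0:6, 1)), k, k)
  if (sum(m) == 0) m[sample(k, 1), sample(k, 1)] <- 1
  dimnames(m) <- list(paste0("c", 1:k), paste0("c", 1:k))
  m
}

tiny_report <- function(id, text, ...) report(id, text, ...)

# minimal single-concept lexicon for precise feature unit tests
mini_lexicon <- function(rows) {
  path <- tempfile(fileext = ".tsv")
  header <- "concept_id\tscope\ttask\tlabel\tpattern"
  writeLines(c(header, rows), path, useBytes = TRUE)
  read_lexicon(path)
}

small_grid <- function() {
  g <- default_grid()
  keep <- vapply(g, function(s) {
    (s$family == "random_forest" && s$n_trees == 100) ||
    (s$family == "svm" && s$kernel == "linear" && s$cost == 1) ||
    (s$family == "multinomial_logistic") ||
    (s$family == "decision_tree" && s$max_depth == 5) ||
    (s$family == "knn" && s$k == 5)
  }, TRUE)
  g[keep]
}
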