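separable_data <- function(n = 60, seed = 1) {
  set.seed(seed)
  y <- rep(c("A", "B"), each = n / 2)
  x <- cbind(f1 = ifelse(y == "A", 1, -1) + rnorm(n, sd = 0.05),
             f2 = rnorm(n))
  list(x = x, y = y)
}

test_that("each kNN grid value yields one candidate model", {
  d <- separable_data()
  grid <- default_grid("knn")
  expect_length(grid, 7L)
  expect_setequal(vapply(grid, `[[`, 0L, "k"), c(1L, 3L, 5L, 9L, 15L, 30L, 45L))
  models <- train_candidates(d$x, d$y, grid, seed = 1)
  expect_length(models, 7L)
})

test_that("a linear SVM separates linearly separable classes perfectly", {
  d <- separable_data()
  grid <- list(list(family = "svm", kernel = "linear", cost = 1))
  m <- train_candidates(d$x, d$y, grid, seed = 1)[[1]]
  pred <- receptex:::predict_model(m, d$x)
  f1 <- macro_f1(confusion_matrix(d$y, pred, c("A", "B")))
  expect_equal(f1, 1)
})

test_that("per-spec failures are recorded, and all-fail raises an error", {
  d <- separable_data()
  x1 <- d$x[1, , drop = FALSE]; y1 <- d$y[1]
  expect_error(
    suppressWarnings(train_candidates(x1, y1,
                                      default_grid("random_forest"), 1)),
    "all classifier specs failed")
  mixed_grid <- c(default_grid("knn")[1],
                  list(list(family = "svm", kernel = "linear", cost = 1)))
  expect_warning(models <- train_candidates(d$x[1:3, ], d$y[c(1, 1, 2)],
                                            mixed_grid, 1),
                 "failed")
  expect_gte(length(models), 1L)
})

test_that("the multinomial-logistic path expands into per-lambda candidates", {
  d <- separable_data(n = 80)
  models <- train_candidates(d$x, d$y,
                             default_grid("multinomial_logistic"), 1)
  expect_gt(length(models), 1L)
  expect_true(all(vapply(models, function(m)
    m$family == "multinomial_logistic", TRUE)))
})

test_that("model selection takes the argmax and breaks ties by fewer features", {
  d <- separable_data(n = 40, seed = 3)
  schema <- c("A", "B")
  m_good <- train_candidates(d$x, d$y,
    list(list(family = "svm", kernel = "linear", cost = 1)), 1)[[1]]
  set.seed(4)
  y_rand <- sample(d$y)  # mislabeled copy trains a bad model
  m_bad <- train_candidates(d$x, y_rand,
    list(list(family = "svm", kernel = "linear", cost = 1)), 1)[[1]]
  best <- select_best_model(list(m_bad, m_good), d$x, d$y, schema)
  expect_identical(best$model$fit, m_good$fit)

  # exact tie: same family/score, one model sees fewer features
  m_small <- train_candidates(d$x[, 1, drop = FALSE], d$y,
    list(list(family = "knn", k = 1)), 1)[[1]]
  m_large <- train_candidates(d$x, d$y,
    list(list(family = "knn", k = 1)), 1)[[1]]
  tie <- select_best_model(list(m_large, m_small), d$x, d$y, schema)
  expect_length(tie$model$feature_names, 1L)

  single <- select_best_model(list(m_good), d$x, d$y, schema)
  expect_identical(single$model$fit, m_good$fit)
})

test_that("self-training with no unlabeled data returns the base unchanged", {
  d <- separable_data()
  base <- train_candidates(d$x, d$y,
    list(list(family = "decision_tree", max_depth = 3)), 1)[[1]]
  out <- self_train(base, d$x[0, , drop = FALSE], d$x, d$y)
  expect_identical(out, base)
  expect_false(out$self_trained)
})

test_that("self-training pseudo-labels match base predictions and flag the refit", {
  d <- separable_data(n = 80, seed = 5)
  base <- train_candidates(d$x, d$y,
    list(list(family = "random_forest", n_trees = 100)), 1)[[1]]
  pseudo_expected <- receptex:::predict_model(base, d$x)
  st <- self_train(base, d$x, d$x, d$y)
  expect_true(st$self_trained)
  expect_identical(st$family, base$family)
  expect_identical(st$params, base$params)
  # with unlabeled copies of training data, the refit saw y + pseudo(y)
  expect_identical(pseudo_expected, receptex:::predict_model(base, d$x))
})

test_that("prediction is deterministic for a fixed fitted model", {
  d <- separable_data()
  for (fam in list(list(family = "knn", k = 3),
                   list(family = "random_forest", n_trees = 100))) {
    m <- train_candidates(d$x, d$y, list(fam), 1)[[1]]
    p1 <- receptex:::predict_model(m, d$x)
    p2 <- receptex:::predict_model(m, d$x)
    expect_identical(p1, p2)
  }
})
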