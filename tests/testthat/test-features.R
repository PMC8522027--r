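features_for <- function(text, config = feature_config()) {
  st <- report_structure(text)
  m <- match_concepts(st, config$lexicon)
  seg <- isolate_segments(st, m)
  list(st = st, m = m, seg = seg,
       regex = regex_match_features(m, config$lexicon, seg),
       loc = location_features(m, st, config$lexicon),
       num = numeric_value_features(st, m, config$lexicon, seg))
}

test_that("regex features count and flag concept matches", {
  f <- features_for("RE positif. RP positif.")
  expect_equal(unname(f$regex["regex.report.positive_term.count"]), 2)
  expect_equal(unname(f$regex["regex.report.positive_term.presence"]), 1)
  f0 <- features_for("Geen maligniteit.")
  expect_equal(unname(f0$regex["regex.report.positive_term.count"]), 0)
  expect_equal(unname(f0$regex["regex.report.positive_term.presence"]), 0)
})

test_that("location features give absolute/relative positions and -1 sentinels", {
  lex <- mini_lexicon("foo\tsentence\t\t\tfoo")
  text <- paste0(strrep("x", 10), "foo", strrep("x", 67), "foo",
                 strrep("x", 17))  # 100 chars, matches at offsets 10 and 80
  st <- report_structure(text)
  m <- match_concepts(st, lex)
  loc <- location_features(m, st, lex)
  expect_equal(unname(loc["loc.report.foo.first_abs"]), 10)
  expect_equal(unname(loc["loc.report.foo.last_abs"]), 80)
  expect_equal(unname(loc["loc.report.foo.first_rel"]), 0.1)
  expect_equal(unname(loc["loc.report.foo.last_rel"]), 0.8)
  # absent concept
  lex2 <- mini_lexicon(c("foo\tsentence\t\t\tfoo", "bar\tsentence\t\t\tbar"))
  loc2 <- location_features(match_concepts(st, lex2), st, lex2)
  expect_equal(unname(loc2["loc.report.bar.first_abs"]), -1)
  expect_equal(unname(loc2["loc.report.bar.last_rel"]), -1)
})

test_that("location features ignore trailing whitespace", {
  t1 <- "ER: positief"
  fa <- features_for(t1)$loc
  fb <- features_for(paste0(t1, "   "))$loc
  expect_equal(fa[grep("_abs$", names(fa))], fb[grep("_abs$", names(fb))])
})

test_that("numeric values parse with ranges, sentinels and presence flags", {
  f <- features_for("ER positief. Allred score: 8/8.")
  expect_equal(unname(f$num["num.report.allred.value"]), 8)
  expect_equal(unname(f$num["num.report.allred.present"]), 1)

  f2 <- features_for("HER2: 2+. FISH: ratio HER2/CEP17: 1.2")
  expect_equal(unname(f2$num["num.report.ratio.value"]), 1.2)
  expect_equal(unname(f2$num["num.report.ihc_score.value"]), 2)

  # decimal comma tolerance
  f3 <- features_for("pas d'amplification (ratio 1,4)")
  expect_equal(unname(f3$num["num.report.ratio.value"]), 1.4)

  # out-of-range H-score is discarded with a warning
  expect_warning(f4 <- features_for("H-score 350"), "out-of-range")
  expect_equal(unname(f4$num["num.report.hscore.value"]), -1)
  expect_equal(unname(f4$num["num.report.hscore.present"]), 0)
})

test_that("jaccard similarity follows the shared-over-union definition", {
  a <- tokenize_words("CerB2 négatif")$norm
  b <- tokenize_words("CerB2 positif")$norm
  expect_equal(jaccard_similarity(a, a), 1)
  expect_equal(jaccard_similarity(a, b), 1 / 3)
  expect_equal(jaccard_similarity(a, tokenize_words("ratio 1.2")$norm), 0)
  expect_equal(jaccard_similarity(character(), character()), 0)
})

test_that("jaccard is symmetric and bounded on random token sets", {
  set.seed(42)
  vocab <- c("er", "pr", "her2", "positief", "negatief", "score", "ratio",
             "fish", "allred", "controle")
  for (i in 1:50) {
    a <- sample(vocab, sample(0:6, 1))
    b <- sample(vocab, sample(1:6, 1))
    j <- jaccard_similarity(a, b)
    expect_equal(j, jaccard_similarity(b, a))
    expect_gte(j, 0); expect_lte(j, 1)
  }
})

test_that("jaccard features take the max over report sentences", {
  refs <- reference_sentences()
  st <- report_structure("Mammabiopsie.\nCerB2 négatif.\nHER2: 0")
  jf <- jaccard_features(st, refs)
  expect_equal(unname(jf["jac.ref_cerb2_neg"]), 1)
  st0 <- report_structure("qqq www zzz")
  expect_true(all(jaccard_features(st0, refs) == 0))
})

test_that("boolean combinations evaluate strict dominance and fail on unknown features", {
  combos <- read_combos()
  base <- setNames(numeric(0), character())
  mk <- function(c0, c1, c2, c3) {
    v <- c(c0, c1, c2, c3)
    names(v) <- sprintf("regex.report.ihc_score_%d.count", 0:3)
    v
  }
  dom <- function(v) {
    combo <- combos[combos$name == "zero_dominates", ]
    unname(boolean_combination_features(v, combo))
  }
  expect_equal(dom(mk(2, 0, 1, 0)), 1)
  expect_equal(dom(mk(1, 0, 0, 1)), 0)  # tie is not strict dominance
  expect_equal(dom(mk(0, 0, 0, 0)), 0)
  expect_error(boolean_combination_features(mk(1, 0, 0, 0)[1:2],
                                            combos[combos$name == "zero_dominates", ]),
               "unknown feature")
})

test_that("meta logistic features are sigmoids of linear scores", {
  spec0 <- list(name = "meta.t.a", input_feature_names = c("f1", "f2"),
                intercept = 0, coefficients = c(0, 0))
  base <- c(f1 = 0, f2 = 0)
  expect_equal(unname(meta_logistic_features(base, list(spec0))), 0.5)
  spec1 <- list(name = "meta.t.b", input_feature_names = c("f1", "f2"),
                intercept = 0, coefficients = c(2, -1))
  expect_equal(unname(meta_logistic_features(c(f1 = 1, f2 = 1), list(spec1))),
               1 / (1 + exp(-1)))
  spec_big <- list(name = "meta.t.c", input_feature_names = "f1",
                   intercept = 1e6, coefficients = 0)
  v <- meta_logistic_features(c(f1 = 0, f2 = 0), list(spec_big))
  expect_true(v > 0 && v < 1 && is.finite(v))
  expect_error(meta_logistic_features(c(zz = 1), list(spec1)),
               "missing input")
})

test_that("normalization learns train constants and never refits", {
  m <- cbind(a = c(3, 7), b = c(5, 5))
  const <- fit_normalization(m)
  expect_equal(unname(const$center), c(5, 5))
  expect_equal(unname(const$scale["b"]), 1)  # zero-variance fallback
  norm <- apply_normalization(m, const)
  expect_equal(unname(norm[, "b"]), c(0, 0))
  # (9 - 5) / 2 = 2 with train mean 5, sd 2
  m2 <- cbind(a = c(3, 5, 7))
  c2 <- fit_normalization(m2)
  expect_equal(as.numeric(apply_normalization(cbind(a = 9), c2)), 2)
  # applying to validation uses the same constants object untouched
  before <- c2
  invisible(apply_normalization(cbind(a = c(100, 200)), c2))
  expect_identical(c2, before)
})

test_that("normalized training features have mean 0 and sd 1", {
  g <- generate_corpus(generator_config(n_reports = 60, seed = 21))
  mat <- build_feature_matrix(g$reports)
  const <- fit_normalization(mat)
  norm <- apply_normalization(mat, const)
  keep <- apply(mat, 2, sd) > 0
  expect_lt(max(abs(colMeans(norm[, keep]))), 1e-9)
  expect_lt(max(abs(apply(norm[, keep], 2, sd) - 1)), 1e-9)
})

test_that("the feature matrix is deterministic, name-stable and finite", {
  g <- generate_corpus(generator_config(n_reports = 30, seed = 31,
                                        heterogeneity = "high"))
  m1 <- build_feature_matrix(g$reports)
  m2 <- build_feature_matrix(g$reports)
  expect_identical(m1, m2)
  expect_true(all(is.finite(m1)))
  # same name sequence for every report, namespaced by family
  expect_true(any(grepl("^regex\\.report\\.", colnames(m1))))
  expect_true(any(grepl("^regex\\.seg_her2\\.", colnames(m1))))
  expect_true(any(grepl("^loc\\.", colnames(m1))))
  expect_true(any(grepl("^num\\.", colnames(m1))))
  expect_true(any(grepl("^jac\\.", colnames(m1))))
  expect_true(any(grepl("^combo\\.", colnames(m1))))
})

test_that("feature matrices export to CSV with report ids", {
  g <- generate_corpus(generator_config(n_reports = 5, seed = 3,
                                        heterogeneity = "clean"))
  m <- build_feature_matrix(g$reports)
  path <- tempfile(fileext = ".csv")
  write_feature_matrix_csv(m, path)
  tab <- read.csv(path, check.names = FALSE)
  expect_equal(tab$report_id, rownames(m))
  expect_equal(ncol(tab), ncol(m) + 1L)
})

test_that("vocabulary respects min document frequency and feeds word counts", {
  texts <- c("positief positief score", "positief score", "score",
             "negatief")
  sts <- lapply(texts, report_structure)
  vocab <- build_vocabulary(sts, min_df = 2L)
  expect_true(all(c("score", "positief") %in% vocab$norm))
  expect_false("negatief" %in% vocab$norm)
  wc <- word_count_features(sts[[1]], vocab)
  expect_equal(unname(wc[vocab$feature_name[vocab$norm == "positief"]]), 2)
  # uppercase counts toward the folded normal form
  wc_up <- word_count_features(report_structure("POSITIEF"), vocab)
  expect_equal(unname(wc_up[vocab$feature_name[vocab$norm == "positief"]]), 1)
})
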