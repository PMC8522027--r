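test_that("generation is deterministic for a fixed seed", {
  g1 <- generate_corpus(generator_config(n_reports = 50, seed = 12))
  g2 <- generate_corpus(generator_config(n_reports = 50, seed = 12))
  expect_identical(g1$reports, g2$reports)
  expect_identical(g1$manifest, g2$manifest)
  g3 <- generate_corpus(generator_config(n_reports = 50, seed = 13))
  expect_false(identical(g1$reports, g3$reports))
})

test_that("the language mix is honored at the extremes", {
  g <- generate_corpus(generator_config(
    n_reports = 40, seed = 2,
    language_mix = c(nl = 1, fr = 0, mixed = 0)))
  expect_true(all(vapply(g$reports, `[[`, "", "language_hint") == "nl"))
})

test_that("probability groups must sum to one", {
  expect_error(generator_config(language_mix = c(nl = 0.5, fr = 0.2,
                                                 mixed = 0.2)),
               "sum to 1")
  expect_error(generator_config(style_mix = c(bullet = 1.2,
                                              narrative = -0.2)),
               "negative")
})

test_that("the uppercase noise operator leaves only uppercase text", {
  g <- generate_corpus(generator_config(
    n_reports = 25, seed = 3,
    noise = c(none = 0, uppercase_all = 1, strip_linebreaks = 0,
              strip_punctuation = 0, misspelling = 0)))
  for (r in g$reports)
    expect_identical(r$text, stringi::stri_trans_toupper(r$text))
})

test_that("realized label frequencies sit within 3 sigma of the config", {
  n <- 4000
  cfg <- generator_config(n_reports = n, seed = 17)
  g <- generate_corpus(cfg)
  for (task in c("ER", "PR", "HER2_IHC")) {
    gold <- vapply(g$reports, function(r) r$labels[[task]], "")
    for (lab in names(cfg$label_distribution[[task]])) {
      p <- cfg$label_distribution[[task]][[lab]]
      tol <- 3 * sqrt(p * (1 - p) / n)
      expect_lt(abs(mean(gold == lab) - p), tol + 0.01)
    }
  }
  # ISH distribution is conditional on an eligible IHC score (2+/3+)
  ihc <- vapply(g$reports, function(r) r$labels$HER2_IHC, "")
  ish <- vapply(g$reports, function(r) r$labels$HER2_ISH, "")
  eligible <- ihc %in% c("2+", "3+")
  n_el <- sum(eligible)
  for (lab in names(cfg$label_distribution$HER2_ISH)) {
    p <- cfg$label_distribution$HER2_ISH[[lab]]
    tol <- 3 * sqrt(p * (1 - p) / n_el)
    expect_lt(abs(mean(ish[eligible] == lab) - p), tol + 0.01)
  }
})

test_that("ISH results only accompany equivocal or positive IHC", {
  g <- generate_corpus(generator_config(n_reports = 800, seed = 23))
  for (r in g$reports) {
    if (r$labels$HER2_ISH %in% c("Negative", "Equivocal", "Positive"))
      expect_true(r$labels$HER2_IHC %in% c("2+", "3+"))
  }
})

test_that("all-Unknown reports mention no biomarker results", {
  cfg <- generator_config(
    n_reports = 20, seed = 5, heterogeneity = "clean",
    label_distribution = list(
      ER = c(Unknown = 1, Negative = 0, Positive = 0),
      PR = c(Unknown = 1, Negative = 0, Positive = 0),
      HER2_IHC = c(Unknown = 1, `0` = 0, `1+` = 0, `2+` = 0, `3+` = 0),
      HER2_ISH = c(CarriedOutNoResult = 0.08, Negative = 0.45,
                   Equivocal = 0.12, Positive = 0.35)))
  g <- generate_corpus(cfg)
  for (r in g$reports) {
    m <- match_concepts(report_structure(r))
    expect_false(any(c("er_mention", "pr_mention", "her2_mention") %in%
                       m$concept_id))
    for (task in biomarker_tasks())
      expect_equal(r$labels[[task]], "Unknown")
  }
})

test_that("the manifest records realized counts and operator frequencies", {
  g <- generate_corpus(generator_config(n_reports = 120, seed = 31))
  man <- g$manifest
  expect_equal(man$n_reports, 120L)
  expect_equal(sum(unlist(man$label_counts$ER)), 120L)
  expect_equal(sum(unlist(man$noise_frequencies)), 120L)
  expect_true(all(g$provenance$multi_tumor ==
                    (g$provenance$decoy == "multi_tumor")))
})

test_that("clean generated reports are recovered by the rule-based parser", {
  g <- generate_corpus(generator_config(n_reports = 400, seed = 41,
                                        heterogeneity = "clean"))
  st <- lapply(g$reports, report_structure)
  for (task in biomarker_tasks()) {
    gold <- vapply(g$reports, function(r) r$labels[[task]], "")
    pred <- rule_based_classify(g$reports, task, structures = st)
    expect_gte(mean(gold == pred), 0.99)
  }
})
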