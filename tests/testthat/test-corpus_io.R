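test_that("label schemas carry the fixed category sets", {
  expect_identical(biomarker_tasks(), c("ER", "PR", "HER2_IHC", "HER2_ISH"))
  expect_identical(label_schema("ER"), c("Unknown", "Negative", "Positive"))
  expect_identical(label_schema("PR"), c("Unknown", "Negative", "Positive"))
  expect_identical(label_schema("HER2_IHC"),
                   c("Unknown", "0", "1+", "2+", "3+"))
  expect_identical(label_schema("HER2_ISH"),
                   c("Unknown", "CarriedOutNoResult", "Negative", "Equivocal",
                     "Positive"))
})

test_that("report records validate labels against their schema", {
  expect_error(report("r1", "ER: +", labels = list(ER = "POS")),
               "not in ER schema")
  expect_error(report("r1", "   "), "non-empty")
  r <- report("r1", "RE négatif", language_hint = "fr",
              labels = list(ER = "Negative"))
  expect_s3_class(r, "receptex_report")
})

test_that("corpus JSONL round-trips exactly, including diacritics", {
  reports <- list(
    report("a", "RE: négatifs (Allred 2/8)", "fr", list(ER = "Negative")),
    report("b", "ER: +\nPR: -", "nl",
           list(ER = "Positive", PR = "Negative")),
    report("c", "FISH wordt uitgevoerd", "nl",
           list(HER2_ISH = "CarriedOutNoResult"), train_only = TRUE))
  path <- tempfile(fileext = ".jsonl")
  write_corpus(reports, path)
  back <- read_corpus(path)
  expect_equal(back, reports)
  expect_identical(back[[1]]$text, "RE: négatifs (Allred 2/8)")
  expect_true(back[[3]]$train_only)
})

test_that("round-trip holds for a synthetic corpus and for an empty one", {
  g <- generate_corpus(generator_config(n_reports = 100, seed = 9))
  path <- tempfile(fileext = ".jsonl")
  write_corpus(g$reports, path)
  expect_equal(read_corpus(path), g$reports)

  empty <- tempfile(fileext = ".jsonl")
  write_corpus(list(), empty)
  expect_identical(read_corpus(empty), list())
})

test_that("malformed records and duplicate ids are rejected with location", {
  path <- tempfile(fileext = ".jsonl")
  writeLines(c('{"report_id":"a","text":"ok"}', '{"report_id":"b"'), path)
  expect_error(read_corpus(path), "line 2")
  writeLines(c('{"report_id":"a","text":"ok"}',
               '{"report_id":"a","text":"ok2"}'), path)
  expect_error(read_corpus(path), "duplicate")
  writeLines('{"report_id":"a","text":"x","labels":{"ER":"POS"}}', path)
  expect_error(read_corpus(path), "not in ER schema")
})

test_that("labels export to a flat CSV", {
  reports <- list(report("a", "ER: +", labels = list(ER = "Positive")))
  path <- tempfile(fileext = ".csv")
  write_labels_csv(reports, path)
  tab <- read.csv(path)
  expect_identical(tab$label, "Positive")
  expect_identical(tab$task, "ER")
})

make_labeled <- function(n, seed = 1) {
  set.seed(seed)
  labs <- sample(c("Unknown", "Negative", "Positive"), n, replace = TRUE,
                 prob = c(0.2, 0.3, 0.5))
  lapply(seq_len(n), function(i)
    report(sprintf("r%04d", i), "ER: +", labels = list(ER = labs[i])))
}

test_that("split respects 60/20/20 with round(0.6N)/round(0.2N)/rest", {
  sp <- split_dataset(make_labeled(1000), "ER", seed = 3)
  expect_length(sp$train_ids, 600)
  expect_length(sp$validation_ids, 200)
  expect_length(sp$test_ids, 200)

  sp5 <- split_dataset(make_labeled(5), "ER", seed = 3)
  expect_length(sp5$train_ids, 3)
  expect_length(sp5$validation_ids, 1)
  expect_length(sp5$test_ids, 1)

  expect_error(split_dataset(make_labeled(4), "ER", 1), "at least 5")
})

test_that("split is deterministic and partitions the labeled ids", {
  reps <- make_labeled(137, seed = 7)
  sp1 <- split_dataset(reps, "ER", seed = 11)
  sp2 <- split_dataset(reps, "ER", seed = 11)
  expect_identical(sp1, sp2)
  for (n in c(7, 23, 50, 101, 137)) {
    reps_n <- make_labeled(n, seed = n)
    sp <- split_dataset(reps_n, "ER", seed = n)
    ids <- c(sp$train_ids, sp$validation_ids, sp$test_ids)
    expect_length(ids, n)
    expect_false(any(duplicated(ids)))
    expect_setequal(ids, vapply(reps_n, `[[`, "", "report_id"))
    expect_length(sp$train_ids, round(0.6 * n))
    expect_length(sp$validation_ids, round(0.2 * n))
  }
})

test_that("splits are stratified by label and honor train_only", {
  reps <- make_labeled(500, seed = 5)
  sp <- split_dataset(reps, "ER", seed = 2)
  labs <- setNames(vapply(reps, function(r) r$labels$ER, ""),
                   vapply(reps, `[[`, "", "report_id"))
  overall <- prop.table(table(labs))
  for (part in list(sp$train_ids, sp$validation_ids, sp$test_ids)) {
    frac <- prop.table(table(labs[part]))
    expect_true(all(abs(frac - overall[names(frac)]) < 0.05))
  }

  extra <- list(report("extra1", "FISH: equivocaal (ratio 2.0)",
                       labels = list(ER = "Positive"), train_only = TRUE))
  sp2 <- split_dataset(c(reps, extra), "ER", seed = 2)
  expect_true("extra1" %in% sp2$train_ids)
  expect_false("extra1" %in% c(sp2$validation_ids, sp2$test_ids))
})
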