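# receptex

Machine-learning extraction of breast cancer receptor status — estrogen
receptor (ER), progesterone receptor (PR), HER2 by immunohistochemistry
(IHC) and HER2 by in-situ hybridization (ISH) — from free-text Dutch and
French pathology reports, as handled by population-based cancer registries.

Registry corpora are heterogeneous: two languages (sometimes mixed in one
report), synonym and abbreviation variants (HER2, ERBB2, Cerb-B2, Her2/neu,
Neu, CerB2…), bullet lists versus narrative prose, missing punctuation or
line breaks, all-uppercase text, and confusable content (HER2 IHC control
results, IHC for other biomarkers, "ISH ongoing" statements, multi-tumor
reports). `receptex` addresses this with feature-based classical machine
learning rather than hand-written rules.

## What it does

Each report is decomposed into lines, sentences and offset-tracked word
tokens, matched against a curated bilingual concept lexicon, and segmented
into ER-, PR- and HER2-related blocks by anchor repetition. Seven numeric
feature families are extracted per report r:

* regex concept presence/counts, on the whole report and per segment;
* absolute and relative match locations (decisive information clusters at
  the end of a report);
* clinical numeric values: Allred (0–8), H-score (0–300), % positive cells,
  IHC score, HER2/CEP17 ratio, copy number — with presence flags;
* word counts over a training vocabulary;
* Jaccard similarities max_s J(s, s_ref) = |s ∩ s_ref| / |s ∪ s_ref| to
  reference sentences such as "CerB2 négatif";
* Boolean AND/OR combinations (e.g. #("0") > max #("1+"), #("2+"), #("3+"));
* logistic-regression scores of regex-count features.

Features are z-scored with training-set constants, ranked and selected by
the coefficients of a cross-validated L1 multinomial logistic regression
(`glmnet`), and fed to a grid of classifiers: random forests, SVMs (four
kernels), regularized multinomial logistic regression, classification trees
(depth 2–10) and k-NN (k = 1…45), with optional one-pass self-training on
unlabeled reports. Per task, the model with the highest **macro-averaged
F1** (mean over classes with gold support of 2PR/(P+R), zero-denominator
convention 0) on the validation split is selected and evaluated once on the
held-out test split, next to a last-match rule-based baseline.

Because real registry data are confidential, the package ships a synthetic
report generator (`generate_corpus()`) that reproduces the documented
heterogeneity with gold labels consistent by construction, so the entire
pipeline is trainable, testable and auditable. See the methods vignette
(`vignettes/receptor-extraction.Rmd`) for the model, parameters and design
choices.

## Worked example

```r
library(receptex)
g <- generate_corpus(generator_config(n_reports = 1500, seed = 101))
flagged <- g$provenance$report_id[g$provenance$multi_tumor]
pl <- run_pipeline(g$reports, seed = 101, exclude_ids = flagged)
print(pl)
```

```
<receptex pipeline>
  ER       best = svm | validation F1 = 0.995 | test F1 = 0.973 | rule-based F1 = 0.837
  PR       best = svm | validation F1 = 1.000 | test F1 = 0.990 | rule-based F1 = 0.839
  HER2_IHC best = svm | validation F1 = 1.000 | test F1 = 1.000 | rule-based F1 = 0.859
  HER2_ISH best = random_forest | validation F1 = 1.000 | test F1 = 1.000 | rule-based F1 = 0.967
```

Reading this: on a 1,500-report synthetic corpus (60/20/20 split; ~300 test
reports per task) the selected classifiers recover report-level labels with
held-out macro-F1 0.97–1.00, well above the rule-based baseline — the gap
widens sharply on the high-heterogeneity generator preset, where unusual
value-only phrasings ("ER: Allred 8/8", "HercepTest: 2+", bare ISH ratios)
defeat label-linked patterns but not the feature system. Predictions for
new reports:

```r
predict_labels(pl$ER, list(report("new", "ER: positief\nPR: -\nHER2: 0")))
#>        new
#> "Positive"
```

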