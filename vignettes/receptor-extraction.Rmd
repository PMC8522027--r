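---
title: "Extracting breast cancer receptor status from bilingual pathology reports"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Extracting breast cancer receptor status from bilingual pathology reports}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(receptex)
```

## The problem

Population-based cancer registries receive free-text pathology reports from
dozens of laboratories. For breast cancer, three biomarkers drive prognosis
and therapy: the estrogen receptor (ER), the progesterone receptor (PR) and
HER2/ERBB2. HER2 status is assessed in two complementary ways:
semi-quantitative immunohistochemistry (IHC, scored 0 / 1+ / 2+ / 3+) and,
for equivocal or positive IHC, in-situ hybridization (ISH), reported through
the HER2/CEP17 ratio and gene copy number. `receptex` turns each report into
four report-level classifications:

* **ER**, **PR**: Unknown / Negative / Positive;
* **HER2_IHC**: Unknown / 0 / 1+ / 2+ / 3+;
* **HER2_ISH**: Unknown / CarriedOutNoResult / Negative / Equivocal /
  Positive ("CarriedOutNoResult" marks reports stating a test was performed
  without transmitting its result).

The corpus this pipeline targets is heterogeneous in ways that defeat simple
rule systems: reports in Dutch or French (occasionally both in one report),
synonym and abbreviation variants (HER2, ERBB2, Cerb-B2, Her2/neu, Neu,
CerB2 …), bullet-point versus narrative style, absent punctuation or line
breaks, all-uppercase text, and confusable content such as HER2 IHC control
results (a positive control reads 3+, a negative one 0 or 1+), IHC results
for other biomarkers (Ki-67, p53), "ISH ongoing" statements and multi-tumor
reports.

## The procedure

1. **Pre-processing** (`report_structure()`): a report is split into lines
   at line breaks, lines into sentences at terminal punctuation (`. ? ! ;`
   followed by whitespace; decimal numbers and a configurable abbreviation
   list are protected), and sentences into word tokens (maximal runs of
   letters, digits and `+`, so `3+` is atomic). Every span carries 0-based
   character offsets into the original text. Matching uses a lower-cased,
   diacritic-folded view; stored text is never altered.

2. **Concept matching** (`match_concepts()`): a curated bilingual lexicon
   (`default_lexicon()`, ~46 pattern records) maps surface variants to
   concepts: biomarker mentions, polarity terms, IHC scores, ISH vocabulary,
   control and ongoing phrases, negations, numeric value extractors, plus
   label-linked patterns used only by the rule-based baseline. The lexicon
   is data, not code: registries can extend it with `merge_lexicons()`.

3. **Segment isolation** (`isolate_segments()`): ER, PR and HER2 results
   typically follow one another with a repeated structure, so each
   biomarker-mention anchor opens a segment running to the next anchor (or
   two sentences past its own). Features are extracted on the whole report
   *and* within these segments, which keeps one biomarker's polarity words
   from contaminating another's features.

4. **Features** (`build_feature_matrix()`), seven families: regex presence
   and counts per scope; first/last absolute and relative match locations
   (decisive information tends to sit at the end of a report, history and
   test indication at the beginning); clinical numeric values (Allred 0–8,
   H-score 0–300, percent positive cells, last IHC score, HER2/CEP17 ratio,
   copy number — each with a presence flag and a `-1` sentinel because such
   values are not systematically provided); word counts over a training
   vocabulary; maximal Jaccard similarity of report sentences to reference
   sentences (unusual but decisive phrasings such as "CerB2 négatif");
   Boolean combinations (e.g. whether "0" occurs strictly more often than
   "1+", "2+" or "3+"); and per-label logistic scores over the regex count
   family. Features are z-scored with constants learned on the training
   partition (zero-variance features get scale 1): the families are of very
   different magnitudes and unscaled they slow and destabilize training.

5. **Selection** (`rank_and_select()`): an L1-penalized multinomial
   logistic regression is fitted over a regularization path with stratified
   10-fold cross-validation on the training set; a feature's importance is
   its maximum absolute coefficient across classes at the one-standard-error
   lambda (the parsimonious choice, in line with the goal of avoiding
   overfitting). Selected features are those with non-zero importance; an
   empty selection falls back to the top 10 at the minimum-deviance lambda.

6. **Training** (`train_candidates()`): random forests (100/300/500 trees),
   SVMs (linear, radial, polynomial, sigmoid kernels; C in 0.1/1/10; radial
   gamma 0.01/0.1; polynomial degree 2/3), multinomial logistic regression
   along a 20-point lambda path, classification trees of depth 2–10, and
   k-NN with k = 1, 3, 5, 9, 15, 30, 45. Optional **self-training**
   (`self_train()`): the selected model pseudo-labels unlabeled reports and
   is refitted once on the enlarged set, keeping all pseudo-labels; the
   refit is retained per task only if it improves validation macro-F1.

7. **Evaluation** (`macro_f1()`): macro-averaged F1 with an explicit
   convention — per-class F1 is 0 when its denominator is 0, and the macro
   average runs over classes with gold support > 0. This makes the analytic
   limits literal: a perfect classifier scores 1, a systematically wrong one
   scores 0, and every label is penalized equally regardless of prevalence,
   which matters under the severe label imbalance (ISH "Equivocal" is
   rare). The model with the highest validation macro-F1 is selected (ties:
   fewer features, then a fixed family order, then lexicographic
   hyperparameters) and test metrics are computed exactly once, after
   selection. A **rule-based baseline** (`rule_based_classify()`) assigns
   the label of the last label-linked pattern match in the report.

## The synthetic corpus

Real registry corpora are confidential, so `generate_corpus()` produces
fictive labeled Dutch/French reports reproducing the documented
heterogeneity. Design points worth knowing:

* **Gold labels are consistent with the rendered phrases by construction**,
  and noise operators never change a gold label. An ISH result block is
  rendered only for IHC 2+ or 3+; an ongoing-ISH statement with a lower IHC
  score makes the gold ISH label "CarriedOutNoResult".
* **Probability groups** (language, style, phrasing, noise, decoy) each sum
  to one and draw a single option per report. The `default` preset is the
  study condition: 55% Dutch / 40% French / 5% mixed; half bullet, half
  narrative; 45% of reports carry one noise operator (all-uppercase,
  stripped line breaks, stripped punctuation, or a misspelling drawn from a
  curated list that includes "CerB2"); 65% carry one decoy (control block,
  other-biomarker IHC, ongoing-ISH, history preamble, or a flagged
  multi-tumor report). Label frequencies are positive-heavy for ER/PR and
  make ISH "Equivocal" rare, qualitatively mirroring registry data; the
  exact real frequencies are not published as numbers, so these defaults
  are configuration, not claims.
* **Unusual phrasings** (10% of reports by default, 30% under the `high`
  preset, absent from `clean`) report a result only through a numeric value
  or a lab-kit name — "ER: Allred 8/8", "HercepTest: 2+", "FISH ratio:
  1.4" — decisive for a reader, but invisible to label-linked patterns.
  This reproduces the documented weakness of rule-based classification on
  heterogeneous corpora, and is exactly the kind of sentence the Jaccard
  reference list and numeric-value features exist for.
* **Multi-tumor reports** (two result blocks with different labels) carry
  the labels of the first, index tumor, and are flagged; the pipeline drops
  them before splitting, as a registry detects and discards such reports.
* The `clean` preset (no noise, no decoys, standard phrasing) is the mutual
  audit regime: the rule-based baseline must recover ≥ 99% of gold labels
  there, which checks the templates and the lexicon against each other.

What the generator does **not** emulate: laboratory-specific templates,
patient-level longitudinal structure, genuinely free clinical narrative and
annotation error. Passing tests on generated corpora therefore show that
the pipeline machinery is correct and that the feature system can exploit
the documented phenomena; they do not certify performance on any real
registry corpus.

## Numerical and design choices

* **Split protocol**: 60/20/20 with `|train| = round(0.6N)`,
  `|validation| = round(0.2N)`, test the remainder; stratified by label via
  largest-remainder allocation so the global sizes stay exact (0.6N and
  0.2N can never land on .5, so rounding is unambiguous). Records flagged
  `train_only` (supplementary annotations for rare classes) always join the
  training partition.
* **Leakage discipline**: `fit_task_models()` sees only training records;
  deleting validation/test records before fitting leaves every fitted
  artifact byte-identical (this is asserted in the test suite).
* **Determinism**: a single root seed fans out to named substreams (split,
  CV folds, each classifier fit, generator); k-NN tie-breaking is seeded at
  prediction time.
* **Sentinels over imputation**: absent numeric values use -1 plus a
  presence flag, letting tree/margin models learn absence rather than
  hiding it behind an imputed mean.
* **Meta logistic features** use ridge (lambda = 0.05) one-vs-rest fits
  over the regex-count family only — the minimal faithful reading of
  "logistic regressions of features" as a feature family.
* **Vocabulary**: training normal forms with document frequency ≥ 3,
  capped at 2,000 — word counts are deliberately weak here (a perfectly
  predictive Dutch word is absent from French reports), the cap bounds
  dimensionality.
* **Problem sizes**: the packaged experiments use a 1,500-report corpus
  (train ≈ 900) for the end-to-end study, 900 reports for the
  high-heterogeneity baseline comparison and 2,000 for the clean audit;
  these sizes give stable macro-F1 estimates for 3–5-class tasks at desk
  scale.

## Worked example

```{r example, eval = FALSE}
g <- generate_corpus(generator_config(n_reports = 1500, seed = 101))
flagged <- g$provenance$report_id[g$provenance$multi_tumor]
pl <- run_pipeline(g$reports, seed = 101, exclude_ids = flagged)
print(pl)
predict_labels(pl$ER, list(report("new", "ER: positief\nPR: -\nHER2: 0")))
```

The acceptance script (`scripts/acceptance.R`, see the README) reruns this
experiment from scratch and writes the headline numbers as JSON.

## Known limitations

* Short abbreviations are ambiguous: "ER" is also a Dutch adverb and "RE"
  appears in French prose. The label-linked patterns require a nearby
  polarity term, and gap tempering stops at other biomarker mentions and
  at commas, but pathological sentences can still misfire — the real
  registry lexicon faces the same ambiguity.
* The lexicon is a functional reconstruction (~46 pattern records covering
  the documented concept inventory), not a reproduction of any registry's
  production pattern set (thousands of regexes); coverage on real reports
  would need lexicon growth, which `merge_lexicons()` supports.
* Patient/tumor-level label merging across multiple reports is out of
  scope, as are deep-learning classifiers.
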