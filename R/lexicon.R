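#' Read a concept lexicon file
#'
#' A lexicon is a tab-separated file with columns `concept_id`, `scope`
#' (`report` or `sentence`), `task`, `label` and `pattern` (an ICU regular
#' expression written against case- and diacritic-folded text). Rows with a
#' non-empty `task`/`label` are label-linked patterns used by the rule-based
#' baseline; rows whose `concept_id` starts with `val_` carry one capture
#' group and feed numeric value extraction. All patterns are compiled (i.e.
#' test-matched) at load time so malformed patterns fail as configuration
#' errors, never during matching.
#'
#' @param path path to a lexicon TSV.
#' @return a `receptex_lexicon` data.frame.
#' @export
read_lexicon <- function(path) {
  if (!file.exists(path)) stopf("lexicon file not found: %s", path)
  lex <- read.delim(path, sep = "\t", quote = "", comment.char = "#",
                    stringsAsFactors = FALSE, na.strings = NULL,
                    colClasses = "character",
                    fileEncoding = "UTF-8")
  need <- c("concept_id", "scope", "task", "label", "pattern")
  if (!all(need %in% names(lex)))
    stopf("lexicon must have columns: %s", paste(need, collapse = ", "))
  if (any(!lex$scope %in% c("report", "sentence")))
    stopf("lexicon scope must be 'report' or 'sentence'")
  dup <- duplicated(lex[, c("concept_id", "scope", "task", "label")])
  if (any(dup)) stopf("duplicate lexicon entries: %s",
                      paste(unique(lex$concept_id[dup]), collapse = ", "))
  for (i in seq_len(nrow(lex))) {
    ok <- tryCatch({
      stringi::stri_detect_regex("probe text", lex$pattern[i]); TRUE
    }, error = function(e) FALSE)
    if (!ok) stopf("invalid pattern for concept '%s' (row %d)",
                   lex$concept_id[i], i)
    if (nzchar(lex$task[i])) {
      task <- lex$task[i]
      if (!task %in% biomarker_tasks())
        stopf("concept '%s': unknown task '%s'", lex$concept_id[i], task)
      if (!lex$label[i] %in% label_schema(task))
        stopf("concept '%s': label '%s' not in %s schema",
              lex$concept_id[i], lex$label[i], task)
    }
  }
  class(lex) <- c("receptex_lexicon", "data.frame")
  lex
}

#' Built-in bilingual concept lexicon
#'
#' Curated Dutch/French lexicon shipped with the package: biomarker mention
#' synonyms (including ERBB2, Cerb-B2, Her2/neu and standalone Neu), result
#' polarity terms, IHC scores, ISH vocabulary, control and ongoing-test
#' phrases, negations, numeric value extractors and label-linked patterns for
#' the rule-based baseline. User lexicons can merge-override by concept id
#' via [merge_lexicons()].
#'
#' @return a `receptex_lexicon` data.frame.
#' @export
default_lexicon <- function() {
  read_lexicon(system.file("extdata", "lexicon.tsv", package = "receptex"))
}

#' Merge a user lexicon over a base lexicon
#'
#' Rows in `override` replace base rows with the same
#' (`concept_id`, `scope`, `task`, `label`); new rows are appended.
#'
#' @param base,override `receptex_lexicon` objects.
#' @return merged lexicon.
#' @export
merge_lexicons <- function(base, override) {
  key <- function(l) paste(l$concept_id, l$scope, l$task, l$label, sep = "\r")
  out <- rbind(base[!key(base) %in% key(override), , drop = FALSE], override)
  rownames(out) <- NULL
  class(out) <- c("receptex_lexicon", "data.frame")
  out
}

#' Reference sentences for Jaccard similarity features
#'
#' Short sentences, identified on training data as unusual but decisive ways
#' of reporting results (e.g. \code{"CerB2 négatif"}), against which every
#' report sentence is compared by Jaccard similarity.
#'
#' @param path optional TSV with columns `sentence_id`, `language`, `text`;
#'   defaults to the packaged set.
#' @return data.frame with columns `sentence_id`, `language`, `text`.
#' @export
reference_sentences <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "reference_sentences.tsv",
                        package = "receptex")
  refs <- read.delim(path, sep = "\t", quote = "", comment.char = "#",
                     stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  stopifnot(all(c("sentence_id", "language", "text") %in% names(refs)),
            all(nzchar(refs$text)))
  refs
}

fold_sentences <- function(structure) {
  lapply(seq_len(nrow(structure$sentences)), function(i)
    fold_with_map(structure$sentences$text[i]))
}

#' Match lexicon concepts in a report
#'
#' Applies every lexicon pattern to the case/diacritic-folded report (scope
#' `report`) or to each folded sentence (scope `sentence`). Offsets in the
#' result are 0-based indices into the original, unfolded text.
#'
#' @param structure a [report_structure()].
#' @param lexicon a `receptex_lexicon`.
#' @return data.frame with columns `concept_id`, `task`, `label`,
#'   `sentence` (NA for report scope), `start`, `end` (half-open) and `text`
#'   (matched original substring).
#' @export
match_concepts <- function(structure, lexicon = default_lexicon()) {
  match_concepts_corpus(list(structure), lexicon)[[1]]
}

# Corpus-level matcher: one vectorized regex call per pattern across all
# sentences (or all report texts) of all structures.
match_concepts_corpus <- function(structures, lexicon) {
  n_rep <- length(structures)
  folded_reports <- lapply(structures, function(st) fold_with_map(st$text))
  sent_rep <- integer(0); sent_idx <- integer(0); sent_start <- integer(0)
  sent_fold <- vector("list", 0)
  for (r in seq_len(n_rep)) {
    st <- structures[[r]]
    k <- nrow(st$sentences)
    if (!k) next
    sent_rep <- c(sent_rep, rep(r, k))
    sent_idx <- c(sent_idx, seq_len(k))
    sent_start <- c(sent_start, st$sentences$start)
    sent_fold <- c(sent_fold, fold_sentences(st))
  }
  sent_txt <- vapply(sent_fold, `[[`, "", "folded")
  rep_txt <- vapply(folded_reports, `[[`, "", "folded")

  acc <- lapply(seq_len(n_rep), function(i) list())
  for (i in seq_len(nrow(lexicon))) {
    pat <- lexicon$pattern[i]
    if (lexicon$scope[i] == "report") {
      locs <- stringi::stri_locate_all_regex(rep_txt, pat,
                                             omit_no_match = TRUE)
      for (r in seq_len(n_rep)) {
        loc <- locs[[r]]
        if (!nrow(loc)) next
        map <- folded_reports[[r]]$map
        acc[[r]][[length(acc[[r]]) + 1L]] <- data.frame(
          concept_id = lexicon$concept_id[i], task = lexicon$task[i],
          label = lexicon$label[i], sentence = rep(NA_integer_, nrow(loc)),
          start = map[loc[, 1]], end = map[loc[, 2]] + 1L,
          stringsAsFactors = FALSE)
      }
    } else {
      if (!length(sent_txt)) next
      locs <- stringi::stri_locate_all_regex(sent_txt, pat,
                                             omit_no_match = TRUE)
      for (s in seq_along(locs)) {
        loc <- locs[[s]]
        if (!nrow(loc)) next
        r <- sent_rep[s]
        map <- sent_fold[[s]]$map
        acc[[r]][[length(acc[[r]]) + 1L]] <- data.frame(
          concept_id = lexicon$concept_id[i], task = lexicon$task[i],
          label = lexicon$label[i], sentence = rep(sent_idx[s], nrow(loc)),
          start = map[loc[, 1]] + sent_start[s],
          end = map[loc[, 2]] + 1L + sent_start[s],
          stringsAsFactors = FALSE)
      }
    }
  }
  lapply(seq_len(n_rep), function(r) {
    out <- do.call(rbind, acc[[r]])
    if (is.null(out))
      return(data.frame(concept_id = character(), task = character(),
                        label = character(), sentence = integer(),
                        start = integer(), end = integer(),
                        text = character(), stringsAsFactors = FALSE))
    out$text <- stringi::stri_sub(structures[[r]]$text, out$start + 1L,
                                  out$end)
    out[order(out$start, out$end), , drop = FALSE]
  })
}

lexicon_concepts <- function(lexicon) {
  unique(lexicon$concept_id[!nzchar(lexicon$task) &
                            !startsWith(lexicon$concept_id, "val_")])
}
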