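feature_scopes <- c("report", "seg_er", "seg_pr", "seg_her2")
.seg_biomarker <- c(seg_er = "ER", seg_pr = "PR", seg_her2 = "HER2")

scope_matches <- function(matches, segments, scope) {
  if (scope == "report") return(matches)
  matches_in_segments(matches, segments, .seg_biomarker[[scope]])
}

#' Regex presence/count features
#'
#' Presence (0/1) and number of matches for every lexicon concept, computed
#' on the whole report and restricted to each biomarker's isolated segments.
#'
#' @param matches concept matches from [match_concepts()].
#' @param lexicon the lexicon the matches came from.
#' @param segments segments from [isolate_segments()].
#' @return named numeric vector (`regex.<scope>.<concept>.{presence,count}`).
#' @export
regex_match_features <- function(matches, lexicon, segments) {
  concepts <- lexicon_concepts(lexicon)
  out <- numeric(0)
  for (scope in feature_scopes) {
    m <- scope_matches(matches, segments, scope)
    counts <- table(factor(m$concept_id, levels = concepts))
    v <- as.numeric(counts)
    names(v) <- sprintf("regex.%s.%s.count", scope, concepts)
    p <- as.numeric(v > 0)
    names(p) <- sprintf("regex.%s.%s.presence", scope, concepts)
    out <- c(out, p, v)
  }
  out
}

#' Match location features
#'
#' Absolute and relative (offset / report length) locations of the first and
#' last match of every concept, plus the relative sentence index of the last
#' match. Decisive information tends to sit at the end of a report, while the
#' beginning holds history and test indication. Absent concepts get the
#' sentinel -1.
#'
#' @param matches concept matches.
#' @param structure the report structure.
#' @param lexicon the lexicon.
#' @return named numeric vector (`loc.report.<concept>.<stat>`).
#' @export
location_features <- function(matches, structure, lexicon) {
  concepts <- lexicon_concepts(lexicon)
  n_char <- max(stringi::stri_length(structure$text), 1L)
  n_sent <- max(nrow(structure$sentences), 1L)
  out <- numeric(0)
  for (con in concepts) {
    m <- matches[matches$concept_id == con, , drop = FALSE]
    if (!nrow(m)) {
      v <- c(-1, -1, -1, -1, -1)
    } else {
      first <- min(m$start); last <- max(m$start)
      last_sent <- suppressWarnings(max(m$sentence, na.rm = TRUE))
      if (!is.finite(last_sent)) last_sent <- n_sent
      v <- c(first, last, first / n_char, last / n_char, last_sent / n_sent)
    }
    names(v) <- sprintf("loc.report.%s.%s", con,
                        c("first_abs", "last_abs", "first_rel", "last_rel",
                          "last_sent_rel"))
    out <- c(out, v)
  }
  out
}

numeric_ranges <- list(allred = c(0, 8), hscore = c(0, 300),
                       percent = c(0, 100), ratio = c(0, 20),
                       copies = c(0, 60), ihc_score = c(0, 3))

extract_numeric_values <- function(structure, lexicon) {
  folded <- fold_with_map(structure$text)
  val_rows <- lexicon[startsWith(lexicon$concept_id, "val_"), , drop = FALSE]
  out <- list()
  for (i in seq_len(nrow(val_rows))) {
    kind <- sub("^val_", "", val_rows$concept_id[i])
    pat <- val_rows$pattern[i]
    loc <- stringi::stri_locate_all_regex(folded$folded, pat,
                                          omit_no_match = TRUE)[[1]]
    if (!nrow(loc)) next
    grp <- stringi::stri_match_all_regex(folded$folded, pat)[[1]]
    raw <- apply(grp[, -1, drop = FALSE], 1, function(g)
      g[which(!is.na(g))[1]])
    val <- suppressWarnings(as.numeric(gsub(",", ".", raw)))
    rng <- numeric_ranges[[kind]] %||% c(-Inf, Inf)
    ok <- !is.na(val) & val >= rng[1] & val <= rng[2]
    if (any(!ok & !is.na(val)))
      warnf("discarding out-of-range %s value(s): %s", kind,
            paste(val[!ok & !is.na(val)], collapse = ", "))
    if (!any(ok)) next
    out[[kind]] <- rbind(out[[kind]],
                         data.frame(start = folded$map[loc[ok, 1]],
                                    value = val[ok]))
  }
  out
}

#' Clinical numeric value features
#'
#' Regex-extracted numeric values tied to the possible labels: Allred score
#' (0-8), H-score (0-300), percentage of positive cells, the last IHC score
#' (0-3 parsed from 0/1+/2+/3+), HER2/CEP17 ratio and mean HER2 copy number.
#' Such values are not systematically provided, so each value comes with a
#' presence flag and the sentinel -1 when absent; out-of-range parses are
#' discarded with a warning. When several occurrences exist, the last one in
#' the report (or segment) wins. Computed at report scope and per biomarker
#' segment scope.
#'
#' @param structure report structure.
#' @param matches concept matches.
#' @param lexicon the lexicon (supplies `val_*` extraction patterns).
#' @param segments segments from [isolate_segments()].
#' @return named numeric vector (`num.<scope>.<kind>.{value,present}`).
#' @export
numeric_value_features <- function(structure, matches, lexicon, segments) {
  vals <- extract_numeric_values(structure, lexicon)
  score_map <- c(ihc_score_0 = 0, ihc_score_1 = 1, ihc_score_2 = 2,
                 ihc_score_3 = 3)
  kinds <- names(numeric_ranges)
  out <- numeric(0)
  for (scope in feature_scopes) {
    seg <- if (scope == "report") NULL else
      segments[segments$biomarker == .seg_biomarker[[scope]], , drop = FALSE]
    in_scope <- function(starts) {
      if (is.null(seg)) rep(TRUE, length(starts))
      else if (!nrow(seg)) rep(FALSE, length(starts))
      else vapply(starts, function(s) any(s >= seg$start & s < seg$end), TRUE)
    }
    for (kind in kinds) {
      if (kind == "ihc_score") {
        m <- matches[matches$concept_id %in% names(score_map), , drop = FALSE]
        keep <- in_scope(m$start)
        v <- if (any(keep)) {
          m <- m[keep, , drop = FALSE]
          score_map[[m$concept_id[which.max(m$start)]]]
        } else NULL
      } else {
        tab <- vals[[kind]]
        v <- NULL
        if (!is.null(tab)) {
          keep <- in_scope(tab$start)
          if (any(keep)) {
            tab <- tab[keep, , drop = FALSE]
            v <- tab$value[which.max(tab$start)]
          }
        }
      }
      fv <- if (is.null(v)) c(-1, 0) else c(v, 1)
      names(fv) <- sprintf("num.%s.%s.%s", scope, kind, c("value", "present"))
      out <- c(out, fv)
    }
  }
  out
}

#' Jaccard similarity between two token sets
#'
#' Ratio of the number of shared words to the total number of unique words
#' in the two sentences; 0 when both are empty.
#'
#' @param a,b character vectors of (normal-form) tokens.
#' @return a number in \[0, 1\].
#' @export
jaccard_similarity <- function(a, b) {
  a <- unique(a); b <- unique(b)
  u <- length(union(a, b))
  if (u == 0L) return(0)
  length(intersect(a, b)) / u
}

#' Jaccard similarity features against reference sentences
#'
#' For each reference sentence, the maximum Jaccard similarity between its
#' normal-form token set and any sentence of the report (0 for an empty
#' report).
#'
#' @param structure report structure.
#' @param references data.frame from [reference_sentences()].
#' @return named numeric vector (`jac.<sentence_id>`).
#' @export
jaccard_features <- function(structure, references) {
  sent_tokens <- split(structure$tokens$norm, structure$tokens$sentence)
  ref_tokens <- lapply(references$text, function(t) tokenize_words(t)$norm)
  v <- vapply(ref_tokens, function(ref) {
    if (!length(sent_tokens)) return(0)
    max(vapply(sent_tokens, jaccard_similarity, 0, b = ref))
  }, 0)
  names(v) <- paste0("jac.", references$sentence_id)
  v
}

sanitize_feature_name <- function(x) gsub("[^A-Za-z0-9_.]", "plus", x)

#' Build a word-count vocabulary from training reports
#'
#' Normal-form words with document frequency at least `min_df` in the
#' training corpus, capped at the `max_size` most frequent entries (ties
#' alphabetical). The vocabulary is a fitted artifact: it must be learned on
#' the training partition only.
#'
#' @param structures list of [report_structure()] for the training reports.
#' @param min_df minimum document frequency (default 3).
#' @param max_size cap on vocabulary size (default 2000).
#' @return data.frame with columns `norm`, `feature_name`, `df`.
#' @export
build_vocabulary <- function(structures, min_df = 3L, max_size = 2000L) {
  df_tab <- table(unlist(lapply(structures, function(st)
    unique(st$tokens$norm))))
  df_tab <- df_tab[df_tab >= min_df]
  ord <- order(-as.numeric(df_tab), names(df_tab))
  df_tab <- df_tab[ord]
  if (length(df_tab) > max_size) df_tab <- df_tab[seq_len(max_size)]
  norms <- names(df_tab)
  data.frame(norm = norms,
             feature_name = make.unique(
               sanitize_feature_name(paste0("wc.", norms))),
             df = as.integer(df_tab), stringsAsFactors = FALSE)
}

#' Word count features
#'
#' Number of occurrences of each vocabulary word (normal forms, so case and
#' diacritics do not matter); out-of-vocabulary words are ignored.
#'
#' @param structure report structure.
#' @param vocabulary from [build_vocabulary()].
#' @return named numeric vector.
#' @export
word_count_features <- function(structure, vocabulary) {
  counts <- table(factor(structure$tokens$norm, levels = vocabulary$norm))
  v <- as.numeric(counts)
  names(v) <- vocabulary$feature_name
  v
}

#' Read Boolean feature combinations
#'
#' A combination is a named Boolean expression over base feature names
#' (comparisons and thresholds joined with `&`/`|`, plus `max()`), evaluating
#' to 0/1 per report. An expression referencing an unknown feature is a
#' configuration error, raised at load time against the supplied feature
#' names.
#'
#' @param path TSV with columns `name`, `expression`; default packaged set.
#' @param feature_names if given, validate referenced features against it.
#' @return data.frame with columns `name`, `expression`.
#' @export
read_combos <- function(path = NULL, feature_names = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "combos.tsv", package = "receptex")
  combos <- read.delim(path, sep = "\t", quote = "", comment.char = "#",
                       stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  stopifnot(all(c("name", "expression") %in% names(combos)))
  combos$parsed <- lapply(combos$expression, function(e)
    tryCatch(parse(text = e)[[1]],
             error = function(err) stopf("invalid combo expression: %s", e)))
  if (!is.null(feature_names)) {
    for (i in seq_len(nrow(combos))) {
      vars <- all.vars(combos$parsed[[i]])
      bad <- setdiff(vars, feature_names)
      if (length(bad))
        stopf("combo '%s' references unknown feature(s): %s",
              combos$name[i], paste(bad, collapse = ", "))
    }
  }
  combos
}

#' Boolean combination features
#'
#' @param base named numeric vector of base features.
#' @param combos from [read_combos()].
#' @return named numeric 0/1 vector (`combo.<name>`).
#' @export
boolean_combination_features <- function(base, combos) {
  env <- list2env(as.list(base), parent = baseenv())
  v <- vapply(seq_len(nrow(combos)), function(i) {
    vars <- all.vars(combos$parsed[[i]])
    bad <- setdiff(vars, names(base))
    if (length(bad))
      stopf("combo '%s' references unknown feature(s): %s", combos$name[i],
            paste(bad, collapse = ", "))
    as.numeric(isTRUE(as.logical(eval(combos$parsed[[i]], env))))
  }, 0)
  names(v) <- paste0("combo.", combos$name)
  v
}

#' Fit meta logistic-regression features
#'
#' One L2-penalized one-vs-rest logistic regression per label of the task,
#' over the report-scope regex count features, fitted on the training
#' partition only. Each fitted model becomes one feature: the predicted
#' probability sigmoid(intercept + coefficients . inputs).
#'
#' @param base_matrix training base feature matrix (rows = reports).
#' @param labels training labels.
#' @param task task id (used to name features).
#' @param lambda ridge penalty (default 0.05).
#' @return list of meta-model specs.
#' @export
fit_meta_models <- function(base_matrix, labels, task, lambda = 0.05) {
  inputs <- grep("^regex\\.report\\..*\\.count$", colnames(base_matrix),
                 value = TRUE)
  x <- base_matrix[, inputs, drop = FALSE]
  specs <- list()
  for (lab in label_schema(task)) {
    y <- as.numeric(labels == lab)
    if (sum(y) < 3L || sum(1 - y) < 3L) next
    # fit along a short descending path (glmnet converges poorly when asked
    # for a single lambda) and keep the coefficients at the target penalty
    fit <- glmnet::glmnet(x, y, family = "binomial", alpha = 0,
                          lambda = c(8, 4, 2, 1, 0.5, 0.2, lambda),
                          standardize = TRUE)
    beta <- coef(fit, s = lambda, exact = FALSE)
    specs[[length(specs) + 1L]] <- list(
      name = sprintf("meta.%s.%s", task, sanitize_feature_name(lab)),
      input_feature_names = inputs,
      intercept = as.numeric(beta[1, 1]),
      coefficients = as.numeric(beta[-1, 1]))
  }
  specs
}

#' Meta logistic features
#'
#' @param base named numeric vector of base features.
#' @param specs from [fit_meta_models()].
#' @return named numeric vector in (0, 1).
#' @export
meta_logistic_features <- function(base, specs) {
  v <- vapply(specs, function(sp) {
    missing <- setdiff(sp$input_feature_names, names(base))
    if (length(missing))
      stopf("meta feature '%s': missing input feature(s): %s", sp$name,
            paste(head(missing, 3), collapse = ", "))
    eta <- sp$intercept +
      sum(sp$coefficients * base[sp$input_feature_names])
    1 / (1 + exp(-pmin(pmax(eta, -30), 30)))
  }, 0)
  names(v) <- vapply(specs, `[[`, "", "name")
  v
}

#' Fit feature normalization constants
#'
#' Features are heterogeneous and span different orders of magnitude, which
#' slows training; they are standardized using constants learned on the
#' training partition only: center = training mean, scale = training
#' standard deviation (1 for zero-variance features).
#'
#' @param matrix training feature matrix.
#' @return list with `center` and `scale` named vectors.
#' @export
fit_normalization <- function(matrix) {
  center <- colMeans(matrix)
  scale <- apply(matrix, 2, sd)
  scale[!is.finite(scale) | scale == 0] <- 1
  list(center = center, scale = scale)
}

#' Apply normalization constants
#'
#' Never refits: applying training constants to validation or test data uses
#' the stored constants as-is.
#'
#' @param matrix feature matrix.
#' @param constants from [fit_normalization()].
#' @return normalized matrix.
#' @export
apply_normalization <- function(matrix, constants) {
  stopifnot(identical(colnames(matrix), names(constants$center)))
  sweep(sweep(matrix, 2, constants$center, "-"), 2, constants$scale, "/")
}

#' Export a feature matrix as CSV
#'
#' Audit view: report ids in the first column, named feature columns after.
#'
#' @param matrix a matrix from [build_feature_matrix()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_feature_matrix_csv <- function(matrix, path) {
  out <- data.frame(report_id = rownames(matrix), matrix,
                    check.names = FALSE, stringsAsFactors = FALSE)
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Feature extraction configuration
#'
#' @param lexicon a `receptex_lexicon`.
#' @param references reference sentences.
#' @param combos Boolean combinations.
#' @param abbreviations sentence-splitting abbreviation list.
#' @param vocabulary optional training vocabulary (skipped when NULL).
#' @param meta_specs optional fitted meta-model specs.
#' @param normalization optional fitted normalization constants.
#' @return a `receptex_feature_config` list.
#' @export
feature_config <- function(lexicon = default_lexicon(),
                           references = reference_sentences(),
                           combos = read_combos(),
                           abbreviations = default_abbreviations(),
                           vocabulary = NULL, meta_specs = NULL,
                           normalization = NULL) {
  structure(list(lexicon = lexicon, references = references, combos = combos,
                 abbreviations = abbreviations, vocabulary = vocabulary,
                 meta_specs = meta_specs, normalization = normalization),
            class = "receptex_feature_config")
}

base_feature_vector <- function(structure, matches, config) {
  segments <- isolate_segments(structure, matches)
  c(regex_match_features(matches, config$lexicon, segments),
    location_features(matches, structure, config$lexicon),
    numeric_value_features(structure, matches, config$lexicon, segments),
    jaccard_features(structure, config$references))
}

#' Build the full feature matrix for a set of reports
#'
#' Concatenates all feature families with namespaced names
#' (`family.scope.concept.statistic`); the name set is identical for every
#' report. Word-count, meta and normalization stages are applied only when
#' the corresponding fitted artifacts are present in `config`.
#'
#' @param reports list of report records.
#' @param config a [feature_config()].
#' @param structures optional precomputed structures (else computed here).
#' @return numeric matrix, rows named by report id.
#' @export
build_feature_matrix <- function(reports, config = feature_config(),
                                 structures = NULL) {
  if (is.null(structures))
    structures <- lapply(reports, report_structure,
                         abbreviations = config$abbreviations)
  matches <- match_concepts_corpus(structures, config$lexicon)
  rows <- vector("list", length(reports))
  for (i in seq_along(reports)) {
    base <- base_feature_vector(structures[[i]], matches[[i]], config)
    v <- base
    if (!is.null(config$vocabulary))
      v <- c(v, word_count_features(structures[[i]], config$vocabulary))
    v <- c(v, boolean_combination_features(base, config$combos))
    if (!is.null(config$meta_specs))
      v <- c(v, meta_logistic_features(base, config$meta_specs))
    rows[[i]] <- v
  }
  mat <- do.call(rbind, rows)
  rownames(mat) <- vapply(reports, `[[`, "", "report_id")
  if (any(!is.finite(mat))) stopf("non-finite feature values produced")
  if (!is.null(config$normalization))
    mat <- apply_normalization(mat, config$normalization)
  mat
}
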