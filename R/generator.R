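#' Synthetic report generator configuration
#'
#' The generator emulates the documented heterogeneity of registry pathology
#' corpora: two languages (sometimes mixed within a report), bullet-point
#' versus narrative style, HER2 synonym/abbreviation variants, absent
#' punctuation or line breaks, all-uppercase text, misspellings, and the
#' documented error sources (IHC results for other biomarkers, positive and
#' negative HER2 IHC control results, ongoing-ISH statements, history
#' preambles, multi-tumor reports). Within each probability group the
#' probabilities sum to 1 and exactly one option is drawn per report.
#'
#' @param n_reports number of reports to generate.
#' @param seed integer seed.
#' @param heterogeneity preset: "default" (study conditions), "high"
#'   (elevated noise and decoys, for baseline stress tests) or "clean"
#'   (no noise, no decoys; used for generator/lexicon audits).
#' @param language_mix,style_mix,noise,decoys,phrasing,label_distribution
#'   optional overrides of the preset's probability groups.
#' @return a `receptex_generator_config` list.
#' @export
generator_config <- function(n_reports = 100L, seed = 1L,
                             heterogeneity = c("default", "high", "clean"),
                             language_mix = NULL, style_mix = NULL,
                             noise = NULL, decoys = NULL, phrasing = NULL,
                             label_distribution = NULL) {
  heterogeneity <- match.arg(heterogeneity)
  preset_noise <- switch(heterogeneity,
    default = c(none = 0.55, uppercase_all = 0.12, strip_linebreaks = 0.08,
                strip_punctuation = 0.10, misspelling = 0.15),
    high = c(none = 0.25, uppercase_all = 0.20, strip_linebreaks = 0.15,
             strip_punctuation = 0.15, misspelling = 0.25),
    clean = c(none = 1, uppercase_all = 0, strip_linebreaks = 0,
              strip_punctuation = 0, misspelling = 0))
  preset_decoys <- switch(heterogeneity,
    default = c(none = 0.35, ihc_control_block = 0.15,
                other_biomarker_ihc = 0.20, ongoing_ish = 0.10,
                history_preamble = 0.17, multi_tumor = 0.03),
    high = c(none = 0.15, ihc_control_block = 0.25,
             other_biomarker_ihc = 0.25, ongoing_ish = 0.12,
             history_preamble = 0.18, multi_tumor = 0.05),
    clean = c(none = 1, ihc_control_block = 0, other_biomarker_ihc = 0,
              ongoing_ish = 0, history_preamble = 0, multi_tumor = 0))
  # "unusual" phrasings report results through values or lab-kit names only
  # (Allred/H-score without a polarity word, HercepTest, bare ISH ratios):
  # decisive for a reader, invisible to label-linked patterns
  preset_phrasing <- switch(heterogeneity,
    default = c(standard = 0.90, unusual = 0.10),
    high = c(standard = 0.70, unusual = 0.30),
    clean = c(standard = 1, unusual = 0))
  cfg <- list(
    n_reports = as.integer(n_reports), seed = as.integer(seed),
    heterogeneity = heterogeneity,
    language_mix = language_mix %||% c(nl = 0.55, fr = 0.40, mixed = 0.05),
    style_mix = style_mix %||% c(bullet = 0.5, narrative = 0.5),
    noise = noise %||% preset_noise,
    decoys = decoys %||% preset_decoys,
    phrasing = phrasing %||% preset_phrasing,
    # positive-heavy hormone receptors, rare ISH "Equivocal" (the ISH group
    # is conditional on an IHC score of 2+ or 3+; otherwise ISH is Unknown)
    label_distribution = label_distribution %||% list(
      ER = c(Unknown = 0.10, Negative = 0.15, Positive = 0.75),
      PR = c(Unknown = 0.10, Negative = 0.25, Positive = 0.65),
      HER2_IHC = c(Unknown = 0.12, `0` = 0.30, `1+` = 0.23, `2+` = 0.20,
                   `3+` = 0.15),
      HER2_ISH = c(CarriedOutNoResult = 0.08, Negative = 0.45,
                   Equivocal = 0.12, Positive = 0.35)))
  for (grp in c("language_mix", "style_mix", "noise", "decoys",
                "phrasing")) {
    if (abs(sum(cfg[[grp]]) - 1) > 1e-9)
      stopf("%s probabilities must sum to 1", grp)
    if (any(cfg[[grp]] < 0)) stopf("%s has negative probabilities", grp)
  }
  for (task in names(cfg$label_distribution)) {
    if (abs(sum(cfg$label_distribution[[task]]) - 1) > 1e-9)
      stopf("label_distribution for %s must sum to 1", task)
  }
  if (cfg$n_reports < 1L) stopf("n_reports must be >= 1")
  structure(cfg, class = "receptex_generator_config")
}

draw <- function(probs) sample(names(probs), 1L, prob = probs)

.her2_names <- c("HER2", "Her2/neu", "HER-2", "ERBB2", "Cerb-B2",
                 "c-erbB-2", "Neu")

r1 <- function(lo, hi) formatC(round(runif(1, lo, hi), 1), format = "f",
                               digits = 1)

pick <- function(x) x[[sample.int(length(x), 1L)]]

# Value-only phrasings: decisive for a human reader (and for numeric
# features), but without any polarity word a label-linked pattern could use.
render_er_pr_unusual <- function(biomarker, label, lang) {
  abbr <- if (biomarker == "ER") {
    if (lang == "fr") pick(c("RE", "ER")) else "ER"
  } else {
    if (lang == "fr") pick(c("RP", "PR")) else "PR"
  }
  if (label == "Positive")
    pick(list(sprintf("%s: Allred %d/8.", abbr, sample(4:8, 1)),
              sprintf("%s: H-score %d.", abbr, sample(12:29, 1) * 10)))
  else
    pick(list(sprintf("%s: Allred %d/8.", abbr, sample(0:2, 1)),
              sprintf("%s: H-score %d.", abbr, sample(0:10, 1))))
}

render_her2_ihc_unusual <- function(label) {
  sprintf("%s: %s.", pick(c("HercepTest", "DAKO HercepTest")), label)
}

render_ish_unusual <- function(label, lang) {
  r <- switch(label, Negative = r1(0.8, 1.7), Equivocal = r1(1.8, 2.2),
              Positive = r1(2.3, 6))
  if (is.null(r)) return(NULL)
  name <- pick(c("FISH", "Dual-probe ISH", "SISH"))
  pick(list(sprintf("%s ratio: %s.", name, r),
            sprintf("%s: ratio %s (CEP17 gecorrigeerd).", name, r)))
}

render_er_pr <- function(biomarker, label, lang, style) {
  a_pos <- sample(3:8, 1); a_neg <- sample(0:2, 1)
  p_pos <- sample(seq(10, 100, 5), 1)
  if (biomarker == "ER") {
    abbr <- if (lang == "fr") pick(c("RE", "ER")) else pick(c("ER", "E.R."))
    full_nl <- "oestrogeenreceptor"; full_fr <- "récepteurs aux œstrogènes"
  } else {
    abbr <- if (lang == "fr") pick(c("RP", "PR")) else "PR"
    full_nl <- "progesteronreceptor"; full_fr <- "récepteurs à la progestérone"
  }
  if (style == "bullet") {
    res <- if (label == "Positive") {
      if (lang == "fr")
        pick(c("+", "positif", sprintf("positifs (Allred %d/8)", a_pos),
               sprintf("positif (%d%%)", p_pos)))
      else
        pick(c("+", "positief", sprintf("positief (Allred %d/8)", a_pos),
               sprintf("%d%% positief", p_pos)))
    } else {
      if (lang == "fr")
        pick(c("-", "négatif", sprintf("négatifs (Allred %d/8)", a_neg), "0%"))
      else
        pick(c("-", "negatief", sprintf("negatief (Allred %d/8)", a_neg), "0%"))
    }
    return(sprintf("%s: %s", abbr, res))
  }
  if (lang == "fr") {
    if (label == "Positive")
      pick(list(
        sprintf("Les %s sont positifs (Allred %d/8).", full_fr, a_pos),
        sprintf("%s: positifs dans %d%% des cellules tumorales.",
                paste0(toupper(substring(full_fr, 1, 1)), substring(full_fr, 2)),
                p_pos),
        sprintf("Expression positive des %s.", full_fr)))
    else
      pick(list(
        sprintf("Les %s sont négatifs.", full_fr),
        sprintf("Absence d'expression des %s.", full_fr),
        sprintf("%s: négatifs (Allred %d/8).",
                paste0(toupper(substring(full_fr, 1, 1)), substring(full_fr, 2)),
                a_neg)))
  } else {
    if (label == "Positive")
      pick(list(
        sprintf("De %s kleuring is duidelijk positief (Allred %d/8).",
                full_nl, a_pos),
        sprintf("%sen: positief in %d%% van de tumorcellen.",
                paste0(toupper(substring(full_nl, 1, 1)), substring(full_nl, 2)),
                p_pos),
        sprintf("De tumorcellen tonen %s expressie (%d%% positief).",
                full_nl, p_pos)))
    else
      pick(list(
        sprintf("De %s kleuring is negatief (Allred %d/8).", full_nl, a_neg),
        sprintf("De tumorcellen zijn negatief voor de %s.", full_nl),
        sprintf("Geen expressie van de %s.", full_nl)))
  }
}

render_her2_ihc <- function(label, lang, style, name) {
  s <- label
  if (style == "bullet")
    return(sprintf("%s: %s", name, pick(c(s, paste("score", s)))))
  if (lang == "fr")
    pick(list(
      sprintf("L'immunohistochimie %s montre un score %s.", name, s),
      sprintf("La coloration %s est de score %s.", name, s),
      sprintf("%s: score %s en immunohistochimie.", name, s)))
  else
    pick(list(
      sprintf("De %s kleuring toont een score van %s.", name, s),
      sprintf("%s immunohistochemie: score %s.", name, s),
      sprintf("%s: score %s bij immunohistochemisch onderzoek.", name, s)))
}

render_ish <- function(label, lang, name) {
  comma <- function(x) if (lang == "fr" && runif(1) < 0.5) gsub("\\.", ",", x) else x
  switch(label,
    Negative = {
      r <- comma(r1(0.8, 1.7)); cp <- r1(2, 4)
      if (lang == "fr")
        pick(list(
          sprintf("FISH: pas d'amplification du gène %s (ratio %s).", name, r),
          sprintf("Le gène %s n'est pas amplifié (ratio HER2/CEP17: %s).",
                  name, r)))
      else
        pick(list(
          sprintf("FISH: geen amplificatie van het %s gen (ratio %s).", name, r),
          sprintf("Het %s gen is niet geamplificeerd (HER2/CEP17 ratio: %s).",
                  name, r),
          sprintf("FISH: geen amplificatie (ratio %s; gemiddeld %s kopieën per kern).",
                  r, cp)))
    },
    Positive = {
      r <- comma(r1(2.3, 6)); cp <- r1(6, 15)
      if (lang == "fr")
        pick(list(
          sprintf("La FISH montre une amplification du gène %s (ratio %s).",
                  name, r),
          sprintf("Le gène %s est amplifié (ratio %s; %s copies en moyenne).",
                  name, r, cp)))
      else
        pick(list(
          sprintf("FISH toont amplificatie van het %s gen (ratio %s).", name, r),
          sprintf("Het %s gen is geamplificeerd (ratio %s; gemiddeld %s kopieën per kern).",
                  name, r, cp)))
    },
    Equivocal = {
      r <- comma(r1(1.8, 2.2))
      if (lang == "fr")
        pick(list(
          sprintf("Résultat FISH équivoque (ratio %s).", r),
          sprintf("Hybridation in situ équivoque (ratio %s).", r)))
      else
        pick(list(
          sprintf("FISH: equivocaal resultaat (ratio %s).", r),
          sprintf("De in-situ hybridisatie is twijfelachtig (ratio %s).", r)))
    },
    CarriedOutNoResult = {
      if (lang == "fr")
        pick(list(
          "Une analyse FISH est en cours; le résultat sera communiqué ultérieurement.",
          "Une FISH a été demandée."))
      else
        pick(list("FISH wordt uitgevoerd; resultaat volgt.",
                  "Een FISH analyse werd aangevraagd."))
    })
}

render_conclusion <- function(labels, lang, her2_name) {
  parts <- character()
  pol <- function(lab) {
    if (lang == "fr") c(Positive = "positif", Negative = "négatif")[[lab]]
    else c(Positive = "positief", Negative = "negatief")[[lab]]
  }
  if (!is.na(labels[["ER"]]) && labels[["ER"]] != "Unknown")
    parts <- c(parts, sprintf("ER %s", pol(labels[["ER"]])))
  if (!is.na(labels[["PR"]]) && labels[["PR"]] != "Unknown")
    parts <- c(parts, sprintf("PR %s", pol(labels[["PR"]])))
  if (labels[["HER2_IHC"]] != "Unknown")
    parts <- c(parts, sprintf("%s %s", her2_name, labels[["HER2_IHC"]]))
  if (!length(parts)) return(NULL)
  head_word <- if (lang == "fr") "Conclusion" else pick(c("Besluit", "Conclusie"))
  line <- sprintf("%s: %s.", head_word, paste(parts, collapse = ", "))
  ish <- labels[["HER2_ISH"]]
  if (ish %in% c("Negative", "Positive", "Equivocal")) {
    tail_txt <- switch(ish,
      Negative = if (lang == "fr") "FISH: pas d'amplification."
                 else "FISH: geen amplificatie.",
      Positive = if (lang == "fr") "FISH: amplification présente."
                 else "FISH: geamplificeerd.",
      Equivocal = if (lang == "fr") "FISH: équivoque."
                  else "FISH: equivocaal.")
    line <- paste(line, tail_txt)
  }
  line
}

.misspellings <- list(
  c("HER2", "CerB2"), c("Her2/neu", "CerB2"),
  c("positief", "positiev"), c("positif", "positiif"),
  c("negatief", "negatiief"), c("négatif", "négaitf"),
  c("oestrogeen", "eostrogeen"), c("progesteron", "porgesteron"),
  c("amplificatie", "amplifikatie"))

apply_noise <- function(text, op) {
  switch(op,
    none = text,
    uppercase_all = stringi::stri_trans_toupper(text),
    strip_linebreaks = gsub("\n", " ", text, fixed = TRUE),
    strip_punctuation = stringi::stri_replace_all_regex(
      text, "(?<!\\d)\\.(?!\\d)|[;:!?]", ""),
    misspelling = {
      applicable <- Filter(function(m)
        stringi::stri_detect_fixed(text, m[1]), .misspellings)
      if (!length(applicable)) return(text)
      m <- pick(applicable)
      stringi::stri_replace_first_fixed(text, m[1], m[2])
    })
}

draw_labels <- function(cfg, ongoing_decoy) {
  ld <- cfg$label_distribution
  labels <- c(ER = draw(ld$ER), PR = draw(ld$PR),
              HER2_IHC = draw(ld$HER2_IHC), HER2_ISH = "Unknown")
  # guideline: ISH is performed on equivocal (2+) or positive (3+) IHC
  if (labels[["HER2_IHC"]] %in% c("2+", "3+"))
    labels[["HER2_ISH"]] <- draw(ld$HER2_ISH)
  else if (ongoing_decoy)
    labels[["HER2_ISH"]] <- "CarriedOutNoResult"
  labels
}

render_result_block <- function(labels, langs, style, her2_name, decoy,
                                unusual = FALSE) {
  lines <- character()
  if (labels[["ER"]] != "Unknown")
    lines <- c(lines, if (unusual)
      render_er_pr_unusual("ER", labels[["ER"]], langs[["ER"]])
      else render_er_pr("ER", labels[["ER"]], langs[["ER"]], style))
  if (labels[["PR"]] != "Unknown")
    lines <- c(lines, if (unusual)
      render_er_pr_unusual("PR", labels[["PR"]], langs[["PR"]])
      else render_er_pr("PR", labels[["PR"]], langs[["PR"]], style))
  if (decoy == "other_biomarker_ihc") {
    lang <- langs[["HER2"]]
    lines <- c(lines, pick(list(
      sprintf("Ki-67: %d%%.", sample(5:60, 1)),
      sprintf("Ki-67 proliferatie-index: %d%%.", sample(5:60, 1)),
      if (lang == "fr") "P53: positive." else "P53: positief.")))
  }
  if (labels[["HER2_IHC"]] != "Unknown")
    lines <- c(lines, if (unusual)
      render_her2_ihc_unusual(labels[["HER2_IHC"]])
      else render_her2_ihc(labels[["HER2_IHC"]], langs[["HER2"]], style,
                           her2_name))
  if (decoy == "ihc_control_block" && labels[["HER2_IHC"]] != "Unknown") {
    lang <- langs[["HER2"]]
    lines <- c(lines, if (runif(1) < 0.5) {
      if (lang == "fr") sprintf("Le témoin positif %s montre 3+.", her2_name)
      else sprintf("De %s positieve controle toont 3+.", her2_name)
    } else {
      if (lang == "fr") "Témoin positif: 3+. Témoin négatif: 0."
      else "Positieve controle: 3+. Negatieve controle: 0."
    })
  }
  if (decoy == "ongoing_ish" || labels[["HER2_ISH"]] == "CarriedOutNoResult") {
    lang <- langs[["HER2"]]
    lines <- c(lines, if (lang == "fr") "Une analyse FISH est en cours."
               else "FISH wordt uitgevoerd.")
  }
  if (labels[["HER2_ISH"]] %in% c("Negative", "Equivocal", "Positive"))
    lines <- c(lines, if (unusual)
      render_ish_unusual(labels[["HER2_ISH"]], langs[["HER2"]])
      else render_ish(labels[["HER2_ISH"]], langs[["HER2"]], her2_name))
  lines
}

#' Generate one synthetic labeled report
#'
#' Draws gold labels, renders them through bilingual bullet/narrative
#' templates (using the field's synonym inventory for HER2, including
#' Cerb-B2 and Her2/neu), then applies at most one noise operator and one
#' decoy. By construction the gold labels are consistent with the rendered
#' result phrases; noise operators never change the gold label. An ISH
#' result block is only rendered when the IHC label is 2+ or 3+; an
#' ongoing-ISH statement with a lower IHC score sets the gold ISH label to
#' "CarriedOutNoResult". Multi-tumor reports carry the labels of the first
#' (index) tumor and are flagged in the provenance.
#'
#' @param config a [generator_config()].
#' @param report_id identifier for the generated report.
#' @return a list: `report` (a [report()]) and `provenance`.
#' @export
generate_report <- function(config, report_id = "R00001") {
  language <- draw(config$language_mix)
  style <- draw(config$style_mix)
  noise_op <- draw(config$noise)
  decoy <- draw(config$decoys)
  phrasing <- draw(config$phrasing)
  block_lang <- function() if (language == "mixed")
    sample(c("nl", "fr"), 1) else language
  langs <- c(ER = block_lang(), PR = block_lang(), HER2 = block_lang())
  labels <- draw_labels(config, ongoing_decoy = decoy == "ongoing_ish")
  her2_name <- pick(.her2_names)
  main_lang <- langs[["HER2"]]

  lines <- character()
  if (decoy == "history_preamble") {
    dx <- if (main_lang == "fr")
      pick(c("carcinome canalaire invasif", "carcinome lobulaire invasif"))
    else pick(c("invasief ductaal carcinoom", "invasief lobulair carcinoom"))
    lines <- c(lines, if (main_lang == "fr")
      sprintf("Renseignements cliniques: %s. Immunohistochimie ER, PR et HER2 demandée.", dx)
      else
      sprintf("Klinische gegevens: %s. Immunohistochemie voor ER, PR en HER2 werd aangevraagd.", dx))
  }
  lines <- c(lines, if (main_lang == "fr")
    pick(c("Biopsie mammaire.", "Pièce de résection mammaire."))
    else pick(c("Mammabiopsie.", "Resectiestuk mamma.")))

  if (all(labels[c("ER", "PR", "HER2_IHC")] == "Unknown") &&
      labels[["HER2_ISH"]] %in% c("Unknown")) {
    lines <- c(lines, if (main_lang == "fr")
      pick(c("Pas de malignité retrouvée.",
             "Contrôle après traitement. Pas de nouvelles lésions."))
      else pick(c("Geen maligniteit weerhouden.",
                  "Controle na eerdere behandeling. Geen nieuwe letsels.")))
  } else {
    lines <- c(lines, render_result_block(labels, langs, style, her2_name,
                                          decoy,
                                          unusual = phrasing == "unusual"))
    if (decoy == "multi_tumor") {
      labels2 <- draw_labels(config, ongoing_decoy = FALSE)
      header <- if (main_lang == "fr") "Deuxieme tumeur (contralatérale):"
                else "Tweede tumor (contralateraal):"
      lines <- c(lines, header,
                 render_result_block(labels2, langs, style,
                                     pick(.her2_names), "none"))
    }
    if (phrasing == "standard" && runif(1) < 0.35) {
      concl <- render_conclusion(labels, main_lang, her2_name)
      if (!is.null(concl)) lines <- c(lines, concl)
    }
  }

  text <- paste(lines, collapse = "\n")
  text <- apply_noise(text, noise_op)
  rep <- report(report_id, text, language_hint = language,
                labels = as.list(labels))
  list(report = rep,
       provenance = list(language = language, style = style,
                         phrasing = phrasing,
                         noise = noise_op, decoy = decoy,
                         multi_tumor = decoy == "multi_tumor",
                         her2_name = her2_name))
}

#' Generate a synthetic labeled corpus
#'
#' Deterministic for a fixed seed. Multi-tumor reports are flagged in the
#' manifest; by default [run_pipeline()] excludes them from training, as a
#' registry would discard them.
#'
#' @param config a [generator_config()].
#' @return list with `reports` (list of [report()] records), `provenance`
#'   (per-report data.frame) and `manifest` (seed, config echo, realized
#'   label counts and operator frequencies).
#' @export
generate_corpus <- function(config = generator_config()) {
  set.seed(derive_seed(config$seed, "generator"))
  out <- vector("list", config$n_reports)
  for (i in seq_len(config$n_reports))
    out[[i]] <- generate_report(config, sprintf("R%05d", i))
  reports <- lapply(out, `[[`, "report")
  prov <- do.call(rbind, lapply(out, function(o)
    as.data.frame(o$provenance, stringsAsFactors = FALSE)))
  prov$report_id <- vapply(reports, `[[`, "", "report_id")
  label_counts <- lapply(setNames(nm = biomarker_tasks()), function(task)
    table(factor(corpus_labels(reports, task), levels = label_schema(task))))
  manifest <- list(seed = config$seed, n_reports = config$n_reports,
                   heterogeneity = config$heterogeneity,
                   label_counts = lapply(label_counts, as.list),
                   noise_frequencies = as.list(table(prov$noise)),
                   decoy_frequencies = as.list(table(prov$decoy)))
  list(reports = reports, provenance = prov, manifest = manifest)
}
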