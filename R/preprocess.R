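default_abbreviations <- function() {
  path <- system.file("extdata", "abbreviations.txt", package = "receptex")
  if (!nzchar(path)) return(character())
  x <- readLines(path, encoding = "UTF-8", warn = FALSE)
  x <- trimws(x)
  fold_text(x[nzchar(x) & !startsWith(x, "#")])
}

#' Split a report into lines
#'
#' Splits at each line break (`\n`, with `\r\n` and `\r` accepted).
#' Concatenating line texts and separators reconstitutes the original text; a
#' text without line breaks yields exactly one line.
#'
#' @param text report text.
#' @return data.frame with columns `text` and 0-based `start` offsets.
#' @export
split_lines <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  breaks <- stringi::stri_locate_all_regex(text, "\r\n|\n|\r")[[1]]
  if (all(is.na(breaks[, 1]))) {
    return(data.frame(text = text, start = 0L, stringsAsFactors = FALSE))
  }
  starts <- c(1L, breaks[, 2] + 1L)
  ends <- c(breaks[, 1] - 1L, stringi::stri_length(text))
  data.frame(text = stringi::stri_sub(text, starts, ends),
             start = as.integer(starts - 1L), stringsAsFactors = FALSE)
}

#' Split a line into sentences
#'
#' Sentence boundaries are terminal punctuation (`. ? ! ;`) followed by
#' whitespace or end of line. Decimal numbers are protected (no whitespace
#' after the point), and a period after a known abbreviation is not a
#' boundary. Leading tabs and bullet glyphs are not part of any sentence. A
#' punctuation-free line is one sentence.
#'
#' @param line_text line text.
#' @param line_start 0-based offset of the line in the report.
#' @param abbreviations folded abbreviation forms whose trailing period never
#'   ends a sentence.
#' @return data.frame with columns `text`, `start` (0-based, report-relative).
#' @export
split_sentences <- function(line_text, line_start = 0L,
                            abbreviations = default_abbreviations()) {
  n <- stringi::stri_length(line_text)
  if (n == 0L)
    return(data.frame(text = character(), start = integer(),
                      stringsAsFactors = FALSE))
  ends <- stringi::stri_locate_all_regex(line_text,
                                         "[.?!;](?=\\s|$)")[[1]][, 1]
  ends <- ends[!is.na(ends)]
  if (length(ends) && length(abbreviations)) {
    keep <- vapply(ends, function(e) {
      if (stringi::stri_sub(line_text, e, e) != ".") return(TRUE)
      prefix <- stringi::stri_sub(line_text, 1L, e - 1L)
      word <- stringi::stri_extract_last_regex(prefix, "[\\p{L}.]+")
      if (is.na(word)) return(TRUE)
      !(fold_text(word) %in% abbreviations)
    }, TRUE)
    ends <- ends[keep]
  }
  bounds <- unique(c(ends, n))
  starts <- c(1L, head(bounds, -1L) + 1L)
  out <- data.frame(start = starts, end = bounds)
  sent <- character(0); sstart <- integer(0)
  for (i in seq_len(nrow(out))) {
    s <- out$start[i]; e <- out$end[i]
    raw <- stringi::stri_sub(line_text, s, e)
    # strip leading whitespace and bullet glyphs; keep offsets in sync
    lead <- stringi::stri_length(
      stringi::stri_extract_first_regex(raw, "^[\\s•·*\\-–]*"))
    if (is.na(lead)) lead <- 0L
    txt <- stringi::stri_sub(raw, lead + 1L)
    if (!nzchar(trimws(txt))) next
    sent <- c(sent, txt)
    sstart <- c(sstart, s + lead - 1L)
  }
  data.frame(text = sent, start = as.integer(sstart + line_start),
             stringsAsFactors = FALSE)
}

#' Tokenize a sentence into words
#'
#' Tokens are maximal runs of letters, digits and `+`, so the IHC score
#' `"3+"` is a single token. The surface form preserves case; a lower-case,
#' diacritic-folded normal form is attached for matching.
#'
#' @param sentence_text sentence text.
#' @param sentence_start 0-based report-relative offset of the sentence.
#' @return data.frame with columns `surface`, `norm`, `start`.
#' @export
tokenize_words <- function(sentence_text, sentence_start = 0L) {
  loc <- stringi::stri_locate_all_regex(sentence_text, "[\\p{L}\\p{N}+]+")[[1]]
  if (all(is.na(loc[, 1])))
    return(data.frame(surface = character(), norm = character(),
                      start = integer(), stringsAsFactors = FALSE))
  surface <- stringi::stri_sub(sentence_text, loc[, 1], loc[, 2])
  data.frame(surface = surface, norm = fold_text(surface),
             start = as.integer(loc[, 1] - 1L + sentence_start),
             stringsAsFactors = FALSE)
}

#' Decompose a report into lines, sentences and tokens
#'
#' All offsets are 0-based character indices into the original report text;
#' every span reconstructs its substring exactly.
#'
#' @param rep a report record (or a single text string).
#' @param abbreviations see [split_sentences()].
#' @return a `receptex_structure` list with `text`, `lines`, `sentences`
#'   (with `line` index) and `tokens` (with `sentence` index).
#' @export
report_structure <- function(rep, abbreviations = default_abbreviations()) {
  text <- if (is.character(rep)) rep else rep$text
  lines <- split_lines(text)
  sent_list <- lapply(seq_len(nrow(lines)), function(i) {
    s <- split_sentences(lines$text[i], lines$start[i], abbreviations)
    if (nrow(s)) s$line <- i
    s
  })
  sentences <- do.call(rbind, sent_list[vapply(sent_list, nrow, 0L) > 0])
  if (is.null(sentences))
    sentences <- data.frame(text = character(), start = integer(),
                            line = integer(), stringsAsFactors = FALSE)
  tok_list <- lapply(seq_len(nrow(sentences)), function(i) {
    t <- tokenize_words(sentences$text[i], sentences$start[i])
    if (nrow(t)) t$sentence <- i
    t
  })
  tokens <- do.call(rbind, tok_list[vapply(tok_list, nrow, 0L) > 0])
  if (is.null(tokens))
    tokens <- data.frame(surface = character(), norm = character(),
                         start = integer(), sentence = integer(),
                         stringsAsFactors = FALSE)
  structure(list(text = text,
                 report_id = if (is.character(rep)) NA_character_ else rep$report_id,
                 lines = lines, sentences = sentences, tokens = tokens),
            class = "receptex_structure")
}

#' @export
print.receptex_structure <- function(x, ...) {
  cat(sprintf("<report structure> %d chars, %d lines, %d sentences, %d tokens\n",
              nchar(x$text), nrow(x$lines), nrow(x$sentences), nrow(x$tokens)))
  invisible(x)
}
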