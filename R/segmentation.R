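anchor_concepts <- c(er_mention = "ER", pr_mention = "PR",
                     her2_mention = "HER2")

#' Isolate biomarker-related report segments
#'
#' Results for ER, PR and HER2 typically appear directly after one another
#' with a repeated structure. Each biomarker-mention match opens a segment
#' that extends to the next biomarker-mention anchor of any biomarker, or —
#' when no anchor follows — to the end of the second sentence after the
#' anchor's sentence (end of report if shorter). Multiple anchors for the
#' same biomarker yield multiple segments, all retained.
#'
#' @param structure a [report_structure()].
#' @param matches concept matches from [match_concepts()].
#' @return data.frame with columns `biomarker`, `start`, `end` (half-open
#'   0-based character offsets) and `anchor_concept`.
#' @export
isolate_segments <- function(structure, matches) {
  anchors <- matches[matches$concept_id %in% names(anchor_concepts), ,
                     drop = FALSE]
  if (!nrow(anchors))
    return(data.frame(biomarker = character(), start = integer(),
                      end = integer(), anchor_concept = character(),
                      stringsAsFactors = FALSE))
  anchors <- anchors[order(anchors$start), , drop = FALSE]
  # collapse anchors opening at the same offset (e.g. her2_mention twice)
  anchors <- anchors[!duplicated(anchors$start), , drop = FALSE]
  n_char <- stringi::stri_length(structure$text)
  sent <- structure$sentences
  ends <- integer(nrow(anchors))
  for (i in seq_len(nrow(anchors))) {
    if (i < nrow(anchors)) {
      ends[i] <- anchors$start[i + 1L]
    } else {
      s_idx <- anchors$sentence[i]
      if (is.na(s_idx) && nrow(sent)) {
        after <- which(sent$start <= anchors$start[i])
        s_idx <- if (length(after)) max(after) else NA_integer_
      }
      if (is.na(s_idx) || !nrow(sent)) {
        ends[i] <- n_char
      } else {
        last_s <- min(s_idx + 2L, nrow(sent))
        ends[i] <- as.integer(sent$start[last_s] +
                              stringi::stri_length(sent$text[last_s]))
      }
    }
  }
  data.frame(biomarker = unname(anchor_concepts[anchors$concept_id]),
             start = anchors$start, end = pmax(ends, anchors$end),
             anchor_concept = anchors$concept_id, stringsAsFactors = FALSE)
}

#' Export segments to a debug TSV
#'
#' Audit view of segment isolation: one row per segment with the covered
#' text.
#'
#' @param structure the segmented report's [report_structure()].
#' @param segments from [isolate_segments()].
#' @param path output TSV path (columns report_id, biomarker, start, end,
#'   text).
#' @return `path`, invisibly.
#' @export
write_segments_tsv <- function(structure, segments, path) {
  out <- data.frame(
    report_id = structure$report_id,
    biomarker = segments$biomarker,
    start = segments$start, end = segments$end,
    text = gsub("[\t\n]", " ",
                substr(rep(structure$text, nrow(segments)),
                       segments$start + 1L, segments$end)),
    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

# matches restricted to the union of a biomarker's segments
matches_in_segments <- function(matches, segments, biomarker) {
  seg <- segments[segments$biomarker == biomarker, , drop = FALSE]
  if (!nrow(seg) || !nrow(matches))
    return(matches[0, , drop = FALSE])
  keep <- vapply(seq_len(nrow(matches)), function(i)
    any(matches$start[i] >= seg$start & matches$start[i] < seg$end), TRUE)
  matches[keep, , drop = FALSE]
}
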