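#' @importFrom stats predict coef sd quantile setNames
#' @importFrom utils head tail write.csv read.csv
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Fold text for matching
#'
#' Lower-cases and strips diacritics (e.g. \code{"é" -> "e"}). Folding is
#' used for matching and token normal forms only; stored surface text is never
#' modified. Folding is idempotent.
#'
#' @param x character vector.
#' @return folded character vector.
#' @export
fold_text <- function(x) {
  stringi::stri_trans_tolower(stringi::stri_trans_general(x, "Latin-ASCII"))
}

# Fold a single string keeping a map from folded character positions back to
# 0-based original positions. Most transliterations are length-preserving; the
# per-character path is only taken when they are not (oe-ligatures, eszett).
fold_with_map <- function(text) {
  folded <- fold_text(text)
  if (stringi::stri_length(folded) == stringi::stri_length(text)) {
    return(list(folded = folded, map = seq_len(stringi::stri_length(text)) - 1L))
  }
  chars <- stringi::stri_sub(text, seq_len(stringi::stri_length(text)),
                             length = 1L)
  pieces <- fold_text(chars)
  lens <- stringi::stri_length(pieces)
  list(
    folded = paste0(pieces, collapse = ""),
    map = rep(seq_along(chars) - 1L, times = lens)
  )
}

# Deterministic 32-bit sub-seed derived from a root seed and a stream label,
# so every stochastic stage has its own named stream.
derive_seed <- function(seed, label, index = 0L) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((abs(as.numeric(seed)) * 7919 + h * 131 + index) %% 2147483587L) + 1L
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)
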