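#' Tokenize a sentence on whitespace and punctuation
#'
#' Splits `text` into maximal runs of non-space, non-punctuation
#' characters, and emits every punctuation character as a token of its
#' own. Hyphenated forms such as `"gliclazide-induced"` therefore come
#' apart into three tokens, so that every entity word has its own node in
#' the dependency tree. Whitespace is discarded but the returned character
#' offsets allow exact reconstruction of the original text.
#'
#' @param text a single non-empty string.
#' @return a data.frame with columns `surface`, `start`, `end`
#'   (1-based inclusive character offsets into `text`).
#' @examples
#' tokenize("gliclazide-induced acute hepatitis")$surface
#' @export
tokenize <- function(text) {
  stopifnot(is.character(text), length(text) == 1L, !is.na(text))
  if (!nzchar(text)) stop("cannot tokenize empty text")
  m <- gregexpr("[^[:space:][:punct:]]+|[[:punct:]]", text)[[1]]
  if (m[1] == -1L) {
    return(data.frame(surface = character(0), start = integer(0),
                      end = integer(0), stringsAsFactors = FALSE))
  }
  start <- as.integer(m)
  end <- start + attr(m, "match.length") - 1L
  data.frame(surface = substring(text, start, end),
             start = start, end = end, stringsAsFactors = FALSE)
}

#' Normalize a token surface form
#'
#' Lowercases and replaces every digit character by `"0"`, preserving
#' token length so that word-shape information survives for the
#' character-level CNN (`"THP-1"` becomes `"thp-0"`).
#'
#' @param surface character vector of surface forms.
#' @return character vector of normalized forms.
#' @export
normalize_token <- function(surface) {
  gsub("[[:digit:]]", "0", tolower(surface))
}

#' Split a document into sentences
#'
#' Heuristic splitter used for standoff documents: a sentence ends at a
#' `.`, `?` or `!` that is followed by whitespace and then an uppercase
#' letter or a digit, or at a newline. The rules are deliberately simple
#' and frozen by tests; abbreviations followed by capitalized words will
#' be over-split.
#'
#' @param text a document string.
#' @return data.frame with columns `start`, `end`: 1-based inclusive
#'   character spans of each sentence (leading/trailing whitespace
#'   trimmed).
#' @export
split_sentences <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  n <- nchar(text)
  if (n == 0L) {
    return(data.frame(start = integer(0), end = integer(0)))
  }
  # candidate breakpoints: position AFTER which a new sentence starts
  breaks <- integer(0)
  m <- gregexpr("[.?!][[:space:]]+[[:upper:][:digit:]]", text)[[1]]
  if (m[1] != -1L) breaks <- c(breaks, as.integer(m))
  m <- gregexpr("\n", text, fixed = TRUE)[[1]]
  if (m[1] != -1L) breaks <- c(breaks, as.integer(m))
  breaks <- sort(unique(breaks))
  bounds <- c(0L, breaks, n)
  out <- data.frame(start = head(bounds, -1L) + 1L, end = bounds[-1L])
  # trim whitespace at both ends of each span
  for (i in seq_len(nrow(out))) {
    s <- out$start[i]; e <- out$end[i]
    while (s <= e && grepl("^[[:space:]]$", substring(text, s, s))) s <- s + 1L
    while (e >= s && grepl("^[[:space:]]$", substring(text, e, e))) e <- e - 1L
    out$start[i] <- s; out$end[i] <- e
  }
  out[out$start <= out$end, , drop = FALSE]
}
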