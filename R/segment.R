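#' Split text into sentences with character offsets
#'
#' Rule-based sentence segmentation tuned for scientific prose: splits on
#' `.`, `!`, `?` followed by whitespace, but refuses to split after common
#' scholarly abbreviations ("et al.", "e.g.", "Fig.", ...), after single
#' initials ("J."), or inside decimal numbers. Offsets are 0-based,
#' half-open, relative to `text`, and each sentence slice is trimmed of
#' surrounding whitespace; concatenating the slices recovers all
#' non-whitespace characters of the input.
#'
#' @param text a single character string.
#' @return data frame with columns `text`, `start`, `end`; zero rows for
#'   empty or all-whitespace input.
#' @examples
#' segment_sentences("A fact. Another fact.")
#' segment_sentences("Smith et al. (2020) showed X.")
#' @export
segment_sentences <- function(text) {
  stopifnot(is.character(text), length(text) == 1)
  empty <- data.frame(text = character(), start = integer(), end = integer(),
                      stringsAsFactors = FALSE)
  if (is.na(text) || !nzchar(trimws(text))) return(empty)

  # candidate boundaries: terminator run (+ closing quotes/brackets) + whitespace
  m <- gregexpr("[.!?]+[\"')\\]]*[[:space:]]+", text, perl = TRUE)[[1]]
  starts <- 1L
  if (m[1] != -1) {
    ends_at <- as.integer(m) + attr(m, "match.length") - 1L
    for (i in seq_along(m)) {
      boundary <- as.integer(m[i])           # position of the terminator
      after <- ends_at[i] + 1L               # first char of the would-be next sentence
      if (after > nchar(text)) next
      if (!is_sentence_boundary(text, boundary, after)) next
      starts <- c(starts, after)
    }
  }
  stops <- c(starts[-1] - 1L, nchar(text))
  pieces <- substring(text, starts, stops)

  keep <- nzchar(trimws(pieces))
  starts <- starts[keep]; pieces <- pieces[keep]
  # trim whitespace but keep offsets anchored to the original text
  lead <- nchar(pieces) - nchar(sub("^[[:space:]]+", "", pieces))
  trail <- nchar(pieces) - nchar(sub("[[:space:]]+$", "", pieces))
  start0 <- starts - 1L + lead               # to 0-based
  trimmed <- trimws(pieces)
  data.frame(text = trimmed, start = as.integer(start0),
             end = as.integer(start0 + nchar(trimmed)), stringsAsFactors = FALSE)
}

# abbreviations that a terminator may follow without ending the sentence
.abbreviations <- c("al", "g", "e", "i", "cf", "ca", "vs", "etc", "fig", "figs",
                    "eq", "eqs", "ref", "refs", "dr", "mr", "ms", "st", "no",
                    "approx", "resp", "suppl", "vol")

is_sentence_boundary <- function(text, boundary, after) {
  prefix <- substr(text, 1, boundary - 1L)
  word <- regmatches(prefix, regexpr("[A-Za-z]+$", prefix))
  if (length(word) == 1) {
    if (tolower(word) %in% .abbreviations) return(FALSE)
    if (nchar(word) == 1 && grepl("[A-Z]", word)) return(FALSE)  # initial
  }
  # next sentence must open with an uppercase letter, digit or bracket/quote
  nxt <- substr(text, after, after)
  grepl("[A-Z0-9\"'([]", nxt)
}

# English stopwords removed before BM25 / overlap scoring
.stopwords <- c(
  "a", "an", "the", "and", "or", "but", "of", "in", "on", "at", "to", "for",
  "from", "by", "with", "as", "is", "are", "was", "were", "be", "been",
  "being", "that", "this", "these", "those", "it", "its", "we", "they",
  "their", "our", "which", "who", "whom", "what", "when", "where", "while",
  "than", "then", "there", "here", "have", "has", "had", "do", "does", "did",
  "can", "could", "may", "might", "will", "would", "shall", "should", "also",
  "such", "into", "over", "under", "between", "among", "both", "each", "per",
  "more", "most", "other", "some", "any", "all", "been", "using", "used",
  "however", "therefore", "thus"
)

#' Tokenize text for lexical scoring
#'
#' Lowercase alphanumeric tokenization (letters, digits, internal hyphens
#' dropped) with English stopword removal. Citation-mask tokens such as
#' `[cit]` survive as `cit`, `multi_cit`, `other_cit`.
#'
#' @param text character vector.
#' @param remove_stopwords drop common English function words (default TRUE).
#' @return list of character vectors, one per input element.
#' @export
tokenize <- function(text, remove_stopwords = TRUE) {
  toks <- strsplit(tolower(text), "[^a-z0-9_]+")
  lapply(toks, function(x) {
    x <- x[nzchar(x)]
    if (remove_stopwords) x <- x[!(x %in% .stopwords)]
    x
  })
}

tokenize1 <- function(text, remove_stopwords = TRUE) {
  tokenize(text, remove_stopwords)[[1]]
}
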