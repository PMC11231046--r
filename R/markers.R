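#' Default citation-marker dialects
#'
#' Regular expressions for the marker styles recognized by
#' [locate_markers()]: bracketed numeric (`[3]`, `[2,4]`, `[2-5]` with
#' hyphen or en-dash), parenthesized numeric (`(3)`, `(2, 5)`; four-digit
#' numbers are excluded so bare years do not match), and author-year
#' (`(Smith et al., 2019)`, possibly several references separated by `";"`).
#' Each pattern is paired with a rule deciding whether a match covers more
#' than one reference (`multi`).
#'
#' @return list of dialect definitions (`name`, `pattern`,
#'   `multi_pattern` — a regex that, if it matches the marker text, makes it
#'   `multi`).
#' @export
marker_patterns <- function() {
  list(
    list(name = "author_year",
         pattern = "\\((?:[A-Z][A-Za-z'-]+(?:\\s+(?:et\\s+al\\.|and\\s+[A-Z][A-Za-z'-]+))?,?\\s+[0-9]{4}[a-z]?)(?:;\\s*[A-Z][A-Za-z'-]+(?:\\s+(?:et\\s+al\\.|and\\s+[A-Z][A-Za-z'-]+))?,?\\s+[0-9]{4}[a-z]?)*\\)",
         multi_pattern = ";"),
    list(name = "bracketed_numeric",
         pattern = "\\[\\s*[0-9]{1,3}(?:\\s*[,;]\\s*[0-9]{1,3}|\\s*[-–—]\\s*[0-9]{1,3})*\\s*\\]",
         multi_pattern = "[,;–—-]"),
    list(name = "parenthesized_numeric",
         pattern = "\\(\\s*[0-9]{1,3}(?:\\s*[,;]\\s*[0-9]{1,3}|\\s*[-–—]\\s*[0-9]{1,3})*\\s*\\)",
         multi_pattern = "[,;–—-]")
  )
}

#' Locate citation markers in a paragraph
#'
#' Scans a citing paragraph for citation markers using a configurable list
#' of marker dialects (see [marker_patterns()]). Matches from
#' earlier-listed dialects win when spans overlap; the result is sorted by
#' position and spans never overlap.
#'
#' @param paragraph paragraph text.
#' @param patterns dialect list, by default [marker_patterns()].
#' @return data frame with columns `start`, `end` (0-based half-open),
#'   `text`, `multiplicity` (`"single"`/`"multi"`); zero rows when nothing
#'   matches.
#' @examples
#' locate_markers("A [1], B [2,4].")
#' @export
locate_markers <- function(paragraph, patterns = marker_patterns()) {
  stopifnot(is.character(paragraph), length(paragraph) == 1,
            nzchar(paragraph))
  hits <- data.frame(start = integer(), end = integer(), text = character(),
                     multiplicity = character(), stringsAsFactors = FALSE)
  for (dialect in patterns) {
    m <- gregexpr(dialect$pattern, paragraph, perl = TRUE)[[1]]
    if (m[1] == -1) next
    starts <- as.integer(m) - 1L
    lens <- attr(m, "match.length")
    for (i in seq_along(starts)) {
      cand <- c(starts[i], starts[i] + lens[i])
      if (nrow(hits) > 0 &&
          any(apply(hits[, c("start", "end")], 1, spans_overlap, b = cand)))
        next
      text <- substr(paragraph, cand[1] + 1, cand[2])
      multi <- grepl(dialect$multi_pattern, text)
      hits <- rbind(hits, data.frame(
        start = cand[1], end = cand[2], text = text,
        multiplicity = if (multi) "multi" else "single",
        stringsAsFactors = FALSE))
    }
  }
  hits <- hits[order(hits$start), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Replace citation markers with special tokens
#'
#' Prepares a sentence for lexical or neural scoring: the target marker
#' becomes `[cit]` (or `[multi_cit]` when it covers several references) and
#' every other marker becomes `[other_cit]`. Replacements are applied
#' right-to-left so earlier offsets stay valid; text outside the marker
#' spans is untouched.
#'
#' @param sentence sentence text.
#' @param target `c(start, end)` span of the target marker (0-based
#'   half-open), or `NULL` if the sentence holds no target.
#' @param others list of spans of non-target markers.
#' @param multiplicity `"single"` or `"multi"`; if `NULL`, inferred from the
#'   marker's surface text via the default dialects.
#' @return the masked sentence.
#' @examples
#' mask_markers("X [3] but Y [4].", c(2, 5), list(c(12, 15)))
#' @export
mask_markers <- function(sentence, target, others = list(),
                         multiplicity = NULL) {
  spans <- others
  if (!is.null(target)) spans <- c(list(target), others)
  if (length(spans) > 1) {
    for (i in seq_along(spans)) {
      for (j in seq_along(spans)) {
        if (i < j && spans_overlap(spans[[i]], spans[[j]]))
          stop("marker spans overlap", call. = FALSE)
      }
    }
  }
  for (sp in spans) {
    if (sp[1] < 0 || sp[2] > nchar(sentence) || sp[1] >= sp[2])
      stop("marker span outside sentence", call. = FALSE)
  }
  if (!is.null(target) && is.null(multiplicity)) {
    text <- substr(sentence, target[1] + 1, target[2])
    found <- locate_markers(text)
    multiplicity <- if (nrow(found) > 0) found$multiplicity[1] else "single"
  }
  repl <- function(s, span, token) {
    paste0(substr(s, 1, span[1]), token,
           substr(s, span[2] + 1, nchar(s)))
  }
  # right-to-left so earlier offsets stay valid
  ord <- order(vapply(spans, function(sp) as.numeric(sp[1]), numeric(1)),
               decreasing = TRUE)
  out <- sentence
  for (k in ord) {
    sp <- spans[[k]]
    is_target <- !is.null(target) && identical(as.integer(sp), as.integer(target))
    token <- if (is_target) {
      if (identical(multiplicity, "multi")) "[multi_cit]" else "[cit]"
    } else "[other_cit]"
    out <- repl(out, sp, token)
  }
  out
}
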