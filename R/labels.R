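#' Citation accuracy label taxonomy
#'
#' Citations are annotated with one of eight fine-grained accuracy labels.
#' `ACCURATE` carries no error; the seven error labels split into major
#' errors (CONTRADICT, NOT_SUBSTANTIATE, IRRELEVANT) and minor errors
#' (OVERSIMPLIFY, MISQUOTE, INDIRECT, ETIQUETTE). Error labels carry a strict
#' priority order (rank 1 = most severe); when several error categories apply
#' to one citation the highest-priority one is kept.
#'
#' @return `fine_labels()` returns the eight label names in priority order
#'   (ACCURATE last); `fine_label_info()` returns a data frame with columns
#'   `name`, `severity` (`NONE`/`MAJOR`/`MINOR`) and `priority_rank`
#'   (`NA` for ACCURATE).
#' @examples
#' fine_label_info()
#' @export
fine_labels <- function() {
  c("CONTRADICT", "NOT_SUBSTANTIATE", "IRRELEVANT", "OVERSIMPLIFY",
    "MISQUOTE", "INDIRECT", "ETIQUETTE", "ACCURATE")
}

#' @rdname fine_labels
#' @export
fine_label_info <- function() {
  data.frame(
    name = fine_labels(),
    severity = c("MAJOR", "MAJOR", "MAJOR", "MINOR", "MINOR", "MINOR",
                 "MINOR", "NONE"),
    priority_rank = c(1L, 2L, 3L, 4L, 5L, 6L, 7L, NA_integer_),
    stringsAsFactors = FALSE
  )
}

#' @rdname fine_labels
#' @export
coarse_labels <- function() c("ACCURATE", "NOT_ACCURATE", "IRRELEVANT")

assert_fine_label <- function(label) {
  bad <- setdiff(label, fine_labels())
  if (length(bad) > 0) {
    stop("unknown fine label(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  invisible(label)
}

#' Consolidate a fine label into the three-way classification scheme
#'
#' ACCURATE and INDIRECT map to ACCURATE (indirect citations usually reflect
#' the reference content correctly, just not its original source);
#' CONTRADICT, NOT_SUBSTANTIATE, OVERSIMPLIFY, MISQUOTE and ETIQUETTE map to
#' NOT_ACCURATE; IRRELEVANT maps to IRRELEVANT. The mapping is total over the
#' eight fine labels and vectorized.
#'
#' @param fine character vector of fine label names.
#' @return character vector of coarse labels (`ACCURATE`, `NOT_ACCURATE`,
#'   `IRRELEVANT`).
#' @examples
#' consolidate_label(c("INDIRECT", "ETIQUETTE", "IRRELEVANT"))
#' @export
consolidate_label <- function(fine) {
  assert_fine_label(fine)
  map <- c(
    ACCURATE = "ACCURATE", INDIRECT = "ACCURATE",
    CONTRADICT = "NOT_ACCURATE", NOT_SUBSTANTIATE = "NOT_ACCURATE",
    OVERSIMPLIFY = "NOT_ACCURATE", MISQUOTE = "NOT_ACCURATE",
    ETIQUETTE = "NOT_ACCURATE",
    IRRELEVANT = "IRRELEVANT"
  )
  unname(map[fine])
}

#' Select the highest-priority label among applicable categories
#'
#' When a citation fits several error categories the one with the smallest
#' priority rank wins. ACCURATE is only returned when it is the sole
#' applicable label: any co-occurring error dominates it.
#'
#' @param applicable non-empty character vector of fine label names.
#' @return a single fine label name.
#' @examples
#' select_priority_label(c("NOT_SUBSTANTIATE", "INDIRECT"))
#' @export
select_priority_label <- function(applicable) {
  if (length(applicable) == 0) stop("'applicable' must be non-empty", call. = FALSE)
  applicable <- unique(assert_fine_label(applicable))
  errors <- setdiff(applicable, "ACCURATE")
  if (length(errors) == 0) return("ACCURATE")
  info <- fine_label_info()
  rank <- info$priority_rank[match(errors, info$name)]
  errors[which.min(rank)]
}

label_severity <- function(label) {
  info <- fine_label_info()
  info$severity[match(assert_fine_label(label), info$name)]
}
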