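round_half_up <- function(x, digits = 2) {
  pow <- 10^digits
  sign(x) * floor(abs(x) * pow + 0.5) / pow
}

#' Corpus-level label and annotation statistics
#'
#' Computes the label distribution table for an annotated corpus: counts and
#' percentages per fine label, the grouped percentages (ACCURATE, MAJOR
#' errors, MINOR errors, total errors), and the mean number of context and
#' evidence sentences per citation. Percentages are rounded half-up to two
#' decimals, matching the convention of printed corpus tables.
#'
#' `corpus_statistics()` derives everything from a list of
#' [citation_instance()] objects (evidence sentences are counted through
#' [expand_segment_to_sentences()] when `reference_docs` is supplied,
#' otherwise one sentence per segment is assumed);
#' `corpus_statistics_from_counts()` takes pre-tabulated counts, e.g. from a
#' published distribution table.
#'
#' @param instances list of [citation_instance()].
#' @param reference_docs optional named list of [reference_document()]
#'   objects keyed by doc id, used to expand paragraph/section evidence
#'   segments to sentences.
#' @return an object of class `corpus_statistics`: counts, `per_label_counts`,
#'   `per_label_percent`, `group_percent` (ACCURATE/MAJOR/MINOR/TOTAL_ERRORS),
#'   `context_per_citation`, `evidence_per_citation`. For an empty corpus all
#'   counts are zero and the ratios are `NA` with `$degenerate = TRUE`.
#' @examples
#' corpus_statistics_from_counts(
#'   c(ACCURATE = 1863, CONTRADICT = 92, NOT_SUBSTANTIATE = 243,
#'     IRRELEVANT = 217, OVERSIMPLIFY = 111, MISQUOTE = 38, INDIRECT = 82,
#'     ETIQUETTE = 417),
#'   n_context_sentences = 3420, n_evidence_sentences = 3791)
#' @export
corpus_statistics <- function(instances, reference_docs = NULL) {
  labels <- vapply(instances, function(x) x$fine_label, character(1))
  counts <- table(factor(labels, levels = fine_labels()))
  counts <- stats::setNames(as.integer(counts), names(counts))
  n_context <- sum(vapply(instances, function(x)
    length(x$context_sentence_ids), integer(1)))
  n_evidence <- sum(vapply(instances, function(x) {
    if (length(x$evidence_segments) == 0) return(0L)
    if (is.null(reference_docs)) return(length(x$evidence_segments))
    doc <- reference_docs[[x$reference_doc_id]]
    length(gold_evidence_sentences(x, doc))
  }, integer(1)))
  corpus_statistics_from_counts(counts, n_context, n_evidence)
}

#' @rdname corpus_statistics
#' @param per_label_counts named integer vector of instance counts per fine
#'   label (missing labels are taken as zero).
#' @param n_context_sentences,n_evidence_sentences total annotated context /
#'   evidence sentence counts over the corpus.
#' @export
corpus_statistics_from_counts <- function(per_label_counts,
                                          n_context_sentences = NA_integer_,
                                          n_evidence_sentences = NA_integer_) {
  assert_fine_label(names(per_label_counts))
  counts <- stats::setNames(integer(length(fine_labels())), fine_labels())
  counts[names(per_label_counts)] <- as.integer(per_label_counts)
  n <- sum(counts)

  pct <- function(k) if (n == 0) NA_real_ else round_half_up(100 * k / n, 2)
  severity <- label_severity(names(counts))
  major <- sum(counts[severity == "MAJOR"])
  minor <- sum(counts[severity == "MINOR"])

  structure(
    list(
      n_instances = n,
      n_context_sentences = n_context_sentences,
      n_evidence_sentences = n_evidence_sentences,
      per_label_counts = counts,
      per_label_percent = vapply(counts, pct, numeric(1)),
      group_counts = c(ACCURATE = unname(counts["ACCURATE"]), MAJOR = major,
                       MINOR = minor, TOTAL_ERRORS = major + minor),
      group_percent = c(ACCURATE = pct(unname(counts["ACCURATE"])),
                        MAJOR = pct(major), MINOR = pct(minor),
                        TOTAL_ERRORS = pct(major + minor)),
      context_per_citation = if (n == 0 || is.na(n_context_sentences)) NA_real_
                             else round_half_up(n_context_sentences / n, 2),
      evidence_per_citation = if (n == 0 || is.na(n_evidence_sentences)) NA_real_
                              else round_half_up(n_evidence_sentences / n, 2),
      degenerate = n == 0
    ),
    class = "corpus_statistics"
  )
}

#' @export
print.corpus_statistics <- function(x, ...) {
  cat(sprintf("Corpus statistics: %d citation instances\n", x$n_instances))
  if (x$degenerate) {
    cat("  (empty corpus; ratios undefined)\n")
    return(invisible(x))
  }
  df <- data.frame(label = names(x$per_label_counts),
                   count = unname(x$per_label_counts),
                   percent = unname(x$per_label_percent))
  print(df, row.names = FALSE)
  cat(sprintf("  groups: ACCURATE %.2f%% | MAJOR %.2f%% | MINOR %.2f%% | errors %.2f%%\n",
              x$group_percent["ACCURATE"], x$group_percent["MAJOR"],
              x$group_percent["MINOR"], x$group_percent["TOTAL_ERRORS"]))
  if (!is.na(x$context_per_citation))
    cat(sprintf("  %.2f context and %.2f evidence sentences per citation\n",
                x$context_per_citation, x$evidence_per_citation))
  invisible(x)
}
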