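#' Evidence segment reference
#'
#' Points at the unit of a reference article that a citation is asserted
#' against: a single sentence, a whole paragraph, or a whole section.
#'
#' @param reference_doc_id id of the reference document.
#' @param granularity one of `"sentence"`, `"paragraph"`, `"section"`.
#' @param unit_id id of the unit at that granularity.
#' @return an object of class `evidence_segment`.
#' @export
evidence_segment <- function(reference_doc_id, granularity, unit_id) {
  granularity <- match.arg(granularity, c("sentence", "paragraph", "section"))
  structure(
    list(reference_doc_id = reference_doc_id, granularity = granularity,
         unit_id = unit_id),
    class = "evidence_segment"
  )
}

#' Reference article as a sentence-segmented document tree
#'
#' Builds the ordered sections -> paragraphs -> sentences structure used by
#' evidence retrieval. Sentence ids (`s1`, `s2`, ...) are assigned in
#' document order and are stable for the life of the object; the abstract is
#' the section titled "Abstract" (case-insensitive), if present.
#'
#' @param doc_id document identifier.
#' @param title article title (one text unit with id `"title"`).
#' @param sections list of sections, each a list with elements `heading`
#'   (string) and `paragraphs` (character vector of paragraph texts).
#' @return an object of class `reference_document` with fields `doc_id`,
#'   `title`, `text` (reconstructed full text), `sentences` (data frame:
#'   `sentence_id`, `text`, `start`, `end`, `paragraph_id`, `section_id`),
#'   `paragraphs` (named list paragraph_id -> sentence ids), `sections`
#'   (data frame `section_id`, `heading` plus named list
#'   `section_paragraphs`), `abstract_sentence_ids`.
#' @export
reference_document <- function(doc_id, title, sections) {
  stopifnot(is.character(doc_id), length(doc_id) == 1, is.character(title))
  sent_rows <- list()
  para_map <- list()
  sec_ids <- character()
  sec_headings <- character()
  sec_paras <- list()
  full <- paste0(title, "\n\n")
  s_counter <- 0L
  p_counter <- 0L

  for (si in seq_along(sections)) {
    sec <- sections[[si]]
    sec_id <- sprintf("sec%d", si)
    full <- paste0(full, sec$heading, "\n\n")
    p_ids <- character()
    for (para_text in sec$paragraphs) {
      p_counter <- p_counter + 1L
      p_id <- sprintf("p%d", p_counter)
      offset <- nchar(full)
      sents <- segment_sentences(para_text)
      if (nrow(sents) == 0) next
      ids <- sprintf("s%d", s_counter + seq_len(nrow(sents)))
      s_counter <- s_counter + nrow(sents)
      sent_rows[[length(sent_rows) + 1L]] <- data.frame(
        sentence_id = ids, text = sents$text,
        start = sents$start + offset, end = sents$end + offset,
        paragraph_id = p_id, section_id = sec_id, stringsAsFactors = FALSE
      )
      para_map[[p_id]] <- ids
      p_ids <- c(p_ids, p_id)
      full <- paste0(full, para_text, "\n\n")
    }
    sec_ids <- c(sec_ids, sec_id)
    sec_headings <- c(sec_headings, sec$heading)
    sec_paras[[sec_id]] <- p_ids
  }

  sentences <- if (length(sent_rows)) do.call(rbind, sent_rows) else
    data.frame(sentence_id = character(), text = character(),
               start = integer(), end = integer(),
               paragraph_id = character(), section_id = character(),
               stringsAsFactors = FALSE)
  rownames(sentences) <- NULL

  abstract_sec <- sec_ids[tolower(sec_headings) == "abstract"]
  abstract_ids <- if (length(abstract_sec)) {
    unlist(para_map[sec_paras[[abstract_sec[1]]]], use.names = FALSE)
  } else character()

  structure(
    list(doc_id = doc_id, title = title, text = full,
         sentences = sentences, paragraphs = para_map,
         sections = data.frame(section_id = sec_ids, heading = sec_headings,
                               stringsAsFactors = FALSE),
         section_paragraphs = sec_paras,
         abstract_sentence_ids = abstract_ids),
    class = "reference_document"
  )
}

#' @export
print.reference_document <- function(x, ...) {
  cat(sprintf("<reference_document %s: %d sections, %d paragraphs, %d sentences>\n",
              x$doc_id, nrow(x$sections), length(x$paragraphs),
              nrow(x$sentences)))
  invisible(x)
}

sentence_text <- function(doc, sentence_ids) {
  doc$sentences$text[match(sentence_ids, doc$sentences$sentence_id)]
}

#' Expand an evidence segment to its member sentences
#'
#' Sentence-level segments map to themselves; paragraph- and section-level
#' segments expand to every member sentence in document order. This is the
#' sentence-level view used for agreement calculation and retrieval
#' evaluation.
#'
#' @param seg an [evidence_segment()].
#' @param doc the [reference_document()] the segment points into.
#' @return character vector of sentence ids, duplicate-free, in document
#'   order.
#' @export
expand_segment_to_sentences <- function(seg, doc) {
  stopifnot(inherits(seg, "evidence_segment"),
            inherits(doc, "reference_document"))
  ids <- switch(seg$granularity,
    sentence = {
      if (!seg$unit_id %in% doc$sentences$sentence_id)
        stop("unknown sentence id '", seg$unit_id, "' in document ",
             doc$doc_id, call. = FALSE)
      seg$unit_id
    },
    paragraph = {
      if (is.null(doc$paragraphs[[seg$unit_id]]))
        stop("unknown paragraph id '", seg$unit_id, "' in document ",
             doc$doc_id, call. = FALSE)
      doc$paragraphs[[seg$unit_id]]
    },
    section = {
      p_ids <- doc$section_paragraphs[[seg$unit_id]]
      if (is.null(p_ids))
        stop("unknown section id '", seg$unit_id, "' in document ",
             doc$doc_id, call. = FALSE)
      unlist(doc$paragraphs[p_ids], use.names = FALSE)
    }
  )
  unique(ids)
}

#' Gold evidence sentence ids of a citation instance
#'
#' Union of all evidence segments expanded to sentences, in document order.
#'
#' @param instance a [citation_instance()].
#' @param doc the instance's [reference_document()].
#' @return character vector of sentence ids (possibly empty).
#' @export
gold_evidence_sentences <- function(instance, doc) {
  ids <- unique(unlist(lapply(instance$evidence_segments,
                              expand_segment_to_sentences, doc = doc)))
  if (is.null(ids)) return(character())
  ids[order(match(ids, doc$sentences$sentence_id))]
}

#' One citation marker in its citing context
#'
#' The unit of annotation and prediction: a citing paragraph, the character
#' span of the target citation marker inside it, the gold context sentences,
#' up to five evidence segments in the reference article, and the
#' fine-grained accuracy label. The coarse label is always derived from the
#' fine label via [consolidate_label()], never stored, so the two cannot
#' drift apart. All spans are 0-based half-open character intervals.
#'
#' @param instance_id opaque identifier.
#' @param citing_doc_id,reference_doc_id document identifiers.
#' @param paragraph_text text of the citing paragraph.
#' @param marker_span integer vector `c(start, end)` of the target marker.
#' @param marker_multiplicity `"single"` or `"multi"` (marker covering
#'   several references, e.g. a numeric range).
#' @param other_marker_spans list of `c(start, end)` spans of non-target
#'   markers in the paragraph.
#' @param context_sentence_ids integer indices (1-based, paragraph-local) of
#'   the gold context sentences; must include the citance.
#' @param evidence_segments list of [evidence_segment()] (0-5 entries; empty
#'   iff the label is IRRELEVANT or ETIQUETTE).
#' @param fine_label one of the eight fine labels.
#' @return an object of class `citation_instance`; `$coarse_label` is the
#'   derived three-way label.
#' @export
citation_instance <- function(instance_id, citing_doc_id, reference_doc_id,
                              paragraph_text, marker_span,
                              marker_multiplicity = c("single", "multi"),
                              other_marker_spans = list(),
                              context_sentence_ids, evidence_segments = list(),
                              fine_label) {
  marker_multiplicity <- match.arg(marker_multiplicity)
  inst <- structure(
    list(instance_id = instance_id, citing_doc_id = citing_doc_id,
         reference_doc_id = reference_doc_id,
         paragraph_text = paragraph_text,
         marker_span = as.integer(marker_span),
         marker_multiplicity = marker_multiplicity,
         other_marker_spans = lapply(other_marker_spans, as.integer),
         context_sentence_ids = as.integer(context_sentence_ids),
         evidence_segments = evidence_segments,
         fine_label = fine_label),
    class = "citation_instance"
  )
  validate_citation_instance(inst)
  inst
}

#' @export
print.citation_instance <- function(x, ...) {
  cat(sprintf("<citation_instance %s: %s -> %s, label %s (%s), %d evidence segment(s)>\n",
              x$instance_id, x$citing_doc_id, x$reference_doc_id,
              x$fine_label, x$coarse_label, length(x$evidence_segments)))
  invisible(x)
}

# coarse_label is derived on access so it can never disagree with fine_label
#' @export
`$.citation_instance` <- function(x, name) {
  if (identical(name, "coarse_label")) {
    return(consolidate_label(unclass(x)$fine_label))
  }
  unclass(x)[[name]]
}

spans_overlap <- function(a, b) a[1] < b[2] && b[1] < a[2]

#' Validate a citation instance against its structural invariants
#'
#' Checks that the marker span lies inside the paragraph and overlaps no
#' other marker, that the citance is in the context set, and that evidence
#' segments are present exactly when the label admits them (absent for
#' IRRELEVANT and ETIQUETTE, 1-5 otherwise).
#'
#' @param inst a [citation_instance()].
#' @return `inst`, invisibly; errors on the first violated invariant.
#' @export
validate_citation_instance <- function(inst) {
  id <- inst$instance_id
  assert_fine_label(inst$fine_label)
  span <- inst$marker_span
  if (length(span) != 2 || span[1] < 0 || span[2] > nchar(inst$paragraph_text) ||
      span[1] >= span[2]) {
    stop("instance ", id, ": marker_span outside paragraph_text", call. = FALSE)
  }
  for (o in inst$other_marker_spans) {
    if (spans_overlap(span, o)) {
      stop("instance ", id, ": marker_span overlaps another marker", call. = FALSE)
    }
  }
  sents <- segment_sentences(inst$paragraph_text)
  citance_idx <- which(sents$start <= span[1] & span[1] < sents$end)
  if (length(citance_idx) != 1 || !(citance_idx %in% inst$context_sentence_ids)) {
    stop("instance ", id, ": citance sentence missing from context_sentence_ids",
         call. = FALSE)
  }
  n_ev <- length(inst$evidence_segments)
  if (inst$fine_label %in% c("IRRELEVANT", "ETIQUETTE")) {
    if (n_ev != 0) stop("instance ", id, ": ", inst$fine_label,
                        " must have no evidence segments", call. = FALSE)
  } else {
    if (n_ev < 1 || n_ev > 5) stop("instance ", id,
                                   ": evidence_segments must have 1-5 entries",
                                   call. = FALSE)
  }
  invisible(inst)
}

#' Index of the citance within the paragraph's sentences
#'
#' @param paragraph_text citing paragraph text.
#' @param marker_span `c(start, end)` of the target marker (0-based
#'   half-open). A marker that straddles a segmentation boundary is assigned
#'   to the sentence containing its start.
#' @return 1-based sentence index.
#' @export
citance_index <- function(paragraph_text, marker_span) {
  sents <- segment_sentences(paragraph_text)
  idx <- which(sents$start <= marker_span[1] & marker_span[1] < sents$end)
  if (length(idx) == 0) stop("marker_span falls outside every sentence", call. = FALSE)
  idx[1]
}
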