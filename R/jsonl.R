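instance_to_list <- function(inst) {
  list(
    instance_id = inst$instance_id,
    citing_doc_id = inst$citing_doc_id,
    reference_doc_id = inst$reference_doc_id,
    paragraph_text = inst$paragraph_text,
    marker_span = inst$marker_span,
    marker_multiplicity = inst$marker_multiplicity,
    other_marker_spans = inst$other_marker_spans,
    context_sentence_ids = inst$context_sentence_ids,
    evidence_segments = lapply(inst$evidence_segments, function(s)
      list(reference_doc_id = s$reference_doc_id,
           granularity = s$granularity, unit_id = s$unit_id)),
    fine_label = inst$fine_label,
    coarse_label = inst$coarse_label
  )
}

#' Read and write the JSONL corpus dialect
#'
#' One citation instance per line, keys mirroring the
#' [citation_instance()] fields (the stored `coarse_label` is informative
#' only; it is re-derived from `fine_label` on read). The schema is
#' documented in `system.file("extdata", "citation-instance-schema.json",
#' package = "citecheck")`.
#'
#' @param instances list of [citation_instance()].
#' @param path output / input file path.
#' @return `write_instances_jsonl()` returns `path` invisibly;
#'   `read_instances_jsonl()` returns a list of [citation_instance()].
#' @export
write_instances_jsonl <- function(instances, path) {
  lines <- vapply(instances, function(inst)
    as.character(jsonlite::toJSON(instance_to_list(inst), auto_unbox = TRUE,
                                  digits = NA)),
    character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_instances_jsonl
#' @export
read_instances_jsonl <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lapply(lines[nzchar(lines)], function(ln) {
    x <- jsonlite::fromJSON(ln, simplifyVector = TRUE, simplifyDataFrame = FALSE)
    citation_instance(
      instance_id = x$instance_id,
      citing_doc_id = x$citing_doc_id,
      reference_doc_id = x$reference_doc_id,
      paragraph_text = x$paragraph_text,
      marker_span = unlist(x$marker_span),
      marker_multiplicity = x$marker_multiplicity,
      other_marker_spans = if (is.matrix(x$other_marker_spans)) {
        lapply(seq_len(nrow(x$other_marker_spans)), function(r)
          x$other_marker_spans[r, ])
      } else lapply(x$other_marker_spans, unlist),
      context_sentence_ids = unlist(x$context_sentence_ids),
      evidence_segments = lapply(x$evidence_segments, function(s)
        evidence_segment(s$reference_doc_id, s$granularity, s$unit_id)),
      fine_label = x$fine_label)
  })
}

#' Read and write reference documents as JSONL
#'
#' One reference article per line: `doc_id`, `title`, and the section /
#' paragraph structure as nested lists of paragraph texts. Sentence ids are
#' re-derived deterministically on read, so they are stable across a
#' write/read round trip.
#'
#' @param docs named list of [reference_document()].
#' @param path file path.
#' @return `write_reference_docs_jsonl()` returns `path` invisibly;
#'   `read_reference_docs_jsonl()` returns a named list of
#'   [reference_document()].
#' @export
write_reference_docs_jsonl <- function(docs, path) {
  lines <- vapply(docs, function(doc) {
    secs <- lapply(seq_len(nrow(doc$sections)), function(si) {
      sec_id <- doc$sections$section_id[si]
      p_ids <- doc$section_paragraphs[[sec_id]]
      paras <- vapply(p_ids, function(pid) {
        paste(sentence_text(doc, doc$paragraphs[[pid]]), collapse = " ")
      }, character(1))
      list(heading = doc$sections$heading[si], paragraphs = unname(paras))
    })
    as.character(jsonlite::toJSON(
      list(doc_id = doc$doc_id, title = doc$title, sections = secs),
      auto_unbox = TRUE, digits = NA))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_reference_docs_jsonl
#' @export
read_reference_docs_jsonl <- function(path) {
  lines <- readLines(path, warn = FALSE)
  docs <- lapply(lines[nzchar(lines)], function(ln) {
    x <- jsonlite::fromJSON(ln, simplifyVector = TRUE,
                            simplifyDataFrame = FALSE)
    sections <- lapply(x$sections, function(s)
      list(heading = s$heading, paragraphs = unlist(s$paragraphs)))
    reference_document(x$doc_id, x$title, sections)
  })
  stats::setNames(docs, vapply(docs, function(d) d$doc_id, character(1)))
}

#' Write a corpus to a directory
#'
#' Emits `instances.jsonl`, `reference_docs.jsonl`, and a brat standoff
#' mirror of every citing paragraph (`standoff/<instance_id>.txt` /
#' `.ann`).
#'
#' @param corpus a `citation_corpus`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_corpus <- function(corpus, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_instances_jsonl(corpus$instances, file.path(dir, "instances.jsonl"))
  write_reference_docs_jsonl(corpus$reference_docs,
                             file.path(dir, "reference_docs.jsonl"))
  so_dir <- file.path(dir, "standoff")
  dir.create(so_dir, showWarnings = FALSE)
  for (inst in corpus$instances) {
    so <- instance_to_standoff(inst)
    base <- file.path(so_dir, inst$instance_id)
    writeLines(so$text, paste0(base, ".txt"))
    writeLines(write_standoff(so), paste0(base, ".ann"))
  }
  invisible(dir)
}

#' @rdname write_corpus
#' @export
read_corpus <- function(dir) {
  structure(list(
    reference_docs = read_reference_docs_jsonl(
      file.path(dir, "reference_docs.jsonl")),
    instances = read_instances_jsonl(file.path(dir, "instances.jsonl")),
    config = NULL), class = "citation_corpus")
}

#' Standoff view of a citation instance
#'
#' Renders one citing paragraph as a brat standoff document: a `Citation`
#' entity for the target marker, `OtherCitation` entities for non-target
#' markers, `Context` entities for the gold context sentences, and a
#' `Label` attribute carrying the fine label on the target entity.
#'
#' @param inst a [citation_instance()].
#' @return a `standoff_document`.
#' @export
instance_to_standoff <- function(inst) {
  txt <- inst$paragraph_text
  slice <- function(sp) substr(txt, sp[1] + 1, sp[2])
  entities <- list(list(id = "T1", type = "Citation",
                        spans = list(inst$marker_span),
                        text = slice(inst$marker_span)))
  eid <- 1L
  for (sp in inst$other_marker_spans) {
    eid <- eid + 1L
    entities[[length(entities) + 1L]] <-
      list(id = paste0("T", eid), type = "OtherCitation",
           spans = list(sp), text = slice(sp))
  }
  sents <- segment_sentences(txt)
  for (ci in inst$context_sentence_ids) {
    eid <- eid + 1L
    sp <- c(sents$start[ci], sents$end[ci])
    entities[[length(entities) + 1L]] <-
      list(id = paste0("T", eid), type = "Context",
           spans = list(sp), text = slice(sp))
  }
  attrs <- data.frame(id = "A1", name = "Label", target = "T1",
                      value = inst$fine_label, stringsAsFactors = FALSE)
  structure(list(text = txt, entities = entities, attributes = attrs),
            class = "standoff_document")
}
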