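#' Citance-only context baseline
#'
#' The simplest (and empirically hard to beat) context identifier: the
#' citation context is exactly the citance, the sentence containing the
#' target marker. Because annotated context always includes the citance,
#' this baseline has perfect precision by construction. A marker straddling
#' a segmentation boundary is assigned to the sentence containing its start.
#'
#' @param paragraph_text citing paragraph.
#' @param marker_span `c(start, end)` of the target marker.
#' @param instance_id optional id carried through to the prediction.
#' @return object of class `context_prediction`: `instance_id`,
#'   `sentence_ids` (1-based paragraph-local indices), `method`.
#' @export
citance_baseline <- function(paragraph_text, marker_span, instance_id = NA_character_) {
  idx <- citance_index(paragraph_text, marker_span)
  structure(list(instance_id = instance_id, sentence_ids = idx,
                 method = "citance_baseline"),
            class = "context_prediction")
}

#' Classifier-based context identification
#'
#' Scores every sentence of the citing paragraph against the citance with a
#' pluggable sentence-pair backend and keeps those scoring at or above the
#' threshold; the citance itself is always included. Both members of each
#' pair are masked with [mask_markers()] before scoring, so backends see
#' `[cit]`/`[multi_cit]`/`[other_cit]` tokens instead of raw markers.
#'
#' @param paragraph_text citing paragraph.
#' @param marker_span target marker span.
#' @param backend function `(masked_sentence, masked_citance) -> score` in
#'   `[0, 1]`, or a registered backend name (see [context_backends()]).
#' @param threshold inclusion threshold (default 0.5).
#' @param other_marker_spans spans of non-target markers in the paragraph.
#' @param marker_multiplicity multiplicity of the target marker, or `NULL`
#'   to infer it.
#' @param instance_id optional id carried through.
#' @return `context_prediction` with `method = "classifier:<name>"`.
#' @export
classify_context <- function(paragraph_text, marker_span, backend,
                             threshold = 0.5, other_marker_spans = list(),
                             marker_multiplicity = NULL,
                             instance_id = NA_character_) {
  backend_name <- if (is.character(backend)) backend else "custom"
  if (is.character(backend)) backend <- get_context_backend(backend)
  sents <- segment_sentences(paragraph_text)
  citance <- citance_index(paragraph_text, marker_span)

  mask_sentence <- function(i) {
    s <- sents[i, ]
    local_target <- NULL
    if (s$start <= marker_span[1] && marker_span[1] < s$end) {
      local_target <- c(max(marker_span[1], s$start) - s$start,
                        min(marker_span[2], s$end) - s$start)
    }
    local_others <- Filter(Negate(is.null), lapply(other_marker_spans, function(o) {
      if (o[1] >= s$start && o[1] < s$end)
        c(o[1] - s$start, min(o[2], s$end) - s$start)
      else NULL
    }))
    mask_markers(s$text, local_target, local_others,
                 multiplicity = marker_multiplicity)
  }

  masked <- vapply(seq_len(nrow(sents)), mask_sentence, character(1))
  masked_citance <- masked[citance]
  scores <- vapply(seq_len(nrow(sents)), function(i) {
    if (i == citance) return(1)
    val <- backend(masked[i], masked_citance)
    if (!is.numeric(val) || length(val) != 1 || is.na(val) || val < 0 || val > 1)
      stop("context backend returned an invalid score for sentence ", i,
           if (!is.na(instance_id)) paste0(" (instance ", instance_id, ")"),
           call. = FALSE)
    val
  }, numeric(1))

  ids <- sort(unique(c(citance, which(scores >= threshold))))
  structure(list(instance_id = instance_id, sentence_ids = ids,
                 method = paste0("classifier:", backend_name)),
            class = "context_prediction")
}

#' Token Jaccard similarity backend
#'
#' Reference lexical backend for context classification: Jaccard similarity
#' of the (stopword-filtered) token sets of the masked sentence and masked
#' citance. A desk-scale stand-in for a fine-tuned sentence-pair encoder.
#'
#' @param a,b two masked sentences.
#' @return similarity in `[0, 1]` (0 when either side has no tokens).
#' @export
jaccard_scorer <- function(a, b) {
  ta <- unique(tokenize1(a))
  tb <- unique(tokenize1(b))
  if (length(ta) == 0 || length(tb) == 0) return(0)
  length(intersect(ta, tb)) / length(union(ta, tb))
}

.context_backends <- new.env(parent = emptyenv())

#' Context backend registry
#'
#' Sentence-pair scorers for [classify_context()] are registered by name so
#' pipeline configurations can reference them declaratively. The `jaccard`
#' backend is pre-registered; `constant0` (citance only) and `constant1`
#' (whole paragraph) are available for degenerate-case testing.
#'
#' @param name backend name.
#' @param fn function `(text, text) -> score in [0, 1]`.
#' @return `context_backends()` returns the registered names.
#' @export
register_context_backend <- function(name, fn) {
  stopifnot(is.character(name), length(name) == 1, is.function(fn))
  assign(name, fn, envir = .context_backends)
  invisible(name)
}

#' @rdname register_context_backend
#' @export
context_backends <- function() sort(ls(.context_backends))

get_context_backend <- function(name) {
  if (!exists(name, envir = .context_backends, inherits = FALSE))
    stop("unknown context backend '", name, "'; registered: ",
         paste(context_backends(), collapse = ", "), call. = FALSE)
  get(name, envir = .context_backends, inherits = FALSE)
}

#' @export
print.context_prediction <- function(x, ...) {
  cat(sprintf("<context_prediction %s [%s]: sentences %s>\n",
              x$instance_id, x$method,
              paste(x$sentence_ids, collapse = ",")))
  invisible(x)
}
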