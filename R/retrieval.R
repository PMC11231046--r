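#' Retrieval configuration
#'
#' Parameters of the two-stage evidence retriever: Okapi BM25 over the
#' sentences of the single reference article returns the top
#' `first_stage_n` candidates (default 60), an optional reranker reorders
#' them, and the top `top_k` (5, 10 or 20; default 20) become the evidence
#' sentences. `query_mode` selects what is used as the query document:
#' the citance alone, the gold context sentences, the gold context plus
#' intervening sentences, or the title-and-abstract baseline which bypasses
#' ranking altogether.
#'
#' @param first_stage_n number of BM25 candidates (default 60).
#' @param top_k evidence cutoff, one of 5, 10, 20 (default 20).
#' @param query_mode one of `"citance"`, `"gold_context"`,
#'   `"gold_context_with_intervening"`, `"title_abstract"`.
#' @param bm25_k1,bm25_b Okapi BM25 parameters (defaults 1.2 and 0.75).
#' @param reranker registered reranker name, or `"none"`.
#' @return object of class `retrieval_config`.
#' @export
retrieval_config <- function(first_stage_n = 60, top_k = 20,
                             query_mode = c("citance", "gold_context",
                                            "gold_context_with_intervening",
                                            "title_abstract"),
                             bm25_k1 = 1.2, bm25_b = 0.75,
                             reranker = "idf_overlap") {
  query_mode <- match.arg(query_mode)
  stopifnot(top_k %in% c(1, 5, 10, 20), first_stage_n >= 1,
            top_k <= first_stage_n, bm25_k1 > 0, bm25_b >= 0, bm25_b <= 1)
  structure(list(first_stage_n = as.integer(first_stage_n),
                 top_k = as.integer(top_k), query_mode = query_mode,
                 bm25_k1 = bm25_k1, bm25_b = bm25_b, reranker = reranker),
            class = "retrieval_config")
}

new_ranked_evidence <- function(instance_id, sentence_id, score, stage,
                                flag = NA_character_) {
  structure(list(instance_id = instance_id,
                 ranking = data.frame(sentence_id = sentence_id,
                                      score = score,
                                      stringsAsFactors = FALSE),
                 stage = stage, flag = flag),
            class = "ranked_evidence")
}

#' @export
print.ranked_evidence <- function(x, ...) {
  cat(sprintf("<ranked_evidence %s [%s]: %d sentences%s>\n", x$instance_id,
              x$stage, nrow(x$ranking),
              if (!is.na(x$flag)) paste0(", flag: ", x$flag) else ""))
  invisible(x)
}

.bm25_cache <- new.env(parent = emptyenv())

bm25_index <- function(doc) {
  # memoise the tokenized sentence collection per document
  hit <- .bm25_cache[[doc$doc_id]]
  if (!is.null(hit) && identical(hit$texts, doc$sentences$text))
    return(hit$index)
  toks <- tokenize(doc$sentences$text)
  lens <- lengths(toks)
  df <- table(unlist(lapply(toks, unique)))
  index <- list(tokens = toks, lens = lens, avg_len = mean(lens),
                df = stats::setNames(as.integer(df), names(df)),
                n = length(toks))
  .bm25_cache[[doc$doc_id]] <- list(texts = doc$sentences$text, index = index)
  index
}

bm25_idf <- function(df, n) log(1 + (n - df + 0.5) / (df + 0.5))

#' Rank reference-article sentences with Okapi BM25
#'
#' Scores every sentence of the reference article against the query with
#' Okapi BM25, treating each sentence as one retrieval unit: document
#' frequencies and the average length are computed over the article's own
#' sentence collection. The non-negative IDF variant
#' `log(1 + (N - df + 0.5)/(df + 0.5))` is used. Ties are broken by document
#' position (earlier sentence first). A query with no in-vocabulary term
#' yields all-zero scores, a document-order ranking, and
#' `flag = "query_out_of_vocabulary"`.
#'
#' @param query query text (typically the masked citance or context).
#' @param doc a [reference_document()].
#' @param config a [retrieval_config()].
#' @param instance_id optional id carried through to the ranking.
#' @return `ranked_evidence` with up to `first_stage_n` rows,
#'   `stage = "bm25"`.
#' @export
bm25_rank <- function(query, doc, config = retrieval_config(),
                      instance_id = NA_character_) {
  stopifnot(inherits(doc, "reference_document"), nrow(doc$sentences) >= 1)
  idx <- bm25_index(doc)
  q_terms <- tokenize1(query)
  if (length(q_terms) == 0)
    stop("query tokenizes to zero terms", call. = FALSE)
  q_terms <- unique(q_terms)
  known <- q_terms[q_terms %in% names(idx$df)]

  k1 <- config$bm25_k1; b <- config$bm25_b
  scores <- vapply(seq_len(idx$n), function(i) {
    toks <- idx$tokens[[i]]
    if (length(toks) == 0 || length(known) == 0) return(0)
    s <- 0
    norm <- k1 * (1 - b + b * idx$lens[i] / idx$avg_len)
    for (term in known) {
      tf <- sum(toks == term)
      if (tf == 0) next
      s <- s + bm25_idf(idx$df[[term]], idx$n) * tf * (k1 + 1) / (tf + norm)
    }
    s
  }, numeric(1))

  flag <- if (length(known) == 0) "query_out_of_vocabulary" else NA_character_
  ord <- order(-scores, seq_along(scores))   # ties -> earlier position first
  keep <- ord[seq_len(min(config$first_stage_n, length(ord)))]
  new_ranked_evidence(instance_id, doc$sentences$sentence_id[keep],
                      scores[keep], "bm25", flag)
}

#' Rerank a candidate list with a cross-scorer
#'
#' Reorders the first-stage candidates by a richer query-sentence relevance
#' function, keeping the same sentence set. Ties are broken by document
#' position. If the scorer fails on any sentence the input ordering is kept
#' and the result is flagged (`"reranker_failed"`).
#'
#' @param candidates a `ranked_evidence` (typically from [bm25_rank()]).
#' @param query query text.
#' @param scorer function `(query, sentence_text) -> numeric`, or a
#'   registered reranker name (see [register_reranker()]).
#' @param doc the [reference_document()] the candidates came from.
#' @return `ranked_evidence` with `stage = "reranked"`.
#' @export
rerank <- function(candidates, query, scorer, doc) {
  stopifnot(inherits(candidates, "ranked_evidence"))
  if (is.character(scorer)) scorer <- get_reranker(scorer)(doc)
  texts <- sentence_text(doc, candidates$ranking$sentence_id)
  scores <- tryCatch(
    vapply(texts, function(s) as.numeric(scorer(query, s)), numeric(1),
           USE.NAMES = FALSE),
    error = function(e) NULL)
  if (is.null(scores) || anyNA(scores)) {
    warning("reranker failed; keeping first-stage ordering")
    out <- candidates
    out$stage <- "reranked"
    out$flag <- "reranker_failed"
    return(out)
  }
  pos <- match(candidates$ranking$sentence_id, doc$sentences$sentence_id)
  ord <- order(-scores, pos)
  new_ranked_evidence(candidates$instance_id,
                      candidates$ranking$sentence_id[ord], scores[ord],
                      "reranked", candidates$flag)
}

#' IDF-weighted token-overlap cross-scorer
#'
#' Default desk-scale reranker: the score of a (query, sentence) pair is the
#' sum of IDF weights of their shared terms, with IDF taken from the
#' article's own sentence collection. A neural cross-encoder (e.g. a MonoT5
#' reranker) can be registered under the same contract.
#'
#' @param doc the [reference_document()] providing the IDF statistics.
#' @return function `(query, sentence) -> score`.
#' @export
idf_overlap_scorer <- function(doc) {
  idx <- bm25_index(doc)
  function(query, sentence) {
    shared <- intersect(unique(tokenize1(query)), unique(tokenize1(sentence)))
    if (length(shared) == 0) return(0)
    sum(vapply(shared, function(t) {
      df <- idx$df[[t]]
      bm25_idf(if (is.null(df)) 0L else df, idx$n)
    }, numeric(1)))
  }
}

.rerankers <- new.env(parent = emptyenv())

#' Reranker registry
#'
#' Rerankers are registered as factories `function(doc) -> scorer` so that
#' document-level statistics (IDF tables, encoder caches) can be prepared
#' once per article. `idf_overlap` is pre-registered.
#'
#' @param name reranker name.
#' @param factory function taking a [reference_document()] and returning a
#'   `(query, sentence) -> score` function.
#' @export
register_reranker <- function(name, factory) {
  stopifnot(is.character(name), length(name) == 1, is.function(factory))
  assign(name, factory, envir = .rerankers)
  invisible(name)
}

#' @rdname register_reranker
#' @export
rerankers <- function() sort(ls(.rerankers))

get_reranker <- function(name) {
  if (!exists(name, envir = .rerankers, inherits = FALSE))
    stop("unknown reranker '", name, "'; registered: ",
         paste(rerankers(), collapse = ", "), call. = FALSE)
  get(name, envir = .rerankers, inherits = FALSE)
}

#' Title-and-abstract evidence baseline
#'
#' The no-retrieval baseline: the title and the abstract sentences, in
#' document order and with uniform scores, are taken as the evidence. The
#' title is reported with the pseudo-id `"title"`. A document without an
#' abstract yields the title alone with `flag = "no_abstract"`.
#'
#' @param doc a [reference_document()].
#' @param instance_id optional id carried through to the ranking.
#' @return `ranked_evidence` with `stage = "title_abstract"`.
#' @export
title_abstract_evidence <- function(doc, instance_id = NA_character_) {
  stopifnot(inherits(doc, "reference_document"), nzchar(doc$title))
  ids <- c("title", doc$abstract_sentence_ids)
  flag <- if (length(doc$abstract_sentence_ids) == 0) "no_abstract"
          else NA_character_
  new_ranked_evidence(instance_id, ids, rep(1, length(ids)),
                      "title_abstract", flag)
}

#' Build the retrieval query for a citation instance
#'
#' Concatenates the selected citing-paragraph sentences, in paragraph order,
#' with citation markers masked. Modes: `citance` (the marker sentence
#' only), `gold_context` (the annotated context sentences),
#' `gold_context_with_intervening` (the span from the first to the last
#' context sentence, including sentences between them).
#'
#' @param instance a [citation_instance()].
#' @param mode query mode (see above).
#' @return query text.
#' @export
build_query <- function(instance,
                        mode = c("citance", "gold_context",
                                 "gold_context_with_intervening")) {
  mode <- match.arg(mode)
  sents <- segment_sentences(instance$paragraph_text)
  citance <- citance_index(instance$paragraph_text, instance$marker_span)
  idx <- switch(mode,
    citance = citance,
    gold_context = {
      if (length(instance$context_sentence_ids) == 0)
        stop("gold context requested but instance ", instance$instance_id,
             " has no context annotation", call. = FALSE)
      sort(instance$context_sentence_ids)
    },
    gold_context_with_intervening = {
      ids <- instance$context_sentence_ids
      if (length(ids) == 0)
        stop("gold context requested but instance ", instance$instance_id,
             " has no context annotation", call. = FALSE)
      seq(min(ids), max(ids))
    }
  )
  masked <- vapply(idx, function(i) {
    s <- sents[i, ]
    target <- NULL
    if (s$start <= instance$marker_span[1] && instance$marker_span[1] < s$end)
      target <- instance$marker_span - s$start
    others <- Filter(Negate(is.null), lapply(instance$other_marker_spans,
      function(o) if (o[1] >= s$start && o[1] < s$end)
        c(o[1], min(o[2], s$end)) - s$start else NULL))
    mask_markers(s$text, target, others,
                 multiplicity = instance$marker_multiplicity)
  }, character(1))
  paste(masked, collapse = " ")
}
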