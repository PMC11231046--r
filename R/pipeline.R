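#' Pipeline configuration
#'
#' Single declarative configuration for the three-stage pipeline: context
#' identification method, retrieval configuration, and classification
#' backend. The default configuration follows the best-performing published
#' setup at desk scale: citance-only context, BM25 top-60 with a reranker,
#' top-20 evidence sentences, and the heuristic verification backend.
#'
#' @param context_method `"citance"` or `"classifier:<backend>"` where
#'   `<backend>` is a registered context backend name.
#' @param context_threshold threshold for the classifier context method.
#' @param retrieval a [retrieval_config()].
#' @param backend registered accuracy backend name, or a backend function.
#' @param seed integer seed threaded to any stochastic component.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(context_method = "citance",
                            context_threshold = 0.5,
                            retrieval = retrieval_config(),
                            backend = "heuristic",
                            seed = 1L) {
  if (!identical(context_method, "citance")) {
    if (!grepl("^classifier:", context_method))
      stop("context_method must be 'citance' or 'classifier:<name>'",
           call. = FALSE)
    get_context_backend(sub("^classifier:", "", context_method))
  }
  if (is.character(backend)) get_accuracy_backend(backend)
  if (is.character(retrieval$reranker) && retrieval$reranker != "none")
    get_reranker(retrieval$reranker)
  structure(list(context_method = context_method,
                 context_threshold = context_threshold,
                 retrieval = retrieval, backend = backend,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

predict_context <- function(inst, config) {
  if (identical(config$context_method, "citance")) {
    citance_baseline(inst$paragraph_text, inst$marker_span, inst$instance_id)
  } else {
    classify_context(inst$paragraph_text, inst$marker_span,
                     sub("^classifier:", "", config$context_method),
                     threshold = config$context_threshold,
                     other_marker_spans = inst$other_marker_spans,
                     marker_multiplicity = inst$marker_multiplicity,
                     instance_id = inst$instance_id)
  }
}

retrieval_query <- function(inst, context_pred, config) {
  mode <- config$retrieval$query_mode
  if (mode %in% c("gold_context", "gold_context_with_intervening"))
    return(build_query(inst, mode))
  # citance mode, but honoring the context stage's prediction when it
  # extends beyond the citance
  sents <- segment_sentences(inst$paragraph_text)
  masked <- vapply(context_pred$sentence_ids, function(i) {
    s <- sents[i, ]
    target <- NULL
    if (s$start <= inst$marker_span[1] && inst$marker_span[1] < s$end)
      target <- inst$marker_span - s$start
    others <- Filter(Negate(is.null), lapply(inst$other_marker_spans,
      function(o) if (o[1] >= s$start && o[1] < s$end)
        c(o[1], min(o[2], s$end)) - s$start else NULL))
    mask_markers(s$text, target, others,
                 multiplicity = inst$marker_multiplicity)
  }, character(1))
  paste(masked, collapse = " ")
}

#' Run the full citation-integrity pipeline
#'
#' For every instance: identify the citation context, build the retrieval
#' query with markers masked, rank the reference article's sentences
#' (BM25 + reranker, or the title-and-abstract baseline), keep the top-k as
#' evidence, and classify the citation. Deterministic under deterministic
#' backends.
#'
#' @param corpus a `citation_corpus` (from [generate_corpus()] or
#'   [read_corpus()]).
#' @param config a [pipeline_config()].
#' @param out_dir optional directory; when given, per-stage TSVs
#'   (`context.tsv`, `ranking.tsv`, `predictions.tsv`) and the JSON run
#'   manifest are written there.
#' @return object of class `pipeline_run`: `context` (data frame
#'   `instance_id`, `sentence_ids`, `method`), `rankings` (named list of
#'   `ranked_evidence`), `predictions` (data frame `instance_id`, `label`,
#'   `p_accurate`, `p_not_accurate`, `p_irrelevant`, `backend`),
#'   `manifest`.
#' @export
run_pipeline <- function(corpus, config = pipeline_config(), out_dir = NULL) {
  t0 <- Sys.time()
  backend <- config$backend
  backend_name <- if (is.character(backend)) backend else "custom"
  if (is.character(backend)) backend <- get_accuracy_backend(backend)

  ctx_rows <- list(); rankings <- list(); pred_rows <- list()
  for (inst in corpus$instances) {
    id <- inst$instance_id
    doc <- corpus$reference_docs[[inst$reference_doc_id]]
    if (is.null(doc))
      stop("instance ", id, ": unknown reference document ",
           inst$reference_doc_id, call. = FALSE)

    ctx <- predict_context(inst, config)
    ctx_rows[[id]] <- data.frame(
      instance_id = id,
      sentence_ids = paste(ctx$sentence_ids, collapse = ","),
      method = ctx$method, stringsAsFactors = FALSE)

    query <- retrieval_query(inst, ctx, config)
    rcfg <- config$retrieval
    ranked <- if (rcfg$query_mode == "title_abstract") {
      title_abstract_evidence(doc, instance_id = id)
    } else {
      first <- bm25_rank(query, doc, rcfg, instance_id = id)
      if (!identical(rcfg$reranker, "none"))
        rerank(first, query, rcfg$reranker, doc)
      else first
    }
    rankings[[id]] <- ranked

    top_ids <- utils::head(ranked$ranking$sentence_id, rcfg$top_k)
    evidence <- ifelse(top_ids == "title", doc$title,
                       sentence_text(doc, top_ids))
    pred <- classify(query, evidence, backend, instance_id = id)
    pred_rows[[id]] <- data.frame(
      instance_id = id, label = pred$label,
      p_accurate = pred$score_per_label[["ACCURATE"]],
      p_not_accurate = pred$score_per_label[["NOT_ACCURATE"]],
      p_irrelevant = pred$score_per_label[["IRRELEVANT"]],
      backend = backend_name, stringsAsFactors = FALSE)
  }

  context <- do.call(rbind, ctx_rows); rownames(context) <- NULL
  predictions <- do.call(rbind, pred_rows); rownames(predictions) <- NULL
  manifest <- list(
    package_version = as.character(utils::packageVersion("citecheck")),
    config = list(context_method = config$context_method,
                  context_threshold = config$context_threshold,
                  retrieval = unclass(config$retrieval),
                  backend = backend_name, seed = config$seed),
    n_instances = length(corpus$instances),
    n_reference_docs = length(corpus$reference_docs),
    corpus_digest = corpus_digest(corpus),
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs"))
  )
  run <- structure(list(context = context, rankings = rankings,
                        predictions = predictions, manifest = manifest),
                   class = "pipeline_run")
  if (!is.null(out_dir)) write_run(run, out_dir)
  run
}

corpus_digest <- function(corpus) {
  tmp <- tempfile(fileext = ".jsonl")
  on.exit(unlink(tmp))
  write_instances_jsonl(corpus$instances, tmp)
  unname(tools::md5sum(tmp))
}

write_run <- function(run, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(run$context, file.path(out_dir, "context.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  rank_df <- do.call(rbind, lapply(run$rankings, function(r)
    data.frame(instance_id = r$instance_id,
               rank = seq_len(nrow(r$ranking)),
               sentence_id = r$ranking$sentence_id,
               score = r$ranking$score, stage = r$stage,
               stringsAsFactors = FALSE)))
  utils::write.table(rank_df, file.path(out_dir, "ranking.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(run$predictions, file.path(out_dir, "predictions.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  jsonlite::write_json(run$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat(sprintf("<pipeline_run: %d instances, backend %s, %.1fs>\n",
              x$manifest$n_instances, x$manifest$config$backend,
              x$manifest$elapsed_s))
  invisible(x)
}

#' Evaluate a pipeline run against gold annotations
#'
#' Scores the classification stage with [prf_report()] over the coarse
#' labels and the retrieval stage with [retrieval_report()] against the
#' expanded gold evidence sentences (instances without gold evidence are
#' excluded from retrieval averages).
#'
#' @param run a `pipeline_run`.
#' @param corpus the gold `citation_corpus` the run was computed on.
#' @return list with `classification` (an `eval_report`) and `retrieval`
#'   (a `retrieval_report`).
#' @export
evaluate_run <- function(run, corpus) {
  gold_ids <- vapply(corpus$instances, function(x) x$instance_id, character(1))
  pred_ids <- run$predictions$instance_id
  if (!setequal(gold_ids, pred_ids)) {
    missing <- setdiff(gold_ids, pred_ids)
    extra <- setdiff(pred_ids, gold_ids)
    stop("instance id mismatch between run and corpus",
         if (length(missing)) paste0("; missing: ",
                                     paste(utils::head(missing, 5), collapse = ", ")),
         if (length(extra)) paste0("; unexpected: ",
                                   paste(utils::head(extra, 5), collapse = ", ")),
         call. = FALSE)
  }
  gold <- vapply(corpus$instances, function(x) x$coarse_label, character(1))
  pred <- run$predictions$label[match(gold_ids, pred_ids)]
  cls <- prf_report(gold, pred, classes = coarse_labels())

  golds <- lapply(corpus$instances, function(x)
    gold_evidence_sentences(x, corpus$reference_docs[[x$reference_doc_id]]))
  retr <- retrieval_report(run$rankings[gold_ids], golds)
  list(classification = cls, retrieval = retr)
}
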