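extract_numbers <- function(text) {
  m <- gregexpr("[0-9]+(\\.[0-9]+)?", text)[[1]]
  if (m[1] == -1) return(character())
  unique(regmatches(text, list(m))[[1]])
}

.negation_words <- c("not", "no", "never", "cannot", "without", "neither",
                     "nor", "lack", "lacks", "lacked", "absent", "fails",
                     "fail", "failed")

has_negation <- function(tokens) any(tokens %in% .negation_words)

# IDF-weighted token overlap of `context` with each evidence sentence,
# normalized by the total IDF mass of the context tokens, so scores live in
# [0, 1]. IDF is computed over the evidence sentence collection itself;
# context terms unseen in that collection are weighted as if df = 1, so a
# handful of novel words cannot swamp the denominator when the collection
# is small (e.g. a single gold evidence sentence).
idf_overlap_profile <- function(context, evidence) {
  ev_toks <- tokenize(evidence)
  n <- length(ev_toks)
  df <- table(unlist(lapply(ev_toks, unique)))
  idf <- function(term) {
    d <- if (term %in% names(df)) as.integer(df[[term]]) else 1L
    bm25_idf(max(d, 1L), n)
  }
  ctx <- unique(tokenize1(context))
  ctx <- setdiff(ctx, c("cit", "multi_cit", "other_cit"))
  denom <- sum(vapply(ctx, idf, numeric(1)))
  vapply(ev_toks, function(toks) {
    shared <- intersect(ctx, toks)
    if (denom == 0) return(0)
    sum(vapply(shared, idf, numeric(1))) / denom
  }, numeric(1))
}

#' Heuristic citation-accuracy backend
#'
#' Desk-scale stand-in for a fine-tuned claim-verification model. A rule
#' cascade over the IDF-weighted lexical overlap between the citation
#' context and each candidate evidence sentence:
#'
#' 1. no evidence, or best overlap below `low` -> IRRELEVANT;
#' 2. overlap at or above `high` with a negation-polarity or numeric
#'    mismatch against the best sentence -> NOT_ACCURATE (contradictions and
#'    misquoted numbers);
#' 3. overlap at or above `high` otherwise -> ACCURATE;
#' 4. intermediate overlap -> NOT_ACCURATE (claims only partially grounded
#'    in the reference).
#'
#' Scores per label are derived from the margins to the thresholds and
#' normalized to sum to one. The thresholds are package choices (defaults
#' `low = 0.1`, `high = 0.6`), not empirical claims.
#'
#' @param context masked citation context text.
#' @param evidence character vector of evidence sentences (may be empty).
#' @param low,high cascade thresholds in `[0, 1]`.
#' @return named numeric vector of scores over [coarse_labels()], summing
#'   to 1.
#' @export
heuristic_backend <- function(context, evidence, low = 0.1, high = 0.6) {
  scores <- c(ACCURATE = 0, NOT_ACCURATE = 0, IRRELEVANT = 0)
  if (length(evidence) == 0) {
    scores["IRRELEVANT"] <- 1
    return(scores)
  }
  overlap <- idf_overlap_profile(context, evidence)
  best <- which.max(overlap)
  o <- overlap[best]

  if (o < low) {
    winner <- "IRRELEVANT"
    margin <- (low - o) / low
  } else if (o >= high) {
    ctx_toks <- tokenize1(context, remove_stopwords = FALSE)
    best_toks <- tokenize1(evidence[best], remove_stopwords = FALSE)
    neg_mismatch <- has_negation(ctx_toks) != has_negation(best_toks)
    ctx_nums <- extract_numbers(context)
    ev_nums <- extract_numbers(evidence[best])
    num_mismatch <- length(ev_nums) > 0 &&
      length(setdiff(ctx_nums, ev_nums)) > 0
    winner <- if (neg_mismatch || num_mismatch) "NOT_ACCURATE" else "ACCURATE"
    margin <- (o - high) / (1 - high)
  } else {
    winner <- "NOT_ACCURATE"
    margin <- 1 - 2 * abs(o - (low + high) / 2) / (high - low)
  }
  # margin in [0,1]; winner gets 0.5 + margin/2 of the mass, rest split evenly
  p <- 0.5 + 0.5 * min(max(margin, 0), 1)
  scores[winner] <- p
  scores[setdiff(names(scores), winner)] <- (1 - p) / 2
  scores / sum(scores)
}

.accuracy_backends <- new.env(parent = emptyenv())

#' Accuracy backend registry
#'
#' Classification backends are functions
#' `(context, evidence, instance_id) -> named score vector` over
#' [coarse_labels()]. `heuristic` is pre-registered;
#' [make_oracle_backend()] builds a gold-reading backend for plumbing tests;
#' [finetune_harness()] wraps trained models under the same contract.
#'
#' @param name backend name.
#' @param fn backend function.
#' @export
register_accuracy_backend <- function(name, fn) {
  stopifnot(is.character(name), length(name) == 1, is.function(fn))
  assign(name, fn, envir = .accuracy_backends)
  invisible(name)
}

#' @rdname register_accuracy_backend
#' @export
accuracy_backends <- function() sort(ls(.accuracy_backends))

get_accuracy_backend <- function(name) {
  if (!exists(name, envir = .accuracy_backends, inherits = FALSE))
    stop("unknown accuracy backend '", name, "'; registered: ",
         paste(accuracy_backends(), collapse = ", "), call. = FALSE)
  get(name, envir = .accuracy_backends, inherits = FALSE)
}

#' Oracle backend reading planted gold labels
#'
#' Returns the gold coarse label of each instance with probability one.
#' Only useful for verifying pipeline plumbing: composed with the full
#' pipeline it must reproduce gold labels exactly.
#'
#' @param instances list of gold [citation_instance()] objects.
#' @return backend function keyed on `instance_id`.
#' @export
make_oracle_backend <- function(instances) {
  gold <- stats::setNames(
    vapply(instances, function(x) x$coarse_label, character(1)),
    vapply(instances, function(x) x$instance_id, character(1)))
  function(context, evidence, instance_id) {
    if (is.null(instance_id) || !instance_id %in% names(gold))
      stop("oracle backend has no gold label for instance '",
           instance_id, "'", call. = FALSE)
    scores <- stats::setNames(rep(0, 3), coarse_labels())
    scores[gold[[instance_id]]] <- 1
    scores
  }
}

#' Classify a citation as ACCURATE / NOT_ACCURATE / IRRELEVANT
#'
#' Applies a classification backend to a (citation context, evidence
#' sentences) pair and wraps the result. The backend must return a full
#' score vector over the three coarse labels; scores are normalized and the
#' argmax becomes the label (ties broken in [coarse_labels()] order).
#'
#' @param context masked citation context (non-empty).
#' @param evidence character vector of evidence sentences (may be empty,
#'   e.g. for etiquette-style citations with no clear referent).
#' @param backend backend function or registered name.
#' @param instance_id optional id passed through to the backend and the
#'   prediction.
#' @return object of class `accuracy_prediction`: `instance_id`, `label`,
#'   `score_per_label`, `backend`, `rationale`.
#' @export
classify <- function(context, evidence, backend,
                     instance_id = NA_character_) {
  stopifnot(is.character(context), length(context) == 1, nzchar(context))
  backend_name <- if (is.character(backend)) backend else "custom"
  if (is.character(backend)) backend <- get_accuracy_backend(backend)
  scores <- backend(context, evidence, instance_id)
  if (!is.numeric(scores) || !setequal(names(scores), coarse_labels()) ||
      anyNA(scores) || any(scores < 0))
    stop("backend '", backend_name, "' violated the score contract",
         if (!is.na(instance_id)) paste0(" (instance ", instance_id, ")"),
         call. = FALSE)
  scores <- scores[coarse_labels()] / sum(scores)
  structure(list(instance_id = instance_id,
                 label = names(scores)[which.max(scores)],
                 score_per_label = scores, backend = backend_name,
                 rationale = attr(scores, "rationale")),
            class = "accuracy_prediction")
}

#' @export
print.accuracy_prediction <- function(x, ...) {
  cat(sprintf("<accuracy_prediction %s: %s (%.2f) [%s]>\n", x$instance_id,
              x$label, max(x$score_per_label), x$backend))
  invisible(x)
}

#' Harness for fine-tuned claim-verification backends
#'
#' Contract wrapper for training a neural sequence-pair classifier (e.g. a
#' Longformer-based multi-task verifier) on an annotated corpus. The
#' harness consolidates fine labels to the three coarse classes before
#' batching, forces the rationale-selection loss weight to 0 (label
#' prediction and rationale selection run in parallel, so disabling the
#' rationale head does not affect the label head), and returns a backend
#' satisfying the [classify()] contract plus a run manifest. No model is
#' bundled: `model_spec$fit` must supply the training routine; without it an
#' "optional backend unavailable" error is raised.
#'
#' @param train_instances list of gold [citation_instance()] objects.
#' @param train_evidence named list mapping instance id to its evidence
#'   sentence texts.
#' @param model_spec list with `name` and `fit`, where `fit(contexts,
#'   evidence, labels, loss_weights)` returns a function
#'   `(context, evidence) -> named score vector` over [coarse_labels()].
#' @return list with `backend` (classification function) and `manifest`
#'   (model name, loss weights, training label counts).
#' @export
finetune_harness <- function(train_instances, train_evidence, model_spec) {
  if (is.null(model_spec$fit) || !is.function(model_spec$fit))
    stop("optional backend unavailable: model_spec$fit missing (no neural ",
         "weights are bundled with this package)", call. = FALSE)
  ids <- vapply(train_instances, function(x) x$instance_id, character(1))
  contexts <- vapply(train_instances, function(x) {
    sents <- segment_sentences(x$paragraph_text)
    sents$text[citance_index(x$paragraph_text, x$marker_span)]
  }, character(1))
  labels <- consolidate_label(
    vapply(train_instances, function(x) x$fine_label, character(1)))
  loss_weights <- c(label = 1, rationale = 0)
  fitted <- model_spec$fit(contexts, train_evidence[ids], labels, loss_weights)
  backend <- function(context, evidence, instance_id = NULL) {
    fitted(context, evidence)
  }
  list(backend = backend,
       manifest = list(model = model_spec$name,
                       loss_weights = loss_weights,
                       n_train = length(train_instances),
                       label_counts = table(factor(labels,
                                                   levels = coarse_labels()))))
}

#' Build an in-context-learning prompt
#'
#' Renders the few-shot prompt used with generative language models: a task
#' instruction with the three class descriptions, four worked
#' demonstrations (one ACCURATE, two NOT_ACCURATE, one IRRELEVANT, each
#' with context, evidence, reasoning and label), and the unlabeled test
#' block. XML-like tags and markdown headers delimit the parts; rendering
#' is byte-stable for fixed inputs. At most `max_evidence` evidence
#' sentences (default 5) are included per block.
#'
#' @param context test citation context.
#' @param evidence test evidence sentences.
#' @param demos list of 4 demonstrations, each a list with `context`,
#'   `evidence` (character vector), `label`, `reasoning`.
#' @param max_evidence evidence sentences kept per block (default 5).
#' @return object of class `prompt_bundle`; `format()` / `as.character()`
#'   yield the rendered prompt.
#' @export
build_icl_prompt <- function(context, evidence, demos, max_evidence = 5) {
  labs <- vapply(demos, function(d) d$label, character(1))
  want <- c(ACCURATE = 1L, NOT_ACCURATE = 2L, IRRELEVANT = 1L)
  have <- table(factor(labs, levels = names(want)))
  if (length(demos) != 4 || !all(as.integer(have) == want))
    stop("demonstrations must be 1 ACCURATE, 2 NOT_ACCURATE, 1 IRRELEVANT",
         call. = FALSE)
  block <- function(ctx, ev) {
    ev <- utils::head(ev, max_evidence)
    paste0("<context>\n", ctx, "\n</context>\n<evidence>\n",
           paste0("- ", ev, collapse = "\n"), "\n</evidence>")
  }
  demo_text <- vapply(demos, function(d) {
    paste0("<example>\n", block(d$context, d$evidence),
           "\nReasoning: ", d$reasoning,
           "\nLabel: ", d$label, "\n</example>")
  }, character(1))
  instruction <- paste(
    "# Task",
    "You check whether a citation accurately represents the reference",
    "article it cites. Given the citation context and evidence sentences",
    "from the reference article, answer with exactly one label:",
    "- ACCURATE: the context is consistent with the evidence (including",
    "  indirect citations whose content is still correct).",
    "- NOT_ACCURATE: the context contradicts, overstates, misquotes or is",
    "  otherwise not substantiated by the evidence.",
    "- IRRELEVANT: the reference article contains no information relevant",
    "  to the citation.",
    "First give your reasoning, then the label on its own line as",
    "'Label: <LABEL>'.", sep = "\n")
  rendered <- paste(instruction, "# Demonstrations",
                    paste(demo_text, collapse = "\n"),
                    "# Test", block(context, evidence), sep = "\n\n")
  structure(list(instruction = instruction, demonstrations = demos,
                 test_context = context,
                 test_evidence = utils::head(evidence, max_evidence),
                 rendered = rendered),
            class = "prompt_bundle")
}

#' @export
format.prompt_bundle <- function(x, ...) x$rendered

#' @export
print.prompt_bundle <- function(x, ...) {
  cat(x$rendered, "\n")
  invisible(x)
}

#' @export
as.character.prompt_bundle <- function(x, ...) x$rendered

#' Parse a model reply into a coarse label
#'
#' Extracts the final `Label: <LABEL>` line from a generative model's reply
#' to an ICL prompt.
#'
#' @param reply reply text.
#' @return one of [coarse_labels()].
#' @export
parse_icl_response <- function(reply) {
  m <- gregexpr("Label:\\s*(ACCURATE|NOT_ACCURATE|IRRELEVANT)", reply,
                perl = TRUE)[[1]]
  if (m[1] == -1)
    stop("no 'Label:' line with a valid class found in reply", call. = FALSE)
  hits <- regmatches(reply, list(m))[[1]]
  sub("Label:\\s*", "", hits[length(hits)])
}
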