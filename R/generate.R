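# --- vocabulary pools -------------------------------------------------------
# Content words are prefix x suffix composites so the pool is large enough to
# keep per-document IDF non-degenerate; the "irrelevant" pool is disjoint from
# every other pool so IRRELEVANT citances share no scoring token with any
# reference article. None of the pools contain negation words.

.content_prefixes <- c("glyco", "neuro", "cardio", "hepato", "immuno", "cyto",
                       "myo", "osteo", "dermo", "angio", "fibro", "lipo",
                       "hemo", "entero", "nephro", "pulmo", "thrombo",
                       "adipo", "chondro", "retino")
.content_suffixes <- c("kinase", "statin", "globin", "peptide", "factor",
                       "receptor", "blast", "cycline", "genase", "lysin",
                       "toxin", "amide", "esterase", "mycin", "ferase",
                       "porin", "crine", "plasmin", "zyme", "merase")
content_pool <- function() {
  as.vector(outer(.content_prefixes, .content_suffixes, paste0))
}

.filler_words <- c("cells", "patients", "expression", "levels", "signaling",
                   "pathway", "tissue", "samples", "cohort", "treatment",
                   "response", "activity", "assay", "baseline", "marker",
                   "serum", "dose", "group", "profile", "outcome")
.verbs <- c("modulates", "alters", "regulates", "affects", "attenuates",
            "enhances", "suppresses", "elevates", "stabilizes", "accelerates")
.irrelevant_pool <- c("asteroid", "basalt", "comet", "crater", "dune",
                      "equinox", "fjord", "geyser", "glacier", "harbor",
                      "island", "jetstream", "lagoon", "meridian", "nebula",
                      "obsidian", "plateau", "quasar", "reef", "savanna",
                      "sediment", "solstice", "tundra", "volcano", "zephyr",
                      "aurora", "canyon", "delta", "estuary", "fossil")
.irrelevant_verbs <- c("erodes", "orbits", "drifts", "crystallizes", "weathers")
.headings <- c("Introduction", "Methods", "Results", "Discussion",
               "Analysis", "Background", "Findings", "Evaluation")

cap_first <- function(x) paste0(toupper(substr(x, 1, 1)), substr(x, 2, nchar(x)))

realize_sentence <- function(tokens, number = NULL, negate = FALSE,
                             verb = NULL) {
  if (is.null(verb)) verb <- sample(.verbs, 1)
  if (negate) verb <- paste("does not", sub("s$", "", verb))
  words <- c(cap_first(tokens[1]), verb, tokens[-1])
  core <- paste(words, collapse = " ")
  if (!is.null(number) && !is.na(number))
    core <- paste0(core, " in ", number, "% of samples")
  paste0(core, ".")
}

filler_sentence <- function(topic) {
  toks <- c(sample(topic, 2), sample(.filler_words, sample(2:3, 1)))
  num <- if (stats::runif(1) < 0.2) sample(5:95, 1) else NULL
  realize_sentence(sample(toks), number = num)
}

single_marker <- function() sprintf("[%d]", sample(1:60, 1))
multi_marker <- function() {
  if (stats::runif(1) < 0.5) {
    a <- sample(1:40, 1)
    sprintf("[%d–%d]", a, a + sample(2:4, 1))
  } else {
    paste0("[", paste(sort(sample(1:40, sample(2:3, 1))), collapse = ","), "]")
  }
}

#' Default fine-label distribution of the generator
#'
#' Proportions of the eight fine labels matching the published distribution
#' of the annotated corpus (1863 / 92 / 243 / 217 / 111 / 38 / 82 / 417 out
#' of 3063 instances).
#'
#' @return named numeric vector summing to 1.
#' @export
default_label_distribution <- function() {
  counts <- c(ACCURATE = 1863, CONTRADICT = 92, NOT_SUBSTANTIATE = 243,
              IRRELEVANT = 217, OVERSIMPLIFY = 111, MISQUOTE = 38,
              INDIRECT = 82, ETIQUETTE = 417)
  counts / sum(counts)
}

#' Configuration of the synthetic corpus generator
#'
#' The generator emulates the annotated-corpus setting at desk scale:
#' citing paragraphs with one highlighted target marker (and occasionally
#' other markers), reference articles of 50-300 sentences organized into
#' titled sections and paragraphs, 1-5 planted evidence segments per
#' evidence-bearing citation, and fine labels drawn from the eight-category
#' taxonomy with the published distribution as default.
#'
#' @param n_reference_docs number of reference articles (default 8).
#' @param sentences_per_doc inclusive range of sentences per article
#'   (default `c(50, 300)`).
#' @param n_instances number of citation instances (default 200).
#' @param label_distribution named probabilities over [fine_labels()],
#'   summing to 1 (default [default_label_distribution()]).
#' @param granularity_mix probabilities of sentence / paragraph / section
#'   evidence granularity (default 0.80 / 0.15 / 0.05).
#' @param extra_context_prob probability that the gold context extends one
#'   sentence beyond the citance (default 0.12, mirroring ~1.12 context
#'   sentences per citation).
#' @param other_marker_prob probability that a neighboring sentence carries
#'   a non-target citation marker (default 0.2).
#' @param medium_copy_frac fraction of evidence content tokens copied into
#'   partially-supported (NOT_SUBSTANTIATE / OVERSIMPLIFY / ETIQUETTE)
#'   citances (default 0.4).
#' @param seed integer seed; generation is a pure function of the config.
#' @return object of class `generator_config`.
#' @export
generator_config <- function(n_reference_docs = 8,
                             sentences_per_doc = c(50, 300),
                             n_instances = 200,
                             label_distribution = default_label_distribution(),
                             granularity_mix = c(sentence = 0.80,
                                                 paragraph = 0.15,
                                                 section = 0.05),
                             extra_context_prob = 0.12,
                             other_marker_prob = 0.2,
                             medium_copy_frac = 0.4,
                             seed = 1L) {
  stopifnot(n_reference_docs >= 1, n_instances >= 1,
            length(sentences_per_doc) == 2,
            sentences_per_doc[1] >= 20,
            sentences_per_doc[1] <= sentences_per_doc[2])
  if (abs(sum(label_distribution) - 1) > 1e-9)
    stop("label_distribution must sum to 1", call. = FALSE)
  assert_fine_label(names(label_distribution))
  structure(list(n_reference_docs = as.integer(n_reference_docs),
                 sentences_per_doc = as.integer(sentences_per_doc),
                 n_instances = as.integer(n_instances),
                 label_distribution = label_distribution,
                 granularity_mix = granularity_mix,
                 extra_context_prob = extra_context_prob,
                 other_marker_prob = other_marker_prob,
                 medium_copy_frac = medium_copy_frac,
                 seed = as.integer(seed)),
            class = "generator_config")
}

# label-conditional citance construction; `planted` is the instance's content
# token vector, `num` its number (or NA)
build_citance_body <- function(label, planted, num, doc_sentences, cfg) {
  fresh <- function(n) sample(content_pool(), n)
  switch(label,
    ACCURATE = realize_sentence(sample(planted), number = num),
    INDIRECT = realize_sentence(sample(planted), number = num),
    CONTRADICT = realize_sentence(sample(planted), number = num,
                                  negate = TRUE),
    MISQUOTE = {
      wrong <- sample(setdiff(5:95, num), 1)
      realize_sentence(sample(planted), number = wrong)
    },
    NOT_SUBSTANTIATE = ,
    OVERSIMPLIFY = {
      keep <- sample(planted, max(2, round(cfg$medium_copy_frac * length(planted))))
      realize_sentence(sample(c(keep, fresh(3))))
    },
    ETIQUETTE = {
      src <- tokenize1(sample(doc_sentences, 1))
      src <- setdiff(src, c("cit", "multi_cit", "other_cit"))
      keep <- sample(src, max(2, round(cfg$medium_copy_frac * length(src))))
      realize_sentence(sample(c(keep, fresh(3))))
    },
    IRRELEVANT = realize_sentence(sample(.irrelevant_pool, 5),
                                  verb = sample(.irrelevant_verbs, 1))
  )
}

#' Generate a synthetic annotated corpus
#'
#' Produces reference articles and citation instances with planted gold
#' annotations, fully reproducible from the config seed. Label-conditional
#' construction: ACCURATE / INDIRECT citances paraphrase a planted evidence
#' sentence (high token overlap; the INDIRECT evidence sentence itself
#' carries a citation marker), CONTRADICT inserts a negation, MISQUOTE
#' perturbs a number, NOT_SUBSTANTIATE / OVERSIMPLIFY copy only part of the
#' evidence content (medium overlap), ETIQUETTE citances are topical but
#' ambiguous multi-citations with no evidence segment, and IRRELEVANT
#' citances draw from a vocabulary disjoint from every reference article.
#'
#' @param config a [generator_config()].
#' @return object of class `citation_corpus`: `reference_docs` (named list
#'   of [reference_document()]), `instances` (list of
#'   [citation_instance()]), `config`.
#' @export
generate_corpus <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  })
  set.seed(config$seed)

  n_docs <- config$n_reference_docs
  pool <- content_pool()

  # phase A: per-instance draws
  n <- config$n_instances
  labels <- sample(names(config$label_distribution), n, replace = TRUE,
                   prob = config$label_distribution)
  doc_of <- sample(rep_len(seq_len(n_docs), n))
  plan <- vector("list", n)
  for (i in seq_len(n)) {
    lab <- labels[i]
    has_evidence <- !lab %in% c("IRRELEVANT", "ETIQUETTE")
    content <- sample(pool, 6)
    num <- if (lab == "MISQUOTE" || stats::runif(1) < 0.3)
      sample(5:95, 1) else NA_integer_
    k <- if (has_evidence)
      sample(1:5, 1, prob = c(0.80, 0.10, 0.05, 0.03, 0.02)) else 0L
    planted_texts <- character(0)
    if (has_evidence) {
      planted_texts <- vapply(seq_len(k), function(j) {
        s <- realize_sentence(sample(content), number = num)
        if (lab == "INDIRECT")
          s <- sub("\\.$", paste0(" ", single_marker(), "."), s)
        s
      }, character(1))
    }
    grans <- if (k > 0)
      sample(names(config$granularity_mix), k, replace = TRUE,
             prob = config$granularity_mix) else character(0)
    plan[[i]] <- list(label = lab, content = content, num = num,
                      planted = planted_texts, granularity = grans)
  }

  # phase B: build reference documents around the planted sentences
  reference_docs <- list()
  planted_pos <- vector("list", n)   # instance -> global sentence positions
  for (d in seq_len(n_docs)) {
    doc_id <- sprintf("ref%02d", d)
    topic <- sample(pool, 12)
    members <- which(doc_of == d)
    planted_all <- unlist(lapply(members, function(i) plan[[i]]$planted))
    owner <- rep(members, vapply(members, function(i)
      length(plan[[i]]$planted), integer(1)))
    target_n <- sample(config$sentences_per_doc[1]:config$sentences_per_doc[2], 1)
    n_total <- max(target_n, length(planted_all) + 20L)
    n_fill <- n_total - length(planted_all)
    sentences <- character(n_total)
    pos <- sort(sample(n_total, length(planted_all)))
    sentences[pos] <- planted_all
    sentences[setdiff(seq_len(n_total), pos)] <-
      vapply(seq_len(n_fill), function(j) filler_sentence(topic), character(1))
    for (i in members) planted_pos[[i]] <- integer(0)
    for (j in seq_along(pos)) {
      i <- owner[j]
      planted_pos[[i]] <- c(planted_pos[[i]], pos[j])
    }

    # partition into abstract + body sections of multi-sentence paragraphs
    abstract_len <- sample(4:8, 1)
    body <- sentences[-seq_len(abstract_len)]
    n_sections <- sample(3:6, 1)
    sec_sizes <- tabulate(sample(n_sections, length(body), replace = TRUE),
                          nbins = n_sections)
    sec_sizes <- sec_sizes[sec_sizes > 0]
    sections <- list(list(
      heading = "Abstract",
      paragraphs = paste(sentences[seq_len(abstract_len)], collapse = " ")))
    offset <- 0
    for (s in seq_along(sec_sizes)) {
      sec_sents <- body[offset + seq_len(sec_sizes[s])]
      offset <- offset + sec_sizes[s]
      para_sizes <- c()
      left <- length(sec_sents)
      while (left > 0) {
        take <- min(left, sample(3:8, 1))
        para_sizes <- c(para_sizes, take)
        left <- left - take
      }
      p_off <- 0
      paras <- vapply(para_sizes, function(sz) {
        out <- paste(sec_sents[p_off + seq_len(sz)], collapse = " ")
        p_off <<- p_off + sz
        out
      }, character(1))
      sections[[length(sections) + 1L]] <-
        list(heading = sample(.headings, 1), paragraphs = paras)
    }
    title <- paste(cap_first(topic[1]), "and", topic[2], "in clinical cohorts")
    doc <- reference_document(doc_id, title, sections)
    if (nrow(doc$sentences) != n_total)
      stop("internal generator error: segmentation drift in ", doc_id,
           " (", nrow(doc$sentences), " vs ", n_total, ")", call. = FALSE)
    reference_docs[[doc_id]] <- doc
  }

  # phase C: citing paragraphs and gold annotations
  instances <- vector("list", n)
  for (i in seq_len(n)) {
    p <- plan[[i]]
    doc_id <- sprintf("ref%02d", doc_of[i])
    doc <- reference_docs[[doc_id]]
    marker <- if (p$label == "ETIQUETTE") multi_marker()
              else if (stats::runif(1) < 0.9) single_marker()
              else multi_marker()
    multiplicity <- if (grepl("[,–]", marker)) "multi" else "single"

    body <- build_citance_body(p$label, p$content, p$num,
                               doc$sentences$text, config)
    citance <- sub("\\.$", paste0(" ", marker, "."), body)

    topic <- sample(pool, 6)
    n_before <- sample(0:2, 1)
    n_after <- sample(0:2, 1)
    before <- vapply(seq_len(n_before), function(j) filler_sentence(topic),
                     character(1))
    after <- vapply(seq_len(n_after), function(j) filler_sentence(topic),
                    character(1))

    # optional second gold context sentence: a neighbor echoing the citance
    extra_context <- FALSE
    if (stats::runif(1) < config$extra_context_prob &&
        !p$label %in% c("IRRELEVANT", "ETIQUETTE")) {
      echo <- realize_sentence(sample(p$content), number = p$num)
      after <- c(echo, after)
      n_after <- n_after + 1L
      extra_context <- TRUE
    }

    # optional non-target marker in a filler neighbor
    other_marker <- NULL
    if ((n_before + n_after) > (if (extra_context) 1L else 0L) &&
        stats::runif(1) < config$other_marker_prob) {
      other_marker <- single_marker()
      if (n_before > 0) {
        before[1] <- sub("\\.$", paste0(" ", other_marker, "."), before[1])
      } else if (n_after > (if (extra_context) 1 else 0)) {
        after[n_after] <- sub("\\.$", paste0(" ", other_marker, "."),
                              after[n_after])
      } else other_marker <- NULL
    }

    sents <- c(before, citance, after)
    paragraph <- paste(sents, collapse = " ")
    starts0 <- cumsum(c(0, utils::head(nchar(sents) + 1L, -1)))
    citance_idx <- n_before + 1L
    m_in <- regexpr(marker, citance, fixed = TRUE)
    marker_span <- starts0[citance_idx] + c(m_in - 1L,
                                            m_in - 1L + nchar(marker))
    other_spans <- list()
    if (!is.null(other_marker)) {
      host <- if (n_before > 0) 1L else length(sents)
      o_in <- regexpr(other_marker, sents[host], fixed = TRUE)
      other_spans <- list(starts0[host] + c(o_in - 1L,
                                            o_in - 1L + nchar(other_marker)))
    }
    context_ids <- citance_idx
    if (extra_context) context_ids <- c(citance_idx, citance_idx + 1L)

    segments <- list()
    if (length(planted_pos[[i]]) > 0) {
      seen <- character(0)
      for (j in seq_along(planted_pos[[i]])) {
        pos <- planted_pos[[i]][j]
        gran <- p$granularity[j]
        unit <- switch(gran,
          sentence = doc$sentences$sentence_id[pos],
          paragraph = doc$sentences$paragraph_id[pos],
          section = doc$sentences$section_id[pos])
        key <- paste(gran, unit)
        if (key %in% seen) next
        seen <- c(seen, key)
        segments[[length(segments) + 1L]] <-
          evidence_segment(doc_id, gran, unit)
      }
    }

    instances[[i]] <- citation_instance(
      instance_id = sprintf("inst%04d", i),
      citing_doc_id = sprintf("citing%04d", i),
      reference_doc_id = doc_id,
      paragraph_text = paragraph,
      marker_span = marker_span,
      marker_multiplicity = multiplicity,
      other_marker_spans = other_spans,
      context_sentence_ids = context_ids,
      evidence_segments = segments,
      fine_label = p$label)
  }

  structure(list(reference_docs = reference_docs, instances = instances,
                 config = config),
            class = "citation_corpus")
}

#' @export
print.citation_corpus <- function(x, ...) {
  cat(sprintf("<citation_corpus: %d instances over %d reference documents (seed %d)>\n",
              length(x$instances), length(x$reference_docs), x$config$seed))
  invisible(x)
}

#' Verify a generated corpus against its construction rules
#'
#' Re-checks every structural invariant of the instances (marker spans,
#' citance membership, evidence cardinality), that all evidence segments
#' resolve in their documents, and the label-conditional planting rules
#' (negation present for CONTRADICT, number mismatch for MISQUOTE, lexical
#' link present for ACCURATE-like labels and absent for IRRELEVANT,
#' multi-citation markers for ETIQUETTE).
#'
#' @param corpus a `citation_corpus`.
#' @return character vector of violation messages (empty when the corpus is
#'   well-formed).
#' @export
plant_check <- function(corpus) {
  violations <- character(0)
  note <- function(id, msg)
    violations <<- c(violations, paste0(id, ": ", msg))

  for (inst in corpus$instances) {
    id <- inst$instance_id
    doc <- corpus$reference_docs[[inst$reference_doc_id]]
    if (is.null(doc)) { note(id, "unknown reference document"); next }
    err <- tryCatch({ validate_citation_instance(inst); NULL },
                    error = function(e) conditionMessage(e))
    if (!is.null(err)) { note(id, err); next }
    gold <- tryCatch(gold_evidence_sentences(inst, doc),
                     error = function(e) { note(id, conditionMessage(e)); NULL })
    if (is.null(gold) && length(inst$evidence_segments) > 0) next

    sents <- segment_sentences(inst$paragraph_text)
    citance <- sents$text[citance_index(inst$paragraph_text, inst$marker_span)]
    ctx_toks <- tokenize1(citance)
    lab <- inst$fine_label

    if (lab %in% c("ACCURATE", "INDIRECT", "CONTRADICT", "MISQUOTE")) {
      ev_texts <- sentence_text(doc, gold)
      best <- max(vapply(ev_texts, function(s)
        length(intersect(ctx_toks, tokenize1(s))), numeric(1)))
      if (best < 3) note(id, paste0(lab, " citance shares too few tokens ",
                                    "with its planted evidence"))
    }
    if (lab == "CONTRADICT" &&
        !has_negation(tokenize1(citance, remove_stopwords = FALSE)))
      note(id, "CONTRADICT citance carries no negation")
    if (lab == "MISQUOTE") {
      ev_nums <- unique(unlist(lapply(sentence_text(doc, gold),
                                      extract_numbers)))
      ctx_nums <- extract_numbers(sub("\\[[0-9,– -]+\\]", "", citance))
      if (length(setdiff(ctx_nums, ev_nums)) == 0)
        note(id, "MISQUOTE citance carries no perturbed number")
    }
    if (lab == "INDIRECT") {
      if (!any(grepl("\\[[0-9]+\\]", sentence_text(doc, gold))))
        note(id, "INDIRECT evidence carries no citation marker")
    }
    if (lab == "ETIQUETTE" && inst$marker_multiplicity != "multi")
      note(id, "ETIQUETTE marker is not a multi-citation")
    if (lab == "IRRELEVANT") {
      doc_toks <- unique(unlist(tokenize(doc$sentences$text)))
      words_only <- function(x) x[!grepl("^[0-9]+$", x)]  # marker digits aside
      if (length(intersect(words_only(setdiff(ctx_toks, "cit")),
                           words_only(doc_toks))) > 0)
        note(id, "IRRELEVANT citance shares vocabulary with the reference")
    }
  }
  violations
}
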