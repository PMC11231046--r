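# Independent brute-force oracles. These are deliberately written from the
# closed forms, not by calling package internals, so they can certify the
# implementation.

# Okapi BM25 with idf = log(1 + (N - df + 0.5)/(df + 0.5)), one score per
# sentence, straight from the formula.
oracle_bm25_scores <- function(query_tokens, sent_tokens, k1 = 1.2, b = 0.75) {
  N <- length(sent_tokens)
  lens <- vapply(sent_tokens, length, integer(1))
  avg <- mean(lens)
  df_of <- function(term) sum(vapply(sent_tokens, function(s) term %in% s,
                                     logical(1)))
  vapply(seq_len(N), function(i) {
    s <- 0
    for (term in unique(query_tokens)) {
      tf <- sum(sent_tokens[[i]] == term)
      if (tf == 0) next
      df <- df_of(term)
      idf <- log(1 + (N - df + 0.5) / (df + 0.5))
      s <- s + idf * tf * (k1 + 1) /
        (tf + k1 * (1 - b + b * lens[i] / avg))
    }
    s
  }, numeric(1))
}

# Cohen's kappa straight from a contingency table of two raters.
oracle_kappa_from_table <- function(tab) {
  n <- sum(tab)
  po <- sum(diag(tab)) / n
  pe <- sum(rowSums(tab) * colSums(tab)) / n^2
  if (abs(pe - 1) < 1e-12) return(NA_real_)
  (po - pe) / (1 - pe)
}

# Exact two-sided McNemar p by direct binomial pmf summation.
oracle_mcnemar_exact_p <- function(b, c) {
  n <- b + c
  if (n == 0) return(1)
  m <- min(b, c)
  lower <- sum(vapply(0:m, function(i) choose(n, i) * 0.5^n, numeric(1)))
  min(1, 2 * lower)
}

# One-vs-rest P/R/F1 from raw label vectors, by counting.
oracle_prf <- function(gold, pred, cl) {
  tp <- sum(gold == cl & pred == cl)
  fp <- sum(gold != cl & pred == cl)
  fn <- sum(gold == cl & pred != cl)
  p <- if (tp + fp == 0) 0 else tp / (tp + fp)
  r <- if (tp + fn == 0) 0 else tp / (tp + fn)
  f1 <- if (p + r == 0) 0 else 2 * p * r / (p + r)
  c(precision = p, recall = r, f1 = f1)
}

# Random word unlikely to collide with abbreviation handling: 3 lowercase
# letters, capitalized on demand.
rand_word <- function() paste(sample(setdiff(letters, c("q")), 3, TRUE),
                              collapse = "")

# Reference document whose sentences are given verbatim, one per paragraph,
# so segmentation can never merge or split them.
doc_from_sentences <- function(texts, doc_id = "d1",
                               title = "Fixture document",
                               heading = "Body") {
  reference_document(doc_id, title,
                     list(list(heading = heading, paragraphs = texts)))
}

# Random standoff document: random text plus entities with 1-2 intervals and
# optional label attributes.
random_standoff <- function() {
  words <- replicate(30, rand_word())
  text <- paste(words, collapse = " ")
  n_ent <- sample(0:4, 1)
  entities <- list()
  attrs <- data.frame(id = character(), name = character(),
                      target = character(), value = character(),
                      stringsAsFactors = FALSE)
  for (i in seq_len(n_ent)) {
    n_spans <- sample(1:2, 1)
    spans <- lapply(seq_len(n_spans), function(j) {
      start <- sample(0:(nchar(text) - 4), 1)
      c(start, start + sample(2:4, 1))
    })
    spans <- spans[order(vapply(spans, `[`, numeric(1), 1))]
    surface <- paste(vapply(spans, function(sp)
      substr(text, sp[1] + 1, sp[2]), character(1)), collapse = " ")
    entities[[i]] <- list(id = paste0("T", i), type = "Mark",
                          spans = spans, text = surface)
    if (stats::runif(1) < 0.5) {
      attrs <- rbind(attrs, data.frame(
        id = paste0("A", nrow(attrs) + 1), name = "Label",
        target = paste0("T", i), value = sample(fine_labels(), 1),
        stringsAsFactors = FALSE))
    }
  }
  structure(list(text = text, entities = entities, attributes = attrs),
            class = "standoff_document")
}

# Minimal hand-built citation instance over a tiny fixture document.
tiny_fixture <- function(fine_label = "ACCURATE") {
  doc <- reference_document("refX", "Alphakinase in cohorts", list(
    list(heading = "Abstract",
         paragraphs = "Alphakinase modulates betatoxin in serum."),
    list(heading = "Results",
         paragraphs = c("Alphakinase elevates gammafactor levels in tissue. Controls stayed at baseline.",
                        "Deltaporin suppresses betatoxin in plasma."))))
  paragraph <- "Prior work set the stage. Alphakinase elevates gammafactor levels in tissue [3]. Later studies differed."
  marker <- locate_markers(paragraph)
  segs <- if (fine_label %in% c("IRRELEVANT", "ETIQUETTE")) list() else
    list(evidence_segment("refX", "sentence", "s2"))
  inst <- citation_instance(
    instance_id = "i1", citing_doc_id = "c1", reference_doc_id = "refX",
    paragraph_text = paragraph,
    marker_span = c(marker$start[1], marker$end[1]),
    marker_multiplicity = marker$multiplicity[1],
    context_sentence_ids = 2L, evidence_segments = segs,
    fine_label = fine_label)
  list(doc = doc, instance = inst)
}

small_corpus <- function(seed = 1, n = 40) {
  generate_corpus(generator_config(n_reference_docs = 3,
                                   sentences_per_doc = c(40, 80),
                                   n_instances = n, seed = seed))
}
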