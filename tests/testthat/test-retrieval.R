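test_that("sentence segmentation handles scientific prose", {
  two <- segment_sentences("A fact. Another fact.")
  expect_identical(two$text, c("A fact.", "Another fact."))
  expect_identical(two$start, c(0L, 8L))
  expect_identical(two$end, c(7L, 21L))

  expect_identical(nrow(segment_sentences("Smith et al. (2020) showed X.")), 1L)
  expect_identical(nrow(segment_sentences("See Fig. 2 for details.")), 1L)
  expect_identical(nrow(segment_sentences("It rose by 3.5 percent. Then fell.")), 2L)
  expect_identical(nrow(segment_sentences("")), 0L)
  expect_identical(nrow(segment_sentences("   ")), 0L)
})

test_that("segmentation covers all non-whitespace text with increasing offsets", {
  corp <- small_corpus(seed = 4, n = 15)
  paras <- vapply(corp$instances, function(x) x$paragraph_text, character(1))
  for (p in paras) {
    sents <- segment_sentences(p)
    expect_false(is.unsorted(sents$start))
    expect_true(all(sents$end > sents$start))
    rebuilt <- paste(sents$text, collapse = "")
    expect_identical(gsub("[[:space:]]", "", rebuilt),
                     gsub("[[:space:]]", "", p))
    for (i in seq_len(nrow(sents))) {
      expect_identical(substr(p, sents$start[i] + 1, sents$end[i]),
                       sents$text[i])
    }
  }
})

test_that("bm25_rank agrees with the brute-force formula on random documents", {
  set.seed(123)
  vocab <- replicate(40, rand_word())
  for (rep in 1:100) {
    n_sent <- sample(3:50, 1)
    texts <- vapply(seq_len(n_sent), function(i) {
      words <- sample(vocab, sample(4:10, 1), replace = TRUE)
      paste0(paste(words, collapse = " "), ".")
    }, character(1))
    doc <- doc_from_sentences(texts, doc_id = paste0("bm", rep))
    query <- paste(sample(vocab, sample(2:5, 1), replace = TRUE),
                   collapse = " ")
    cfg <- retrieval_config(first_stage_n = n_sent, top_k = 1, reranker = "none")
    got <- bm25_rank(query, doc, cfg)

    oracle <- oracle_bm25_scores(unlist(tokenize(query)),
                                 tokenize(texts), k1 = 1.2, b = 0.75)
    ord <- order(-oracle, seq_along(oracle))
    expect_identical(got$ranking$sentence_id,
                     doc$sentences$sentence_id[ord])
    expect_equal(got$ranking$score, oracle[ord], tolerance = 1e-9)
  }
})

test_that("bm25 edge behavior: exact match, duplicates, out-of-vocabulary", {
  texts <- c("Alphakinase elevates gammafactor strongly.",
             "Weather stayed calm and dry.",
             "Harvest finished early this season.")
  doc <- doc_from_sentences(texts, doc_id = "edge1")
  got <- bm25_rank("alphakinase elevates gammafactor strongly", doc,
                   retrieval_config(first_stage_n = 3, top_k = 1))
  expect_identical(got$ranking$sentence_id[1], "s1")

  dup <- doc_from_sentences(c("Alpha beta gamma now.", "Alpha beta gamma now.",
                              "Delta epsilon zeta here."), doc_id = "edge2")
  r <- bm25_rank("alpha beta", dup, retrieval_config(first_stage_n = 3, top_k = 1))
  expect_equal(r$ranking$score[1], r$ranking$score[2])
  expect_identical(r$ranking$sentence_id[1:2], c("s1", "s2"))  # position ties

  oov <- bm25_rank("zzqqy wwxxv", dup, retrieval_config(first_stage_n = 3, top_k = 1))
  expect_identical(oov$flag, "query_out_of_vocabulary")
  expect_true(all(oov$ranking$score == 0))
  expect_identical(oov$ranking$sentence_id, c("s1", "s2", "s3"))

  expect_error(bm25_rank("of the and", dup, retrieval_config()),
               "zero terms")
})

test_that("adding a non-matching sentence leaves the positive-score set intact", {
  texts <- c("Alphakinase elevates gammafactor strongly.",
             "Gammafactor appears in serum.",
             "Weather stayed calm and dry.")
  doc1 <- doc_from_sentences(texts, doc_id = "mono1")
  doc2 <- doc_from_sentences(c(texts, "Harvest finished early again."),
                             doc_id = "mono2")
  q <- "alphakinase gammafactor"
  s1 <- bm25_rank(q, doc1, retrieval_config(first_stage_n = 10, top_k = 5))
  s2 <- bm25_rank(q, doc2, retrieval_config(first_stage_n = 10, top_k = 5))
  pos1 <- sort(s1$ranking$sentence_id[s1$ranking$score > 0])
  pos2 <- sort(s2$ranking$sentence_id[s2$ranking$score > 0])
  expect_identical(pos1, pos2)
})

test_that("reranking reorders but never changes the candidate set", {
  texts <- c("Alphakinase elevates gammafactor strongly.",
             "Gammafactor appears in serum samples.",
             "Alphakinase stays inert in plasma.",
             "Weather stayed calm and dry.")
  doc <- doc_from_sentences(texts, doc_id = "rr1")
  q <- "alphakinase gammafactor serum"
  first <- bm25_rank(q, doc, retrieval_config(first_stage_n = 4, top_k = 1,
                                              reranker = "none"))
  expect_true(all(diff(first$ranking$score) <= 0))

  # identity scorer: returns each sentence's BM25 score -> order unchanged
  lookup <- stats::setNames(first$ranking$score, first$ranking$sentence_id)
  ident <- rerank(first, q, function(query, sent) {
    id <- doc$sentences$sentence_id[match(sent, doc$sentences$text)]
    lookup[[id]]
  }, doc)
  expect_identical(ident$ranking$sentence_id, first$ranking$sentence_id)
  expect_identical(ident$stage, "reranked")

  # negated scorer: exact reversal (scores are distinct here)
  expect_identical(length(unique(first$ranking$score)), 4L)
  neg <- rerank(first, q, function(query, sent) {
    id <- doc$sentences$sentence_id[match(sent, doc$sentences$text)]
    -lookup[[id]]
  }, doc)
  expect_identical(neg$ranking$sentence_id, rev(first$ranking$sentence_id))

  # IDF-overlap reranker agrees with brute-force scoring
  rr <- rerank(first, q, "idf_overlap", doc)
  scorer <- idf_overlap_scorer(doc)
  brute <- vapply(sentence_text(doc, first$ranking$sentence_id),
                  function(s) scorer(q, s), numeric(1), USE.NAMES = FALSE)
  pos <- match(first$ranking$sentence_id, doc$sentences$sentence_id)
  expect_identical(rr$ranking$sentence_id,
                   first$ranking$sentence_id[order(-brute, pos)])

  # failing scorer falls back to the input ordering with a warning
  expect_warning(
    fb <- rerank(first, q, function(query, sent) stop("boom"), doc),
    "reranker failed")
  expect_identical(fb$ranking$sentence_id, first$ranking$sentence_id)
  expect_identical(fb$flag, "reranker_failed")
})

test_that("title-and-abstract baseline returns document-ordered units", {
  doc <- reference_document("ta1", "Alphakinase in cohorts", list(
    list(heading = "Abstract",
         paragraphs = "One. Two. Three. Four. Five."),
    list(heading = "Results", paragraphs = "Alpha rises. Beta falls.")))
  got <- title_abstract_evidence(doc)
  expect_identical(got$ranking$sentence_id,
                   c("title", "s1", "s2", "s3", "s4", "s5"))
  expect_true(is.na(got$flag))

  bare <- reference_document("ta2", "No abstract here", list(
    list(heading = "Results", paragraphs = "Alpha rises. Beta falls.")))
  got2 <- title_abstract_evidence(bare)
  expect_identical(got2$ranking$sentence_id, "title")
  expect_identical(got2$flag, "no_abstract")
})

test_that("build_query selects and masks the right sentences", {
  fx <- tiny_fixture("ACCURATE")
  inst <- fx$instance
  q <- build_query(inst, "citance")
  expect_identical(q, "Alphakinase elevates gammafactor levels in tissue [cit].")

  # instance with a two-sentence gold context separated by a gap
  para <- paste("Alphakinase elevates gammafactor [2].",
                "An unrelated filler sits between.",
                "Gammafactor stays high in tissue.")
  mk <- locate_markers(para)
  gap <- citation_instance("g1", "c", "refX", para,
                           c(mk$start[1], mk$end[1]), "single", list(),
                           context_sentence_ids = c(1L, 3L),
                           evidence_segments = list(
                             evidence_segment("refX", "sentence", "s2")),
                           fine_label = "ACCURATE")
  expect_identical(build_query(gap, "gold_context"),
                   paste("Alphakinase elevates gammafactor [cit].",
                         "Gammafactor stays high in tissue."))
  expect_identical(build_query(gap, "gold_context_with_intervening"),
                   paste("Alphakinase elevates gammafactor [cit].",
                         "An unrelated filler sits between.",
                         "Gammafactor stays high in tissue."))
})
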