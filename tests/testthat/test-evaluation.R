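test_that("prf_report matches the count-based oracle on a fixed confusion matrix", {
  # 3-class confusion matrix [[5,1,0],[2,3,1],[0,0,8]] (rows gold, cols pred)
  cm <- matrix(c(5, 1, 0,
                 2, 3, 1,
                 0, 0, 8), nrow = 3, byrow = TRUE)
  classes <- c("A", "B", "C")
  gold <- rep(classes, times = rowSums(cm))
  pred <- unlist(lapply(1:3, function(i) rep(classes, times = cm[i, ])))

  rep_ <- prf_report(gold, pred, classes)
  for (i in seq_along(classes)) {
    want <- oracle_prf(gold, pred, classes[i])
    row <- rep_$per_class[rep_$per_class$class == classes[i], ]
    expect_equal(row$precision, unname(want["precision"]))
    expect_equal(row$recall, unname(want["recall"]))
    expect_equal(row$f1, unname(want["f1"]))
  }
  expect_equal(rep_$micro_f1, sum(diag(cm)) / sum(cm))
  expect_equal(rep_$macro_f1, mean(rep_$per_class$f1))

  perfect <- prf_report(gold, gold, classes)
  expect_equal(perfect$micro_f1, 1)
  expect_equal(perfect$macro_f1, 1)
  expect_true(all(perfect$per_class$f1 == 1))
})

test_that("prf_report conventions: absent classes, mismatches, micro = accuracy", {
  rep_ <- prf_report(c("A", "A", "B"), c("A", "B", "B"),
                     classes = c("A", "B", "GHOST"))
  ghost <- rep_$per_class[rep_$per_class$class == "GHOST", ]
  expect_identical(ghost$f1, 0)
  expect_true(rep_$zero_division)
  expect_equal(rep_$macro_f1, mean(rep_$per_class$f1))  # ghost included

  expect_error(prf_report(c("A", "B"), c("A")), "equal length")
  expect_error(prf_report(c("A"), c("Z"), classes = c("A", "B")),
               "outside the class universe")

  set.seed(99)
  for (rep in 1:20) {
    labs <- sample(LETTERS[1:4], 60, replace = TRUE)
    preds <- sample(LETTERS[1:4], 60, replace = TRUE)
    r <- prf_report(labs, preds, LETTERS[1:4])
    expect_equal(r$micro_f1, mean(labs == preds))   # micro-F1 == accuracy
  }
})

test_that("recall@k and MRR match brute-force scans", {
  expect_equal(recall_at_k(c("s1", "s3", "s7"), "s3", k = 1), 0)
  expect_equal(recall_at_k(c("s1", "s3", "s7"), "s3", k = 5), 1)
  expect_equal(recall_at_k(c("s2", "s5", "s9", "s1", "s4"),
                           c("s2", "s9"), k = 2), 0.5)
  expect_true(is.na(recall_at_k(c("s1"), character(), k = 5)))

  m <- mean_reciprocal_rank(list(c("s9", "s3")), list("s3"))
  expect_equal(m$mrr, 0.5)
  deep <- mean_reciprocal_rank(list(paste0("s", 1:30)), list("s25"),
                               cutoff = 20)
  expect_equal(deep$mrr, 0)                       # beyond the cutoff

  set.seed(17)
  all_ids <- paste0("s", 1:60)
  rankings <- list(); golds <- list()
  for (i in 1:100) {
    rankings[[i]] <- sample(all_ids, 40)
    golds[[i]] <- if (i %% 10 == 0) character() else sample(all_ids, sample(1:4, 1))
  }
  for (k in c(1, 5, 10, 20)) {
    got <- retrieval_report(rankings, golds, ks = k)$recall_at[[1]]
    brute <- mean(mapply(function(r, g) {
      if (length(g) == 0) return(NA_real_)
      sum(g %in% r[seq_len(min(k, length(r)))]) / length(g)
    }, rankings, golds), na.rm = TRUE)
    expect_equal(got, brute)
  }
  got_mrr <- mean_reciprocal_rank(rankings, golds)
  brute_rr <- mapply(function(r, g) {
    if (length(g) == 0) return(NA_real_)
    hits <- which(r[1:20] %in% g)
    if (length(hits) == 0) 0 else 1 / min(hits)
  }, rankings, golds)
  expect_equal(got_mrr$mrr, mean(brute_rr, na.rm = TRUE))
  expect_identical(got_mrr$n_excluded, 10L)

  # recall@k non-decreasing in k
  rep_ <- retrieval_report(rankings, golds)
  expect_false(is.unsorted(rep_$recall_at))
})

test_that("recall at the full document size is 1 when gold is in the ranking", {
  corp <- small_corpus(seed = 12, n = 20)
  for (inst in corp$instances[1:10]) {
    doc <- corp$reference_docs[[inst$reference_doc_id]]
    gold <- gold_evidence_sentences(inst, doc)
    if (length(gold) == 0) next
    full <- bm25_rank(build_query(inst, "citance"), doc,
                      retrieval_config(first_stage_n = nrow(doc$sentences)))
    expect_equal(recall_at_k(full, gold, k = nrow(doc$sentences)), 1)
  }
})

test_that("Cohen's kappa matches the closed form", {
  expect_equal(cohen_kappa(c("x", "y", "x", "z"), c("x", "y", "x", "z")), 1)

  # 2x2 table a=20, b=5, c=5, d=20: po = 0.8, pe = 0.5, kappa = 0.6
  a_lab <- c(rep("P", 25), rep("N", 25))
  b_lab <- c(rep("P", 20), rep("N", 5), rep("P", 5), rep("N", 20))
  expect_equal(cohen_kappa(a_lab, b_lab), 0.6)
  expect_equal(cohen_kappa(a_lab, b_lab),
               oracle_kappa_from_table(table(a_lab, b_lab)))

  # one annotator constant: kappa <= 0 or undefined, per the closed form
  const <- rep("P", 50)
  expect_equal(cohen_kappa(const, b_lab),
               oracle_kappa_from_table(table(factor(const, c("N", "P")),
                                             factor(b_lab, c("N", "P")))))
  expect_true(cohen_kappa(const, b_lab) <= 0)
  expect_warning(k_undef <- cohen_kappa(const, const), "undefined")
  expect_true(is.na(k_undef))

  expect_error(cohen_kappa(c("a", "b"), c("a")), "equal length")
})

test_that("kappa is invariant under relabeling of categories", {
  set.seed(31)
  for (rep in 1:20) {
    a <- sample(c("u", "v", "w"), 40, replace = TRUE)
    b <- sample(c("u", "v", "w"), 40, replace = TRUE)
    perm <- sample(c("u", "v", "w"))
    relabel <- function(x) stats::setNames(perm, c("u", "v", "w"))[x]
    expect_equal(cohen_kappa(a, b), cohen_kappa(relabel(a), relabel(b)))
  }
})

test_that("agreement_report averages pairwise kappas", {
  ann <- list(r1 = c("x", "x", "y", "y", "x", "y"),
              r2 = c("x", "x", "y", "x", "x", "y"),
              r3 = c("y", "x", "y", "y", "x", "x"))
  rep_ <- agreement_report(ann)
  expect_identical(nrow(rep_$pairwise), 3L)
  expect_equal(rep_$pairwise$kappa[1], cohen_kappa(ann$r1, ann$r2))
  expect_equal(rep_$average, mean(rep_$pairwise$kappa))
})

test_that("sentence-level kappa via segment expansion works end to end", {
  doc <- reference_document("r", "Title here", list(
    list(heading = "Results",
         paragraphs = c("Alpha rises. Beta falls. Gamma holds.",
                        "Delta shifts. Epsilon stays."))))
  universe <- doc$sentences$sentence_id
  ann_a <- expand_segment_to_sentences(evidence_segment("r", "paragraph", "p1"),
                                       doc)
  ann_b <- expand_segment_to_sentences(evidence_segment("r", "sentence", "s2"),
                                       doc)
  vec <- function(sel) as.integer(universe %in% sel)
  got <- cohen_kappa(vec(ann_a), vec(ann_b))
  expect_equal(got, oracle_kappa_from_table(table(vec(ann_a), vec(ann_b))))
})

test_that("McNemar's test matches direct binomial summation", {
  gold <- rep("A", 8)
  pa <- c(rep("A", 4), rep("B", 4))
  pb <- c(rep("B", 4), rep("A", 4))     # b = c = 4
  sym <- mcnemar_test(gold, pa, pb)
  expect_equal(sym$p_value, 1)
  expect_identical(sym$method, "exact_binomial")

  # b = 10, c = 2
  gold2 <- rep("A", 12)
  pa2 <- c(rep("A", 10), rep("B", 2))
  pb2 <- c(rep("B", 10), rep("A", 2))
  got <- mcnemar_test(gold2, pa2, pb2)
  expect_equal(got$p_value, oracle_mcnemar_exact_p(10, 2))
  swapped <- mcnemar_test(gold2, pb2, pa2)
  expect_equal(swapped$p_value, got$p_value)      # symmetry under swap

  tie <- mcnemar_test(c("A", "A"), c("A", "A"), c("A", "A"))
  expect_equal(tie$p_value, 1)
  expect_identical(tie$flag, "no_discordant_pairs")

  # large discordant counts switch to the continuity-corrected chi-square
  gold3 <- rep("A", 40)
  pa3 <- c(rep("A", 25), rep("B", 15))
  pb3 <- c(rep("B", 25), rep("A", 15))
  big <- mcnemar_test(gold3, pa3, pb3)
  expect_identical(big$method, "chi2_cc")
  expect_equal(big$statistic, (abs(25 - 15) - 1)^2 / 40)
  expect_equal(big$p_value,
               stats::pchisq(big$statistic, 1, lower.tail = FALSE))
})
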