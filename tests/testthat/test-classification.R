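test_that("heuristic cascade: the four rules fire where designed", {
  # (1) no evidence, or no lexical link -> IRRELEVANT
  empty <- heuristic_backend("Alphakinase elevates gammafactor.", character())
  expect_identical(names(which.max(empty)), "IRRELEVANT")
  disjoint <- heuristic_backend(
    "Glacier sediment drifts toward the lagoon.",
    c("Alphakinase elevates gammafactor.", "Betatoxin stays inert."))
  expect_identical(names(which.max(disjoint)), "IRRELEVANT")

  # (2a) high overlap + negation mismatch -> NOT_ACCURATE; the second
  # evidence sentence keeps "not" in-vocabulary so the overlap stays high
  # and the negation rule (not the intermediate-overlap rule) decides
  neg <- heuristic_backend(
    "Alphakinase does not improves survival outcome markedly.",
    c("Alphakinase improves survival outcome markedly.",
      "Betatoxin does not alter recovery."))
  expect_identical(names(which.max(neg)), "NOT_ACCURATE")

  # (2b) high overlap + numeric mismatch (a misquoted percentage)
  num <- heuristic_backend(
    "Response reached 45 percent under alphakinase treatment regime.",
    c("Response reached 54 percent under alphakinase treatment regime.",
      "Controls reported 45 events."))
  expect_identical(names(which.max(num)), "NOT_ACCURATE")

  # (3) token-identical context -> ACCURATE
  same <- heuristic_backend(
    "Alphakinase improves survival outcome markedly.",
    c("Alphakinase improves survival outcome markedly.",
      "Betatoxin stays inert in plasma."))
  expect_identical(names(which.max(same)), "ACCURATE")

  # (4) intermediate overlap -> NOT_ACCURATE
  partial <- heuristic_backend(
    "Alphakinase improves crop rotation and harvest logistics.",
    c("Alphakinase improves survival outcome markedly.",
      "Betatoxin stays inert in plasma."))
  expect_identical(names(which.max(partial)), "NOT_ACCURATE")

  for (scores in list(empty, disjoint, neg, num, same, partial)) {
    expect_equal(sum(scores), 1, tolerance = 1e-6)
    expect_setequal(names(scores), coarse_labels())
    expect_true(all(scores >= 0))
  }
})

test_that("classify enforces the backend contract", {
  pred <- classify("Alphakinase improves outcome.",
                   "Alphakinase improves outcome.", "heuristic",
                   instance_id = "x1")
  expect_s3_class(pred, "accuracy_prediction")
  expect_identical(pred$label,
                   names(which.max(pred$score_per_label)))
  expect_equal(sum(pred$score_per_label), 1, tolerance = 1e-6)

  bad <- function(context, evidence, instance_id) c(FOO = 1, BAR = 0)
  expect_error(classify("text", character(), bad, instance_id = "x2"),
               "score contract")
  expect_error(classify("", character(), "heuristic"), "nzchar")
})

test_that("the oracle backend reproduces gold labels through classify", {
  corp <- small_corpus(seed = 6, n = 20)
  oracle <- make_oracle_backend(corp$instances)
  for (inst in corp$instances) {
    pred <- classify("placeholder context", character(), oracle,
                     instance_id = inst$instance_id)
    expect_identical(pred$label, inst$coarse_label)
  }
  expect_error(classify("text", character(), oracle, instance_id = "nope"),
               "no gold label")
})

test_that("ICL prompts render deterministically and round-trip labels", {
  demos <- list(
    list(context = "C1", evidence = c("E1a", "E1b"), label = "ACCURATE",
         reasoning = "matches the evidence"),
    list(context = "C2", evidence = "E2", label = "NOT_ACCURATE",
         reasoning = "contradicts the evidence"),
    list(context = "C3", evidence = "E3", label = "NOT_ACCURATE",
         reasoning = "overstates the finding"),
    list(context = "C4", evidence = "E4", label = "IRRELEVANT",
         reasoning = "no related content"))
  test_evidence <- paste("ev", 1:8)
  p1 <- build_icl_prompt("test context", test_evidence, demos)
  p2 <- build_icl_prompt("test context", test_evidence, demos)
  expect_identical(format(p1), format(p2))      # byte-stable

  demo_labels <- regmatches(format(p1),
    gregexpr("Label: (ACCURATE|NOT_ACCURATE|IRRELEVANT)", format(p1)))[[1]]
  expect_identical(sub("Label: ", "", demo_labels),
                   c("ACCURATE", "NOT_ACCURATE", "NOT_ACCURATE", "IRRELEVANT"))

  # evidence truncated to five sentences in the rendered test block
  expect_length(p1$test_evidence, 5)
  expect_false(grepl("ev 6", format(p1), fixed = TRUE))

  wrong <- demos[c(1, 1, 2, 4)]
  expect_error(build_icl_prompt("ctx", "ev", wrong), "demonstrations must be")

  expect_identical(
    parse_icl_response("Reasoning: the numbers differ.\nLabel: NOT_ACCURATE"),
    "NOT_ACCURATE")
  expect_error(parse_icl_response("no label here"), "no 'Label:'")
})

test_that("the fine-tuning harness honors the loss-weight and label contracts", {
  corp <- small_corpus(seed = 8, n = 10)
  evidence <- stats::setNames(
    lapply(corp$instances, function(inst) {
      doc <- corp$reference_docs[[inst$reference_doc_id]]
      sentence_text(doc, gold_evidence_sentences(inst, doc))
    }),
    vapply(corp$instances, function(x) x$instance_id, character(1)))

  expect_error(
    finetune_harness(corp$instances, evidence, list(name = "multivers")),
    "optional backend unavailable")

  seen <- new.env()
  trivial_fit <- function(contexts, evidence, labels, loss_weights) {
    seen$labels <- labels
    seen$loss_weights <- loss_weights
    majority <- names(which.max(table(labels)))
    function(context, evidence) {
      s <- stats::setNames(c(0.1, 0.1, 0.1), coarse_labels())
      s[majority] <- 0.8
      s / sum(s)
    }
  }
  out <- finetune_harness(corp$instances, evidence,
                          list(name = "dryrun", fit = trivial_fit))
  expect_identical(unname(seen$loss_weights["rationale"]), 0)
  expect_identical(unname(seen$loss_weights["label"]), 1)
  # labels consolidated 8 -> 3 before batching
  expect_true(all(seen$labels %in% coarse_labels()))
  expect_identical(unname(out$manifest$loss_weights["rationale"]), 0)
  pred <- classify("any context", character(), out$backend)
  expect_true(pred$label %in% coarse_labels())
})

test_that("heuristic backend recovers planted labels from gold evidence", {
  # evidence-bearing labels only: IRRELEVANT/ETIQUETTE carry no gold
  # evidence, so classification there is exercised via the pipeline instead
  corp <- generate_corpus(generator_config(n_reference_docs = 4,
                                           n_instances = 120, seed = 13))
  n_ok <- 0L; n_tot <- 0L
  for (inst in corp$instances) {
    if (length(inst$evidence_segments) == 0) next
    doc <- corp$reference_docs[[inst$reference_doc_id]]
    evidence <- sentence_text(doc, gold_evidence_sentences(inst, doc))
    query <- build_query(inst, "citance")
    pred <- classify(query, evidence, "heuristic",
                     instance_id = inst$instance_id)
    n_tot <- n_tot + 1L
    if (pred$label == inst$coarse_label) n_ok <- n_ok + 1L
  }
  expect_gt(n_ok / n_tot, 0.9)
})
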