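Package: citecheck
Title: Citation Integrity Assessment for Biomedical Literature
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for screening the accuracy of citations in
    biomedical articles. Given a citing paragraph with a highlighted citation
    marker and the full text of the reference article, the pipeline identifies
    the citation context sentences, retrieves candidate evidence sentences from
    the reference article with Okapi BM25 and a pluggable reranker, and assigns
    a three-way accuracy label (ACCURATE, NOT_ACCURATE, IRRELEVANT) through
    pluggable classification backends. Ships the eight-category quotation-error
    taxonomy with priority and consolidation logic, brat standoff and JSONL
    corpus readers and writers, evaluation metrics (precision/recall/F1,
    recall@k, mean reciprocal rank, Cohen's kappa, McNemar's test), and a
    seeded synthetic corpus generator with planted evidence so every stage is
    testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
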