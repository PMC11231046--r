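# citecheck

Citation integrity screening for biomedical literature: does a citing
sentence actually say what the cited article says?

A substantial fraction of citations in biomedical papers misrepresent the
work they cite — they contradict it, overstate it, misquote its numbers, or
cite an article that contains nothing relevant at all. `citecheck`
implements an end-to-end pipeline for detecting such quotation errors,
together with the annotation data model, the evaluation protocol, and a
seeded synthetic-corpus generator so the whole pipeline is testable on a
laptop without any external corpus.

## The task

Given a citing paragraph with one highlighted citation marker and the full
text of the reference article, the pipeline runs three stages:

1. **Citation context identification** — which sentences of the citing
   paragraph discuss the reference. The default is the *citance baseline*
   (the marker's own sentence), which has perfect precision by construction
   because annotated context always contains the citance. A classifier
   route scores every (sentence, citance) pair with a pluggable backend
   after replacing markers with `[cit]` / `[multi_cit]` / `[other_cit]`
   tokens.
2. **Evidence sentence retrieval** — which sentences of the reference
   article the citation should be checked against. Okapi BM25
   (`k1 = 1.2`, `b = 0.75`, each sentence of the single reference article
   is one retrieval unit) returns the top 60 candidates; a reranker (an
   IDF-weighted token-overlap cross-scorer by default, a neural
   cross-encoder by registration) reorders them; the top *k* ∈ {5, 10, 20}
   become the evidence. A title-and-abstract baseline is also provided.
3. **Citation accuracy classification** — a three-way label over the
   (context, evidence) pair: `ACCURATE`, `NOT_ACCURATE`, `IRRELEVANT`.
   Backends are pluggable: a deterministic lexical rule cascade (shipped),
   a harness contract for fine-tuned claim-verification models, and an
   in-context-learning prompt builder / response parser for generative
   models.

The annotation model is the eight-category quotation-error taxonomy:
`ACCURATE`, major errors (`CONTRADICT`, `NOT_SUBSTANTIATE`, `IRRELEVANT`)
and minor errors (`OVERSIMPLIFY`, `MISQUOTE`, `INDIRECT`, `ETIQUETTE`),
with a strict priority order for citations fitting several categories and
a fixed consolidation onto the three coarse classes
(`ACCURATE`+`INDIRECT` → `ACCURATE`; the remaining errors →
`NOT_ACCURATE`; `IRRELEVANT` → `IRRELEVANT`). Evaluation covers one-vs-rest
precision/recall/F1 with micro and macro averages, recall@k and mean
reciprocal rank for retrieval, sentence-level Cohen's κ for
inter-annotator agreement, and McNemar's exact test for paired system
comparison. Annotations are read and written both as brat standoff
(`.txt`/`.ann`, 0-based half-open offsets) and as a JSONL dialect
(schema in `inst/extdata/citation-instance-schema.json`).

## Worked example

Corpus statistics from pre-tabulated counts (here, the label counts of a
3063-citation annotated corpus):

```r
library(citecheck)
corpus_statistics_from_counts(
  c(ACCURATE = 1863, CONTRADICT = 92, NOT_SUBSTANTIATE = 243,
    IRRELEVANT = 217, OVERSIMPLIFY = 111, MISQUOTE = 38, INDIRECT = 82,
    ETIQUETTE = 417),
  n_context_sentences = 3420, n_evidence_sentences = 3791)
#> Corpus statistics: 3063 citation instances
#>             label count percent
#>        CONTRADICT    92    3.00
#>  NOT_SUBSTANTIATE   243    7.93
#>        IRRELEVANT   217    7.08
#>      OVERSIMPLIFY   111    3.62
#>          MISQUOTE    38    1.24
#>          INDIRECT    82    2.68
#>         ETIQUETTE   417   13.61
#>          ACCURATE  1863   60.82
#>   groups: ACCURATE 60.82% | MAJOR 18.02% | MINOR 21.16% | errors 39.18%
#>   1.12 context and 1.24 evidence sentences per citation
```

Roughly 39% of citations carry some error; 60.82% are accurate, and each
citation has on average 1.12 annotated context sentences and 1.24 evidence
sentences.

Full pipeline on a synthetic corpus with planted gold annotations:

```r
corpus <- generate_corpus(generator_config(seed = 1))   # 200 instances, 8 articles
run    <- run_pipeline(corpus, pipeline_config())       # citance -> BM25+rerank -> heuristic
ev     <- evaluate_run(run, corpus)
ev$classification
#> Evaluation over 200 instances
#>         class precision recall    f1 support
#>      ACCURATE     0.992  1.000 0.996     122
#>  NOT_ACCURATE     1.000  0.968 0.984      63
#>    IRRELEVANT     0.938  1.000 0.968      15
#> micro-F1 0.990 | macro-F1 0.983
ev$retrieval
#> Retrieval over 155 instances (45 excluded, empty gold)
#>   recall@1 = 0.743
#>   recall@5 = 0.836
#>   recall@10 = 0.840
#>   recall@20 = 0.850
#>   MRR(@20) = 1.000
```

The 45 excluded instances are `IRRELEVANT`/`ETIQUETTE` citations, which by
definition have no gold evidence; MRR = 1 means the first retrieved
sentence is a planted evidence sentence whenever one exists. The
sub-1 recall@k at higher k reflects paragraph- and section-level evidence
segments, whose expansion can exceed the retrieval cutoff. These numbers
describe the synthetic stated world, not performance on real articles —
real quotation errors are much subtler (see the vignette).

Classifying one (context, evidence) pair directly:

```r
classify("Alphakinase does not improves survival outcome markedly.",
         c("Alphakinase improves survival outcome markedly.",
           "Betatoxin does not alter recovery."),
         "heuristic", instance_id = "demo")
#> <accuracy_prediction demo: NOT_ACCURATE (0.79) [heuristic]>
```

A shell front end over the same functions lives in `exec/citecheck`
(subcommands `make-fixtures`, `stats`, `run`, `evaluate`).

## Acceptance script

`scripts/acceptance.R` regenerates the synthetic corpus from the given
seed, verifies the planted invariants, runs the default pipeline end to
end, prints the classification and retrieval summary to stderr, and writes
its JSON report to `--out`:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
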