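---
title: "Citation integrity screening: models, choices, and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Citation integrity screening: models, choices, and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(citecheck)
```

## The problem

A citation is a factual claim: "reference R says X". Quotation errors —
mismatches between what the citing article attributes to a reference and
what the reference actually states — are distinct from bibliographic
errors and are surprisingly common in biomedical writing. `citecheck`
frames their detection as a three-stage pipeline: find the citation
context in the citing paragraph, retrieve candidate evidence sentences
from the reference article, and classify the (context, evidence) pair as
`ACCURATE`, `NOT_ACCURATE`, or `IRRELEVANT`. This mirrors scientific
claim-verification systems (claim → rationale retrieval → entailment
label), with two differences that shape the design: the evidence source is
a single full-length article rather than a pool of abstracts, and the
label space comes from a citation-specific error taxonomy rather than
Support/Refute/NEI.

## The label taxonomy

Eight fine categories, listed in priority order for the seven errors:

| label | severity | meaning |
|---|---|---|
| CONTRADICT | major | context contradicts a statement in the reference |
| NOT_SUBSTANTIATE | major | reference is relevant but does not support all claims |
| IRRELEVANT | major | reference contains nothing relevant to the citation |
| OVERSIMPLIFY | minor | findings overgeneralized or oversimplified |
| MISQUOTE | minor | numbers or percentages misquoted |
| INDIRECT | minor | reference itself cites the original source of the claim |
| ETIQUETTE | minor | citation style too ambiguous to tell what is cited (often multi-citations) |

`ACCURATE` carries no error. When several categories apply,
`select_priority_label()` keeps the highest-priority one (smallest rank);
`ACCURATE` survives only alone. The taxonomy gives an *order*, not
numbers, so the package assigns ranks 1–7 in listing order. One
under-specified corner: a citation that is simultaneously IRRELEVANT and
ETIQUETTE-styled resolves to IRRELEVANT by that order; the package applies
the listing order uniformly rather than special-casing it.

Downstream models use the three-way consolidation implemented in
`consolidate_label()`: `INDIRECT` joins `ACCURATE` (such citations usually
describe the reference's content correctly, only its originality is at
issue), the five remaining errors join `NOT_ACCURATE`, and `IRRELEVANT`
stands alone, the analogue of "not enough information". The coarse label
is always derived, never stored, so fine and coarse labels cannot drift
apart in data files.

## Stage 1: citation context

Annotated citation context always includes the citance (the sentence
holding the marker). Hence the citance baseline — predict exactly the
citance — has precision 1 by construction against any well-formed gold
set, and is hard to beat in F1; it is the package default. The classifier
route (`classify_context()`) scores each (masked sentence, masked citance)
pair with any backend mapping two texts to [0, 1] and keeps sentences at
or above a threshold, always adding the citance. The shipped reference
backend is token Jaccard similarity at threshold 0.5 — a deterministic,
desk-scale stand-in for a fine-tuned sentence-pair encoder, which can be
registered under the same contract. Masking replaces the target marker
with `[cit]` (`[multi_cit]` for markers covering several references) and
other markers with `[other_cit]`, right-to-left so offsets stay valid.

Sub-sentence context spans exist in annotation practice; this package
stores and evaluates context at sentence level only, which is how
agreement and model evaluation are defined.

## Stage 2: evidence retrieval

Sentences of the single reference article form the retrieval collection —
document frequencies and average length are computed within the article,
not across a corpus, because the task considers one evidence source at a
time. `bm25_rank()` implements Okapi BM25 with defaults `k1 = 1.2`,
`b = 0.75` (standard textbook values; the method name fixes the family,
not the parameters), lowercase alphanumeric tokenization, and a small
English stopword list. The IDF is the non-negative variant
`log(1 + (N - df + 0.5)/(df + 0.5))`; the classic Okapi IDF can go
negative for terms in more than half the collection, which is common
within a single article and would make scores uninterpretable. Ties are
broken by document position (earlier sentence first) — unstated in the
original task description, chosen for determinism. A query with no
in-vocabulary term yields all-zero scores, a document-order ranking, and
an explicit flag rather than an error, because genuinely irrelevant
citances produce exactly this situation.

The first stage keeps 60 candidates; `rerank()` reorders them with a
cross-scorer and keeps the set fixed. The default reranker is an
IDF-weighted token-overlap scorer — again a deterministic stand-in
honoring the same contract as a neural cross-encoder (e.g. MonoT5), which
can be registered by name. A failing reranker falls back to the
first-stage order with a flag rather than aborting a batch run. Query
construction supports the citance alone (default), the gold context
sentences, the gold context plus intervening sentences, and the
title-and-abstract baseline that skips ranking entirely.

## Stage 3: accuracy classification

Backends are functions `(context, evidence, instance_id) →` score vector
over the three coarse labels; `classify()` normalizes scores and takes the
argmax. The shipped heuristic backend is a rule cascade over IDF-weighted
lexical overlap between the context and each evidence sentence:

1. no evidence, or best overlap < 0.1 → `IRRELEVANT`;
2. overlap ≥ 0.6 with a negation-polarity or numeric mismatch against the
   best sentence → `NOT_ACCURATE`;
3. overlap ≥ 0.6 otherwise → `ACCURATE`;
4. intermediate overlap → `NOT_ACCURATE`.

The thresholds (0.1 / 0.6) are package choices documented here, not
empirical claims; they sit far from the score mass the generator produces
on either side. Overlap is normalized by the IDF mass of the context's
tokens so it lives in [0, 1]. One numerical subtlety: IDF is computed over
the handed evidence collection, and context terms unseen there are
weighted as if `df = 1`. Without that cap, a single novel word would carry
more weight than several matched content words whenever the evidence list
is short (the extreme case being one gold evidence sentence), deflating
the overlap of genuinely supported citations. Scores are derived from the
margin to the governing threshold and normalized; empty evidence maps to
`IRRELEVANT`, a convention needed because etiquette-style gold items carry
no evidence segments and verifier behavior on evidence-free input is
otherwise undefined.

Two further backends exercise the contract without shipping any model:
`finetune_harness()` wraps a user-supplied training routine, consolidates
the eight labels to three before batching, and pins the rationale-selection
loss weight to 0 in its manifest (label prediction and rationale selection
run in parallel heads, so zeroing one does not bias the other) — absent a
training routine it raises an explicit "optional backend unavailable"
error rather than failing tests. `build_icl_prompt()` renders the few-shot
prompt for generative models — instruction with the three class
definitions, four demonstrations (one `ACCURATE`, two `NOT_ACCURATE`, one
`IRRELEVANT`), then the unlabeled test block, delimited with XML-like tags
and markdown, at most five evidence sentences per block — and
`parse_icl_response()` inverts the label from a reply. No live model calls
occur anywhere in the package or its tests.

## Evaluation

`prf_report()` gives one-vs-rest precision/recall/F1 per class, micro
(pooled; equal to accuracy for single-label full-coverage input — asserted
as a test property) and macro (unweighted mean) averages, with
zero-denominator cases scored 0 and flagged. Retrieval is scored by
recall@k (k ∈ {1, 5, 10, 20}) and MRR with rank cutoff 20; instances
without gold evidence are excluded from averages (they have nothing to
retrieve), and an instance with no gold sentence inside the cutoff
contributes 0 to MRR. The package follows the universal convention that
higher MRR is better — a source text stating the opposite preference is
taken as a slip, not implemented.

Cohen's κ handles agreement; for the context and evidence tasks the
labelings are per-sentence binary membership vectors, with paragraph- and
section-level evidence segments expanded to their member sentences first.
The negative-class universe is not dictated by the task definition; the
package uses the containing paragraph for the context task and the whole
reference article for the evidence task, the two natural candidate sets.
`mcnemar_test()` compares two systems on their discordant counts: exact
two-sided binomial (doubled smaller tail, capped at 1) below 25 discordant
pairs, continuity-corrected χ² above — the test family is standard; the
exact/asymptotic switch is the package's convention and is recorded in the
result.

## The synthetic stated world

`generate_corpus()` produces the fixture corpus every stage is tested on.
Defaults, chosen once: 8 reference articles of 50–300 sentences (titled
sections, multi-sentence paragraphs, an Abstract section), 200 citation
instances, fine labels drawn from the published corpus distribution
(60.82% accurate, 13.61% etiquette, ...), 1–5 evidence segments per
evidence-bearing citation skewed to 1 (mean ≈ 1.3, near the 1.24
sentences/citation of the real corpus), granularity mix 80% sentence / 15%
paragraph / 5% section, a 0.12 chance of a second gold context sentence
(matching ≈ 1.12 context sentences per citation), and a 0.2 chance of a
non-target marker in the paragraph. Instance counts are not dictated by
the emulated setting; 8 × ~25 citations per article matches its typical
citation density at a size that keeps the full test suite around a minute.

Label-conditional construction makes every category mechanically
recoverable: `ACCURATE`/`INDIRECT` citances paraphrase a planted evidence
sentence (the INDIRECT evidence itself carries a citation marker, the
signature of a non-original source); `CONTRADICT` inserts a negation;
`MISQUOTE` swaps the percentage; `NOT_SUBSTANTIATE`/`OVERSIMPLIFY` copy
only ~40% of the evidence content plus fresh qualifiers (medium overlap);
`IRRELEVANT` draws from a vocabulary disjoint from every article;
`ETIQUETTE` produces a topical-but-ambiguous multi-citation with no
evidence segment but medium overlap to some real article sentence —
ambiguous citations are rarely about *nothing*, and this choice lets the
cascade's intermediate band catch them as the errors they are.
`plant_check()` re-verifies all of this plus every structural invariant on
any corpus, and generation is a pure function of the config (the caller's
RNG stream is saved and restored).

What a green test establishes: the plumbing is lossless (offsets, ids,
round trips), each algorithm equals its independent brute-force oracle,
and the pipeline recovers *planted* signals at the stated rates
(sentence-level evidence recall@20 ≥ 0.9, coarse micro-F1 ≥ 0.8 across
seeds 1–5 — in practice both are ≥ 0.99 and ≥ 0.98). What it does not
establish: performance on real articles. Real quotation errors are subtle
paraphrases, not template perturbations; fluent prose, hedging, and
discourse structure are absent here by design (test clarity over realism).
Published results on the real annotated corpus — micro-F1 around 0.6 for a
fine-tuned verifier — show how much harder the real task is than the
synthetic one, and reproducing them requires the released corpus and GPU
fine-tuning, both outside this package's scope.

## Numerical conventions

* All character offsets are 0-based half-open (brat convention), in both
  standoff and JSONL dialects.
* Percentages in corpus statistics are rounded half-up to two decimals —
  `round_half_up`, not banker's rounding — to match how distribution
  tables are conventionally printed; ratios likewise.
* Sentence ids (`s1`, `s2`, ...) are assigned by the segmenter in document
  order and persisted through JSONL round trips, so evidence references
  are stable across runs.
* The rule-based sentence segmenter refuses to split after scholarly
  abbreviations ("et al.", "e.g.", "Fig."), single initials, or inside
  decimal numbers, and requires the next sentence to open with an
  uppercase letter, digit, bracket or quote. It is a deliberate
  hand-rolled component: no sentence tokenizer is available in the
  package's dependency footprint, and the tests pin its behavior on the
  corpus it must handle.
* A citation marker straddling a segmentation boundary is assigned to the
  sentence containing its start, and flagged cases degrade gracefully
  rather than erroring.

## Known limitations

* The heuristic verifier is lexical; it cannot detect contradictions
  expressed through antonyms, quantifier scope, or world knowledge — by
  design, it is the deterministic reference point that neural backends
  plug in against.
* Marker dialects cover bracketed/parenthesized numerics (including
  ranges and lists) and author–year styles; superscript numerals and
  footnote markers would need additional patterns (the dialect list is
  user-extensible).
* Agreement coefficients computed on synthetic annotations exercise the
  formulas, not human behavior; the package deliberately does not claim to
  reproduce published inter-annotator κ values, which require the human
  annotation data.
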