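#' Precision / recall / F1 report for multi-class predictions
#'
#' One-vs-rest precision, recall and F1 per class, plus micro- and
#' macro-averages. Micro-averaging pools true positives and errors over all
#' classes; for single-label predictions with full coverage it equals
#' accuracy. Macro-averaging is the unweighted mean of per-class F1. A zero
#' denominator yields 0 for the affected metric and sets the `zero_division`
#' flag.
#'
#' @param gold,pred equal-length character vectors of labels.
#' @param classes label universe (default: union of observed labels).
#' @return object of class `eval_report`: `per_class` data frame
#'   (`class`, `precision`, `recall`, `f1`, `support`), `micro_f1`,
#'   `macro_f1`, `accuracy`, `zero_division`.
#' @export
prf_report <- function(gold, pred, classes = NULL) {
  if (length(gold) != length(pred))
    stop("gold and pred must have equal length", call. = FALSE)
  if (is.null(classes)) classes <- sort(unique(c(gold, pred)))
  bad <- setdiff(c(gold, pred), classes)
  if (length(bad) > 0)
    stop("labels outside the class universe: ",
         paste(unique(bad), collapse = ", "), call. = FALSE)

  zero_division <- FALSE
  safe_div <- function(num, den) {
    if (den == 0) { zero_division <<- TRUE; return(0) }
    num / den
  }
  rows <- lapply(classes, function(cl) {
    tp <- sum(gold == cl & pred == cl)
    fp <- sum(gold != cl & pred == cl)
    fn <- sum(gold == cl & pred != cl)
    p <- safe_div(tp, tp + fp)
    r <- safe_div(tp, tp + fn)
    f1 <- safe_div(2 * p * r, p + r)
    data.frame(class = cl, precision = p, recall = r, f1 = f1,
               support = sum(gold == cl), stringsAsFactors = FALSE)
  })
  per_class <- do.call(rbind, rows)

  tp_all <- sum(gold == pred)
  micro_p <- safe_div(tp_all, length(pred))
  micro_r <- safe_div(tp_all, length(gold))
  micro_f1 <- safe_div(2 * micro_p * micro_r, micro_p + micro_r)

  structure(list(per_class = per_class,
                 micro_f1 = micro_f1,
                 macro_f1 = mean(per_class$f1),
                 accuracy = safe_div(tp_all, length(gold)),
                 n = length(gold),
                 zero_division = zero_division),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("Evaluation over %d instances\n", x$n))
  print(transform(x$per_class,
                  precision = round(precision, 3),
                  recall = round(recall, 3), f1 = round(f1, 3)),
        row.names = FALSE)
  cat(sprintf("micro-F1 %.3f | macro-F1 %.3f\n", x$micro_f1, x$macro_f1))
  invisible(x)
}

ranking_ids <- function(ranking) {
  if (inherits(ranking, "ranked_evidence")) ranking$ranking$sentence_id
  else as.character(ranking)
}

#' Recall at rank k
#'
#' Fraction of the gold evidence sentences found among the top `k` retrieved
#' sentences. Instances with empty gold evidence are undefined and return
#' `NA` (callers exclude them from averages).
#'
#' @param ranking a `ranked_evidence` or a character vector of sentence ids
#'   in rank order.
#' @param gold character vector of gold sentence ids.
#' @param k rank cutoff (>= 1).
#' @return recall in `[0, 1]`, or `NA` for empty gold.
#' @export
recall_at_k <- function(ranking, gold, k) {
  stopifnot(k >= 1)
  if (length(gold) == 0) return(NA_real_)
  ids <- ranking_ids(ranking)
  length(intersect(utils::head(ids, k), gold)) / length(gold)
}

#' Mean reciprocal rank
#'
#' Mean over instances of the reciprocal rank of the first gold sentence in
#' the ranking, considering only the top `cutoff` (default 20) positions; an
#' instance with no gold sentence in the cutoff contributes 0. Instances
#' with empty gold are excluded and counted in `n_excluded`.
#'
#' @param rankings list of rankings (each as in [recall_at_k()]).
#' @param golds list of gold sentence id vectors, parallel to `rankings`.
#' @param cutoff rank cutoff (default 20).
#' @return list with `mrr` and `n_excluded`.
#' @export
mean_reciprocal_rank <- function(rankings, golds, cutoff = 20) {
  stopifnot(length(rankings) == length(golds))
  keep <- lengths(golds) > 0
  rr <- mapply(function(r, g) {
    ids <- utils::head(ranking_ids(r), cutoff)
    pos <- which(ids %in% g)
    if (length(pos) == 0) 0 else 1 / pos[1]
  }, rankings[keep], golds[keep])
  list(mrr = if (any(keep)) mean(rr) else NA_real_,
       n_excluded = sum(!keep))
}

#' Retrieval report over a batch of instances
#'
#' Averages [recall_at_k()] at k = 1, 5, 10, 20 and computes
#' [mean_reciprocal_rank()] (cutoff 20), excluding empty-gold instances.
#'
#' @param rankings,golds as in [mean_reciprocal_rank()].
#' @param ks rank cutoffs (default `c(1, 5, 10, 20)`).
#' @return object of class `retrieval_report`: `recall_at` (named numeric),
#'   `mrr`, `n_evaluated`, `n_excluded`.
#' @export
retrieval_report <- function(rankings, golds, ks = c(1, 5, 10, 20)) {
  keep <- lengths(golds) > 0
  recall_at <- vapply(ks, function(k) {
    vals <- mapply(recall_at_k, rankings[keep], golds[keep],
                   MoreArgs = list(k = k))
    if (any(keep)) mean(vals) else NA_real_
  }, numeric(1))
  names(recall_at) <- paste0("recall@", ks)
  mrr <- mean_reciprocal_rank(rankings, golds)
  structure(list(recall_at = recall_at, mrr = mrr$mrr,
                 n_evaluated = sum(keep), n_excluded = sum(!keep)),
            class = "retrieval_report")
}

#' @export
print.retrieval_report <- function(x, ...) {
  cat(sprintf("Retrieval over %d instances (%d excluded, empty gold)\n",
              x$n_evaluated, x$n_excluded))
  for (nm in names(x$recall_at))
    cat(sprintf("  %s = %.3f\n", nm, x$recall_at[[nm]]))
  cat(sprintf("  MRR(@20) = %.3f\n", x$mrr))
  invisible(x)
}

#' Cohen's kappa
#'
#' Chance-corrected agreement between two categorical labelings:
#' `(p_o - p_e) / (1 - p_e)` with the expected agreement `p_e` taken from
#' the marginal label distributions. When `p_e = 1` (both raters constant
#' and identical) kappa is undefined and `NA` is returned with a warning.
#' For the context / evidence annotation tasks the inputs are per-sentence
#' binary membership vectors (see [agreement_report()]).
#'
#' @param labels_a,labels_b equal-length categorical vectors.
#' @return kappa in `[-1, 1]`, or `NA` when undefined.
#' @export
cohen_kappa <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b))
    stop("label sequences must have equal length", call. = FALSE)
  if (length(labels_a) == 0) stop("empty label sequences", call. = FALSE)
  lev <- sort(unique(c(as.character(labels_a), as.character(labels_b))))
  a <- factor(as.character(labels_a), levels = lev)
  b <- factor(as.character(labels_b), levels = lev)
  po <- mean(a == b)
  pe <- sum((table(a) / length(a)) * (table(b) / length(b)))
  if (isTRUE(all.equal(pe, 1))) {
    warning("expected agreement is 1; kappa undefined")
    return(NA_real_)
  }
  (po - pe) / (1 - pe)
}

#' Average pairwise inter-annotator agreement
#'
#' Computes [cohen_kappa()] for every annotator pair on a shared item set
#' and averages the pairwise coefficients, the standard protocol for
#' multi-annotator corpora. For sentence-level tasks, convert each
#' annotator's selections to a binary membership vector over the candidate
#' universe first (the containing paragraph for context annotation, the
#' whole reference article for evidence annotation), expanding paragraph-
#' and section-level segments via [expand_segment_to_sentences()].
#'
#' @param annotations named list (one element per annotator) of
#'   equal-length label vectors.
#' @return object of class `agreement_report`: `pairwise` data frame
#'   (`annotator_a`, `annotator_b`, `kappa`) and `average`.
#' @export
agreement_report <- function(annotations) {
  stopifnot(is.list(annotations), length(annotations) >= 2)
  who <- names(annotations)
  if (is.null(who)) who <- paste0("annotator", seq_along(annotations))
  pairs <- utils::combn(seq_along(annotations), 2)
  rows <- lapply(seq_len(ncol(pairs)), function(j) {
    i1 <- pairs[1, j]; i2 <- pairs[2, j]
    data.frame(annotator_a = who[i1], annotator_b = who[i2],
               kappa = cohen_kappa(annotations[[i1]], annotations[[i2]]),
               stringsAsFactors = FALSE)
  })
  pairwise <- do.call(rbind, rows)
  structure(list(pairwise = pairwise,
                 average = mean(pairwise$kappa, na.rm = TRUE)),
            class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  print(transform(x$pairwise, kappa = round(kappa, 3)), row.names = FALSE)
  cat(sprintf("average pairwise kappa = %.3f\n", x$average))
  invisible(x)
}

#' McNemar's test for paired classifier comparison
#'
#' Compares two systems evaluated on the same instances through their
#' discordant counts: `b` = instances system A got right and system B got
#' wrong, `c` = the reverse. For `b + c < 25` the exact two-sided binomial
#' test is used (doubled smaller tail, capped at 1); otherwise the
#' continuity-corrected chi-square approximation
#' `(|b - c| - 1)^2 / (b + c)` on one degree of freedom. `b + c = 0` yields
#' `p = 1` with a flag.
#'
#' @param gold gold labels.
#' @param pred_a,pred_b predictions of the two systems, parallel to `gold`.
#' @return object of class `comparison_result`: `discordant` (`b`, `c`),
#'   `statistic`, `p_value`, `method`, `flag`.
#' @export
mcnemar_test <- function(gold, pred_a, pred_b) {
  if (length(gold) != length(pred_a) || length(gold) != length(pred_b))
    stop("gold, pred_a, pred_b must have equal length", call. = FALSE)
  ok_a <- pred_a == gold
  ok_b <- pred_b == gold
  b <- sum(ok_a & !ok_b)
  c_ <- sum(!ok_a & ok_b)
  n <- b + c_
  if (n == 0) {
    return(structure(list(discordant = c(b = b, c = c_), statistic = 0,
                          p_value = 1, method = "exact_binomial",
                          flag = "no_discordant_pairs"),
                     class = "comparison_result"))
  }
  if (n < 25) {
    p <- min(1, 2 * stats::pbinom(min(b, c_), n, 0.5))
    structure(list(discordant = c(b = b, c = c_), statistic = min(b, c_),
                   p_value = p, method = "exact_binomial",
                   flag = NA_character_),
              class = "comparison_result")
  } else {
    stat <- (abs(b - c_) - 1)^2 / n
    structure(list(discordant = c(b = b, c = c_), statistic = stat,
                   p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE),
                   method = "chi2_cc", flag = NA_character_),
              class = "comparison_result")
  }
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("McNemar (%s): b = %d, c = %d, statistic = %.4g, p = %.4g\n",
              x$method, x$discordant["b"], x$discordant["c"], x$statistic,
              x$p_value))
  invisible(x)
}
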