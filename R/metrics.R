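#' Label retrieved pairs as TP / FP / ignore
#'
#' Fold-recognition labeling at three hierarchy levels, or by structural
#' similarity:
#' \itemize{
#'   \item `family`: TP iff same family; hits from a different fold are
#'     FP; same-fold hits outside the stratum (same superfamily or fold
#'     only) are `ignore` -- neither rewarded nor penalized.
#'   \item `superfamily`: TP iff same superfamily but different family;
#'     different fold is FP; rest `ignore`.
#'   \item `fold`: TP iff same fold but different superfamily; different
#'     fold is FP; rest `ignore`.
#'   \item `tm_score`: TP iff TM-score strictly exceeds 0.5, else FP.
#' }
#' Self-hits are always labeled `ignore`.
#'
#' @param results data.frame with columns `query`, `target` (and
#'   optionally `similarity`, carried through).
#' @param labels fold-label data.frame (see [read_fold_labels()]) for the
#'   three hierarchy levels, or a data.frame `query`, `target`,
#'   `tm_score` for `level = "tm_score"`.
#' @param level one of `"family"`, `"superfamily"`, `"fold"`,
#'   `"tm_score"`.
#' @return `results` with an added `label` column in
#'   `c("TP", "FP", "ignore")`.
#' @export
judge_pairs <- function(results, labels,
                        level = c("family", "superfamily", "fold", "tm_score")) {
  level <- match.arg(level)
  out <- results
  if (level == "tm_score") {
    key <- function(q, t) paste(q, t, sep = "\r")
    tm <- setNames(labels$tm_score, key(labels$query, labels$target))
    v <- tm[key(results$query, results$target)]
    if (anyNA(v)) {
      miss <- which(is.na(v))[1]
      stop_("missing TM-score label for pair %s -> %s",
            results$query[miss], results$target[miss])
    }
    out$label <- ifelse(v > 0.5, "TP", "FP")
  } else {
    idx <- match(results$query, labels$id)
    jdx <- match(results$target, labels$id)
    if (anyNA(idx)) stop_("missing label for %s", results$query[which(is.na(idx))[1]])
    if (anyNA(jdx)) stop_("missing label for %s", results$target[which(is.na(jdx))[1]])
    same_fam <- labels$family[idx] == labels$family[jdx]
    same_sf <- labels$superfamily[idx] == labels$superfamily[jdx]
    same_fold <- labels$fold[idx] == labels$fold[jdx]
    tp <- switch(level,
                 family = same_fam,
                 superfamily = same_sf & !same_fam,
                 fold = same_fold & !same_sf)
    out$label <- ifelse(tp, "TP", ifelse(!same_fold, "FP", "ignore"))
  }
  out$label[results$query == results$target] <- "ignore"
  out
}

# Per-query judged list, sorted for metric computation: ignores and
# self-hits removed, similarity descending, score ties broken FP-first
# (the conservative, deterministic choice), then target id.
sorted_judged <- function(judged) {
  judged <- judged[judged$label != "ignore", , drop = FALSE]
  fp_first <- ifelse(judged$label == "FP", 0L, 1L)
  judged[order(judged$query, -judged$similarity, fp_first, judged$target), ,
         drop = FALSE]
}

#' Sensitivity up to the first false positive
#'
#' For one query's ranked hit list: the fraction of the query's true
#' positives that appear before the first false positive.
#'
#' @param labels character vector of `"TP"` / `"FP"` in rank order
#'   (ignores and self-hits already removed).
#' @param total_tp total number of true positives for the query; defaults
#'   to the number of TPs in `labels` (i.e. all relevant targets were
#'   retrieved).
#' @return a scalar in \[0, 1\], or `NA` if the query has no true
#'   positives (such queries are excluded from the mean).
#' @export
sensitivity_to_first_fp <- function(labels, total_tp = sum(labels == "TP")) {
  if (total_tp == 0L) return(NA_real_)
  first_fp <- match("FP", labels)
  upto <- if (is.na(first_fp)) labels else head(labels, first_fp - 1L)
  sum(upto == "TP") / total_tp
}

#' Mean sensitivity to the first false positive over all queries
#'
#' The benchmark's "AUROC": each query's ranked result list is truncated
#' at its first false positive and the fraction of the query's true
#' positives found up to that point is averaged over queries.  Queries
#' with zero true positives are excluded from the mean and reported in
#' the `n_excluded` attribute.
#'
#' @param judged judged result data.frame (see [judge_pairs()]) with a
#'   `similarity` column.
#' @param total_tp optional named vector giving each query's total number
#'   of relevant targets; defaults to the TP count present in `judged`
#'   (appropriate for untruncated all-vs-all results).
#' @return mean sensitivity, with attribute `per_query`.
#' @export
auroc_mean_sensitivity <- function(judged, total_tp = NULL) {
  judged <- sorted_judged(judged)
  per_query <- vapply(split(judged, judged$query), function(df) {
    tot <- if (is.null(total_tp)) sum(df$label == "TP") else
      total_tp[[df$query[1]]]
    sensitivity_to_first_fp(df$label, tot)
  }, numeric(1))
  eligible <- per_query[!is.na(per_query)]
  if (length(eligible) == 0L) stop_("no query has any true positive")
  structure(mean(eligible), per_query = per_query,
            n_excluded = sum(is.na(per_query)))
}

#' Size-weighted precision-recall curve
#'
#' Precision and recall swept over score thresholds, with every count
#' (TP, FP, FN) weighted by the reciprocal of the query's stratum size
#' (its family, superfamily or fold, at the evaluation level) so that
#' strata contribute linearly rather than quadratically with their size.
#' False-negative mass is the weight of relevant pairs not retrieved
#' above the threshold; the full query-by-target cross product (excluding
#' self-hits) defines the relevant set.
#'
#' @param judged judged result data.frame with `similarity`.
#' @param labels fold-label table covering queries and targets.
#' @param level `"family"`, `"superfamily"` or `"fold"`.
#' @param weights optional named per-query weight vector overriding the
#'   reciprocal-stratum-size rule (e.g. all 1 for the classic unweighted
#'   curve).
#' @param target_ids ids of the searched target dataset; defaults to
#'   `labels$id`.
#' @return data.frame with columns `threshold`, `recall`, `precision`,
#'   plus attribute `aupr` (trapezoidal area over the achieved points).
#' @export
weighted_pr_curve <- function(judged, labels,
                              level = c("family", "superfamily", "fold"),
                              weights = NULL, target_ids = labels$id) {
  level <- match.arg(level)
  stratum <- setNames(labels[[level]], labels$id)
  sizes <- table(stratum[target_ids])
  qids <- unique(judged$query)
  if (is.null(weights)) {
    weights <- setNames(1 / as.numeric(sizes[stratum[qids]]), qids)
  }
  # total relevant mass: weighted count of would-be TPs over the full
  # cross product, excluding self-hits
  universe <- expand.grid(query = qids, target = target_ids,
                          stringsAsFactors = FALSE)
  universe <- universe[universe$query != universe$target, , drop = FALSE]
  uni_judged <- judge_pairs(universe, labels, level)
  total_relevant <- sum(weights[uni_judged$query[uni_judged$label == "TP"]])
  if (total_relevant == 0) stop_("no relevant pair at level %s", level)

  judged <- judged[judged$label != "ignore", , drop = FALSE]
  # global ranking across queries for the threshold sweep; ties FP-first
  judged <- judged[order(-judged$similarity,
                         ifelse(judged$label == "FP", 0L, 1L),
                         judged$query, judged$target), , drop = FALSE]
  w <- weights[judged$query]
  is_tp <- judged$label == "TP"
  cum_tp <- cumsum(w * is_tp)
  cum_fp <- cumsum(w * !is_tp)
  # achieved points: one per distinct threshold (take the last row of
  # each tied-score block in the global ranking)
  keep <- !duplicated(judged$similarity, fromLast = TRUE)
  curve <- data.frame(threshold = judged$similarity[keep],
                      recall = cum_tp[keep] / total_relevant,
                      precision = cum_tp[keep] / (cum_tp[keep] + cum_fp[keep]))
  rownames(curve) <- NULL
  ord <- order(curve$recall)
  r <- c(0, curve$recall[ord])
  p <- c(if (nrow(curve)) curve$precision[ord][1] else 1, curve$precision[ord])
  aupr <- sum(diff(r) * (head(p, -1) + p[-1]) / 2)
  structure(curve, aupr = aupr)
}

#' Mean average precision
#'
#' For each query, average precision is the mean over its relevant ranks
#' r of precision-at-r; MAP is the mean of average precision over queries.
#' Queries with no relevant target are excluded from the mean.
#'
#' @param judged judged result data.frame with `similarity`.
#' @return MAP in \[0, 1\], with attribute `per_query`.
#' @export
mean_average_precision <- function(judged) {
  judged <- sorted_judged(judged)
  per_query <- vapply(split(judged, judged$query), function(df) {
    is_tp <- df$label == "TP"
    if (!any(is_tp)) return(NA_real_)
    ranks <- which(is_tp)
    mean(cumsum(is_tp)[ranks] / ranks)
  }, numeric(1))
  eligible <- per_query[!is.na(per_query)]
  if (length(eligible) == 0L) stop_("no query has any relevant target")
  structure(mean(eligible), per_query = per_query,
            n_excluded = sum(is.na(per_query)))
}

#' Precision at k
#'
#' Per query, the fraction of true positives among the top k retrieved
#' targets (lists shorter than k count the missing slots as
#' non-relevant); averaged over queries.
#'
#' @param judged judged result data.frame with `similarity`.
#' @param k positive integer cutoff.
#' @return mean P\@k in \[0, 1\], with attribute `per_query`.
#' @export
precision_at_k <- function(judged, k) {
  stopifnot(k >= 1)
  judged <- sorted_judged(judged)
  per_query <- vapply(split(judged, judged$query), function(df) {
    sum(head(df$label, k) == "TP") / k
  }, numeric(1))
  structure(mean(per_query), per_query = per_query)
}

#' Summary metric report
#'
#' Convenience wrapper computing the mean sensitivity to the first FP,
#' MAP and P\@k in one pass over a judged result table.
#'
#' @param judged judged result data.frame with `similarity`.
#' @param k_values integer vector of P\@k cutoffs.
#' @return list with elements `auroc`, `map`, `p_at_k` (named vector).
#' @export
metric_report <- function(judged, k_values = c(1L, 10L)) {
  list(auroc = as.numeric(auroc_mean_sensitivity(judged)),
       map = as.numeric(mean_average_precision(judged)),
       p_at_k = setNames(vapply(k_values,
                                function(k) as.numeric(precision_at_k(judged, k)),
                                numeric(1)),
                         paste0("P@", k_values)))
}

#' Easy / remote homology quadrant analysis
#'
#' Classifies homologous pairs by the conventional thresholds sequence
#' identity 0.3 and TM-score 0.5: "easy" pairs have identity above 0.3
#' with TM-score above 0.5, "remote homology" pairs identity below 0.3
#' but TM-score above 0.5; pairs with TM-score at or below 0.5 fall in
#' neither quadrant (not homologs under the TM rule).  Each pair
#' carries a `recalled` flag (present in a method's top-N list or not).
#'
#' @param pairs data.frame with columns `tm_score`, `identity`,
#'   `recalled` (logical).
#' @param identity_threshold,tm_threshold quadrant boundaries.
#' @return named integer vector: `easy_recalled`, `easy_missed`,
#'   `remote_recalled`, `remote_missed`.
#' @export
quadrant_analysis <- function(pairs, identity_threshold = 0.3,
                              tm_threshold = 0.5) {
  easy <- pairs$identity > identity_threshold & pairs$tm_score > tm_threshold
  remote <- pairs$identity < identity_threshold & pairs$tm_score > tm_threshold
  c(easy_recalled = sum(easy & pairs$recalled),
    easy_missed = sum(easy & !pairs$recalled),
    remote_recalled = sum(remote & pairs$recalled),
    remote_missed = sum(remote & !pairs$recalled))
}
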