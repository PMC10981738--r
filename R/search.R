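#' Search configuration
#'
#' @param method ranking similarity: `"ss_predictor"` (bilinear TM-score
#'   prediction combined with cosine), `"cos"`, or `"euclidean"`.
#' @param prefilter candidate pre-filter: `"clan"` (shared Pfam clan),
#'   `"family"` (shared Pfam family; ablation variant), or `"none"`
#'   (score the full query x target matrix).
#' @param top_k keep at most this many targets per query (`Inf` = all).
#' @param align_threshold similarity a pair must strictly exceed to be
#'   forwarded to the aligner (default 0.3, below which pairs are usually
#'   irrelevant).
#' @return an object of class `search_config`.
#' @export
search_config <- function(method = c("ss_predictor", "cos", "euclidean"),
                          prefilter = c("clan", "family", "none"),
                          top_k = Inf, align_threshold = 0.3) {
  method <- match.arg(method)
  prefilter <- match.arg(prefilter)
  stopifnot(top_k >= 1, align_threshold >= 0, align_threshold <= 1)
  structure(list(method = method, prefilter = prefilter, top_k = top_k,
                 align_threshold = align_threshold),
            class = "search_config")
}

#' Search a target dataset for homologs of each query
#'
#' Orchestrates the pipeline: build candidate pairs (all pairs, or those
#' retained by the clan/family pre-filter with its retain-all fallback),
#' score every candidate in one vectorized pass with the configured
#' similarity, and rank targets per query.  Ordering is fully
#' deterministic: targets are sorted by decreasing similarity, ties broken
#' by ascending target id.
#'
#' @param store an [embedding_store()] with pooled embeddings for all ids.
#' @param model a [bilinear_model()] (required for
#'   `method = "ss_predictor"`, ignored otherwise).
#' @param query_ids,target_ids character vectors of protein ids.
#' @param config a [search_config()].
#' @param query_annotations,target_annotations named lists of family sets
#'   (required when `config$prefilter != "none"`).
#' @param clan_map family -> clan map (used when `prefilter = "clan"`).
#' @return data.frame with columns `query`, `target`, `rank`,
#'   `similarity`, `provenance`, `self`; self-hits are kept but flagged so
#'   that evaluation can exclude them.
#' @export
search_homologs <- function(store, model = NULL, query_ids, target_ids,
                            config = search_config(),
                            query_annotations = NULL,
                            target_annotations = NULL,
                            clan_map = NULL) {
  stopifnot(inherits(config, "search_config"))
  if (config$method == "ss_predictor" && is.null(model)) {
    stop_("method 'ss_predictor' requires a bilinear model")
  }
  if (config$prefilter != "none") {
    for (id in query_ids) {
      if (is.null(query_annotations) || !id %in% names(query_annotations)) {
        stop_("missing annotation for %s", id)
      }
    }
    for (id in target_ids) {
      if (is.null(target_annotations) || !id %in% names(target_annotations)) {
        stop_("missing annotation for %s", id)
      }
    }
    pairs <- if (config$prefilter == "clan") {
      prefilter_pairs(assign_clans(query_annotations[query_ids], clan_map),
                      assign_clans(target_annotations[target_ids], clan_map))
    } else {
      prefilter_pairs_family(query_annotations[query_ids],
                             target_annotations[target_ids])
    }
  } else {
    pairs <- expand.grid(target = target_ids, query = query_ids,
                         stringsAsFactors = FALSE)[, c("query", "target")]
    pairs$provenance <- "all_pairs"
  }

  Z1 <- pooled_matrix(store, pairs$query)
  Z2 <- pooled_matrix(store, pairs$target)
  pairs$similarity <- switch(config$method,
    ss_predictor = ss_similarity_rows(model, Z1, Z2),
    cos = cos_similarity_rows(Z1, Z2),
    euclidean = euclidean_similarity_rows(Z1, Z2))
  pairs$self <- pairs$query == pairs$target

  # Deterministic per-query ranking: similarity desc, target id asc.
  pairs <- pairs[order(pairs$query, -pairs$similarity, pairs$target), ,
                 drop = FALSE]
  pairs$rank <- unlist(lapply(split(seq_len(nrow(pairs)), pairs$query),
                              seq_along), use.names = FALSE)
  if (is.finite(config$top_k)) {
    pairs <- pairs[pairs$rank <= config$top_k, , drop = FALSE]
  }
  rownames(pairs) <- NULL
  pairs[, c("query", "target", "rank", "similarity", "provenance", "self")]
}

#' All-versus-all search over one dataset
#'
#' [search_homologs()] with queries equal to targets.  Self-pairs are
#' retained in the output but flagged `self = TRUE`; evaluation excludes
#' them.
#'
#' @inheritParams search_homologs
#' @param ids protein ids of the dataset.
#' @param annotations named list of family sets for `ids`.
#' @return as [search_homologs()].
#' @export
all_vs_all_search <- function(store, model = NULL, ids,
                              config = search_config(),
                              annotations = NULL, clan_map = NULL) {
  search_homologs(store, model, ids, ids, config,
                  query_annotations = annotations,
                  target_annotations = annotations,
                  clan_map = clan_map)
}

#' Select pairs for alignment
#'
#' Returns the search-result pairs whose similarity strictly exceeds the
#' threshold, preserving per-query rank order.  Restricting alignment to
#' these pairs avoids a large number of low-similarity, meaningless
#' alignments at a marginal cost in recall.
#'
#' @param results search-result data.frame (see [search_homologs()]).
#' @param threshold similarity cutoff (strict; default 0.3).
#' @param include_self keep self-hits (default FALSE).
#' @return data.frame with columns `query`, `target`, `similarity`.
#' @export
select_align_candidates <- function(results, threshold = 0.3,
                                    include_self = FALSE) {
  keep <- results$similarity > threshold
  if (!include_self && "self" %in% names(results)) {
    keep <- keep & !results$self
  }
  out <- results[keep, c("query", "target", "similarity"), drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a search-result table as TSV
#' @param results search-result data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_search_results <- function(results, path) {
  write.table(results, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
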