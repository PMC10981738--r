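#' Embedding dot-product substitution matrix
#'
#' `S[i, j]` is the dot product of query residue i's embedding with target
#' residue j's embedding.  Context-aware embeddings make this a
#' position-specific substitution matrix carrying deep evolutionary
#' information, replacing the static substitution matrix of classic DP
#' alignment.  An optional affine rescale (`scale * S + shift`) is applied
#' uniformly; the default is the raw dot product.
#'
#' @param E_q,E_t per-residue embedding matrices (`m x d`, `n x d`).
#' @param scale,shift optional affine rescale constants.
#' @return an `m x n` numeric matrix.
#' @export
substitution_matrix <- function(E_q, E_t, scale = 1, shift = 0) {
  if (ncol(E_q) != ncol(E_t)) {
    stop_("embedding dimension mismatch: %d vs %d", ncol(E_q), ncol(E_t))
  }
  scale * tcrossprod(E_q, E_t) + shift
}

# Build the alignment-result object shared by both DP modes.
alignment_result <- function(mode, score, qi, ti, m, n,
                             query_id = NA_character_,
                             target_id = NA_character_,
                             query_seq = NULL, target_seq = NULL) {
  pairs <- cbind(query_index = as.integer(qi), target_index = as.integer(ti))
  res <- list(query_id = query_id, target_id = target_id, mode = mode,
              score = score, pairs = pairs, m = m, n = n)
  if (!is.null(query_seq) && !is.null(target_seq)) {
    g <- gapped_strings(pairs, mode, m, n, query_seq, target_seq)
    res$query_aligned <- g[1]
    res$target_aligned <- g[2]
  }
  structure(res, class = "alignment_result")
}

#' @export
print.alignment_result <- function(x, ...) {
  cat(sprintf("<alignment_result> %s, score %.4g, %d aligned pairs\n",
              x$mode, x$score, nrow(x$pairs)))
  if (!is.null(x$query_aligned)) {
    cat(" ", x$query_aligned, "\n ", x$target_aligned, "\n")
  }
  invisible(x)
}

# Render gapped display strings from an aligned-pair list.  Global
# alignments span the full sequences; local alignments span the region
# from the first to the last aligned pair.
gapped_strings <- function(pairs, mode, m, n, query_seq, target_seq) {
  qs <- strsplit(query_seq, "")[[1]]
  ts <- strsplit(target_seq, "")[[1]]
  if (nrow(pairs) == 0L) {
    if (mode == "local") return(c("", ""))
    return(c(paste0(c(qs, rep("-", n)), collapse = ""),
             paste0(c(rep("-", m), ts), collapse = "")))
  }
  if (mode == "global") {
    qlo <- 0L; qhi <- m - 1L; tlo <- 0L; thi <- n - 1L
  } else {
    qlo <- pairs[1, 1]; qhi <- pairs[nrow(pairs), 1]
    tlo <- pairs[1, 2]; thi <- pairs[nrow(pairs), 2]
  }
  out_q <- character(); out_t <- character()
  i <- qlo; j <- tlo
  for (k in seq_len(nrow(pairs))) {
    pi <- pairs[k, 1]; pj <- pairs[k, 2]
    while (i < pi) { out_q <- c(out_q, qs[i + 1]); out_t <- c(out_t, "-"); i <- i + 1L }
    while (j < pj) { out_q <- c(out_q, "-"); out_t <- c(out_t, ts[j + 1]); j <- j + 1L }
    out_q <- c(out_q, qs[pi + 1]); out_t <- c(out_t, ts[pj + 1])
    i <- pi + 1L; j <- pj + 1L
  }
  while (i <= qhi) { out_q <- c(out_q, qs[i + 1]); out_t <- c(out_t, "-"); i <- i + 1L }
  while (j <= thi) { out_q <- c(out_q, "-"); out_t <- c(out_t, ts[j + 1]); j <- j + 1L }
  c(paste0(out_q, collapse = ""), paste0(out_t, collapse = ""))
}

#' Global (Needleman-Wunsch) alignment over a substitution matrix
#'
#' Linear gap penalty: every gapped position costs `gap`, including
#' leading and trailing gaps (`H[0, j] = -gap * j`).  The recurrence
#' `H[i,j] = max(H[i-1,j-1] + S[i,j], H[i-1,j] - gap, H[i,j-1] - gap)` runs
#' in O(mn); traceback is deterministic with precedence
#' diagonal > up > left.
#'
#' @param S substitution matrix (see [substitution_matrix()]).
#' @param gap non-negative linear gap penalty per gapped position.
#' @param query_seq,target_seq optional sequences for gapped display
#'   strings.
#' @param query_id,target_id optional identifiers carried into the result.
#' @return an `alignment_result` with the DP-optimal score `H[m, n]` and
#'   the aligned index pairs (0-based, strictly increasing).
#' @export
align_global <- function(S, gap = 3.0, query_seq = NULL, target_seq = NULL,
                         query_id = NA_character_, target_id = NA_character_) {
  stopifnot(is.matrix(S), gap >= 0)
  r <- nw_align_cpp(S, gap)
  alignment_result("global", r$score, r$query_index, r$target_index,
                   nrow(S), ncol(S), query_id, target_id,
                   query_seq, target_seq)
}

#' Local (Smith-Waterman) alignment over a substitution matrix
#'
#' As [align_global()] but with the cell floor at zero; the score is the
#' maximum cell and traceback runs from that cell back to the first zero.
#' Ties on the maximum cell are broken toward the smallest `(i, j)`.
#'
#' @inheritParams align_global
#' @return an `alignment_result`; score is always >= 0, and an
#'   all-non-positive `S` yields score 0 with an empty alignment.
#' @export
align_local <- function(S, gap = 3.0, query_seq = NULL, target_seq = NULL,
                        query_id = NA_character_, target_id = NA_character_) {
  stopifnot(is.matrix(S), gap >= 0)
  r <- sw_align_cpp(S, gap)
  alignment_result("local", r$score, r$query_index, r$target_index,
                   nrow(S), ncol(S), query_id, target_id,
                   query_seq, target_seq)
}

#' Align a list of query-target pairs from per-residue embeddings
#'
#' @param pairs data.frame with columns `query`, `target`.
#' @param store an [embedding_store()] holding per-residue matrices.
#' @param mode `"global"` (default; global alignment scores drive
#'   reranking) or `"local"`.
#' @param gap linear gap penalty.
#' @param records optional data.frame of sequences (`id`, `sequence`) for
#'   gapped display strings.
#' @param normalize `"none"` (raw DP score, default) or
#'   `"aligned_length"` (score divided by the number of aligned pairs).
#' @return data.frame with columns `query`, `target`, `score`,
#'   `n_aligned`, `query_start`, `query_end`, `target_start`, `target_end`
#'   (0-based, end-exclusive) and, when `records` is given,
#'   `query_aligned` / `target_aligned`.
#' @export
align_pairs <- function(pairs, store, mode = c("global", "local"),
                        gap = 3.0, records = NULL,
                        normalize = c("none", "aligned_length")) {
  mode <- match.arg(mode)
  normalize <- match.arg(normalize)
  seq_of <- if (!is.null(records)) setNames(records$sequence, records$id)
  rows <- lapply(seq_len(nrow(pairs)), function(k) {
    q <- pairs$query[k]; t <- pairs$target[k]
    S <- substitution_matrix(get_embedding(store, q), get_embedding(store, t))
    fn <- if (mode == "global") align_global else align_local
    a <- fn(S, gap, query_seq = seq_of[[q]], target_seq = seq_of[[t]],
            query_id = q, target_id = t)
    score <- a$score
    if (normalize == "aligned_length" && nrow(a$pairs) > 0) {
      score <- score / nrow(a$pairs)
    }
    data.frame(query = q, target = t, score = score,
               n_aligned = nrow(a$pairs),
               query_start = if (nrow(a$pairs)) a$pairs[1, 1] else NA_integer_,
               query_end = if (nrow(a$pairs)) a$pairs[nrow(a$pairs), 1] + 1L else NA_integer_,
               target_start = if (nrow(a$pairs)) a$pairs[1, 2] else NA_integer_,
               target_end = if (nrow(a$pairs)) a$pairs[nrow(a$pairs), 2] + 1L else NA_integer_,
               query_aligned = a$query_aligned %||% NA_character_,
               target_aligned = a$target_aligned %||% NA_character_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Rerank search results by alignment score
#'
#' For each query, the aligned candidate pairs are re-sorted by alignment
#' score (descending, ties by ascending target id); pairs that were not
#' aligned (below the alignment threshold) are dropped, trading a marginal
#' loss in recall for better precision at the top of the list.
#'
#' @param results search-result data.frame (see [search_homologs()]).
#' @param alignments data.frame from [align_pairs()]; must cover exactly
#'   the selected alignment candidates.
#' @return data.frame with columns `query`, `target`, `rank`,
#'   `similarity`, `align_score`.
#' @export
rerank_by_alignment <- function(results, alignments) {
  key <- function(q, t) paste(q, t, sep = "\r")
  res_keys <- key(results$query, results$target)
  aln_keys <- key(alignments$query, alignments$target)
  unknown <- setdiff(aln_keys, res_keys)
  if (length(unknown)) {
    stop_("alignment for a pair absent from the search results: %s",
          gsub("\r", " -> ", unknown[1]))
  }
  merged <- merge(results[, c("query", "target", "similarity")],
                  alignments[, c("query", "target", "score")],
                  by = c("query", "target"))
  names(merged)[names(merged) == "score"] <- "align_score"
  merged <- merged[order(merged$query, -merged$align_score, merged$target), ,
                   drop = FALSE]
  merged$rank <- unlist(lapply(split(seq_len(nrow(merged)), merged$query),
                               seq_along), use.names = FALSE)
  rownames(merged) <- NULL
  merged[, c("query", "target", "rank", "similarity", "align_score")]
}
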