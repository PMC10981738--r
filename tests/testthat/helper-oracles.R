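# Independent oracles, written directly from first principles and kept
# free of any package internals so they can certify the implementation.

# All monotone sets of aligned index pairs for an m x n problem, as a list
# of k x 2 matrices (1-based); includes the empty alignment.
enumerate_monotone_alignments <- function(m, n) {
  out <- list(matrix(integer(), 0, 2))
  for (k in seq_len(min(m, n))) {
    rows <- utils::combn(m, k)
    cols <- utils::combn(n, k)
    for (a in seq_len(ncol(rows))) {
      for (b in seq_len(ncol(cols))) {
        out[[length(out) + 1L]] <- cbind(rows[, a], cols[, b])
      }
    }
  }
  out
}

# Optimal global score by exhaustive enumeration: every unmatched position
# in either sequence costs `gap`.
oracle_global_score <- function(S, gap) {
  m <- nrow(S); n <- ncol(S)
  best <- -Inf
  for (al in enumerate_monotone_alignments(m, n)) {
    k <- nrow(al)
    sc <- sum(S[al]) - gap * ((m - k) + (n - k))
    if (sc > best) best <- sc
  }
  best
}

# Optimal local score by exhaustive enumeration: gaps are only charged
# inside the spanned window; the empty alignment scores 0.
oracle_local_score <- function(S, gap) {
  best <- 0
  for (al in enumerate_monotone_alignments(nrow(S), ncol(S))) {
    k <- nrow(al)
    if (k == 0L) next
    span_q <- al[k, 1] - al[1, 1] + 1L
    span_t <- al[k, 2] - al[1, 2] + 1L
    sc <- sum(S[al]) - gap * ((span_q - k) + (span_t - k))
    if (sc > best) best <- sc
  }
  best
}

# Textbook character-level Needleman-Wunsch: match 1, mismatch 0, linear
# gap penalty including terminal gaps.  Written over characters, not over
# any package substitution matrix.
textbook_nw_score <- function(seq_a, seq_b, gap) {
  a <- strsplit(seq_a, "")[[1]]
  b <- strsplit(seq_b, "")[[1]]
  m <- length(a); n <- length(b)
  H <- matrix(0, m + 1, n + 1)
  H[, 1] <- -gap * (0:m)
  H[1, ] <- -gap * (0:n)
  for (i in 1:m) {
    for (j in 1:n) {
      H[i + 1, j + 1] <- max(H[i, j] + (a[i] == b[j]),
                             H[i, j + 1] - gap,
                             H[i + 1, j] - gap)
    }
  }
  H[m + 1, n + 1]
}

# --- retrieval-metric oracles, straight from the definitions ------------

# labels: character vector of "TP"/"FP" in rank order.
oracle_sensitivity <- function(labels, total_tp = sum(labels == "TP")) {
  if (total_tp == 0) return(NA_real_)
  hits <- 0
  for (l in labels) {
    if (l == "FP") break
    if (l == "TP") hits <- hits + 1
  }
  hits / total_tp
}

oracle_avep <- function(labels) {
  ranks <- which(labels == "TP")
  if (length(ranks) == 0) return(NA_real_)
  prec <- vapply(ranks, function(r) sum(labels[1:r] == "TP") / r, numeric(1))
  mean(prec)
}

oracle_p_at_k <- function(labels, k) {
  sum(labels[seq_len(min(k, length(labels)))] == "TP") / k
}

# Weighted precision/recall at every achieved threshold, by brute-force
# re-scan of the whole list for each distinct score.
oracle_weighted_pr <- function(scores, labels, weights, total_relevant) {
  ths <- sort(unique(scores), decreasing = TRUE)
  do.call(rbind, lapply(ths, function(t) {
    sel <- scores >= t
    wtp <- sum(weights[sel & labels == "TP"])
    wfp <- sum(weights[sel & labels == "FP"])
    data.frame(threshold = t, recall = wtp / total_relevant,
               precision = wtp / (wtp + wfp))
  }))
}

# Deterministic per-query sort used before applying rank-based oracles:
# similarity descending, FP before TP on ties, then target id.
oracle_sort <- function(df) {
  df[order(-df$similarity, ifelse(df$label == "FP", 0L, 1L), df$target), ,
     drop = FALSE]
}
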