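#' Reciprocal-Euclidean similarity between pooled embeddings
#'
#' `1 / (||p - q||_2 + 1)`: a symmetric similarity in (0, 1] that equals 1
#' iff the embeddings coincide and decreases strictly with distance.
#'
#' @param p,q numeric vectors of equal length.
#' @return a scalar in (0, 1].
#' @export
euclidean_similarity <- function(p, q) {
  if (length(p) != length(q)) {
    stop_("dimension mismatch: %d vs %d", length(p), length(q))
  }
  1 / (sqrt(sum((p - q)^2)) + 1)
}

#' Cosine similarity between pooled embeddings
#'
#' `p . q / max(||p|| ||q||, epsilon)`; the epsilon floor guards against
#' division by zero for degenerate all-zero embeddings.
#'
#' @param p,q numeric vectors of equal length.
#' @param epsilon small positive floor for the denominator.
#' @return a scalar in \[-1, 1\] for nonzero vectors.
#' @export
cos_similarity <- function(p, q, epsilon = 1e-8) {
  if (length(p) != length(q)) {
    stop_("dimension mismatch: %d vs %d", length(p), length(q))
  }
  sum(p * q) / max(sqrt(sum(p^2)) * sqrt(sum(q^2)), epsilon)
}

#' Construct a bilinear similarity model
#'
#' The model is a single learned `d x d` matrix `W`; the predicted
#' structural similarity (TM-score) of a pair of pooled embeddings
#' `(z1, z2)` is the bilinear form `z1' W z2`.
#'
#' @param W numeric `d x d` matrix with finite entries.
#' @return an object of class `bilinear_model`.
#' @export
bilinear_model <- function(W) {
  if (!is.matrix(W) || nrow(W) != ncol(W)) stop_("W must be a square matrix")
  if (!all(is.finite(W))) stop_("W must have finite entries")
  structure(list(W = W, dim = nrow(W)), class = "bilinear_model")
}

#' @export
print.bilinear_model <- function(x, ...) {
  cat(sprintf("<bilinear_model> d = %d, ||W||_F = %.4g\n",
              x$dim, sqrt(sum(x$W^2))))
  invisible(x)
}

#' Write / read a bilinear model
#'
#' Serialized as a binary container holding `W` plus metadata.
#'
#' @param model a `bilinear_model`.
#' @param path file path.
#' @return `path` (write) or the model (read).
#' @export
write_bilinear_model <- function(model, path) {
  stopifnot(inherits(model, "bilinear_model"))
  saveRDS(list(W = model$W, dim = model$dim), path)
  invisible(path)
}

#' @rdname write_bilinear_model
#' @export
read_bilinear_model <- function(path) {
  raw <- readRDS(path)
  bilinear_model(raw$W)
}

#' Predict TM-score for one pair of pooled embeddings
#'
#' Computes `z1' W z2` and clamps the result to \[0, 1\]: TM-score is
#' bounded, and the downstream combination rule multiplies the prediction
#' by a cosine similarity, so out-of-range values are truncated rather
#' than propagated.  (Training uses the unclamped form in its loss.)
#'
#' @param model a [bilinear_model()].
#' @param z1,z2 numeric vectors of length `d`.
#' @param clamp clamp the output to \[0,1\] (default TRUE).
#' @return predicted TM-score in \[0, 1\] (or the raw bilinear form when
#'   `clamp = FALSE`).
#' @export
predict_tm <- function(model, z1, z2, clamp = TRUE) {
  stopifnot(inherits(model, "bilinear_model"))
  if (length(z1) != model$dim || length(z2) != model$dim) {
    stop_("dimension mismatch with model (d = %d)", model$dim)
  }
  v <- drop(crossprod(z1, model$W %*% z2))
  if (clamp) v <- min(max(v, 0), 1)
  v
}

#' Predict TM-scores for all query x target pairs in one pass
#'
#' Batch form of [predict_tm()]: a single matrix product
#' `Z1 W Z2'` yields the full `n x m` score matrix, mirroring one forward
#' pass through the bilinear network for millions of pairs.
#'
#' @param model a [bilinear_model()].
#' @param Z1 `n x d` matrix of query pooled embeddings (rows named by id).
#' @param Z2 `m x d` matrix of target pooled embeddings.
#' @param clamp clamp scores to \[0,1\] (default TRUE).
#' @return `n x m` numeric matrix of predicted TM-scores.
#' @export
predict_tm_matrix <- function(model, Z1, Z2, clamp = TRUE) {
  stopifnot(inherits(model, "bilinear_model"))
  if (ncol(Z1) != model$dim || ncol(Z2) != model$dim) {
    stop_("dimension mismatch with model (d = %d)", model$dim)
  }
  S <- Z1 %*% model$W %*% t(Z2)
  if (clamp) S <- pmin(pmax(S, 0), 1)
  S
}

#' Combined structural-similarity score for a pair
#'
#' The final similarity combines the predicted TM-score with the cosine
#' similarity of the pooled embeddings: when the cosine similarity exceeds
#' `cos_threshold` (strictly), the similarity is the cosine similarity
#' itself -- near-duplicate sequences are ranked by cosine, where the
#' TM-score regressor (trained only on pairs with sequence identity below
#' 0.4) is unreliable; otherwise it is the predicted TM-score multiplied
#' by the cosine similarity.
#'
#' @param model a [bilinear_model()].
#' @param z1,z2 pooled embeddings.
#' @param cos_threshold switch point of the combination rule
#'   (default 0.995).
#' @param epsilon denominator floor passed to [cos_similarity()].
#' @return the combined similarity (scalar).
#' @export
ss_similarity <- function(model, z1, z2, cos_threshold = 0.995,
                          epsilon = 1e-8) {
  cs <- cos_similarity(z1, z2, epsilon)
  if (cs > cos_threshold) {
    cs
  } else {
    predict_tm(model, z1, z2) * cs
  }
}

# Vectorized combined score over paired rows of Z1/Z2 (one score per row
# pair); used by the search pipeline on candidate pair lists.
ss_similarity_rows <- function(model, Z1, Z2, cos_threshold = 0.995,
                               epsilon = 1e-8) {
  dots <- rowSums(Z1 * Z2)
  norms <- pmax(sqrt(rowSums(Z1^2)) * sqrt(rowSums(Z2^2)), epsilon)
  cs <- dots / norms
  tm <- rowSums((Z1 %*% model$W) * Z2)
  tm <- pmin(pmax(tm, 0), 1)
  ifelse(cs > cos_threshold, cs, tm * cs)
}

cos_similarity_rows <- function(Z1, Z2, epsilon = 1e-8) {
  dots <- rowSums(Z1 * Z2)
  norms <- pmax(sqrt(rowSums(Z1^2)) * sqrt(rowSums(Z2^2)), epsilon)
  dots / norms
}

euclidean_similarity_rows <- function(Z1, Z2) {
  1 / (sqrt(rowSums((Z1 - Z2)^2)) + 1)
}
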