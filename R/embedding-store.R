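#' Construct an embedding store
#'
#' A store holds the per-residue embedding matrix (`m x d`, one row per
#' residue) and/or the mean-pooled per-protein embedding (`1 x d`) of each
#' protein, keyed by identifier.  Pooled vectors are stored alongside the
#' matrices so that search never has to re-pool; large-scale search only
#' needs the pooled group in memory.
#'
#' @param per_residue named list of numeric matrices, one per protein.
#' @param pooled named list of numeric vectors, or NULL to derive by mean
#'   pooling from `per_residue`.
#' @return an object of class `embedding_store`.
#' @export
embedding_store <- function(per_residue = list(), pooled = NULL) {
  if (length(per_residue)) {
    if (is.null(names(per_residue)) || any(!nzchar(names(per_residue)))) {
      stop_("per-residue embeddings must be named by protein id")
    }
    dims <- vapply(per_residue, ncol, integer(1))
    if (length(unique(dims)) > 1L) {
      stop_("inconsistent embedding dimension across proteins: %s",
            paste(unique(dims), collapse = ", "))
    }
    if (!all(vapply(per_residue, function(m) all(is.finite(m)), logical(1)))) {
      stop_("non-finite values in per-residue embeddings")
    }
  }
  if (is.null(pooled)) {
    pooled <- lapply(per_residue, pool_embedding)
  }
  if (length(pooled)) {
    if (is.null(names(pooled)) || any(!nzchar(names(pooled)))) {
      stop_("pooled embeddings must be named by protein id")
    }
    pd <- unique(vapply(pooled, length, integer(1)))
    if (length(pd) > 1L) {
      stop_("inconsistent pooled embedding dimension: %s",
            paste(pd, collapse = ", "))
    }
    if (length(per_residue) && pd != ncol(per_residue[[1]])) {
      stop_("pooled dimension %d does not match per-residue dimension %d",
            pd, ncol(per_residue[[1]]))
    }
    if (!all(vapply(pooled, function(v) all(is.finite(v)), logical(1)))) {
      stop_("non-finite values in pooled embeddings")
    }
  }
  d <- if (length(pooled)) length(pooled[[1]]) else
    if (length(per_residue)) ncol(per_residue[[1]]) else NA_integer_
  structure(list(per_residue = per_residue, pooled = pooled, dim = d),
            class = "embedding_store")
}

#' @export
print.embedding_store <- function(x, ...) {
  cat(sprintf("<embedding_store> %d per-residue matrices, %d pooled vectors, d = %s\n",
              length(x$per_residue), length(x$pooled), x$dim))
  invisible(x)
}

#' Write an embedding store to disk
#'
#' The store is serialized as a single binary container holding one named
#' matrix per protein plus the pooled-vector group; the write/read
#' roundtrip is bit-exact.
#'
#' @param store an `embedding_store`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_embedding_store <- function(store, path) {
  stopifnot(inherits(store, "embedding_store"))
  saveRDS(unclass(store), path)
  invisible(path)
}

#' Read an embedding store from disk
#'
#' @param path path written by [write_embedding_store()].
#' @return an `embedding_store`; all invariants are re-validated on load.
#' @export
read_embedding_store <- function(path) {
  if (!file.exists(path)) stop_("embedding store not found: %s", path)
  raw <- readRDS(path)
  embedding_store(per_residue = raw$per_residue, pooled = raw$pooled)
}

#' Fetch one per-residue embedding matrix from a store
#' @param store an `embedding_store`.
#' @param id protein identifier.
#' @return the `m x d` matrix for `id`.
#' @export
get_embedding <- function(store, id) {
  m <- store$per_residue[[id]]
  if (is.null(m)) stop_("missing embedding for %s", id)
  m
}

#' Fetch one pooled per-protein embedding from a store
#' @param store an `embedding_store`.
#' @param id protein identifier.
#' @return the length-`d` pooled vector for `id`.
#' @export
get_pooled <- function(store, id) {
  v <- store$pooled[[id]]
  if (is.null(v)) stop_("missing embedding for %s", id)
  v
}

# Pooled embeddings for several ids as an n x d matrix (row names = ids).
pooled_matrix <- function(store, ids) {
  missing <- setdiff(ids, names(store$pooled))
  if (length(missing)) stop_("missing embedding for %s", missing[1])
  do.call(rbind, store$pooled[ids])
}
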