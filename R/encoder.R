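AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y", "X")

#' Describe an embedding encoder
#'
#' A pluggable producer of per-residue embeddings.  The `mock` backend is a
#' deterministic, context-free stand-in for a protein language model: every
#' residue letter has a fixed profile (one-hot over the 21-letter alphabet
#' plus reproducible Gaussian jitter on any extra dimensions), a pure
#' function of `(letter, seed)`.  Real encoders (transformer protein
#' language models producing 1024- or 1280-dimensional embeddings) can be
#' slotted in through the `external` backend without changing callers.
#'
#' @param backend `"mock"` or `"external"`.
#' @param dim embedding dimension `d` (mock backend requires
#'   `dim >= 21` so the one-hot block fits; default 32).
#' @param seed integer seed for the mock profiles.
#' @param noise_sd standard deviation of the jitter added to the one-hot
#'   profile (0 gives exact one-hot rows, which makes dot-product
#'   substitution scores equal identity scores).
#' @param encode_fun for `backend = "external"`: a function
#'   `(sequence) -> m x d matrix`.
#' @return an object of class `encoder_spec`.
#' @export
encoder_spec <- function(backend = c("mock", "external"), dim = 32L,
                         seed = 0L, noise_sd = 0, encode_fun = NULL) {
  backend <- match.arg(backend)
  dim <- as.integer(dim)
  if (dim < 1L) stop_("embedding dimension must be positive")
  if (backend == "mock" && dim < length(AA_ALPHABET)) {
    stop_("mock encoder needs dim >= %d (one-hot alphabet block)",
          length(AA_ALPHABET))
  }
  structure(list(backend = backend, dim = dim, seed = as.integer(seed),
                 noise_sd = noise_sd, encode_fun = encode_fun),
            class = "encoder_spec")
}

# Fixed per-letter profile table for the mock encoder: 21 x d, one-hot on
# the first 21 dims, seeded Gaussian jitter (sd = noise_sd) elsewhere.
mock_profiles <- function(spec) {
  n <- length(AA_ALPHABET)
  prof <- matrix(0, n, spec$dim, dimnames = list(AA_ALPHABET, NULL))
  prof[cbind(seq_len(n), seq_len(n))] <- 1
  if (spec$noise_sd > 0) {
    noise <- with_seed(derive_seed(spec$seed, "mock-profiles"),
                       matrix(rnorm(n * spec$dim, sd = spec$noise_sd), n, spec$dim))
    prof <- prof + noise
  }
  prof
}

#' Encode a protein sequence into per-residue embeddings
#'
#' @param sequence a single amino-acid sequence (non-empty).
#' @param spec an [encoder_spec()].
#' @return an `m x d` numeric matrix, one row per residue.  Mock output is
#'   bit-reproducible for the same `(sequence, seed)`, and context-free:
#'   editing one residue changes only that row.
#' @export
encode_protein <- function(sequence, spec) {
  stopifnot(inherits(spec, "encoder_spec"))
  if (!is.character(sequence) || length(sequence) != 1L || !nzchar(sequence)) {
    stop_("sequence must be a single non-empty string")
  }
  if (spec$backend == "external") {
    if (is.null(spec$encode_fun)) stop_("encoder backend unavailable")
    m <- spec$encode_fun(sequence)
    if (!is.matrix(m) || nrow(m) != nchar(sequence) || ncol(m) != spec$dim) {
      stop_("external encoder returned a matrix of the wrong shape")
    }
    return(m)
  }
  letters <- strsplit(toupper(sequence), "")[[1]]
  letters[!letters %in% AA_ALPHABET] <- "X"
  prof <- mock_profiles(spec)
  m <- prof[letters, , drop = FALSE]
  rownames(m) <- NULL
  m
}

#' Encode a set of protein records into an embedding store
#'
#' @param records data.frame with columns `id`, `sequence`.
#' @param spec an [encoder_spec()].
#' @return an [embedding_store()] holding per-residue matrices and their
#'   mean-pooled vectors.
#' @export
encode_dataset <- function(records, spec) {
  per_res <- lapply(setNames(records$sequence, records$id),
                    encode_protein, spec = spec)
  embedding_store(per_residue = per_res)
}

#' Mean-pool a per-residue embedding matrix
#'
#' Column-wise arithmetic mean, collapsing an `m x d` matrix into the
#' `1 x d` per-protein embedding used by the similarity predictor.
#'
#' @param matrix numeric matrix with at least one row.
#' @return numeric vector of length `d`.
#' @export
pool_embedding <- function(matrix) {
  if (!is.matrix(matrix) || nrow(matrix) < 1L) {
    stop_("per-residue embedding must be a matrix with >= 1 row")
  }
  colMeans(matrix)
}
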