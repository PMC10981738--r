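# Small shared builders for tests.

# Pooled-only store over given row vectors.
pooled_store <- function(Z, ids = sprintf("p%03d", seq_len(nrow(Z)))) {
  embedding_store(pooled = setNames(lapply(seq_len(nrow(Z)), function(i) Z[i, ]),
                                    ids))
}

# Planted-bilinear recovery problem: embeddings uniform in [0,1]^d so the
# raw bilinear scores of the scaled-identity planted model stay in [0,1].
make_recovery_problem <- function(n_proteins = 300L, d = 8L,
                                  n_pairs = 5000L, sigma = 0.02,
                                  seed = 42L) {
  set.seed(seed)
  Z <- matrix(runif(n_proteins * d), n_proteins, d)
  ids <- sprintf("p%03d", seq_len(n_proteins))
  store <- pooled_store(Z, ids)
  A <- matrix(runif(d * d), d, d)
  Wstar <- (A + t(A)) / 2        # symmetric, non-negative
  qi <- sample(ids, n_pairs, replace = TRUE)
  ti <- sample(ids, n_pairs, replace = TRUE)
  Z1 <- Z[match(qi, ids), , drop = FALSE]
  Z2 <- Z[match(ti, ids), , drop = FALSE]
  raw <- rowSums((Z1 %*% Wstar) * Z2)
  scale <- 0.5 / stats::median(raw)   # centre scores near 0.5, inside [0,1]
  Wstar <- Wstar * scale
  raw <- raw * scale
  tm <- pmin(pmax(raw + rnorm(n_pairs, sd = sigma), 0), 1)
  list(store = store,
       pairs = data.frame(query = qi, target = ti, tm_score = tm,
                          stringsAsFactors = FALSE),
       Wstar = Wstar, Z1 = Z1, Z2 = Z2, raw = raw)
}

# Random judged result table over a random planted hierarchy; returns the
# judged data.frame plus its labels, for metric-oracle comparisons.
random_judged_fixture <- function(seed, n_proteins = 24L, n_folds = 3L) {
  set.seed(seed)
  ids <- sprintf("x%02d", seq_len(n_proteins))
  fold <- sample(n_folds, n_proteins, replace = TRUE)
  sf <- fold * 10 + sample(2, n_proteins, replace = TRUE)
  fam <- sf * 10 + sample(2, n_proteins, replace = TRUE)
  labels <- data.frame(id = ids, family = paste0("f", fam),
                       superfamily = paste0("s", sf),
                       fold = paste0("F", fold), stringsAsFactors = FALSE)
  res <- expand.grid(query = ids, target = ids, stringsAsFactors = FALSE)
  res$similarity <- round(runif(nrow(res)), 2)   # deliberate score ties
  list(results = res, labels = labels)
}

desk_config <- function(seed = 3L) {
  train_config(batch_size = 100L, learning_rate = 1e-2, epochs = 50L,
               seed = seed)
}
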