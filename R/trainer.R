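#' Training configuration for the bilinear predictor
#'
#' Defaults record the full-scale regime used when training against tens
#' of millions of TM-score-labeled pairs from real embeddings (batch 100,
#' learning rate 1e-6, 200 epochs, Adam, MSE loss).  On small synthetic
#' fixtures the useful learning rate is much larger because the loss
#' landscape scales with embedding magnitude; tests use desk-scale values
#' such as `lr = 1e-2, epochs = 50`.
#'
#' @param batch_size mini-batch size.
#' @param learning_rate Adam step size.
#' @param epochs number of passes over the training pairs.
#' @param seed integer seed fixing initialization and shuffle order.
#' @return an object of class `train_config`.
#' @export
train_config <- function(batch_size = 100L, learning_rate = 1e-6,
                         epochs = 200L, seed = 0L) {
  stopifnot(batch_size >= 1, learning_rate > 0, epochs >= 1)
  structure(list(batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 epochs = as.integer(epochs),
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Train the bilinear TM-score predictor
#'
#' Fits the `d x d` matrix `W` minimizing the mean squared error between
#' the raw bilinear form `z1' W z2` (unclamped) and the TM-score label of
#' each pair, by mini-batch gradient descent with adaptive moment
#' estimation (Adam).  Only `W` is trained; the encoder producing the
#' embeddings is frozen.  Training is deterministic given the config seed:
#' fixed initialization (identity scaled to 1/d plus small Gaussian
#' jitter, which biases the start toward cosine-like behaviour) and fixed
#' shuffle order.
#'
#' @param pairs data.frame with columns `query`, `target`, `tm_score`
#'   (labels in \[0, 1\]).
#' @param store an [embedding_store()] holding pooled embeddings for every
#'   id in `pairs`.
#' @param config a [train_config()].
#' @return a [bilinear_model()] with attribute `loss_history` (per-epoch
#'   mean training loss).
#' @export
train_bilinear <- function(pairs, store, config = train_config()) {
  stopifnot(inherits(config, "train_config"))
  if (any(pairs$tm_score < 0 | pairs$tm_score > 1)) {
    stop_("tm_score labels must lie in [0,1]")
  }
  Z1 <- pooled_matrix(store, pairs$query)
  Z2 <- pooled_matrix(store, pairs$target)
  y <- pairs$tm_score
  n <- nrow(Z1)
  d <- ncol(Z1)

  with_seed(config$seed, {
    W <- diag(d) / d + matrix(rnorm(d * d, sd = 1e-3 / d), d, d)
    mW <- matrix(0, d, d)          # Adam first moment
    vW <- matrix(0, d, d)          # Adam second moment
    beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
    step <- 0L
    loss_history <- numeric(config$epochs)
    for (epoch in seq_len(config$epochs)) {
      ord <- sample.int(n)
      batch_losses <- c()
      for (start in seq(1L, n, by = config$batch_size)) {
        idx <- ord[start:min(start + config$batch_size - 1L, n)]
        B1 <- Z1[idx, , drop = FALSE]
        B2 <- Z2[idx, , drop = FALSE]
        yb <- y[idx]
        pred <- rowSums((B1 %*% W) * B2)
        resid <- pred - yb
        batch_losses <- c(batch_losses, mean(resid^2))
        grad <- crossprod(B1, B2 * (2 * resid / length(idx)))
        step <- step + 1L
        mW <- beta1 * mW + (1 - beta1) * grad
        vW <- beta2 * vW + (1 - beta2) * grad^2
        mhat <- mW / (1 - beta1^step)
        vhat <- vW / (1 - beta2^step)
        W <- W - config$learning_rate * mhat / (sqrt(vhat) + eps)
      }
      loss_history[epoch] <- mean(batch_losses)
    }
    model <- bilinear_model(W)
    attr(model, "loss_history") <- loss_history
    model
  })
}
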