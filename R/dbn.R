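#' Train one restricted Boltzmann machine layer by CD-1
#'
#' Binary visible units (counts binarized at >= 1), sigmoid hidden units,
#' single-step contrastive divergence with mini-batches. The mean squared
#' reconstruction error per epoch is recorded.
#'
#' @param X Binary matrix (samples x visible units); counts are binarized.
#' @param n_hidden Number of hidden units.
#' @param epochs Training epochs.
#' @param lr Learning rate.
#' @param batch_size Mini-batch size.
#' @param seed Seed; training is bitwise-reproducible given it.
#' @return An `rbm_layer` list: `W` (visible x hidden), `vbias`, `hbias`,
#'   `recon_error` (per epoch).
#' @export
train_rbm <- function(X, n_hidden, epochs = 10, lr = 0.1, batch_size = 64,
                      seed = 1) {
  X <- as.matrix(X)
  if (nrow(X) == 0L) abort("empty training data.")
  # counts binarize at >= 1; values already in [0, 1] (e.g. activation
  # probabilities from a lower layer) pass through as Bernoulli means
  if (any(X > 1)) X <- (X >= 1) * 1
  d <- ncol(X)
  withr::with_seed(seed, {
    W <- matrix(rnorm(d * n_hidden, sd = 0.01), d, n_hidden)
    vb <- numeric(d)
    hb <- numeric(n_hidden)
    recon <- numeric(epochs)
    n <- nrow(X)
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      err <- 0
      for (b in split(ord, ceiling(seq_along(ord) / batch_size))) {
        v0 <- X[b, , drop = FALSE]
        h0p <- plogis(sweep(v0 %*% W, 2, hb, "+"))
        h0 <- (matrix(runif(length(h0p)), nrow(h0p)) < h0p) * 1
        v1p <- plogis(sweep(h0 %*% t(W), 2, vb, "+"))
        h1p <- plogis(sweep(v1p %*% W, 2, hb, "+"))
        nb <- length(b)
        W <- W + lr * (t(v0) %*% h0p - t(v1p) %*% h1p) / nb
        vb <- vb + lr * colMeans(v0 - v1p)
        hb <- hb + lr * colMeans(h0p - h1p)
        err <- err + sum((v0 - v1p)^2)
      }
      recon[ep] <- err / (n * d)
    }
    structure(list(W = W, vbias = vb, hbias = hb, recon_error = recon),
              class = "rbm_layer")
  })
}

#' Train a stacked deep belief network
#'
#' Greedy layer-wise RBM pre-training: each trained layer's mean-field
#' hidden activations feed the next RBM.
#'
#' @param X Binary feature matrix (counts are binarized at >= 1).
#' @param hidden Integer vector of hidden-layer widths (the classic
#'   configuration is `c(2000, 1000, 500)`; scale down for small vocabularies).
#' @param epochs,lr,batch_size Per-layer RBM training parameters.
#' @param seed Seed.
#' @return A `dbn_model` list of `rbm_layer`s plus the input width.
#' @export
train_dbn <- function(X, hidden = c(2000, 1000, 500), epochs = 10, lr = 0.1,
                      batch_size = 64, seed = 1) {
  X <- (as.matrix(X) >= 1) * 1
  layers <- vector("list", length(hidden))
  input <- X
  for (p in seq_along(hidden)) {
    layers[[p]] <- train_rbm(input, hidden[p], epochs = epochs, lr = lr,
                             batch_size = batch_size,
                             seed = derive_seed(seed, p))
    # deterministic mean-field activation probabilities feed the next RBM
    input <- plogis(sweep(input %*% layers[[p]]$W, 2, layers[[p]]$hbias, "+"))
  }
  structure(list(layers = layers, input_width = ncol(X), hidden = hidden),
            class = "dbn_model")
}

#' Deterministic DBN forward pass
#'
#' Mean-field sigmoid activations through the stack, no sampling; returns
#' the top-layer activation matrix.
#'
#' @param model A `dbn_model`.
#' @param X Feature matrix (messages x input width); counts are binarized.
#' @return Matrix of top-layer activations in (0, 1).
#' @export
dbn_features <- function(model, X) {
  stopifnot(inherits(model, "dbn_model"))
  X <- as.matrix(X)
  if (ncol(X) != model$input_width) {
    abort(sprintf("width mismatch: model expects %d inputs, got %d.",
                  model$input_width, ncol(X)))
  }
  A <- (X >= 1) * 1
  for (layer in model$layers) {
    A <- plogis(sweep(A %*% layer$W, 2, layer$hbias, "+"))
  }
  A
}
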