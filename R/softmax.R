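# Softmax regression core shared by the topic classifier, the subtopic head,
# and the affect-tree node classifiers.
#
# Parameters are a k x d weight matrix W (one weight vector per class, no
# intercept). The penalized cost is
#   J(W) = -(1/n) sum_i log p(y_i | x_i; W) + (lambda/2) ||W||^2,
# with gradient (1/n) (P - Y)' X + lambda W.

softmax_probs <- function(W, X) {
  S <- as.matrix(X %*% Matrix::t(W))      # n x k scores
  S <- S - apply(S, 1, max)               # shift invariance / overflow guard
  E <- exp(S)
  E / rowSums(E)
}

softmax_cost <- function(W, X, Y, lambda) {
  P <- softmax_probs(W, X)
  -(1 / nrow(X)) * sum(Y * log(pmax(P, 1e-300))) + (lambda / 2) * sum(W^2)
}

softmax_grad <- function(W, X, Y, lambda) {
  P <- softmax_probs(W, X)
  as.matrix(Matrix::t(P - Y) %*% X) / nrow(X) + lambda * W
}

one_hot <- function(y, classes) {
  Y <- matrix(0, length(y), length(classes))
  Y[cbind(seq_along(y), match(y, classes))] <- 1
  Y
}

# Full-batch fit by L-BFGS (stats::optim, lmm = stored-update memory) or by
# gradient descent with backtracking line search (cost trace non-increasing;
# a failed line search raises a step-size error). With `intercept = TRUE` a
# constant feature is appended (the parameter index-0 convention), so the
# returned W has d + 1 columns, the last being the per-class bias.
fit_softmax <- function(X, y, classes = sort(unique(y)), lambda = 1,
                        method = c("lbfgs", "gd"), maxit = 200, tol = 1e-8,
                        memory = 6, lr = 0.5, W0 = NULL, intercept = TRUE) {
  method <- match.arg(method)
  if (intercept) X <- cbind(X, `(bias)` = rep(1, nrow(X)))
  k <- length(classes)
  d <- ncol(X)
  if (k < 2) abort("degenerate training set: need at least 2 classes.")
  Y <- one_hot(y, classes)
  if (is.null(W0)) W0 <- matrix(0, k, d)
  if (method == "lbfgs") {
    fn <- function(par) softmax_cost(matrix(par, k, d), X, Y, lambda)
    gr <- function(par) as.vector(softmax_grad(matrix(par, k, d), X, Y, lambda))
    opt <- optim(as.vector(W0), fn, gr, method = "L-BFGS-B",
                 control = list(maxit = maxit, lmm = memory, factr = 1e4))
    W <- matrix(opt$par, k, d)
    trace <- c(fn(as.vector(W0)), opt$value)
  } else {
    W <- W0
    trace <- softmax_cost(W, X, Y, lambda)
    for (it in seq_len(maxit)) {
      G <- softmax_grad(W, X, Y, lambda)
      step <- lr
      repeat {
        W_new <- W - step * G
        cost_new <- softmax_cost(W_new, X, Y, lambda)
        if (cost_new <= trace[length(trace)] + 1e-12) break
        step <- step / 2
        if (step < 1e-12) {
          abort(paste("gradient descent diverged: no decreasing step found.",
                      "Reduce the learning rate or switch to L-BFGS."))
        }
      }
      W <- W_new
      trace <- c(trace, cost_new)
      delta <- trace[length(trace) - 1] - trace[length(trace)]
      if (delta < tol) break
    }
  }
  dimnames(W) <- list(classes, colnames(X))
  list(W = W, classes = classes, lambda = lambda, cost = trace[length(trace)],
       trace = trace, intercept = intercept)
}

# Class probabilities / argmax labels for a fit_softmax() result.
softmax_fit_probs <- function(fit, X) {
  if (isTRUE(fit$intercept)) X <- cbind(X, rep(1, nrow(X)))
  softmax_probs(fit$W, X)
}

softmax_predict <- function(fit, X) {
  P <- softmax_fit_probs(fit, X)
  fit$classes[max.col(P, ties.method = "first")]
}

# Mini-batch SGD with momentum and weight decay; records per-epoch loss.
# Used by the affect-tree node classifiers.
sgd_softmax <- function(X, y, classes = sort(unique(y)), epochs = 50,
                        lr = 0.1, momentum = 0.9, weight_decay = 0.001,
                        batch_size = 32, seed = 1) {
  X <- as.matrix(X)
  k <- length(classes)
  if (k < 2) abort("degenerate training set: need at least 2 classes.")
  Y <- one_hot(y, classes)
  W <- matrix(0, k, ncol(X))
  V <- matrix(0, k, ncol(X))
  n <- nrow(X)
  loss <- numeric(epochs)
  withr::with_seed(seed, {
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      for (b in split(ord, ceiling(seq_along(ord) / batch_size))) {
        G <- softmax_grad(W, X[b, , drop = FALSE], Y[b, , drop = FALSE],
                          lambda = weight_decay)
        V <- momentum * V - lr * G
        W <- W + V
      }
      loss[ep] <- softmax_cost(W, X, Y, weight_decay)
    }
  })
  dimnames(W) <- list(classes, colnames(X))
  list(W = W, classes = classes, loss = loss)
}
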