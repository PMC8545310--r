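test_that("CD-1 training reduces reconstruction error on prototype data", {
  withr::with_seed(42, {
    proto <- matrix(rbinom(8 * 16, 1, 0.5), 8, 16)
    X <- proto[sample(8, 500, replace = TRUE), ]
  })
  rbm <- train_rbm(X, n_hidden = 20, epochs = 15, lr = 0.2, seed = 4)
  expect_lt(tail(rbm$recon_error, 1), rbm$recon_error[1])
})

test_that("a zero learning rate leaves RBM weights at their initialization", {
  X <- matrix(rbinom(50 * 6, 1, 0.4), 50, 6)
  r0 <- train_rbm(X, 4, epochs = 0, lr = 0.5, seed = 9)
  r1 <- train_rbm(X, 4, epochs = 5, lr = 0, seed = 9)
  expect_identical(r0$W, r1$W)
  expect_identical(r1$vbias, numeric(6))
})

test_that("RBM training is bitwise-reproducible under a fixed seed", {
  X <- matrix(rbinom(60 * 8, 1, 0.3), 60, 8)
  expect_identical(train_rbm(X, 5, epochs = 3, seed = 12),
                   train_rbm(X, 5, epochs = 3, seed = 12))
  expect_error(train_rbm(X[0, ], 5), "empty")
})

test_that("the DBN forward pass matches hand-computed sigmoids", {
  # zero weights and input: every activation is sigmoid(0) = 0.5
  dbn0 <- structure(list(
    layers = list(structure(list(W = matrix(0, 3, 2), vbias = numeric(3),
                                 hbias = numeric(2)), class = "rbm_layer")),
    input_width = 3L, hidden = 2L), class = "dbn_model")
  expect_equal(as.numeric(dbn_features(dbn0, matrix(0, 1, 3))), c(0.5, 0.5))

  # two hand-set units: activations equal plogis(Wx + b) exactly
  W <- matrix(c(0.5, -1, 2, 0.25, 1, -0.5), 3, 2)
  b <- c(0.1, -0.2)
  dbn1 <- structure(list(
    layers = list(structure(list(W = W, vbias = numeric(3), hbias = b),
                            class = "rbm_layer")),
    input_width = 3L, hidden = 2L), class = "dbn_model")
  x <- c(1, 0, 1)
  expect_equal(as.numeric(dbn_features(dbn1, matrix(x, 1))),
               as.numeric(plogis(x %*% W + b)), tolerance = 1e-12)

  # activations stay strictly inside (0, 1)
  A <- dbn_features(dbn1, matrix(rbinom(30, 1, 0.5), 10, 3))
  expect_true(all(A > 0 & A < 1))
  expect_error(dbn_features(dbn1, matrix(0, 1, 5)), "width mismatch")
})

test_that("the softmax head equals a brute-force evaluation", {
  expect_equal(softmax_forward(matrix(1, 4, 3), c(1, 2, 3)), rep(0.25, 4),
               ignore_attr = TRUE)
  withr::with_seed(200, {
    for (r in 1:10) {
      W <- matrix(rnorm(4 * 6), 4, 6, dimnames = list(paste0("s", 1:4), NULL))
      m <- rnorm(6)
      expect_equal(unname(softmax_forward(W, m)), unname(oracle_softmax(W, m)),
                   tolerance = 1e-9)
      expect_equal(sum(softmax_forward(W, m)), 1, tolerance = 1e-12)
    }
  })
  expect_error(softmax_forward(matrix(1, 2, 3), c(1, NA, 2)), "non-finite")
})

test_that("softmax head is shift-invariant in its parameters", {
  withr::with_seed(201, {
    W <- matrix(rnorm(12), 3, 4)
    m <- rnorm(4)
  })
  shift <- rep(1, 3) %o% c(2, -1, 0.5, 3)
  expect_equal(softmax_forward(W, m), softmax_forward(W + shift, m),
               tolerance = 1e-12)
})

test_that("the fine-tuning gradient matches central finite differences", {
  withr::with_seed(303, {
    X <- matrix(rnorm(15 * 4), 15, 4)
    y <- sample(c("a", "b", "c"), 15, replace = TRUE)
    W <- matrix(rnorm(12, sd = 0.3), 3, 4)
  })
  Y <- osnevents:::one_hot(y, c("a", "b", "c"))
  lambda <- 2
  g <- osnevents:::softmax_grad(W, X, Y, lambda)
  eps <- 1e-5
  for (idx in seq_along(W)) {
    Wp <- W; Wp[idx] <- Wp[idx] + eps
    Wm <- W; Wm[idx] <- Wm[idx] - eps
    fd <- (osnevents:::softmax_cost(Wp, X, Y, lambda) -
             osnevents:::softmax_cost(Wm, X, Y, lambda)) / (2 * eps)
    expect_equal(g[idx], fd, tolerance = 1e-5)
  }
})

test_that("zero penalty reduces the cost to plain cross-entropy", {
  withr::with_seed(304, {
    X <- matrix(rnorm(10 * 3), 10, 3)
    y <- sample(c("a", "b"), 10, replace = TRUE)
    W <- matrix(rnorm(6), 2, 3)
  })
  Y <- osnevents:::one_hot(y, c("a", "b"))
  P <- osnevents:::softmax_probs(W, X)
  ce <- -mean(log(P[cbind(1:10, match(y, c("a", "b")))]))
  expect_equal(osnevents:::softmax_cost(W, X, Y, 0), ce, tolerance = 1e-12)
})

test_that("fine-tuning separates a separable three-subtopic toy", {
  withr::with_seed(305, {
    X <- rbind(matrix(rnorm(30 * 2, mean = 0), 30, 2),
               matrix(rnorm(30 * 2, mean = 5), 30, 2),
               matrix(c(rnorm(30, 10), rnorm(30, 0)), 30, 2))
  })
  y <- rep(c("s1", "s2", "s3"), each = 30)
  fit <- finetune(X, y, finetune_config(lambda = 0.001))
  pred <- osnevents:::softmax_predict(fit, X)
  expect_equal(mean(pred == y), 1)
  expect_error(finetune(X[0, , drop = FALSE], character(0)), "empty")
})

test_that("gradient descent and L-BFGS agree on a convex head-only problem", {
  withr::with_seed(306, {
    X <- matrix(rnorm(40 * 3), 40, 3)
    y <- sample(c("a", "b"), 40, replace = TRUE)
  })
  f1 <- finetune(X, y, finetune_config(optimizer = "lbfgs", maxit = 500))
  f2 <- finetune(X, y, finetune_config(optimizer = "gd", maxit = 2000, tol = 1e-12))
  expect_lt(abs(f1$cost - f2$cost), 1e-3)
  expect_true(all(diff(f2$trace) <= 1e-12))
})

test_that("the frozen-stack penalty enters the reported cost as a constant", {
  withr::with_seed(307, {
    X <- matrix(rnorm(20 * 2), 20, 2)
    y <- sample(c("a", "b"), 20, replace = TRUE)
  })
  dbn <- structure(list(layers = list(structure(list(
    W = matrix(2, 2, 2), vbias = numeric(2), hbias = numeric(2)),
    class = "rbm_layer")), input_width = 2L, hidden = 2L), class = "dbn_model")
  cfg <- finetune_config(lambda = 2)
  f_plain <- finetune(X, y, cfg)
  f_stack <- finetune(X, y, cfg, dbn = dbn)
  expect_equal(f_stack$cost - f_plain$cost, (2 / 2) * sum(matrix(2, 2, 2)^2))
})

test_that("subtopic discovery recovers well-separated clusters", {
  withr::with_seed(99, {
    vocabA <- paste0("flu", 1:6); vocabB <- paste0("diet", 1:6)
    toks <- c(replicate(60, sample(vocabA, 5, TRUE), simplify = FALSE),
              replicate(60, sample(vocabB, 5, TRUE), simplify = FALSE))
  })
  vocab <- c(vocabA, vocabB)
  X <- vectorize(toks, vocab)
  dbn <- train_dbn(X, hidden = c(8, 4), epochs = 20, lr = 0.5, seed = 5)
  feats <- dbn_features(dbn, X)
  disc <- discover_subtopics(feats, 2, counts = X, seed = 6)
  truth <- rep(c(1, 2), each = 60)
  purity <- max(mean((disc$assignments$cluster == truth)),
                mean((disc$assignments$cluster != truth)))
  expect_gte(purity, 0.95)
  # identical partition across runs with the same seed
  disc2 <- discover_subtopics(feats, 2, counts = X, seed = 6)
  expect_identical(disc$assignments, disc2$assignments)
  expect_error(discover_subtopics(feats, nrow(feats) + 1), "exceeds")
})

test_that("cluster labels pick the highest-lift tokens of each subtopic", {
  withr::with_seed(98, {
    vocabA <- c("flu", "fever", "breathe"); vocabB <- c("gym", "yoga", "run")
    toks <- c(replicate(50, sample(vocabA, 6, TRUE), simplify = FALSE),
              replicate(50, sample(vocabB, 6, TRUE), simplify = FALSE))
  })
  X <- vectorize(toks, c(vocabA, vocabB))
  dbn <- train_dbn(X, hidden = c(6), epochs = 10, lr = 0.2, seed = 7)
  feats <- dbn_features(dbn, X)
  disc <- discover_subtopics(feats, 2, counts = X, seed = 8)
  all_top <- unlist(disc$clusters$top_tokens)
  expect_gte(mean(vocabA %in% all_top), 0.9)
})

test_that("subtopic ranking reports descending percentages that total 100", {
  assignments <- tibble::tibble(
    topic = "health",
    subtopic = rep(c("flu", "fever", "other"), c(7, 3, 190))
  )
  rk <- rank_subtopics(assignments, "health")
  expect_equal(rk$pct[rk$subtopic == "flu"], 3.50)
  expect_true(all(diff(rk$pct) <= 0))
  expect_equal(sum(rk$pct), 100, tolerance = 0.01)
  single <- rank_subtopics(tibble::tibble(topic = "t", subtopic = "only"), "t")
  expect_equal(single$pct, 100)
  expect_error(rank_subtopics(assignments, "nope"), "no messages")
})

test_that("the model bundle round-trips through disk", {
  X <- matrix(rbinom(40 * 6, 1, 0.4), 40, 6)
  dbn <- train_dbn(X, hidden = c(4, 3), epochs = 3, seed = 2)
  head_fit <- finetune(dbn_features(dbn, X),
                       rep(c("a", "b"), 20), finetune_config())
  dir <- withr::local_tempdir()
  write_subtopic_bundle(dbn, head_fit, dir, meta = list(seed = 2))
  back <- read_subtopic_bundle(dir)
  expect_equal(back$dbn$layers[[1]]$W, dbn$layers[[1]]$W, tolerance = 1e-12)
  expect_equal(unname(back$head$W), unname(head_fit$W), tolerance = 1e-12)
  expect_equal(dbn_features(back$dbn, X), dbn_features(dbn, X), tolerance = 1e-10)
})
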