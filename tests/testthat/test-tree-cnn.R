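test_that("growth actions follow the softmax-gap rules", {
  expect_identical(grow_decision(c(0.50, 0.30, 0.20))$action, "add_to_child")
  expect_identical(grow_decision(c(0.40, 0.35, 0.10))$action, "merge_children")
  expect_identical(grow_decision(c(0.36, 0.33, 0.31))$action, "new_child")
  # a full node always grows horizontally
  expect_identical(grow_decision(c(0.50, 0.30, 0.20), node_full = TRUE)$action,
                   "new_child")
  expect_error(grow_decision(c(0.2, 0.5, 0.3)), "descending")
  expect_error(grow_decision(c(0.9, 0.8, 0.7)), "exceed")
})

test_that("the simplex sweep matches an independent rule oracle off-boundary", {
  alpha <- beta <- 0.1
  grid <- seq(0, 1, by = 0.01)
  checked <- 0L
  for (o1 in grid) for (o2 in grid[grid <= o1]) {
    o3 <- round(1 - o1 - o2, 10)
    if (o3 < 0 || o3 > o2) next
    expected <- oracle_grow(o1, o2, o3, alpha, beta, FALSE)
    got <- grow_decision(c(o1, o2, o3), alpha, beta)$action
    if (is.na(expected)) {
      # boundary cases resolve to the conservative horizontal growth
      expect_identical(got, "new_child")
    } else {
      expect_identical(got, expected)
      checked <- checked + 1L
    }
  }
  expect_gt(checked, 700)
})

test_that("the first word becomes a single child under the root", {
  tree <- build_tree("hello")
  expect_identical(nrow(tree$nodes), 2L)
  expect_identical(tree$nodes$depth, c(0L, 1L))
  expect_identical(tree$nodes$words[[2]], "hello")
})

# outputs so flat that both softmax gaps stay below the thresholds,
# forcing horizontal growth on every insertion
force_new_child <- function(tree, node, word) {
  k <- length(osnevents:::tree_children(tree, node))
  rep(1 / max(k, 20), k)
}

test_that("an adversarial new-child stream respects depth and capacity limits", {
  cfg <- tree_cnn_config(max_children = 5, max_depth = 3)
  words <- sprintf("w%04d", 1:1000)
  tree <- build_tree(words, cfg, output_fn = force_new_child)
  a <- audit_tree(tree)
  expect_true(a$ok)
  expect_lte(a$max_depth, 3L)
  expect_lte(a$max_children_observed, 5L)
  # the log records one decision per insertion and the running max depth
  expect_identical(nrow(tree$log), 1000L)
  expect_true(all(tree$log$depth <= 3L))
  # every inserted word is held somewhere in the tree
  expect_identical(sort(unlist(tree$nodes$words)), sort(words))
})

test_that("strict mode raises a capacity error naming the offending word", {
  cfg <- tree_cnn_config(max_children = 2, max_depth = 1)
  expect_error(build_tree(sprintf("w%d", 1:10), cfg, strict = TRUE,
                          output_fn = force_new_child),
               "capacity exhausted at word")
})

test_that("tree construction is deterministic given fixed decisions", {
  cfg <- tree_cnn_config(max_children = 5)
  words <- sprintf("w%03d", 1:200)
  t1 <- build_tree(words, cfg, output_fn = force_new_child)
  t2 <- build_tree(words, cfg, output_fn = force_new_child)
  expect_identical(t1$nodes, t2$nodes)
  expect_identical(t1$log, t2$log)
})

test_that("merge decisions create a branch holding both children", {
  # w1: first insertion; w2 sees a weak single-child likelihood (0.05, 0, 0)
  # so both gaps are small -> second child; w3 sees (0.40, 0.38, 0):
  # gap1 = 0.02 < alpha and gap2 = 0.38 > beta -> merge the two children.
  fn <- function(tree, node, word) {
    k <- length(osnevents:::tree_children(tree, node))
    if (word == "w2") 0.05 else c(0.40, 0.38)[seq_len(k)]
  }
  tree <- build_tree(c("w1", "w2", "w3"), tree_cnn_config(), output_fn = fn)
  expect_identical(tree$log$action, c("new_child", "new_child", "merge_children"))
  merged <- tree$nodes[tree$nodes$depth == 1 & tree$nodes$id > 1, ]
  expect_identical(nrow(merged), 1L)
  expect_identical(sum(tree$nodes$depth == 2L), 2L)
})

make_emotion_clean <- function(n, seed, shuffle = FALSE) {
  emotions <- c("anger", "disgust", "fear", "joy", "sadness", "surprise")
  markers <- setNames(lapply(emotions, function(e) paste0(e, "_mk", 1:5)),
                      emotions)
  withr::with_seed(seed, {
    emo <- sample(emotions, n, replace = TRUE)
    tokens <- lapply(emo, function(e) {
      c(sample(markers[[e]], 3, replace = TRUE),
        sample(paste0("neutral", 1:20), 4, replace = TRUE))
    })
    if (shuffle) emo <- sample(emo)
  })
  tibble::tibble(id = sprintf("e%04d", seq_len(n)), tokens = tokens,
                 emotion = emo)
}

test_that("marker-separable emotions classify almost perfectly held out", {
  clean <- make_emotion_clean(600, seed = 61)
  train <- clean[1:480, ]; test <- clean[481:600, ]
  cfg <- tree_cnn_config(epochs = 40)
  model <- train_affect(train, cfg, seed = 3)
  pred <- predict_affect(model, test)
  expect_gte(mean(pred$emotion == test$emotion), 0.95)
  # the polarity mapping rides along
  expect_true(all(pred$polarity[pred$emotion == "fear"] == "negative"))
  expect_true(all(pred$polarity[pred$emotion == "joy"] == "positive"))
})

test_that("single-emotion data is rejected as degenerate", {
  clean <- make_emotion_clean(60, seed = 62)
  clean$emotion <- "joy"
  expect_error(train_affect(clean, tree_cnn_config(epochs = 2)), "degenerate")
})

test_that("training loss is reproducible to full precision under a seed", {
  clean <- make_emotion_clean(120, seed = 63)
  cfg <- tree_cnn_config(epochs = 5)
  m1 <- train_affect(clean, cfg, seed = 9)
  m2 <- train_affect(clean, cfg, seed = 9)
  expect_equal(glance(m1)$final_loss, glance(m2)$final_loss, tolerance = 1e-9)
  expect_identical(m1$classifiers, m2$classifiers)
})

test_that("classification is deterministic and errors on empty input", {
  clean <- make_emotion_clean(120, seed = 64)
  model <- train_affect(clean, tree_cnn_config(epochs = 10), seed = 2)
  tk <- clean$tokens[[1]]
  expect_identical(classify_emotion(model, tk), classify_emotion(model, tk))
  expect_error(classify_emotion(model, character(0)), "unclassifiable")
})

test_that("the polarity map follows the configured surprise convention", {
  expect_identical(unname(emotion_polarity()[c("joy", "fear", "surprise")]),
                   c("positive", "negative", "positive"))
  expect_identical(unname(emotion_polarity(FALSE)["surprise"]), "negative")
})

test_that("tidiers expose tree structure and limits", {
  tree <- build_tree(sprintf("w%d", 1:50), tree_cnn_config())
  td <- tidy(tree)
  expect_true(all(c("id", "parent", "depth", "label", "n_words") %in% names(td)))
  g <- glance(tree)
  expect_true(g$within_limits)
})
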