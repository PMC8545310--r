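#' Softmax head over DBN features
#'
#' `h[t] = exp(s_t . m) / sum_u exp(s_u . m)` for each subtopic class t.
#'
#' @param head Weight matrix (classes x feature dimension), e.g. the `W`
#'   element returned by [finetune()].
#' @param m Feature vector, or a matrix of feature rows.
#' @return Probability vector (or matrix of rows) summing to one.
#' @export
softmax_forward <- function(head, m) {
  W <- if (is.list(head)) head$W else head
  if (is.null(dim(m))) m <- matrix(m, nrow = 1)
  if (any(!is.finite(m))) abort("non-finite input to softmax_forward.")
  if (is.list(head) && isTRUE(head$intercept)) m <- cbind(m, rep(1, nrow(m)))
  if (ncol(m) != ncol(W)) abort("feature dimension mismatch.")
  P <- softmax_probs(W, m)
  colnames(P) <- rownames(W)
  if (nrow(P) == 1L) P[1, ] else P
}

#' Fine-tuning configuration
#'
#' @param lambda Penalty factor on the squared parameters (default 2).
#' @param memory Number of stored updates for the limited-memory
#'   quasi-Newton optimizer (default 6).
#' @param optimizer `"lbfgs"` or `"gd"` (gradient descent with backtracking
#'   line search).
#' @param maxit Maximum iterations.
#' @param tol Convergence tolerance on the cost decrease.
#' @return A list of class `finetune_config`.
#' @export
finetune_config <- function(lambda = 2, memory = 6,
                            optimizer = c("lbfgs", "gd"),
                            maxit = 200, tol = 1e-8) {
  if (lambda < 0) abort("`lambda` must be non-negative.")
  if (memory < 1) abort("`memory` must be at least 1.")
  structure(list(lambda = lambda, memory = memory,
                 optimizer = match.arg(optimizer),
                 maxit = maxit, tol = tol),
            class = "finetune_config")
}

#' Fine-tune the softmax head on labeled data
#'
#' Minimizes the penalized cross-entropy cost
#' `J = -(1/n) sum_i sum_t y_t^i log h_t(x_i) + (lambda/2)||s||^2
#'  + (lambda/2) sum_p ||theta_p||^2`,
#' where the last term penalizes the (fixed) RBM stack weights and is
#' constant in the head parameters. Only the head is optimized; the stack
#' stays frozen at its pre-trained weights.
#'
#' @param features Feature matrix (samples x d), e.g. [dbn_features()] output.
#' @param labels Class labels (subtopic names or indices), length `nrow(features)`.
#' @param cfg A [finetune_config()].
#' @param dbn Optional `dbn_model`; when given, its squared stack weights
#'   enter the reported cost as the constant penalty term.
#' @param classes Optional fixed class ordering.
#' @return List with `W` (head weights), `classes`, `trace` (cost trace,
#'   non-increasing), `cost`.
#' @export
finetune <- function(features, labels, cfg = finetune_config(), dbn = NULL,
                     classes = NULL) {
  if (length(labels) != nrow(features)) abort("one label per feature row required.")
  if (length(labels) == 0L) abort("labeled subset is empty.")
  if (is.null(classes)) classes <- sort(unique(as.character(labels)))
  stack_penalty <- 0
  if (!is.null(dbn)) {
    stack_penalty <- (cfg$lambda / 2) *
      sum(vapply(dbn$layers, function(l) sum(l$W^2), numeric(1)))
  }
  fit <- fit_softmax(as.matrix(features), as.character(labels),
                     classes = classes, lambda = cfg$lambda,
                     method = if (cfg$optimizer == "lbfgs") "lbfgs" else "gd",
                     maxit = cfg$maxit, tol = cfg$tol, memory = cfg$memory)
  list(W = fit$W, classes = classes, intercept = fit$intercept,
       trace = fit$trace + stack_penalty, cost = fit$cost + stack_penalty)
}

#' Discover subtopics by clustering DBN features
#'
#' Seeded k-means partition of the feature vectors into K clusters; each
#' cluster is labeled by its highest-lift token (cluster frequency over
#' corpus frequency) when token counts are supplied. The resulting
#' pseudo-labels are the "partial labeled data" that [finetune()] consumes.
#'
#' @param features Feature matrix (messages x d).
#' @param K Number of subtopics (>= 2, at most the number of distinct rows).
#' @param counts Optional token-count matrix (messages x vocabulary) used
#'   for cluster labeling.
#' @param seed Seed; the partition is identical across runs given it.
#' @param n_label_tokens Tokens listed per cluster label.
#' @return List with `assignments` (tibble: row, cluster, subtopic) and
#'   `clusters` (tibble: cluster, subtopic, size, top_tokens list-column).
#' @export
discover_subtopics <- function(features, K, counts = NULL, seed = 1,
                               n_label_tokens = 5) {
  features <- as.matrix(features)
  if (K < 2) abort("K must be at least 2.")
  if (K > nrow(features)) abort("K exceeds the number of messages.")
  uniq <- unique(features)
  if (K > nrow(uniq)) abort("K exceeds the number of distinct feature vectors.")
  km <- withr::with_seed(derive_seed(seed, 1L), {
    if (K == nrow(uniq)) kmeans(features, centers = uniq)
    else kmeans(features, centers = K, nstart = 5, iter.max = 50)
  })
  cluster <- km$cluster

  labels <- sprintf("sub%02d", seq_len(K))
  top_tokens <- rep(list(character(0)), K)
  if (!is.null(counts)) {
    counts <- as.matrix(counts)
    overall <- colSums(counts) / sum(counts)
    for (k in seq_len(K)) {
      ck <- colSums(counts[cluster == k, , drop = FALSE])
      if (sum(ck) == 0) next
      lift <- (ck / sum(ck)) / pmax(overall, 1e-12)
      ord <- order(-lift, colnames(counts))
      top_tokens[[k]] <- colnames(counts)[head(ord, n_label_tokens)]
      labels[k] <- top_tokens[[k]][1]
    }
  }
  list(
    assignments = tibble(row = seq_along(cluster), cluster = cluster,
                         subtopic = labels[cluster]),
    clusters = tibble(cluster = seq_len(K), subtopic = labels,
                      size = as.integer(table(factor(cluster, seq_len(K)))),
                      top_tokens = top_tokens)
  )
}

#' Rank a topic's subtopics by message share
#'
#' Percentage of the topic's messages per subtopic, descending; report
#' percentages are rounded to two decimals and sum to 100 up to rounding.
#'
#' @param assignments Tibble with columns `topic` and `subtopic` (one row
#'   per message).
#' @param topic Topic to rank within.
#' @return Tibble (topic, subtopic, pct) classed `subtopic_ranking`.
#' @export
rank_subtopics <- function(assignments, topic) {
  rows <- assignments[assignments$topic == topic, , drop = FALSE]
  if (nrow(rows) == 0L) abort(sprintf("no messages for topic '%s'.", topic))
  tab <- sort(table(rows$subtopic), decreasing = TRUE)
  out <- tibble(topic = topic, subtopic = names(tab),
                pct = round(100 * as.numeric(tab) / nrow(rows), 2))
  structure(out, class = c("subtopic_ranking", class(out)))
}

#' Save and load a subtopic model bundle
#'
#' A directory with per-layer weight matrices as TSV, the head weights, and
#' a JSON manifest (layer sizes, class list, penalty, seed).
#'
#' @param dbn A `dbn_model`.
#' @param head A fine-tuned head as returned by [finetune()].
#' @param dir Bundle directory (created if needed).
#' @param meta Extra manifest entries (named list).
#' @export
write_subtopic_bundle <- function(dbn, head, dir, meta = list()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (p in seq_along(dbn$layers)) {
    l <- dbn$layers[[p]]
    readr::write_tsv(as.data.frame(l$W), file.path(dir, sprintf("layer%d_W.tsv", p)),
                     col_names = FALSE)
    readr::write_tsv(data.frame(vbias = l$vbias),
                     file.path(dir, sprintf("layer%d_vbias.tsv", p)), col_names = FALSE)
    readr::write_tsv(data.frame(hbias = l$hbias),
                     file.path(dir, sprintf("layer%d_hbias.tsv", p)), col_names = FALSE)
  }
  readr::write_tsv(as.data.frame(head$W), file.path(dir, "head_W.tsv"),
                   col_names = FALSE)
  manifest <- c(list(input_width = dbn$input_width, hidden = dbn$hidden,
                     classes = head$classes,
                     intercept = isTRUE(head$intercept)), meta)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_subtopic_bundle
#' @export
read_subtopic_bundle <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  layers <- lapply(seq_along(manifest$hidden), function(p) {
    W <- as.matrix(readr::read_tsv(file.path(dir, sprintf("layer%d_W.tsv", p)),
                                   col_names = FALSE, col_types = readr::cols(),
                                   progress = FALSE))
    dimnames(W) <- NULL
    structure(list(
      W = W,
      vbias = readr::read_tsv(file.path(dir, sprintf("layer%d_vbias.tsv", p)),
                              col_names = FALSE, col_types = "d", progress = FALSE)[[1]],
      hbias = readr::read_tsv(file.path(dir, sprintf("layer%d_hbias.tsv", p)),
                              col_names = FALSE, col_types = "d", progress = FALSE)[[1]],
      recon_error = NULL), class = "rbm_layer")
  })
  W <- as.matrix(readr::read_tsv(file.path(dir, "head_W.tsv"),
                                 col_names = FALSE, col_types = readr::cols(),
                                 progress = FALSE))
  dimnames(W) <- list(manifest$classes, NULL)
  list(dbn = structure(list(layers = layers, input_width = manifest$input_width,
                            hidden = manifest$hidden), class = "dbn_model"),
       head = list(W = W, classes = manifest$classes,
                   intercept = isTRUE(manifest$intercept)),
       manifest = manifest)
}
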