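#' Build a training vocabulary
#'
#' Tokens appearing at least `min_count` times, capped at `max_size` by
#' descending frequency (ties broken alphabetically for determinism).
#'
#' @param token_lists List of character vectors (one per message).
#' @param min_count Minimum corpus frequency.
#' @param max_size Vocabulary cap (kept consistent with the DBN input width).
#' @return Character vector of vocabulary tokens.
#' @export
build_vocabulary <- function(token_lists, min_count = 5, max_size = 2000) {
  counts <- table(unlist(token_lists))
  counts <- counts[counts >= min_count]
  counts <- counts[order(-as.numeric(counts), names(counts))]
  head(names(counts), max_size)
}

#' Vectorize token bags over a fixed vocabulary
#'
#' Token counts as a sparse document-term matrix; out-of-vocabulary tokens
#' contribute nothing.
#'
#' @param token_lists List of character vectors, or a single character
#'   vector (treated as one message).
#' @param vocabulary Fixed vocabulary from training time.
#' @return A sparse `dgCMatrix` (messages x vocabulary).
#' @export
vectorize <- function(token_lists, vocabulary) {
  if (!length(vocabulary)) abort("configuration error: empty vocabulary.")
  if (is.character(token_lists)) token_lists <- list(token_lists)
  n <- length(token_lists)
  doc <- rep(seq_len(n), lengths(token_lists))
  j <- match(unlist(token_lists), vocabulary)
  keep <- !is.na(j)
  # repeated (i, j) triplets sum on conversion, giving token counts
  Matrix::sparseMatrix(i = doc[keep], j = j[keep], x = 1,
                       dims = c(n, length(vocabulary)),
                       dimnames = list(NULL, vocabulary))
}

#' Train the ten-class topic classifier
#'
#' Multinomial logistic (softmax) regression minimizing L2-penalized
#' cross-entropy by L-BFGS, with seeded k-fold cross-validation for the
#' performance report and an optional 80/20 holdout evaluation.
#'
#' @param clean Tibble with `tokens` (list-column) and `topic` labels, e.g.
#'   [preprocess_messages()] output joined with labels.
#' @param folds Number of CV folds (default 10).
#' @param lambda L2 penalty strength.
#' @param min_count,max_size Vocabulary construction parameters.
#' @param holdout Fraction held out for a final train/test report (0 skips).
#' @param seed Seed for fold assignment and the holdout split.
#' @return An object of class `topic_model` with the weight matrix,
#'   vocabulary, class list, `cv` fold report, and optional `holdout` report.
#' @export
train_topic_classifier <- function(clean, folds = 10, lambda = 1,
                                   min_count = 5, max_size = 2000,
                                   holdout = 0, seed = 1) {
  classes <- sort(unique(clean$topic))
  if (length(classes) < 2) {
    abort("degenerate training set: need messages from at least 2 topics.")
  }
  vocab <- build_vocabulary(clean$tokens, min_count = min_count,
                            max_size = max_size)
  X <- vectorize(clean$tokens, vocab)
  y <- clean$topic
  n <- nrow(X)

  cv <- NULL
  if (folds > 1) {
    fold_id <- withr::with_seed(derive_seed(seed, 1L),
                                sample(rep(seq_len(folds), length.out = n)))
    if (any(tabulate(fold_id, folds) == 0)) abort("every CV fold must be non-empty.")
    cv <- bind_rows(lapply(seq_len(folds), function(f) {
      tr <- fold_id != f
      fit_f <- fit_softmax(X[tr, , drop = FALSE], y[tr], classes = classes,
                           lambda = lambda)
      pred <- softmax_predict(fit_f, X[!tr, , drop = FALSE])
      mm <- multiclass_metrics(y[!tr], pred, classes = classes)
      tibble(fold = f, accuracy = mean(pred == y[!tr]),
             macro_f = mm$macro$f_measure, macro_gmean = mm$macro$g_mean)
    }))
  }

  ho <- NULL
  train_idx <- seq_len(n)
  if (holdout > 0) {
    test_idx <- withr::with_seed(derive_seed(seed, 2L),
                                 sample.int(n, round(holdout * n)))
    train_idx <- setdiff(seq_len(n), test_idx)
    fit_h <- fit_softmax(X[train_idx, , drop = FALSE], y[train_idx],
                         classes = classes, lambda = lambda)
    pred <- softmax_predict(fit_h, X[test_idx, , drop = FALSE])
    ho <- list(accuracy = mean(pred == y[test_idx]), n_test = length(test_idx))
  }

  fit <- fit_softmax(X, y, classes = classes, lambda = lambda)
  structure(
    list(W = fit$W, classes = classes, vocabulary = vocab, lambda = lambda,
         intercept = fit$intercept, cost = fit$cost, cv = cv, holdout = ho,
         n_train = n, seed = seed),
    class = "topic_model"
  )
}

#' Predict topic probabilities
#'
#' Class probabilities proportional to `exp(sum_i w_xi t_i)`, normalized over
#' the model's classes.
#'
#' @param model A `topic_model`.
#' @param clean Tibble with `id` and `tokens` list-column, a bare list of
#'   token vectors, or a feature matrix over the model vocabulary.
#' @return Tibble with `id`, `.topic` (argmax class), and one probability
#'   column per class.
#' @export
predict_topic <- function(model, clean) {
  stopifnot(inherits(model, "topic_model"))
  if (is.data.frame(clean)) {
    X <- vectorize(clean$tokens, model$vocabulary)
    ids <- clean$id
  } else if (is.list(clean) && !is.matrix(clean)) {
    X <- vectorize(clean, model$vocabulary)
    ids <- sprintf("m%d", seq_len(nrow(X)))
  } else {
    X <- clean
    ids <- sprintf("m%d", seq_len(nrow(X)))
  }
  if (isTRUE(model$intercept)) X <- cbind(X, rep(1, nrow(X)))
  if (ncol(X) != ncol(model$W)) abort("feature dimension mismatch.")
  P <- softmax_probs(model$W, X)
  out <- as_tibble(as.data.frame(P))
  names(out) <- model$classes
  bind_cols(tibble(id = ids,
                   .topic = model$classes[max.col(P, ties.method = "first")]),
            out)
}

#' Topic prevalence report
#'
#' Percentage of messages per topic over all predictions; topics under
#' `min_pct` are dropped from the report but still count in the denominator.
#'
#' @param predictions Tibble with a `.topic` column (or a character vector).
#' @param min_pct Reporting floor in percent (default 2).
#' @return Tibble (topic, pct) sorted by descending prevalence, classed
#'   `osn_topic_prevalence`.
#' @export
topic_prevalence <- function(predictions, min_pct = 2) {
  topics <- if (is.data.frame(predictions)) predictions$.topic else predictions
  if (!length(topics)) abort("empty input: no predictions to summarize.")
  tab <- sort(table(topics), decreasing = TRUE)
  out <- tibble(topic = names(tab),
                pct = 100 * as.numeric(tab) / length(topics))
  structure(filter(out, .data$pct >= min_pct), class = c("osn_topic_prevalence",
                                                         class(out)))
}

#' Serialize a topic model to JSON
#'
#' Stores vocabulary, class names, and the dense weight matrix.
#'
#' @param model A `topic_model`.
#' @param path File path.
#' @export
write_topic_model <- function(model, path) {
  jsonlite::write_json(
    list(classes = model$classes, vocabulary = model$vocabulary,
         lambda = model$lambda, intercept = isTRUE(model$intercept),
         weights = unname(as.matrix(model$W))),
    path, digits = NA
  )
  invisible(path)
}

#' @rdname write_topic_model
#' @export
read_topic_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  W <- matrix(obj$weights, nrow = length(obj$classes))
  structure(list(W = W, classes = obj$classes, vocabulary = obj$vocabulary,
                 lambda = obj$lambda, intercept = isTRUE(obj$intercept),
                 cv = NULL, holdout = NULL),
            class = "topic_model")
}

#' @export
print.topic_model <- function(x, ...) {
  cat("<topic_model>", length(x$classes), "classes,",
      length(x$vocabulary), "features\n")
  if (!is.null(x$cv)) cat("  CV accuracy:", round(mean(x$cv$accuracy), 4), "\n")
  invisible(x)
}
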