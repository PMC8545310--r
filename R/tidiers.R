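#' Tidy a topic model
#'
#' One row per (class, feature) weight.
#'
#' @param x A `topic_model`.
#' @param ... Ignored.
#' @return Tibble (class, term, weight).
#' @export
tidy.topic_model <- function(x, ...) {
  tidyr::pivot_longer(
    bind_cols(tibble(class = x$classes), as_tibble(as.data.frame(x$W))),
    -"class", names_to = "term", values_to = "weight"
  )
}

#' One-row topic model summary
#'
#' @param x A `topic_model`.
#' @param ... Ignored.
#' @return Tibble with class/feature counts, final cost, and mean CV and
#'   holdout accuracies when available.
#' @export
glance.topic_model <- function(x, ...) {
  tibble(
    n_classes = length(x$classes),
    n_features = length(x$vocabulary),
    lambda = x$lambda,
    cost = x$cost %||% NA_real_,
    cv_accuracy = if (!is.null(x$cv)) mean(x$cv$accuracy) else NA_real_,
    holdout_accuracy = if (!is.null(x$holdout)) x$holdout$accuracy else NA_real_
  )
}

#' Tidy an affect model
#'
#' One row per tree node with its depth and (for group nodes) emotions.
#'
#' @param x An `affect_model`.
#' @param ... Ignored.
#' @return Tibble (node, depth, emotions list-column).
#' @export
tidy.affect_model <- function(x, ...) {
  bind_rows(
    tibble(node = "root", depth = 0L, emotions = list(x$emotions)),
    bind_rows(lapply(names(x$groups), function(g) {
      tibble(node = g, depth = 1L, emotions = list(x$groups[[g]]))
    }))
  )
}

#' One-row affect model summary
#'
#' @param x An `affect_model`.
#' @param ... Ignored.
#' @return Tibble with emotion count, vocabulary size, and final losses.
#' @export
glance.affect_model <- function(x, ...) {
  tibble(
    n_emotions = length(x$emotions),
    n_features = length(x$vocabulary),
    filter_width = x$cfg$filter_width,
    final_loss = sum(vapply(x$losses, function(l) l[length(l)], numeric(1)))
  )
}

#' Tidy a grown tree
#'
#' One row per node of an `affect_tree` built by [build_tree()].
#'
#' @param x An `affect_tree`.
#' @param ... Ignored.
#' @return The node tibble (id, parent, depth, label, n_words).
#' @export
tidy.affect_tree <- function(x, ...) {
  mutate(x$nodes, n_words = lengths(.data$words)) |>
    select("id", "parent", "depth", "label", "n_words")
}

#' One-row tree summary
#'
#' @param x An `affect_tree`.
#' @param ... Ignored.
#' @return Tibble with node count, max depth, max observed children.
#' @export
glance.affect_tree <- function(x, ...) {
  a <- audit_tree(x)
  tibble(n_nodes = nrow(x$nodes), max_depth = a$max_depth,
         max_children = a$max_children_observed, within_limits = a$ok)
}
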