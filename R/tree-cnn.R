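#' Tree classifier configuration
#'
#' Growth thresholds and training hyper-parameters for the hierarchical
#' affect classifier.
#'
#' @param alpha,beta Softmax-gap thresholds governing growth (default 0.1).
#' @param max_depth Maximum node depth, root at depth 0 (default 3).
#' @param max_children Maximum children per branch node (5, 10, or 20).
#' @param epochs,lr,momentum,weight_decay,batch_size Mini-batch SGD settings
#'   for the node classifiers (defaults: 300 epochs, learning rate 0.1,
#'   momentum 0.9, weight decay 0.001, batch size 32).
#' @param filter_width Token-window width of the node scorers: 1 scores the
#'   bag of tokens; 3 adds consecutive-token window features.
#' @param surprise_positive Polarity of "surprise" (default positive).
#' @return A list of class `tree_cnn_config`.
#' @export
tree_cnn_config <- function(alpha = 0.1, beta = 0.1, max_depth = 3,
                            max_children = 5, epochs = 300, lr = 0.1,
                            momentum = 0.9, weight_decay = 0.001,
                            batch_size = 32, filter_width = 1,
                            surprise_positive = TRUE) {
  if (alpha <= 0 || beta <= 0) abort("`alpha` and `beta` must be positive.")
  structure(list(alpha = alpha, beta = beta, max_depth = as.integer(max_depth),
                 max_children = as.integer(max_children), epochs = epochs,
                 lr = lr, momentum = momentum, weight_decay = weight_decay,
                 batch_size = batch_size, filter_width = filter_width,
                 surprise_positive = surprise_positive),
            class = "tree_cnn_config")
}

#' Growth decision from the top-3 softmax outputs
#'
#' Given the sorted top-3 softmax outputs `o1 >= o2 >= o3` at a node:
#' a full node always grows horizontally (`new_child`); otherwise
#' `add_to_child` when `o1 - o2 > alpha` (strong association with one
#' child); `merge_children` when `o1 - o2 < alpha` and `o2 - o3 > beta`
#' (two children compete); `new_child` when both gaps are small. Boundary
#' equalities resolve to `new_child`, the most conservative structural
#' action.
#'
#' @param o Numeric vector of the top-3 softmax outputs, sorted descending
#'   (pad with zeros when a node has fewer than 3 children).
#' @param alpha,beta Thresholds.
#' @param node_full Whether the node is at its child-capacity limit.
#' @return A list with `action` and `o`, classed `growth_decision`.
#' @export
grow_decision <- function(o, alpha = 0.1, beta = 0.1, node_full = FALSE) {
  o <- c(o, 0, 0, 0)[1:3]
  if (any(diff(o) > 1e-12)) {
    abort("softmax outputs must be sorted in descending order.")
  }
  if (sum(o) > 1 + 1e-9) abort("top-3 softmax outputs cannot exceed 1.")
  action <- if (node_full) {
    "new_child"
  } else if (o[1] - o[2] > alpha) {
    "add_to_child"
  } else if (o[1] - o[2] < alpha && o[2] - o[3] > beta) {
    "merge_children"
  } else {
    "new_child"
  }
  structure(list(action = action, o = o), class = "growth_decision")
}

# Children of a node, during construction (environment) or after
# finalization (tibble-backed affect_tree).
tree_children <- function(tree, id) {
  if (is.environment(tree)) return(tb_children(tree, id))
  tree$nodes$id[which(tree$nodes$parent == id)]
}

#' Grow a word-routing tree from a training stream
#'
#' Words are routed through [grow_decision()] at the root: a strong
#' association adds the word to the best child, competing children merge
#' into a new branch node (when depth allows), and otherwise the tree grows
#' horizontally with a new child. A full node first tries to merge its two
#' highest-likelihood children to free a slot; if the depth limit forbids
#' that, the word falls back into the best existing child (logged as
#' `capacity_fallback`) unless `strict = TRUE`, in which case a capacity
#' error names the offending word. Every decision is recorded in the
#' construction log, and the structural invariants (depth, capacity) hold
#' after every insertion.
#'
#' @param words Character vector, inserted in order.
#' @param cfg A [tree_cnn_config()].
#' @param output_fn `function(tree, node_id, word)` returning unsorted
#'   softmax outputs over the node's children; the default returns a uniform
#'   distribution (no trained classifiers yet).
#' @param strict Raise a capacity error instead of falling back.
#' @return An `affect_tree` with `nodes` and `log` tibbles.
#' @export
build_tree <- function(words, cfg = tree_cnn_config(), output_fn = NULL,
                       strict = FALSE) {
  if (!length(words)) abort("empty training stream.")
  if (is.null(output_fn)) {
    output_fn <- function(tree, node, word) {
      k <- length(tree_children(tree, node))
      rep(1 / max(k, 1), k)
    }
  }
  e <- tb_new(cfg)
  add_word_to <- function(id, w) {
    i <- match(id, e$id)
    e$words[[i]] <- c(e$words[[i]], w)
  }
  for (s in seq_along(words)) {
    w <- words[s]
    kids <- tb_children(e, 1L)
    if (!length(kids)) {
      tb_add_leaf(e, 1L, w)
      tb_log(e, s, w, 1L, "new_child")
      next
    }
    o_raw <- output_fn(e, 1L, w)
    ord <- order(o_raw, decreasing = TRUE)
    o <- sort(o_raw, decreasing = TRUE)
    full <- length(kids) >= cfg$max_children
    action <- grow_decision(o, cfg$alpha, cfg$beta, node_full = full)$action
    if (action == "add_to_child") {
      add_word_to(kids[ord[1]], w)
    } else if (action == "merge_children") {
      a <- kids[ord[1]]; b <- kids[ord[2]]
      if (tb_subtree_depth(e, c(a, b)) + 1L <= cfg$max_depth) {
        nid <- tb_merge(e, 1L, a, b)
        add_word_to(nid, w)
      } else {
        action <- "new_child"
      }
    }
    if (action == "new_child") {
      if (!full) {
        tb_add_leaf(e, 1L, w)
      } else if (tb_can_merge(e, 1L, kids[ord[1:2]])) {
        tb_merge(e, 1L, kids[ord[1]], kids[ord[2]])
        tb_add_leaf(e, 1L, w)
      } else if (strict) {
        abort(sprintf("capacity exhausted at word '%s': depth and children limits reached.", w))
      } else {
        action <- "capacity_fallback"
        add_word_to(kids[ord[1]], w)
      }
    }
    tb_log(e, s, w, 1L, action)
  }
  tb_finalize(e)
}

#' Audit a tree's structural invariants
#'
#' Checks that every node respects the depth limit and every branch the
#' child-capacity limit.
#'
#' @param tree An `affect_tree`.
#' @return A list with `ok`, `max_depth`, `max_children_observed`.
#' @export
audit_tree <- function(tree) {
  cfg <- tree$cfg
  kid_counts <- vapply(tree$nodes$id,
                       function(id) length(tree_children(tree, id)), integer(1))
  list(ok = all(tree$nodes$depth <= cfg$max_depth) &&
         all(kid_counts <= cfg$max_children),
       max_depth = max(tree$nodes$depth),
       max_children_observed = max(kid_counts))
}

#' Polarity mapping for the six emotions
#'
#' joy and (configurably) surprise are positive; anger, disgust, fear and
#' sadness are negative.
#'
#' @param surprise_positive Whether surprise maps to positive.
#' @return Named character vector emotion -> polarity.
#' @export
emotion_polarity <- function(surprise_positive = TRUE) {
  c(anger = "negative", disgust = "negative", fear = "negative",
    joy = "positive", sadness = "negative",
    surprise = if (surprise_positive) "positive" else "negative")
}

affect_features <- function(token_lists, vocabulary, filter_width = 1) {
  X <- as.matrix(vectorize(token_lists, vocabulary))
  if (filter_width > 1) {
    windows <- lapply(token_lists, function(tk) {
      if (length(tk) < filter_width) return(character(0))
      vapply(seq_len(length(tk) - filter_width + 1L), function(i) {
        paste(tk[i:(i + filter_width - 1L)], collapse = "_")
      }, character(1))
    })
    # hashed window features keep the width-3 scorer's dimension bounded
    n_buckets <- 256L
    H <- matrix(0, length(token_lists), n_buckets)
    for (i in seq_along(windows)) {
      if (!length(windows[[i]])) next
      h <- (vapply(windows[[i]], function(s) {
        sum(utf8ToInt(s) * seq_len(nchar(s))) %% n_buckets
      }, numeric(1))) + 1L
      tb <- table(h)
      H[i, as.integer(names(tb))] <- as.numeric(tb)
    }
    colnames(H) <- sprintf("w%d_bucket%03d", filter_width, seq_len(n_buckets))
    X <- cbind(X, H)
  }
  X
}

#' Train the hierarchical affect classifier
#'
#' Builds a two-level tree (root separates the polarity groups; each group
#' node's children are the emotions present in its group) and trains one
#' softmax scorer per internal node by mini-batch SGD with momentum and
#' weight decay, recording per-epoch loss.
#'
#' @param clean Tibble with `tokens` (list-column) and `emotion` labels.
#' @param cfg A [tree_cnn_config()].
#' @param seed Seed for SGD shuffling; the final loss is reproducible.
#' @return An `affect_model` with the tree, vocabulary, node classifiers,
#'   polarity map, and loss traces.
#' @export
train_affect <- function(clean, cfg = tree_cnn_config(), seed = 1) {
  emotions <- sort(unique(clean$emotion))
  if (length(emotions) < 2) {
    abort("degenerate training set: need at least 2 emotions.")
  }
  polarity <- emotion_polarity(cfg$surprise_positive)
  groups <- split(emotions, polarity[emotions])
  vocab <- build_vocabulary(clean$tokens, min_count = 1, max_size = 5000)
  X <- affect_features(clean$tokens, vocab, cfg$filter_width)

  classifiers <- list()
  losses <- list()
  y_group <- unname(polarity[clean$emotion])
  if (length(groups) > 1) {
    fit_root <- sgd_softmax(X, y_group, classes = names(groups),
                            epochs = cfg$epochs, lr = cfg$lr,
                            momentum = cfg$momentum,
                            weight_decay = cfg$weight_decay,
                            batch_size = cfg$batch_size,
                            seed = derive_seed(seed, 1L))
    classifiers$root <- fit_root$W
    losses$root <- fit_root$loss
  }
  for (g in names(groups)) {
    emos <- groups[[g]]
    rows <- which(y_group == g)
    if (length(emos) < 2) {
      classifiers[[g]] <- emos  # single-emotion group: trivial assignment
      next
    }
    fit_g <- sgd_softmax(X[rows, , drop = FALSE], clean$emotion[rows],
                         classes = emos, epochs = cfg$epochs, lr = cfg$lr,
                         momentum = cfg$momentum,
                         weight_decay = cfg$weight_decay,
                         batch_size = cfg$batch_size,
                         seed = derive_seed(seed, 2L + match(g, names(groups))))
    classifiers[[g]] <- fit_g$W
    losses[[g]] <- fit_g$loss
  }
  structure(list(cfg = cfg, vocabulary = vocab, groups = groups,
                 classifiers = classifiers, losses = losses,
                 polarity = polarity, emotions = emotions, seed = seed),
            class = "affect_model")
}

#' Classify the emotion of one message
#'
#' Routes the token bag root-to-leaf through the node classifiers and maps
#' the winning emotion to its polarity.
#'
#' @param model An `affect_model` from [train_affect()].
#' @param tokens Character vector of tokens.
#' @return A list with `emotion` and `polarity`.
#' @export
classify_emotion <- function(model, tokens) {
  if (!length(tokens)) abort("unclassifiable: the message has no tokens.")
  x <- affect_features(list(tokens), model$vocabulary, model$cfg$filter_width)
  group <- if (length(model$groups) > 1) {
    p <- softmax_probs(model$classifiers$root, x)
    names(model$groups)[which.max(p)]
  } else names(model$groups)
  clf <- model$classifiers[[group]]
  emotion <- if (is.character(clf)) clf else {
    p <- softmax_probs(clf, x)
    rownames(clf)[which.max(p)]
  }
  list(emotion = emotion, polarity = unname(model$polarity[emotion]))
}

#' Classify emotions for a message table
#'
#' @param model An `affect_model`.
#' @param clean Tibble with `id` and `tokens` list-column; token-less
#'   messages get `NA` rather than an error.
#' @return Tibble (id, emotion, polarity).
#' @export
predict_affect <- function(model, clean) {
  emotion <- rep(NA_character_, nrow(clean))
  nonempty <- lengths(clean$tokens) > 0
  if (any(nonempty)) {
    X <- affect_features(clean$tokens[nonempty], model$vocabulary,
                         model$cfg$filter_width)
    group <- if (length(model$groups) > 1) {
      P <- softmax_probs(model$classifiers$root, X)
      names(model$groups)[max.col(P, ties.method = "first")]
    } else rep(names(model$groups), nrow(X))
    emo <- character(nrow(X))
    for (g in unique(group)) {
      rows <- which(group == g)
      clf <- model$classifiers[[g]]
      emo[rows] <- if (is.character(clf)) clf else {
        Pg <- softmax_probs(clf, X[rows, , drop = FALSE])
        rownames(clf)[max.col(Pg, ties.method = "first")]
      }
    }
    emotion[nonempty] <- emo
  }
  tibble(id = clean$id, emotion = emotion,
         polarity = unname(model$polarity[emotion]))
}
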