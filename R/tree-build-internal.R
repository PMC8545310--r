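# Internal mutable tree representation used during construction: plain
# parallel vectors inside an environment, converted to tibbles at the end.
# Keeps 1,000-insertion builds linear instead of quadratic.

tb_new <- function(cfg) {
  e <- new.env(parent = emptyenv())
  e$id <- 1L; e$parent <- NA_integer_; e$depth <- 0L; e$label <- "root"
  e$words <- list(character(0))
  e$cfg <- cfg
  e$log_step <- integer(0); e$log_word <- character(0)
  e$log_node <- integer(0); e$log_action <- character(0)
  e$log_depth <- integer(0)
  e
}

tb_children <- function(e, id) e$id[!is.na(e$parent) & e$parent == id]

tb_add_leaf <- function(e, parent, word) {
  nid <- max(e$id) + 1L
  e$id <- c(e$id, nid)
  e$parent <- c(e$parent, parent)
  e$depth <- c(e$depth, e$depth[match(parent, e$id)] + 1L)
  e$label <- c(e$label, word)
  e$words <- c(e$words, list(word))
  nid
}

tb_subtree_ids <- function(e, roots) {
  ids <- roots
  repeat {
    kids <- e$id[!is.na(e$parent) & e$parent %in% ids & !e$id %in% ids]
    if (!length(kids)) break
    ids <- c(ids, kids)
  }
  ids
}

tb_subtree_depth <- function(e, roots) {
  max(e$depth[e$id %in% tb_subtree_ids(e, roots)])
}

tb_merge <- function(e, parent, a, b) {
  nid <- max(e$id) + 1L
  e$id <- c(e$id, nid)
  e$parent <- c(e$parent, parent)
  e$depth <- c(e$depth, e$depth[match(parent, e$id)] + 1L)
  e$label <- c(e$label, paste(e$label[match(a, e$id)], e$label[match(b, e$id)],
                              sep = "+"))
  e$words <- c(e$words, list(character(0)))
  e$parent[e$id %in% c(a, b)] <- nid
  for (sid in tb_subtree_ids(e, c(a, b))) {
    e$depth[match(sid, e$id)] <-
      e$depth[match(e$parent[match(sid, e$id)], e$id)] + 1L
  }
  nid
}

tb_can_merge <- function(e, node, kids) {
  if (length(kids) < 2) return(FALSE)
  tb_subtree_depth(e, kids[1:2]) + 1L <= e$cfg$max_depth
}

tb_log <- function(e, step, word, node, action) {
  e$log_step <- c(e$log_step, step)
  e$log_word <- c(e$log_word, word)
  e$log_node <- c(e$log_node, node)
  e$log_action <- c(e$log_action, action)
  e$log_depth <- c(e$log_depth, max(e$depth))
}

tb_finalize <- function(e) {
  structure(list(
    nodes = tibble(id = e$id, parent = e$parent, depth = e$depth,
                   label = e$label, words = e$words),
    cfg = e$cfg,
    log = tibble(step = e$log_step, word = e$log_word, node = e$log_node,
                 action = e$log_action, depth = e$log_depth)
  ), class = "affect_tree")
}
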