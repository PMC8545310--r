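# Shared fixtures: small stream specs and hand-built message tables.

two_topic_spec <- function(seed = 1, users = 50, base_rate = 6, n_days = 20,
                           events = list(), regions = c("A", "B")) {
  topics <- c("health", "work")
  stream_spec(regions = regions, users_per_region = users, topics = topics,
              vocab = default_vocab(topics), base_rate = base_rate,
              n_days = n_days, events = events, seed = seed)
}

# Messages with known timestamps/text for preprocessing and counting tests.
fixture_messages <- function(texts, users = "u1", times = NULL, hashtags = NULL) {
  n <- length(texts)
  if (is.null(times)) {
    times <- as.POSIXct("2020-01-01 12:00:00", tz = "UTC") + seq_len(n) * 60
  }
  tibble::tibble(
    id = sprintf("f%03d", seq_len(n)),
    text = texts,
    username = rep_len(users, n),
    created_at = times,
    hashtags = if (is.null(hashtags)) rep(list(character(0)), n) else hashtags
  )
}

# Independent softmax oracle: direct transcription of the normalized
# exponential, no shared code with the implementation.
oracle_softmax <- function(W, x) {
  scores <- apply(W, 1, function(w) sum(w * x))
  e <- exp(scores)
  e / sum(e)
}

# Independent growth-rule oracle used by the simplex sweep.
oracle_grow <- function(o1, o2, o3, alpha, beta, full) {
  if (full) return("new_child")
  if (o1 - o2 > alpha) return("add_to_child")
  if (o1 - o2 < alpha && o2 - o3 > beta) return("merge_children")
  if (o1 - o2 < alpha && o2 - o3 < beta) return("new_child")
  NA_character_  # boundary
}

# A deterministic daily-count series builder.
series_tbl <- function(counts, region = "R", topic = "health",
                       start = as.Date("2020-01-01")) {
  tibble::tibble(region = region, topic = topic,
                 date = start + seq_along(counts) - 1, count = counts)
}
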