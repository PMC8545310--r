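#' Generate synthetic users and community accounts
#'
#' Draws one community gazetteer and one user table from a [stream_spec()].
#' Each user gets a home region, a declared-location flag, a follow type
#' (Unique/Low/Moderate/High/Extreme) drawn from the spec's follow-type
#' distribution, and a list of followed community accounts. Each followed
#' community lies in the user's home region with probability
#' `p_home_community`, else in a uniformly random other region. Deterministic
#' given `spec$seed`.
#'
#' @param spec A [stream_spec()].
#' @return A list with tibbles `users` (user_id, region, declared,
#'   declared_region, user_type, n_follows, communities list-column) and
#'   `gazetteer` (name, category, lat, lon, region).
#' @export
generate_users <- function(spec) {
  stopifnot(inherits(spec, "stream_spec"))
  withr::with_seed(derive_seed(spec$seed, 1L), {
    gaz <- make_gazetteer(spec)
    n_regions <- length(spec$regions)
    n <- n_regions * spec$users_per_region
    home <- rep(spec$regions, each = spec$users_per_region)
    declared <- runif(n) < spec$p_declared
    type_levels <- c("Unique", "Low", "Moderate", "High", "Extreme")
    user_type <- sample(type_levels, n, replace = TRUE,
                        prob = spec$follow_distribution[type_levels])
    n_follows <- integer(n)
    n_follows[user_type == "Unique"] <- 1L
    n_follows[user_type == "Low"] <- 2L
    n_follows[user_type == "Moderate"] <-
      sample(3:9, sum(user_type == "Moderate"), replace = TRUE)
    n_follows[user_type == "High"] <-
      sample(10:49, sum(user_type == "High"), replace = TRUE)
    n_follows[user_type == "Extreme"] <-
      sample(50:80, sum(user_type == "Extreme"), replace = TRUE)

    # One Bernoulli draw per follow edge decides home vs external region.
    n_edges <- sum(n_follows)
    edge_user <- rep(seq_len(n), n_follows)
    is_home <- runif(n_edges) < spec$p_home_community
    if (n_regions == 1L) is_home[] <- TRUE
    edge_region <- rep(home[edge_user], length.out = n_edges)
    ext <- which(!is_home)
    if (length(ext)) {
      # uniform draw over the other regions
      others <- vapply(ext, function(i) {
        pool <- setdiff(spec$regions, home[edge_user[i]])
        pool[sample.int(length(pool), 1L)]
      }, character(1))
      edge_region[ext] <- others
    }
    comm_idx <- sample.int(spec$communities_per_region, n_edges, replace = TRUE)
    edge_comm <- community_name(edge_region, comm_idx)
    communities <- unname(split(edge_comm, factor(edge_user, levels = seq_len(n))))

    users <- tibble(
      user_id = sprintf("user%05d", seq_len(n)),
      region = home,
      declared = declared,
      declared_region = ifelse(declared, home, NA_character_),
      user_type = user_type,
      n_follows = n_follows,
      communities = communities
    )
    list(users = users, gazetteer = gaz)
  })
}

community_name <- function(region, idx) {
  sprintf("%s_comm_%02d", gsub("[^a-z0-9]+", "_", tolower(region)), idx)
}

make_gazetteer <- function(spec) {
  n_regions <- length(spec$regions)
  centers_lat <- runif(n_regions, -55, 55)
  centers_lon <- runif(n_regions, -175, 175)
  k <- spec$communities_per_region
  tibble(
    name = community_name(rep(spec$regions, each = k), rep(seq_len(k), n_regions)),
    category = sample(community_categories(), n_regions * k, replace = TRUE),
    lat = rep(centers_lat, each = k) + runif(n_regions * k, -0.3, 0.3),
    lon = rep(centers_lon, each = k) + runif(n_regions * k, -0.3, 0.3),
    region = rep(spec$regions, each = k)
  )
}

# multiplier[region, topic, day] combining all active event injections
event_multipliers <- function(spec) {
  M <- array(1, dim = c(length(spec$regions), length(spec$topics), spec$n_days),
             dimnames = list(spec$regions, spec$topics, NULL))
  for (ev in spec$events) {
    days <- ev$start_day:(ev$start_day + ev$duration_days - 1L)
    M[ev$region, ev$topic, days] <- M[ev$region, ev$topic, days] * ev$rate_multiplier
  }
  M
}

# Which injection (if any) is active for region/topic/day; first match wins.
active_event <- function(spec, region, topic, day) {
  for (ev in spec$events) {
    if (ev$region == region && ev$topic == topic &&
        day >= ev$start_day && day < ev$start_day + ev$duration_days) {
      return(ev)
    }
  }
  NULL
}

#' Generate a synthetic message stream
#'
#' Simulates per-user per-day message counts as independent Poisson draws per
#' topic (rate = `base_rate` x topic share x any active event multiplier),
#' then samples each message's subtopic, emotion, token bag (5-15 tokens from
#' the topic/subtopic vocabulary plus one emotion marker token), and 0-2
#' hashtags. An event injection concentrates its extra traffic on the named
#' subtopic and, if given, swaps in its emotion mixture for the window.
#' Ground-truth labels are returned in a sidecar table keyed by message id.
#'
#' @param spec A [stream_spec()].
#' @param users Output of [generate_users()] on the same spec (or its `users`
#'   tibble).
#' @return A list with tibbles `messages` (JSONL-serializable schema: id,
#'   text, username, created_at, hashtags, geo, mentions, favorites,
#'   communities, iso_language_code, town) and `truth` (id, topic, subtopic,
#'   emotion).
#' @export
generate_stream <- function(spec, users) {
  stopifnot(inherits(spec, "stream_spec"))
  if (is.list(users) && !is.data.frame(users)) users <- users$users
  missing_vocab <- setdiff(spec$topics, names(spec$vocab$topics))
  if (length(missing_vocab)) {
    abort(sprintf("configuration error: no vocabulary for topic(s): %s.",
                  paste(missing_vocab, collapse = ", ")))
  }
  withr::with_seed(derive_seed(spec$seed, 2L), {
    M <- event_multipliers(spec)
    n_u <- nrow(users)
    region_idx <- match(users$region, spec$regions)

    # message skeleton: one row per (user, day, topic) with count > 0
    skel <- vector("list", length(spec$topics))
    ud_region <- rep(region_idx, times = spec$n_days)
    ud_user <- rep(seq_len(n_u), times = spec$n_days)
    ud_day <- rep(seq_len(spec$n_days), each = n_u)
    for (ti in seq_along(spec$topics)) {
      lam <- spec$base_rate * spec$topic_shares[[spec$topics[ti]]] *
        M[cbind(ud_region, ti, ud_day)]
      cnt <- rpois(length(lam), lam)
      pos <- which(cnt > 0L)
      if (length(pos)) {
        skel[[ti]] <- tibble(
          user = rep(ud_user[pos], cnt[pos]),
          day = rep(ud_day[pos], cnt[pos]),
          topic = spec$topics[ti]
        )
      }
    }
    msgs <- bind_rows(skel)
    if (nrow(msgs) == 0L) {
      return(list(messages = empty_messages(), truth = empty_truth()))
    }
    msgs <- msgs[order(msgs$day), , drop = FALSE]
    msgs$region <- users$region[msgs$user]
    n <- nrow(msgs)

    # subtopic and emotion, event-aware per (region, topic, day) block
    msgs$subtopic <- NA_character_
    msgs$emotion <- NA_character_
    blocks <- split(seq_len(n), list(msgs$region, msgs$topic, msgs$day), drop = TRUE)
    for (rows in blocks) {
      region <- msgs$region[rows[1]]
      topic <- msgs$topic[rows[1]]
      day <- msgs$day[rows[1]]
      subs <- names(spec$vocab$subtopics[[topic]])
      K <- length(subs)
      p_sub <- rep(1 / K, K)
      mix <- spec$emotion_mixture[[topic]]
      ev <- active_event(spec, region, topic, day)
      if (!is.null(ev)) {
        m <- ev$rate_multiplier
        # baseline traffic keeps the uniform subtopic split; all extra
        # traffic carries the injected subtopic
        p_sub <- (1 / K) / m + (subs == ev$subtopic) * (m - 1) / m
        if (!is.null(ev$emotion_shift)) mix <- ev$emotion_shift
      }
      msgs$subtopic[rows] <- sample(subs, length(rows), replace = TRUE, prob = p_sub)
      msgs$emotion[rows] <- sample(names(mix), length(rows), replace = TRUE, prob = mix)
    }

    # token bags, grouped by (topic, subtopic) for vectorized sampling
    len <- sample(5:15, n, replace = TRUE)
    n_hash <- sample(0:2, n, replace = TRUE)
    text <- character(n)
    hashtags <- vector("list", n)
    for (rows in split(seq_len(n), list(msgs$topic, msgs$subtopic), drop = TRUE)) {
      topic <- msgs$topic[rows[1]]
      pool <- c(spec$vocab$topics[[topic]],
                spec$vocab$subtopics[[topic]][[msgs$subtopic[rows[1]]]])
      toks <- sample(pool, sum(len[rows]), replace = TRUE)
      text[rows] <- vapply(split(toks, rep(seq_along(rows), len[rows])),
                           paste, character(1), collapse = " ")
      ht <- paste0("#", sample(pool, sum(n_hash[rows]), replace = TRUE))
      grp <- rep(seq_along(rows), n_hash[rows])
      hashtags[rows] <- unname(split(ht, factor(grp, levels = seq_along(rows))))
    }
    marker <- sprintf("em_%s_%d", msgs$emotion, sample.int(5, n, replace = TRUE))
    text <- paste(text, marker)

    secs <- floor(runif(n, 0, 86400))
    created <- as.POSIXct(spec$start_date, tz = "UTC") +
      (msgs$day - 1L) * 86400 + secs
    ids <- sprintf("m%07d", seq_len(n))

    messages <- tibble(
      id = ids,
      text = text,
      username = users$user_id[msgs$user],
      created_at = created,
      hashtags = hashtags,
      geo = rep(list(NULL), n),
      mentions = rep(list(character(0)), n),
      favorites = rpois(n, 1),
      communities = users$communities[msgs$user],
      iso_language_code = "en",
      town = msgs$region
    )
    truth <- tibble(id = ids, topic = msgs$topic,
                    subtopic = msgs$subtopic, emotion = msgs$emotion)
    list(messages = messages, truth = truth)
  })
}

empty_messages <- function() {
  tibble(id = character(), text = character(), username = character(),
         created_at = as.POSIXct(character(), tz = "UTC"),
         hashtags = list(), geo = list(), mentions = list(),
         favorites = integer(), communities = list(),
         iso_language_code = character(), town = character())
}

empty_truth <- function() {
  tibble(id = character(), topic = character(),
         subtopic = character(), emotion = character())
}

#' Read and write message streams as JSON Lines
#'
#' One JSON object per line with keys id, text, username, created_at
#' (ISO-8601 UTC), hashtags, geo, mentions, favorites, communities,
#' iso_language_code, town. The round trip preserves every field.
#'
#' @param messages Message tibble as produced by [generate_stream()].
#' @param path File path.
#' @return `write_messages_jsonl()` returns `path` invisibly;
#'   `read_messages_jsonl()` returns the message tibble.
#' @export
write_messages_jsonl <- function(messages, path) {
  recs <- lapply(seq_len(nrow(messages)), function(i) {
    jsonlite::toJSON(list(
      id = messages$id[i],
      text = messages$text[i],
      username = messages$username[i],
      created_at = format(messages$created_at[i], "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
      hashtags = as.character(messages$hashtags[[i]]),
      geo = messages$geo[[i]],
      mentions = as.character(messages$mentions[[i]]),
      favorites = messages$favorites[i],
      communities = as.character(messages$communities[[i]]),
      iso_language_code = messages$iso_language_code[i],
      town = messages$town[i]
    ), auto_unbox = TRUE, null = "null", digits = NA)
  })
  writeLines(unlist(recs), path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_messages_jsonl
#' @export
read_messages_jsonl <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  if (!length(lines)) return(empty_messages())
  recs <- lapply(lines, jsonlite::fromJSON, simplifyVector = TRUE)
  tibble(
    id = map_chr(recs, "id"),
    text = map_chr(recs, "text"),
    username = map_chr(recs, "username"),
    created_at = as.POSIXct(map_chr(recs, "created_at"),
                            format = "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
    hashtags = map(recs, ~ as.character(.x$hashtags)),
    geo = map(recs, ~ .x$geo),
    mentions = map(recs, ~ as.character(.x$mentions)),
    favorites = map_int(recs, ~ as.integer(.x$favorites)),
    communities = map(recs, ~ as.character(.x$communities)),
    iso_language_code = map_chr(recs, "iso_language_code"),
    town = map_chr(recs, "town")
  )
}

#' Read and write the community gazetteer (TSV)
#'
#' Columns: name, category, lat, lon, region.
#'
#' @param gazetteer Gazetteer tibble.
#' @param path File path.
#' @export
write_gazetteer <- function(gazetteer, path) {
  readr::write_tsv(gazetteer, path)
  invisible(path)
}

#' @rdname write_gazetteer
#' @export
read_gazetteer <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    name = readr::col_character(), category = readr::col_character(),
    lat = readr::col_double(), lon = readr::col_double(),
    region = readr::col_character()
  ))
}

#' Read and write the ground-truth sidecar (TSV)
#'
#' Columns: id, topic, subtopic, emotion.
#'
#' @param truth Truth tibble from [generate_stream()].
#' @param path File path.
#' @export
write_truth <- function(truth, path) {
  readr::write_tsv(truth, path)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()))
}
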