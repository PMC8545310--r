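#' Default topic/subtopic vocabulary for the synthetic stream
#'
#' Builds a pseudo-language vocabulary: each topic owns a disjoint set of
#' topic tokens and (by default) two subtopics with their own token sets.
#' Downstream classifiers are bag-of-words, so tokens need no internal
#' structure; disjoint token sets give a controllable degree of class
#' separation.
#'
#' @param topics Character vector of topic names.
#' @param n_topic_tokens Tokens per topic.
#' @param subtopics Named list mapping topic -> character vector of subtopic
#'   names. Defaults to two generic subtopics per topic.
#' @param n_subtopic_tokens Tokens per subtopic.
#' @return A list with elements `topics` (topic -> tokens) and `subtopics`
#'   (topic -> subtopic -> tokens).
#' @export
default_vocab <- function(topics = osn_topics(), n_topic_tokens = 20,
                          subtopics = NULL, n_subtopic_tokens = 8) {
  if (is.null(subtopics)) {
    subtopics <- setNames(lapply(topics, function(tp) paste0(tp, c("_a", "_b"))), topics)
  }
  topic_tok <- setNames(
    lapply(topics, function(tp) sprintf("%s_tok%02d", tp, seq_len(n_topic_tokens))),
    topics
  )
  sub_tok <- setNames(lapply(topics, function(tp) {
    setNames(
      lapply(subtopics[[tp]], function(sb) sprintf("%s_tok%02d", sb, seq_len(n_subtopic_tokens))),
      subtopics[[tp]]
    )
  }), topics)
  list(topics = topic_tok, subtopics = sub_tok)
}

#' Default emotion mixture
#'
#' A single baseline distribution over the six emotions, used for every topic
#' unless overridden. Mildly positive-leaning, reflecting ordinary
#' (non-event) chatter.
#'
#' @return Named numeric vector over the six emotions, summing to one.
#' @export
default_emotion_mixture <- function() {
  c(anger = 0.14, disgust = 0.10, fear = 0.13, joy = 0.30,
    sadness = 0.18, surprise = 0.15)
}

#' Default follow-type distribution
#'
#' Probabilities that a user follows exactly 1 (Unique), 2 (Low), 3-9
#' (Moderate), 10-49 (High), or 50+ (Extreme) community organizations.
#' The published shares (90%, 9.2%, 0.3%, 0.1%, 0.3%) sum to 99.9%; they are
#' renormalized here so the vector is a proper distribution.
#'
#' @return Named numeric vector of length five summing to one.
#' @export
default_follow_distribution <- function() {
  p <- c(Unique = 0.90, Low = 0.092, Moderate = 0.003, High = 0.001, Extreme = 0.003)
  p / sum(p)
}

#' Describe an event to inject into a synthetic stream
#'
#' An injection multiplies the Poisson message rate of one (region, topic)
#' pair over a day window, concentrates the extra traffic on one subtopic,
#' and optionally replaces the topic's emotion mixture for the window.
#'
#' @param region,topic,subtopic Names identifying where the event happens.
#' @param start_day First affected day (1-based index into the stream days).
#' @param duration_days Number of affected days.
#' @param rate_multiplier Positive multiplier on the topic's message rate.
#' @param emotion_shift Optional named distribution over the six emotions in
#'   force during the event; `NULL` keeps the topic's baseline mixture.
#' @return An object of class `event_injection`.
#' @export
event_injection <- function(region, topic, subtopic, start_day, duration_days,
                            rate_multiplier, emotion_shift = NULL) {
  stopifnot(is.character(region), is.character(topic), is.character(subtopic))
  if (rate_multiplier <= 0) abort("`rate_multiplier` must be positive.")
  if (duration_days < 1 || start_day < 1) abort("event window must be within the stream.")
  if (!is.null(emotion_shift)) check_prob_vector(emotion_shift, osn_emotions(), "emotion_shift")
  structure(
    list(region = region, topic = topic, subtopic = subtopic,
         start_day = as.integer(start_day),
         duration_days = as.integer(duration_days),
         rate_multiplier = rate_multiplier, emotion_shift = emotion_shift),
    class = "event_injection"
  )
}

check_prob_vector <- function(p, names_expected, what) {
  if (!isTRUE(all.equal(sum(p), 1, tolerance = 1e-9))) {
    abort(sprintf("`%s` must sum to 1 (got %.12f).", what, sum(p)))
  }
  if (any(p < 0)) abort(sprintf("`%s` has negative entries.", what))
  if (!is.null(names_expected)) {
    if (is.null(names(p)) || !setequal(names(p), names_expected)) {
      abort(sprintf("`%s` must be named over: %s.", what,
                    paste(names_expected, collapse = ", ")))
    }
  }
  invisible(p)
}

#' Specify a synthetic OSN message stream
#'
#' Defines the statistical conditions of a seeded synthetic message stream:
#' regions, users, topic mix, vocabulary, per-user Poisson posting rate,
#' community-follow behavior, emotion mixtures, and injected events.
#'
#' @param regions Character vector of region (city) names.
#' @param users_per_region Positive integer, users generated per region.
#' @param topics Character vector of topic names.
#' @param topic_shares Named distribution of messages over topics
#'   (default uniform).
#' @param vocab Vocabulary as from [default_vocab()].
#' @param base_rate Mean messages per user per day (Poisson).
#' @param n_days Number of stream days.
#' @param start_date First calendar day (UTC) of the stream.
#' @param follow_distribution Length-5 distribution over the user follow
#'   types (Unique, Low, Moderate, High, Extreme).
#' @param p_home_community Probability that each followed community lies in
#'   the user's home region (default 0.92).
#' @param p_declared Probability a user declares their location (default 0.18).
#' @param communities_per_region Community accounts generated per region.
#' @param emotion_mixture Either a single named distribution over the six
#'   emotions or a named list topic -> distribution.
#' @param events List of [event_injection()] objects.
#' @param seed Integer seed; every random draw in the generator derives from it.
#' @return An object of class `stream_spec`.
#' @export
stream_spec <- function(regions = c("Sao Paulo", "Lima", "New York City", "Madrid"),
                        users_per_region = 100,
                        topics = osn_topics(),
                        topic_shares = NULL,
                        vocab = default_vocab(topics),
                        base_rate = 2,
                        n_days = 30,
                        start_date = as.Date("2019-11-15"),
                        follow_distribution = default_follow_distribution(),
                        p_home_community = 0.92,
                        p_declared = 0.18,
                        communities_per_region = 30,
                        emotion_mixture = default_emotion_mixture(),
                        events = list(),
                        seed = 1L) {
  if (length(regions) < 1) abort("invalid spec: at least one region is required.")
  if (users_per_region < 1) abort("invalid spec: `users_per_region` must be positive.")
  if (base_rate <= 0) abort("invalid spec: `base_rate` must be positive.")
  if (n_days < 1) abort("invalid spec: `n_days` must be at least 1.")
  if (length(follow_distribution) != 5) {
    abort("invalid spec: `follow_distribution` must have exactly 5 entries.")
  }
  check_prob_vector(follow_distribution,
                    c("Unique", "Low", "Moderate", "High", "Extreme"),
                    "follow_distribution")
  if (is.null(topic_shares)) {
    topic_shares <- setNames(rep(1 / length(topics), length(topics)), topics)
  }
  check_prob_vector(topic_shares, topics, "topic_shares")
  if (!setequal(names(vocab$topics), topics)) {
    abort("configuration error: `vocab$topics` must cover every declared topic.")
  }
  if (is.numeric(emotion_mixture)) {
    check_prob_vector(emotion_mixture, osn_emotions(), "emotion_mixture")
    emotion_mixture <- setNames(rep(list(emotion_mixture), length(topics)), topics)
  } else {
    lapply(emotion_mixture, check_prob_vector, names_expected = osn_emotions(),
           what = "emotion_mixture")
  }
  if (p_home_community < 0 || p_home_community > 1) abort("`p_home_community` must be in [0, 1].")
  events <- lapply(events, function(ev) {
    if (!inherits(ev, "event_injection")) abort("`events` must contain event_injection objects.")
    if (ev$start_day + ev$duration_days - 1 > n_days) {
      abort("invalid spec: event window extends beyond `n_days`.")
    }
    if (!ev$region %in% regions || !ev$topic %in% topics) {
      abort("invalid spec: event region/topic not declared in the spec.")
    }
    ev
  })
  structure(
    list(regions = regions, users_per_region = as.integer(users_per_region),
         topics = topics, topic_shares = topic_shares, vocab = vocab,
         base_rate = base_rate, n_days = as.integer(n_days),
         start_date = as.Date(start_date),
         follow_distribution = follow_distribution,
         p_home_community = p_home_community, p_declared = p_declared,
         communities_per_region = as.integer(communities_per_region),
         emotion_mixture = emotion_mixture, events = events,
         seed = as.integer(seed)),
    class = "stream_spec"
  )
}

#' @export
print.stream_spec <- function(x, ...) {
  cat("<stream_spec>\n")
  cat("  regions:", paste(x$regions, collapse = ", "), "\n")
  cat("  users/region:", x$users_per_region,
      " days:", x$n_days, " base rate:", x$base_rate, "\n")
  cat("  topics:", length(x$topics), " events:", length(x$events),
      " seed:", x$seed, "\n")
  invisible(x)
}
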