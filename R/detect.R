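#' Aggregate messages into daily per-region per-topic count series
#'
#' Messages are assigned to the UTC calendar day of their timestamp. Days
#' with no messages appear with count 0 over the global date range, so every
#' series is gap-free and aligned. Total counts are conserved.
#'
#' @param messages Tibble with `created_at` (POSIXct or Date), `region`
#'   (falls back to `town`), and `topic`.
#' @return Tibble (region, topic, date, count) of class `osn_daily_counts`.
#'   Rows with unparseable timestamps are dropped and reported via the
#'   `rejected` attribute.
#' @export
aggregate_daily <- function(messages) {
  region <- if ("region" %in% names(messages)) messages$region else messages$town
  date <- as.Date(messages$created_at, tz = "UTC")
  bad <- is.na(date)
  if (any(bad)) {
    warn(sprintf("dropping %d message(s) with unparseable timestamps.", sum(bad)))
  }
  df <- tibble(region = region[!bad], topic = messages$topic[!bad],
               date = date[!bad])
  out <- df |>
    count(.data$region, .data$topic, .data$date, name = "count") |>
    tidyr::complete(
      tidyr::nesting(region, topic),
      date = if (nrow(df)) seq(min(df$date), max(df$date), by = "day") else as.Date(character()),
      fill = list(count = 0L)
    ) |>
    arrange(.data$region, .data$topic, .data$date)
  attr(out, "rejected") <- if (any(bad)) messages$id[bad] else character(0)
  class(out) <- c("osn_daily_counts", class(out))
  out
}

#' Change-detector configuration
#'
#' @param threshold Relative change that flags a behavior change
#'   (default 0.30, i.e. a 30% increase or decrease).
#' @param window Baseline window in days for the trailing mean (default 7).
#' @param floor Minimum baseline (messages/day) below which no flag is
#'   raised; suppresses small-count false alarms.
#' @param mode `"trailing-mean"` compares each day against the mean of the
#'   `window` prior days; `"day-over-day"` against the previous day alone.
#' @return A list of class `detector_config`.
#' @export
detector_config <- function(threshold = 0.30, window = 7, floor = 5,
                            mode = c("trailing-mean", "day-over-day")) {
  if (threshold <= 0) abort("`threshold` must be positive.")
  if (window < 1) abort("`window` must be at least 1.")
  structure(list(threshold = threshold, window = as.integer(window),
                 floor = floor, mode = match.arg(mode)),
            class = "detector_config")
}

#' Flag behavior changes in daily count series
#'
#' For each day with baseline `b` (trailing mean of the prior `window` days,
#' or the previous day's count in day-over-day mode) at or above the floor,
#' a flag is raised when `|count - b| / b >= threshold`.
#'
#' @param counts An [aggregate_daily()] tibble, or any tibble with region,
#'   topic, date, count.
#' @param cfg A [detector_config()].
#' @return Tibble of flags: region, topic, date, count, baseline,
#'   rel_change, direction.
#' @export
detect_change <- function(counts, cfg = detector_config()) {
  w <- if (cfg$mode == "day-over-day") 1L else cfg$window
  flags <- counts |>
    group_by(.data$region, .data$topic) |>
    group_modify(function(d, key) {
      d <- arrange(d, .data$date)
      if (nrow(d) <= w) {
        abort(sprintf("insufficient history: series has %d day(s), baseline window is %d.",
                      nrow(d), w))
      }
      x <- d$count
      n <- length(x)
      cs <- cumsum(x)
      t_idx <- (w + 1L):n
      base <- (cs[t_idx - 1L] - c(0, cs)[t_idx - w]) / w
      rel <- (x[t_idx] - base) / base
      ok <- base >= cfg$floor & abs(rel) >= cfg$threshold
      tibble(date = d$date[t_idx][ok], count = x[t_idx][ok],
             baseline = base[ok], rel_change = rel[ok],
             direction = if_else(rel[ok] > 0, "increase", "decrease"))
    }) |>
    ungroup()
  flags
}

#' Assemble events from change flags
#'
#' Flags on consecutive days for the same (region, topic) merge into one
#' event whose onset is the first flagged day; direction and relative change
#' are taken from the onset day.
#'
#' @param counts Daily counts as in [detect_change()].
#' @param cfg A [detector_config()].
#' @return Tibble of events: region, topic, onset, end, direction,
#'   rel_change, n_flagged_days; classed `osn_events`.
#' @export
detect_events <- function(counts, cfg = detector_config()) {
  flags <- detect_change(counts, cfg)
  if (nrow(flags) == 0L) {
    ev <- tibble(region = character(), topic = character(),
                 onset = as.Date(character()), end = as.Date(character()),
                 direction = character(), rel_change = numeric(),
                 n_flagged_days = integer())
    return(structure(ev, class = c("osn_events", class(ev)), config = cfg))
  }
  ev <- flags |>
    group_by(.data$region, .data$topic) |>
    arrange(.data$date, .by_group = TRUE) |>
    mutate(run = cumsum(c(1, diff(.data$date) > 1))) |>
    group_by(.data$region, .data$topic, .data$run) |>
    summarise(onset = min(.data$date), end = max(.data$date),
              direction = first(.data$direction),
              rel_change = first(.data$rel_change),
              n_flagged_days = n(), .groups = "drop") |>
    select(-"run") |>
    arrange(.data$onset)
  structure(ev, class = c("osn_events", class(ev)),
            config = cfg)
}

#' Attribute an event to its dominant subtopic and keywords
#'
#' Messages within `lookback` days of the onset (either side) vote: the
#' dominant subtopic is the mode of the subtopic assignments (ties broken
#' lexicographically and annotated), keywords are the `top_k` most frequent
#' non-stopword tokens — the word-cloud analogue.
#'
#' @param event One event row (from [detect_events()]) or a list with
#'   `region`, `topic`, `onset`.
#' @param messages Tibble with `id`, `date` (or `created_at`), `region`,
#'   `topic`, `subtopic`, and `tokens` list-column.
#' @param lookback Days either side of the onset (default 3).
#' @param top_k Number of keywords (default 25).
#' @param stopwords Tokens excluded from keywords.
#' @return The event as a one-row tibble with dominant_subtopic,
#'   subtopic_tie, subtopic_counts and keywords list-columns.
#' @export
attribute_event <- function(event, messages, lookback = 3, top_k = 25,
                            stopwords = character(0)) {
  if (is.data.frame(event)) event <- as.list(event[1, ])
  if (!"date" %in% names(messages)) {
    messages$date <- as.Date(messages$created_at, tz = "UTC")
  }
  win <- messages |>
    filter(.data$region == event$region, .data$topic == event$topic,
           abs(as.numeric(.data$date - event$onset)) <= lookback)
  if (nrow(win) == 0L) abort("empty attribution window: no messages near the onset.")
  tab <- sort(table(win$subtopic), decreasing = TRUE)
  top <- names(tab)[tab == max(tab)]
  dominant <- sort(top)[1]
  toks <- unlist(win$tokens)
  toks <- toks[!toks %in% stopwords]
  kw <- names(sort(table(toks), decreasing = TRUE))
  tibble(
    region = event$region, topic = event$topic, onset = event$onset,
    direction = event$direction %||% NA_character_,
    rel_change = event$rel_change %||% NA_real_,
    dominant_subtopic = dominant,
    subtopic_tie = length(top) > 1,
    subtopic_counts = list(tibble(subtopic = names(tab),
                                  count = as.integer(tab))),
    keywords = list(head(kw, top_k))
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Per-emotion daily series around an event
#'
#' Daily counts per emotion over `[onset - half_window, onset + half_window]`,
#' each emotion's series divided by its own maximum for comparable plotting;
#' an all-zero emotion stays zero rather than NaN. A window extending beyond
#' the available data is truncated with a warning.
#'
#' @param event Event row or list with `onset` (and optionally `region`).
#' @param emotion_messages Tibble with `date` (or `created_at`), `emotion`,
#'   and optionally `region` (filtered to the event's region when both
#'   present).
#' @param half_window Days before and after the onset (default 15).
#' @return Tibble (emotion, date, count, norm) classed `osn_emotion_window`.
#' @export
emotion_window <- function(event, emotion_messages, half_window = 15) {
  if (is.data.frame(event)) event <- as.list(event[1, ])
  m <- emotion_messages
  if (!"date" %in% names(m)) m$date <- as.Date(m$created_at, tz = "UTC")
  if (!is.null(event$region) && "region" %in% names(m)) {
    m <- filter(m, .data$region == event$region)
  }
  lo <- event$onset - half_window
  hi <- event$onset + half_window
  if (nrow(m) && (lo < min(m$date) || hi > max(m$date))) {
    warn("emotion window truncated: it extends beyond the available data.")
    lo <- max(lo, min(m$date)); hi <- min(hi, max(m$date))
  }
  grid <- tidyr::expand_grid(emotion = osn_emotions(),
                             date = seq(lo, hi, by = "day"))
  out <- m |>
    filter(.data$date >= lo, .data$date <= hi) |>
    count(.data$emotion, .data$date, name = "count") |>
    right_join(grid, by = c("emotion", "date")) |>
    mutate(count = tidyr::replace_na(.data$count, 0L)) |>
    group_by(.data$emotion) |>
    mutate(norm = if (max(.data$count) > 0) .data$count / max(.data$count) else 0) |>
    ungroup() |>
    arrange(.data$emotion, .data$date)
  attr(out, "onset") <- event$onset
  class(out) <- c("osn_emotion_window", class(out))
  out
}
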