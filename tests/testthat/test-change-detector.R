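test_that("daily aggregation conserves totals and zero-fills gaps", {
  base <- as.POSIXct("2020-02-01 10:00:00", tz = "UTC")
  msgs <- tibble::tibble(
    id = sprintf("m%d", 1:8),
    created_at = base + c(rep(0, 6), 2 * 86400, 2 * 86400),
    region = "Lima", topic = c(rep("health", 6), "health", "work")
  )
  cnt <- aggregate_daily(msgs)
  expect_equal(sum(cnt$count), 8)
  h <- dplyr::filter(cnt, topic == "health")
  expect_equal(h$count, c(6, 0, 1))  # day 2 present with count 0
  # totals conserved across arbitrary region/topic splits
  expect_equal(sum(dplyr::filter(cnt, topic == "work")$count), 1)
})

test_that("a 15-to-30 step flags on the step day as an increase", {
  s <- series_tbl(c(rep(15, 10), rep(30, 4)))
  flags <- detect_change(s, detector_config())
  expect_identical(flags$date[1], as.Date("2020-01-11"))
  expect_identical(flags$direction[1], "increase")
  expect_equal(flags$rel_change[1], 1.0)
})

test_that("constant series and sub-threshold changes never flag", {
  expect_identical(nrow(detect_change(series_tbl(rep(20, 14)))), 0L)
  # 10 -> 12 is a 20% change, below the 30% threshold
  expect_identical(nrow(detect_change(series_tbl(c(rep(10, 10), rep(12, 4))))), 0L)
})

test_that("a 50% decrease flags with direction decrease", {
  flags <- detect_change(series_tbl(c(rep(20, 10), rep(10, 4))))
  expect_gt(nrow(flags), 0)
  expect_identical(flags$direction[1], "decrease")
  expect_equal(flags$rel_change[1], -0.5)
})

test_that("the baseline floor suppresses small-count alarms", {
  s <- series_tbl(c(rep(2, 10), rep(10, 2)))  # baseline 2 < floor 5
  expect_identical(nrow(detect_change(s)), 0L)
  flags <- detect_change(s, detector_config(floor = 1))
  expect_gt(nrow(flags), 0)
})

test_that("day-over-day mode compares against the previous day only", {
  s <- series_tbl(c(10, 10, 20, 20))
  flags <- detect_change(s, detector_config(mode = "day-over-day"))
  expect_identical(flags$date, as.Date("2020-01-03"))
})

test_that("short series raise an insufficient-history error", {
  expect_error(detect_change(series_tbl(rep(10, 7))), "insufficient history")
})

test_that("stronger steps flag no later than weaker ones", {
  base <- rep(20, 10)
  flag_day <- function(mult) {
    s <- series_tbl(c(base, round(20 * mult), rep(20, 3)))
    f <- detect_change(s)
    if (nrow(f)) min(f$date) else as.Date("2100-01-01")
  }
  days <- vapply(c(1.4, 2, 3, 5), flag_day, as.Date("2000-01-01"))
  expect_true(all(diff(as.numeric(days)) <= 0))
})

test_that("identical series and config give identical flags", {
  s <- series_tbl(c(rep(15, 10), rep(40, 4)))
  expect_identical(detect_change(s), detect_change(s))
})

test_that("consecutive flags merge into one event with the first day as onset", {
  s <- series_tbl(c(rep(15, 10), rep(45, 4)))
  ev <- detect_events(s)
  expect_identical(nrow(ev), 1L)
  expect_identical(ev$onset, as.Date("2020-01-11"))
  expect_gt(ev$n_flagged_days, 1)
})

test_that("event attribution takes the modal subtopic and counts keywords", {
  msgs <- tibble::tibble(
    id = sprintf("m%d", 1:35),
    region = "R", topic = "health",
    date = as.Date("2020-01-11") + rep(c(-1, 0, 1), length.out = 35),
    subtopic = rep(c("flu", "sport"), c(30, 5)),
    tokens = c(replicate(30, c("fever", "fever", "cough"), simplify = FALSE),
               replicate(5, c("gym"), simplify = FALSE))
  )
  ev <- list(region = "R", topic = "health", onset = as.Date("2020-01-11"))
  att <- attribute_event(ev, msgs)
  expect_identical(att$dominant_subtopic, "flu")
  expect_false(att$subtopic_tie)
  expect_identical(att$keywords[[1]][1], "fever")

  # tie breaks to the lexicographically first subtopic, annotated
  msgs2 <- dplyr::mutate(msgs[1:20, ], subtopic = rep(c("flu", "fever"), 10))
  att2 <- attribute_event(ev, msgs2)
  expect_identical(att2$dominant_subtopic, "fever")
  expect_true(att2$subtopic_tie)
  expect_error(attribute_event(list(region = "X", topic = "health",
                                    onset = as.Date("2020-01-11")), msgs),
               "empty attribution window")
})

test_that("a dominant keyword outranks the rest in the word-cloud table", {
  msgs <- tibble::tibble(
    id = sprintf("m%d", 1:50), region = "R", topic = "health",
    date = as.Date("2020-01-10"), subtopic = "flu",
    tokens = c(replicate(40, "fever", simplify = FALSE),
               replicate(10, sample(c("x", "y", "z"), 1), simplify = FALSE))
  )
  att <- attribute_event(list(region = "R", topic = "health",
                              onset = as.Date("2020-01-11")), msgs)
  expect_identical(att$keywords[[1]][1], "fever")
})

test_that("emotion windows are max-normalized with guarded zeros", {
  msgs <- tibble::tibble(
    date = as.Date("2020-01-01") + 0:30,
    emotion = rep(c("fear", "joy"), length.out = 31)
  )
  ev <- list(onset = as.Date("2020-01-16"))
  w <- emotion_window(ev, msgs, half_window = 15)
  fear <- dplyr::filter(w, emotion == "fear")
  expect_equal(max(fear$norm), 1)
  # an emotion absent from the window is all zeros, never NaN
  anger <- dplyr::filter(w, emotion == "anger")
  expect_true(all(anger$norm == 0) && !any(is.nan(anger$norm)))
  expect_warning(emotion_window(list(onset = as.Date("2020-01-02")), msgs),
                 "truncated")
})

test_that("the detector flags no later than a two-consecutive-day baseline", {
  withr::with_seed(808, {
    for (r in 1:20) {
      counts <- c(rpois(10, 30), rpois(6, 75))
      flags <- detect_change(series_tbl(counts))
      consec <- flags$date[(flags$date - 1) %in% flags$date]
      if (length(consec)) expect_lte(min(flags$date), min(consec))
    }
  })
})

test_that("an injected fear shift is visible in the normalized window", {
  ratio <- function(seed) {
    shift <- c(anger = 0.07, disgust = 0.05, fear = 0.26, joy = 0.30,
               sadness = 0.18, surprise = 0.14)
    spec <- stream_spec(regions = "A", users_per_region = 10,
                        topics = c("health", "work"),
                        vocab = default_vocab(c("health", "work")),
                        base_rate = 2, n_days = 31,
                        events = list(event_injection("A", "health", "health_a",
                                                      16, 16, 1.0,
                                                      emotion_shift = shift)),
                        seed = seed)
    s <- generate_stream(spec, generate_users(spec))
    m <- dplyr::mutate(s$messages,
                       date = as.Date(created_at, tz = "UTC"),
                       emotion = s$truth$emotion, topic = s$truth$topic,
                       region = town)
    # the window is scoped to the event topic, as in event reports
    m <- dplyr::filter(m, topic == "health")
    w <- emotion_window(list(onset = spec$start_date + 15, region = "A"),
                        m, half_window = 15)
    fear <- dplyr::filter(w, emotion == "fear")
    onset <- spec$start_date + 15
    c(before = mean(fear$norm[fear$date < onset]),
      after = mean(fear$norm[fear$date >= onset]))
  }
  reps <- vapply(1:200, ratio, numeric(2))
  # fear rate doubles (0.13 -> 0.26) at the onset
  expect_gte(mean(reps["after", ]) / mean(reps["before", ]), 1.5)
})
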