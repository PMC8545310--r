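test_that("follow-type distribution is honored at scale", {
  spec <- stream_spec(regions = c("A", "B", "C", "D"), users_per_region = 2500,
                      topics = c("health", "work"),
                      vocab = default_vocab(c("health", "work")), seed = 42)
  g <- generate_users(spec)
  p <- unname(default_follow_distribution()["Unique"])
  frac <- mean(g$users$n_follows == 1)
  se <- sqrt(p * (1 - p) / nrow(g$users))
  expect_lt(abs(frac - p), 3 * se)
  expect_setequal(unique(g$users$user_type),
                  intersect(c("Unique", "Low", "Moderate", "High", "Extreme"),
                            g$users$user_type))
})

test_that("p_home_community = 1 places every followed community at home", {
  spec <- two_topic_spec(seed = 5)
  spec$p_home_community <- 1
  g <- generate_users(spec)
  region_of <- setNames(g$gazetteer$region, g$gazetteer$name)
  home_ok <- purrr::map2_lgl(g$users$communities, g$users$region,
                             ~ all(region_of[.x] == .y))
  expect_true(all(home_ok))
})

test_that("generation is byte-identical under a fixed seed", {
  spec <- two_topic_spec(seed = 11, users = 20, n_days = 5)
  g1 <- generate_users(spec); g2 <- generate_users(spec)
  expect_identical(g1, g2)
  s1 <- generate_stream(spec, g1); s2 <- generate_stream(spec, g2)
  expect_identical(s1, s2)
})

test_that("total message volume matches the Poisson mean", {
  spec <- stream_spec(regions = "A", users_per_region = 10,
                      topics = c("health", "work"),
                      vocab = default_vocab(c("health", "work")),
                      base_rate = 2, n_days = 5, seed = 9)
  s <- generate_stream(spec, generate_users(spec))
  expect_lt(abs(nrow(s$messages) - 100), 3 * sqrt(100))
})

test_that("an identity-multiplier injection leaves the stream unchanged", {
  base <- two_topic_spec(seed = 13, users = 20, n_days = 10)
  with_ev <- two_topic_spec(seed = 13, users = 20, n_days = 10,
                            events = list(event_injection("A", "health", "health_a",
                                                          5, 3, 1.0)))
  expect_identical(generate_stream(base, generate_users(base)),
                   generate_stream(with_ev, generate_users(with_ev)))
})

test_that("a 2x injection doubles the topic's event-day mean across replicates", {
  day_count <- function(seed) {
    spec <- stream_spec(regions = "A", users_per_region = 10,
                        topics = c("health", "work"),
                        vocab = default_vocab(c("health", "work")),
                        base_rate = 2, n_days = 12,
                        events = list(event_injection("A", "health", "health_a",
                                                      10, 2, 2.0)),
                        seed = seed)
    s <- generate_stream(spec, generate_users(spec))
    day <- as.integer(as.Date(s$messages$created_at, tz = "UTC") - spec$start_date) + 1L
    health <- s$truth$topic == "health"
    c(pre = sum(health & day < 10) / 9, on = sum(health & day == 10))
  }
  reps <- vapply(1:200, day_count, numeric(2))
  pre_mean <- mean(reps["pre", ])     # expect 10 (10 users x 2 x 0.5)
  on_mean <- mean(reps["on", ])       # expect 20 under the 2x multiplier
  diff <- on_mean - 2 * pre_mean
  se_diff <- sqrt(stats::var(reps["on", ]) + 4 * stats::var(reps["pre", ])) /
    sqrt(ncol(reps))
  expect_lt(abs(diff), 3 * se_diff)
})

test_that("JSONL round trip preserves every message field", {
  spec <- two_topic_spec(seed = 21, users = 5, n_days = 3)
  s <- generate_stream(spec, generate_users(spec))
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_messages_jsonl(s$messages, path)
  back <- read_messages_jsonl(path)
  expect_equal(back, s$messages)
})

test_that("gazetteer and truth TSV round trips are faithful", {
  spec <- two_topic_spec(seed = 22, users = 5, n_days = 2)
  g <- generate_users(spec)
  s <- generate_stream(spec, g)
  p1 <- withr::local_tempfile(fileext = ".tsv")
  p2 <- withr::local_tempfile(fileext = ".tsv")
  write_gazetteer(g$gazetteer, p1)
  expect_equal(as.data.frame(read_gazetteer(p1)), as.data.frame(g$gazetteer))
  write_truth(s$truth, p2)
  expect_equal(as.data.frame(read_truth(p2)), as.data.frame(s$truth))
})

test_that("marginal topic shares converge to the spec shares", {
  topics <- osn_topics()
  spec <- stream_spec(regions = c("A", "B"), users_per_region = 250,
                      topics = topics, vocab = default_vocab(topics),
                      base_rate = 5, n_days = 20, seed = 33)
  s <- generate_stream(spec, generate_users(spec))
  n <- nrow(s$truth)
  expect_gte(n, 40000)
  counts <- table(factor(s$truth$topic, topics))
  # joint goodness-of-fit (ten shares are not independent, so a per-share
  # 3-SE bound over-rejects); individual deviations still bounded grossly
  gof <- stats::chisq.test(counts, p = unname(spec$topic_shares[topics]))
  expect_gt(gof$p.value, 1e-3)
  for (tp in topics) {
    p <- spec$topic_shares[[tp]]
    expect_lt(abs(counts[[tp]] / n - p), 5 * sqrt(p * (1 - p) / n))
  }
})

test_that("the ground-truth sidecar is a bijection over message ids", {
  spec <- two_topic_spec(seed = 34, users = 10, n_days = 5)
  s <- generate_stream(spec, generate_users(spec))
  expect_identical(sort(s$messages$id), sort(unique(s$truth$id)))
  expect_identical(nrow(s$messages), nrow(s$truth))
})

test_that("invalid specs are rejected", {
  expect_error(stream_spec(regions = character(0)), "region")
  expect_error(stream_spec(users_per_region = 0), "users_per_region")
  expect_error(stream_spec(base_rate = 0), "base_rate")
  expect_error(stream_spec(follow_distribution = c(a = 1)), "5 entries")
  expect_error(two_topic_spec(events = list(event_injection("A", "health", "x",
                                                            19, 5, 2))),
               "beyond")
  spec <- two_topic_spec()
  spec$vocab$topics$health <- NULL
  expect_error(generate_stream(spec, generate_users(two_topic_spec())),
               "configuration error")
})
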