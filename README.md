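# osnevents

Early event detection from online social network (OSN) message streams.

People in a region change what they post about when something important is
about to unfold there — an outbreak, a protest, a disaster. `osnevents`
turns that observation into a working surveillance pipeline for
epidemiologists and computational social scientists: it geolocates users,
cleans and classifies their messages, watches the daily per-region
per-topic message counts for behavior changes, and characterizes every
detected event by its dominant subtopic, keywords, and emotional
signature. Because OSN firehoses are not redistributable, the package
ships a seeded synthetic stream generator with injectable events, so every
stage is testable with known ground truth.

## What's inside

* **Social triangulation geolocation** — a user's region is inferred from
  the geocoded community accounts (media, government, businesses) they
  follow: the declared region when present, otherwise the majority region
  among followed communities, with confidence equal to the majority share.
  Users are typed by embeddedness (Unique/Low/Moderate/High/Extreme from
  1 / 2 / 3–9 / 10–49 / 50+ followed organizations) and scored with the
  E–I homophily index `(E − I)/(E + I)` over their community-follow ties.
* **Preprocessing** — spam/bot/ad filtering with an audit log, synonym
  normalization, unique edit-distance-1 spelling correction, greedy
  longest-match hashtag segmentation (`#prayformyMother → pray for my
  mother`), stopword removal, table-driven lemmatization.
* **Topic model** — ten-class softmax regression,
  `P(x | t) ∝ exp(Σᵢ w_xi tᵢ)`, L2-penalized cross-entropy fit by L-BFGS,
  10-fold cross-validation, topic-prevalence reports with a 2% floor.
* **Subtopic discovery** — a stacked-RBM deep belief network trained by
  CD-1 compresses the sparse counts; seeded k-means on its features yields
  subtopic pseudo-labels; a softmax head
  `h_t(m) = exp(s_tᵀm) / Σ_u exp(s_uᵀm)` is fine-tuned by minimizing the
  penalized cost `J(s) = −(1/n) Σᵢ Σ_t y_tⁱ log h_t(mᵢ) + (λ/2)‖s‖² +
  (λ/2) Σ_p ‖θ_p‖²` (λ = 2, quasi-Newton memory 6 by default).
* **Change detector** — a day flags when its count deviates from the
  baseline (trailing 7-day mean, or previous day) by at least 30% in
  either direction, subject to a 5-count baseline floor; consecutive flags
  merge into events with subtopic attribution, keyword extraction, and
  ±15-day max-normalized emotion windows.
* **Affect analysis** — a hierarchical tree-grown classifier over the six
  emotions (anger, disgust, fear, joy, sadness, surprise) with the
  softmax-gap growth rules (thresholds α = β = 0.1, depth ≤ 3, bounded
  branch capacity) and a positive/negative polarity mapping.
* **Metrics** — accuracy, sensitivity, precision, F-measure, and the
  G-mean `√(TP_rate × TN_rate)`; macro-averaged multi-class reports;
  detection latency against injected ground truth.

Everything is tibble-in/tibble-out and pipe-friendly; result objects have
`autoplot()`, `tidy()`, and `glance()` methods. A thin command-line
wrapper (`inst/cli/osnevents`) exposes `simulate`, `geolocate`,
`preprocess`, `detect`, `evaluate`, and `run-all`.

## A worked example

Simulate two cities for 30 days, inject a 2× health-topic surge in Sao
Paulo starting on day 21, and run the full pipeline:

```r
library(osnevents)

topics <- c("health", "work", "family")
spec <- stream_spec(
  regions = c("Sao Paulo", "Lima"), users_per_region = 100,
  topics = topics, vocab = default_vocab(topics),
  base_rate = 6, n_days = 30,
  events = list(event_injection("Sao Paulo", "health", "health_a",
                                start_day = 21, duration_days = 10,
                                rate_multiplier = 2)),
  seed = 5
)
res <- run_pipeline(pipeline_config(spec = spec, topic_folds = 0,
                                    affect_epochs = 15, seed = 5))
res$events
#> # A tibble: 1 × 7
#>   region    topic  onset      end        direction rel_change n_flagged_days
#> * <chr>     <chr>  <date>     <date>     <chr>          <dbl>          <int>
#> 1 Sao Paulo health 2019-12-05 2019-12-08 increase        1.03              4
```

The stream starts on 2019-11-15, so 2019-12-05 *is* day 21: the detector
fires on the first event day, because the surge roughly doubles the daily
health count (`rel_change = 1.03` against the trailing-mean baseline) and
stays flagged for four days while the baseline catches up. Attribution
recovers the injected subtopic and its vocabulary as keywords:

```r
res$attributed[, c("region", "topic", "onset", "dominant_subtopic")]
#> # A tibble: 1 × 4
#>   region    topic  onset      dominant_subtopic
#>   <chr>     <chr>  <date>     <chr>
#> 1 Sao Paulo health 2019-12-05 health_a
head(res$attributed$keywords[[1]], 5)
#> [1] "health"       "health_tok20" "health_tok03" "health_tok01" "health_tok19"
```

Measured against the injection, detection latency is zero days with no
misses:

```r
truth <- tibble::tibble(region = "Sao Paulo", topic = "health",
                        start_date = spec$start_date + 20)
detection_latency(res$events, truth)$summary
#> $mean_offset
#> [1] 0
#> $miss_rate
#> [1] 0
#> $n
#> [1] 1
```

`autoplot(res$counts)` shows the day-by-day monitoring view and
`autoplot(res$emotion_windows[[1]])` the normalized emotion series around
the onset.

## Documentation

The methods vignette (`vignettes/event-detection.Rmd`) documents the
models, their assumptions, every tunable parameter with its default and
rationale, what the synthetic generator does and does not emulate, and the
package's numerical conventions.
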