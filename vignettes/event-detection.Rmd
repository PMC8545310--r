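---
title: "Detecting emerging events from changes in social-media posting behavior"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting emerging events from changes in social-media posting behavior}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(osnevents)
```

## The surveillance problem

When something important happens in a city — an outbreak, a protest, a
disaster — the people living there change what they post about on online
social networks (OSNs) before official channels react. `osnevents`
implements a complete early-warning pipeline over a stream of short
region-tagged messages:

1. **Geolocation by social triangulation.** Most users never declare a
   location, but they follow local community accounts (media, government,
   businesses) whose locations are known. A user's region is inferred from
   the communities they follow.
2. **Text preprocessing.** Spam/bot/ad filtering, normalization, spelling
   correction, hashtag segmentation, stopword removal, lemmatization.
3. **Topic classification.** A ten-class softmax (multinomial logistic)
   classifier over bag-of-words counts.
4. **Subtopic discovery.** A stacked-RBM deep belief network (DBN)
   compresses the sparse text vectors; clustering its features yields
   subtopic pseudo-labels that train a softmax head, fine-tuned by L-BFGS.
5. **Behavior-change detection.** Daily per-region per-topic message counts
   are monitored; a relative change of at least 30% against a baseline
   flags a potential event, which is then attributed to its dominant
   subtopic and keywords.
6. **Affective analysis.** A hierarchical tree-grown classifier labels each
   message with one of six emotions (anger, disgust, fear, joy, sadness,
   surprise) and a polarity, characterizing the event's emotional signature
   over a 15-day window either side of the onset.

Because real OSN firehoses are not redistributable, the package is built
around a seeded synthetic stream generator whose ground truth makes every
stage testable.

## The synthetic stream generator

`stream_spec()` fixes the conditions of a simulated stream; `generate_users()`
and `generate_stream()` realize it deterministically from a seed.

* **Users and communities.** Each user has a home region and follows a
  number of community accounts drawn from the five-type embeddedness
  distribution (Unique 1, Low 2, Moderate 3–9, High 10–49, Extreme 50+),
  with default probabilities 0.90 / 0.092 / 0.003 / 0.001 / 0.003
  (renormalized to sum to one). Each followed community lies in the user's
  home region with probability `p_home_community = 0.92`; 18% of users
  declare their location (`p_declared = 0.18`).
* **Counts.** Message counts per user, day and topic are independent
  Poisson draws with mean `base_rate × topic share × event multiplier`.
  A Poisson model is the simplest count process consistent with the daily
  means the monitored series exhibit (tens of messages per day per topic).
* **Text.** A message is a bag of 5–15 tokens from its topic/subtopic
  vocabulary plus one emotion-marker token and 0–2 hashtags. There is no
  grammar: every downstream consumer is bag-of-words, so token
  co-occurrence statistics are the only thing that matters.
* **Events.** An `event_injection()` multiplies one (region, topic) rate
  over a day window, routes the extra traffic to one subtopic, and can
  replace the emotion mixture for the window.

The generator emulates multi-region, multi-topic Poisson traffic with
ground-truthed injections. It does **not** emulate: bursty within-day
dynamics, retweet cascades or virality, bot networks beyond duplicate
spam, natural language (negation, sarcasm, code-switching), or
non-stationary baselines (weekday/weekend cycles). Tests passing on this
generator therefore demonstrate the *mechanics* of each stage — not
performance on real social-media text, which depends on vocabulary overlap
and annotation quality that only real data can supply.

The message-length range (5–15 tokens) and the per-user rate default
(2/day) are package conventions chosen to resemble microblog traffic; no
published value fixes them.

## Geolocation: social triangulation

A user's declared region always wins, with confidence 1. Otherwise the
majority region among their resolvable followed communities is assigned,
with confidence equal to the majority share; a Unique user inherits their
single community's region. Ties between regions are broken by the most
specific community-asset category present (the `community_categories()`
order), then lexicographically — deterministic and auditable; no published
rule covers the multi-city case, so majority vote is this package's
convention.

The E–I homophily index treats community-follow edges as ties:
`(External − Internal) / (External + Internal)`, in [−1, 1], where a tie is
internal when the community's region equals the assigned region.

Geocoding is an offline gazetteer lookup keyed by case-folded exact name.
This replaces interactive map-API geocoding with a reproducible fixture;
unresolved names are flagged, never guessed.

For single-community (Unique) users the expected triangulation accuracy
equals `p_home_community` — the package's acceptance checks exploit exactly
this identity.

## Preprocessing

The stage order is fixed: noise removal → normalization (synonyms, then
spelling) → hashtag segmentation → stopword removal → lemmatization.
Noise rules: a user posting identical text ≥ 3 times within an hour keeps
only the first copy; messages whose token stream is more than half URLs
are ads; per-user daily volume is capped at 50 with the excess dropped as
bot traffic. Every removal is logged with its rule.

Spelling correction replaces a purely alphabetic out-of-lexicon token only
when it has a **unique** lexicon neighbour at edit distance 1; ambiguity
keeps the original. This is deliberately conservative — silent corruption
is worse than a missed fix. Hashtag segmentation is greedy longest-match
left-to-right with the unsegmentable remainder kept whole, which
reproduces the canonical `#prayformyMother → pray for my mother` example
deterministically. Emoticons and other opaque tokens pass through
unchanged (they may carry emotion signal).

## Topic model

For class $x$ with weight vector $w_x$ over $d$ features,

$$P(x \mid t) \propto \exp\Big(\sum_{i=1}^{d} w_{xi}\, t_i\Big),$$

normalized over the ten classes. Training minimizes L2-penalized
cross-entropy

$$J(W) = -\frac{1}{n}\sum_i \log P(y_i \mid t_i)
       + \frac{\lambda}{2}\lVert W \rVert^2$$

by L-BFGS, with a per-class bias term (the penalty's parameter sum starting
at index 0 is read as including an intercept). The default penalty is
λ = 1; the vocabulary keeps tokens occurring ≥ 5 times, capped at 2000
(the DBN input width) for bounded memory. Both 10-fold cross-validation
and an optional 80/20 holdout are provided — CV for model selection, the
holdout for a final report. Topic prevalence reports drop topics under 2%
but keep them in the denominator.

## Subtopic discovery

The DBN is a stack of restricted Boltzmann machines trained greedily by
single-step contrastive divergence (CD-1) on binarized counts
(count ≥ 1 → 1; RBM visible units are Bernoulli). Between layers the
deterministic mean-field activation *probabilities* are passed upward
rather than re-binarized samples — re-thresholding near-0.5 activations
early in training destroys the learned signal, while probabilities keep it
(the standard mean-field practice). The classic layer widths are
2000-1000-500; tests and examples scale the stack to their vocabulary.

Subtopics are discovered unsupervised: seeded k-means partitions the
top-layer features into K clusters (default 100 in full-scale use), each
labeled by its highest-lift token. These pseudo-labels are the "partial
labeled data" that train the softmax head

$$h_t(m) = \frac{e^{s_t^\top m}}{\sum_{u=1}^{l} e^{s_u^\top m}},$$

fine-tuned by minimizing

$$J(s) = -\frac{1}{n}\sum_i \sum_t y^i_t \log h_t(m_i)
       + \frac{\lambda}{2}\lVert s \rVert^2
       + \frac{\lambda}{2}\sum_p \lVert \theta_p \rVert^2,$$

where $\theta_p$ are the (frozen) RBM weights: their penalty term is a
constant offset in the reported cost. Only the head is optimized — the
deep gradient through the stack is not defined by the cost as printed, so
the package keeps the stack frozen rather than inventing one. The `1/n`
factor is read as one over the number of training samples. Defaults
λ = 2 and quasi-Newton memory m = 6 follow the published configuration
but are config-exposed, since λ = 2 with an unnormalized penalty is a
strong shrinkage; both optimizers (L-BFGS via `stats::optim`, and gradient
descent with a backtracking line search whose cost trace is
non-increasing) are available and agree on convex head-only problems.

## Behavior-change detection

For each (region, topic) series of UTC-calendar-day counts, day $t$ with
baseline $b_t$ flags when $|c_t - b_t| / b_t \ge \theta$, with θ = 0.30 —
the printed 30% increase-or-decrease rule. Two conventions the rule's
source leaves open are fixed here and config-exposed:

* **Baseline** — trailing mean of the 7 prior days (default), or the
  previous day alone (`day-over-day`) for the literal reading.
* **Floor** — no flag when the baseline is under 5 messages/day,
  suppressing the false alarms that plague noisy low-count series
  (a 30% excursion on a mean of 3 is one message).

Flags on consecutive days for the same series merge into one event with
onset at the first flagged day. Attribution looks ±3 days around the
onset: the dominant subtopic is the mode of the subtopic assignments
(ties break lexicographically and are annotated), and the top-25
non-stopword tokens form the keyword list. Emotion windows count each
emotion daily over onset ± 15 days, dividing each series by its own
maximum for comparable plotting; an all-zero series stays zero rather
than NaN.

With per-topic daily means around 150–200, the trailing-mean detector's
per-day false-flag probability is below $10^{-3}$ (a 30% excursion is
≳3.4 Poisson standard deviations), which is what makes the
injection-recovery checks feasible at 100 replicates.

## Affective analysis

The affect classifier is hierarchical. Its growth machinery inserts words
under the root according to the sorted top-3 softmax outputs
$o_1 \ge o_2 \ge o_3$ at a node with thresholds α = β = 0.1:

* $o_1 - o_2 > \alpha$ (node not full) → **add to the best child**;
* $o_1 - o_2 < \alpha$ and $o_2 - o_3 > \beta$ → **merge the two best
  children** into a new branch and add the word there;
* both gaps small, or the node full → **new child**.

Boundary equalities (the published rules use strict inequalities only)
resolve to `new_child`, the most conservative structural action, and are
logged. Structural limits default to depth ≤ 3 and ≤ 5 children per
branch. A full node first merges its two most likely children to free a
slot; when the depth limit forbids even that, the default behavior files
the word into the best existing child (logged as `capacity_fallback`) so
long insertion streams complete — `strict = TRUE` raises a capacity error
instead. The word-routing reading (nodes hold words) is implemented
literally; the growth rules themselves are identical under a
class-incremental reading.

Trained node classifiers are softmax scorers over token counts
(width-1 "convolution" = bag of tokens; width 3 adds hashed
consecutive-token window features), trained by mini-batch SGD with
momentum 0.9, weight decay 0.001, learning rate 0.1 and (at full scale)
300 epochs, recording per-epoch loss. The production tree is two-level:
the root separates polarity groups, group nodes separate their emotions.
Polarity maps joy and surprise to positive and anger/disgust/fear/sadness
to negative; surprise's polarity is config-exposed since no published
mapping fixes it.

## Evaluation metrics

From confusion counts: accuracy, sensitivity (recall), precision,
F-measure $2PR/(P+R)$, and the G-mean
$\sqrt{\mathrm{TP_{rate}} \times \mathrm{TN_{rate}}}$. Any metric with a
zero denominator is reported as `NA` with a reason — never silently 0.
Multi-class reports are one-vs-rest per class, macro-averaged (the
reduction is not fixed by the metric definitions; macro is invariant to
relabeling). Detection latency is the signed day offset between a
detected onset and the injected start, matched by (region, topic);
unmatched injections are misses, excluded from the mean offset and
counted in the miss rate.

## Numerical and design choices

* Softmax scores subtract the row maximum before exponentiation (shift
  invariance doubles as an overflow guard); probabilities are floored at
  `1e-300` inside logs.
* All seeding derives from one integer via a fixed affine map into the
  32-bit range; generation, fold assignment, k-means, SGD shuffling and
  RBM initialization each get their own derived seed, so stages are
  independently reproducible. (A per-user counter-based RNG substream was
  considered and dropped: stage-level derived seeds give the same
  reproducibility with far less machinery.)
* k-means uses 5 restarts under a derived seed; when K equals the number
  of distinct feature vectors the distinct rows seed the centers directly.
* The pipeline trains the affect classifier on a bounded annotated subset
  (3,000 messages) standing in for assessor-labeled data; inference covers
  the full stream.
* Problem sizes in the shipped tests: topic recovery uses a 5,000-message
  ten-topic stream with 10-fold CV; emotion recovery 1,200 messages with
  an 80/20 split; injection recovery 100 event streams and 100 quiet
  streams of ~6,000 messages each; the end-to-end pipeline check uses two
  regions × 100 users × 30 days. These sizes put the Monte-Carlo
  tolerances (3 standard errors) well inside the asserted margins.

## Known limitations

* Headline accuracies from real-world deployments of this architecture are
  tied to private datasets and human annotation; the package's checks are
  property-based (oracle equivalence, separable-recovery, permutation
  nulls, injection recovery) and say nothing about accuracy on real text.
* The detector is univariate per (region, topic); no spatial correlation
  across cities and no multiscale analysis.
* The DBN brings no benefit on the synthetic pseudo-language (whose topics
  are linearly separable by construction); it earns its keep only on
  high-dimensional real vocabularies.
* Language handling is token-level only; the `iso_language_code` field is
  trusted and no translation is attempted.

## A worked example

```{r example, eval = FALSE}
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
res$attributed$dominant_subtopic
autoplot(res$counts)
autoplot(res$emotion_windows[[1]])
```
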