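#' Confusion counts
#'
#' @param TP,TN,FP,FN Non-negative integer counts.
#' @return A list of class `confusion_counts` with the counts plus the
#'   positive/negative totals `p`, `n`.
#' @export
confusion_counts <- function(TP, TN, FP, FN) {
  counts <- c(TP = TP, TN = TN, FP = FP, FN = FN)
  if (any(counts < 0)) abort("confusion counts must be non-negative.")
  structure(list(TP = TP, TN = TN, FP = FP, FN = FN,
                 p = TP + FN, n = TN + FP),
            class = "confusion_counts")
}

#' Classification metrics from confusion counts
#'
#' Accuracy `(TP+TN)/(TP+TN+FP+FN)`, sensitivity (recall) `TP/(TP+FN)`,
#' precision `TP/(TP+FP)`, F-measure `2PR/(P+R)`, and the G-mean
#' `sqrt(TP_rate x TN_rate)` with `TP_rate = TP/p`, `TN_rate = TN/n`. A
#' metric with a zero denominator is reported as `NA` with a reason — never
#' silently as 0.
#'
#' @param c A [confusion_counts()] object (or TP/TN/FP/FN given directly).
#' @return A tibble (metric, value, note) of class `metric_report`.
#' @export
compute_metrics <- function(c) {
  if (!inherits(c, "confusion_counts")) c <- do.call(confusion_counts, as.list(c))
  total <- c$TP + c$TN + c$FP + c$FN
  if (total == 0) abort("all confusion counts are zero.")
  safe <- function(num, den, what) {
    if (den == 0) list(value = NA_real_, note = sprintf("undefined: %s", what))
    else list(value = num / den, note = NA_character_)
  }
  acc <- safe(c$TP + c$TN, total, "no samples")
  sens <- safe(c$TP, c$TP + c$FN, "no positive samples")
  prec <- safe(c$TP, c$TP + c$FP, "no positive predictions")
  f <- if (is.na(sens$value) || is.na(prec$value) ||
           (prec$value + sens$value) == 0) {
    list(value = NA_real_, note = "undefined: precision + recall is zero or undefined")
  } else {
    list(value = 2 * prec$value * sens$value / (prec$value + sens$value),
         note = NA_character_)
  }
  tpr <- safe(c$TP, c$p, "no positive samples")
  tnr <- safe(c$TN, c$n, "no negative samples")
  g <- if (is.na(tpr$value) || is.na(tnr$value)) {
    list(value = NA_real_, note = "undefined: a class rate has zero denominator")
  } else {
    list(value = sqrt(tpr$value * tnr$value), note = NA_character_)
  }
  out <- tibble(
    metric = c("accuracy", "sensitivity", "precision", "f_measure", "g_mean"),
    value = c(acc$value, sens$value, prec$value, f$value, g$value),
    note = c(acc$note, sens$note, prec$note, f$note, g$note)
  )
  structure(out, class = c("metric_report", class(out)))
}

#' Multi-class metrics by one-vs-rest macro-averaging
#'
#' Each class is scored one-vs-rest with [compute_metrics()]; macro averages
#' ignore classes whose metric is undefined. Invariant to class relabeling.
#'
#' @param truth,pred Vectors of class labels.
#' @param classes Class set (default: observed).
#' @return A list with `per_class` (tibble) and `macro` (named list).
#' @export
multiclass_metrics <- function(truth, pred, classes = NULL) {
  if (is.null(classes)) classes <- sort(unique(c(truth, pred)))
  per <- bind_rows(lapply(classes, function(cl) {
    cc <- confusion_counts(
      TP = sum(truth == cl & pred == cl),
      TN = sum(truth != cl & pred != cl),
      FP = sum(truth != cl & pred == cl),
      FN = sum(truth == cl & pred != cl)
    )
    mutate(compute_metrics(cc), class = cl, .before = 1)
  }))
  macro <- per |>
    group_by(.data$metric) |>
    summarise(value = mean(.data$value, na.rm = TRUE), .groups = "drop")
  list(per_class = per, macro = setNames(as.list(macro$value), macro$metric))
}

#' Detection latency against injected ground truth
#'
#' Matches detected events to injections by (region, topic) and reports the
#' signed day offset (detected onset minus injected start). Unmatched
#' injections are misses: they are excluded from the mean offset and counted
#' in the miss rate.
#'
#' @param events Detected events tibble (region, topic, onset, direction).
#' @param injections Tibble of ground truth (region, topic, start_date), or
#'   a list of [event_injection()]s plus the spec's `start_date`.
#' @param directions Which event directions may match (default increases).
#' @return A list with `offsets` tibble (region, topic, start_date,
#'   detected_onset, offset_days, missed) and a `summary` list (mean_offset,
#'   miss_rate, n).
#' @export
detection_latency <- function(events, injections,
                              directions = c("increase")) {
  ev <- filter(events, .data$direction %in% directions)
  rows <- lapply(seq_len(nrow(injections)), function(i) {
    hit <- ev |>
      filter(.data$region == injections$region[i],
             .data$topic == injections$topic[i]) |>
      arrange(.data$onset) |>
      head(1)
    if (nrow(hit) == 0) {
      tibble(region = injections$region[i], topic = injections$topic[i],
             start_date = injections$start_date[i],
             detected_onset = as.Date(NA), offset_days = NA_real_,
             missed = TRUE)
    } else {
      tibble(region = injections$region[i], topic = injections$topic[i],
             start_date = injections$start_date[i],
             detected_onset = hit$onset,
             offset_days = as.numeric(hit$onset - injections$start_date[i]),
             missed = FALSE)
    }
  })
  offsets <- bind_rows(rows)
  list(offsets = offsets,
       summary = list(
         mean_offset = if (any(!offsets$missed))
           mean(offsets$offset_days[!offsets$missed]) else NA_real_,
         miss_rate = mean(offsets$missed),
         n = nrow(offsets)
       ))
}
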