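#' Read a pipeline configuration from YAML
#'
#' One structured document drives every stage. Unknown keys are rejected and
#' the schema is versioned (`schema_version: 1`). Nested sections `spec`,
#' `detector`, `rules`, and `affect` map onto [stream_spec()],
#' [detector_config()], [noise_rules()], and [tree_cnn_config()]; events are
#' given as a list of mappings with the [event_injection()] fields.
#'
#' @param path Path to a YAML file.
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    abort("the 'yaml' package is required to read YAML configs.")
  }
  doc <- yaml::read_yaml(path)
  check_keys <- function(x, allowed, where) {
    extra <- setdiff(names(x), allowed)
    if (length(extra)) {
      abort(sprintf("unknown key(s) in %s: %s", where,
                    paste(extra, collapse = ", ")))
    }
  }
  check_keys(doc, c("schema_version", "spec", "detector", "rules",
                    "topic_folds", "topic_lambda", "affect", "affect_epochs",
                    "subtopic_source", "dbn_hidden", "dbn_epochs",
                    "subtopic_k", "seed"), "config")
  if (!identical(as.integer(doc$schema_version %||% NA), 1L)) {
    abort("config must declare `schema_version: 1`.")
  }

  spec <- NULL
  if (!is.null(doc$spec)) {
    sp <- doc$spec
    check_keys(sp, c("regions", "users_per_region", "topics", "topic_shares",
                     "base_rate", "n_days", "start_date",
                     "follow_distribution", "p_home_community", "p_declared",
                     "communities_per_region", "events", "seed"), "spec")
    events <- lapply(sp$events %||% list(), function(ev) {
      check_keys(ev, c("region", "topic", "subtopic", "start_day",
                       "duration_days", "rate_multiplier", "emotion_shift"),
                 "event")
      do.call(event_injection, ev)
    })
    args <- sp[setdiff(names(sp), "events")]
    if (!is.null(args$topics)) args$vocab <- default_vocab(args$topics)
    if (!is.null(args$topic_shares)) args$topic_shares <- unlist(args$topic_shares)
    if (!is.null(args$follow_distribution)) {
      args$follow_distribution <- unlist(args$follow_distribution)
    }
    spec <- do.call(stream_spec, c(args, list(events = events)))
  }

  detector <- do.call(detector_config, doc$detector %||% list())
  rules <- do.call(noise_rules, doc$rules %||% list())
  affect <- do.call(tree_cnn_config, doc$affect %||% list())
  extra <- doc[intersect(names(doc), c("topic_folds", "topic_lambda",
                                       "affect_epochs", "subtopic_source",
                                       "dbn_hidden", "dbn_epochs",
                                       "subtopic_k", "seed"))]
  do.call(pipeline_config, c(list(spec = spec, detector = detector,
                                  rules = rules, affect = affect), extra))
}
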