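#' Noise-filter rules
#'
#' Thresholds for spam/bot/ad removal: a user posting the same text at least
#' `duplicate_threshold` times within `duplicate_window_hours` keeps only the
#' first copy (spam); messages whose URL token density exceeds
#' `max_url_density` are ads; a user exceeding `max_user_daily` messages in a
#' calendar day has the excess dropped as bot traffic.
#'
#' @param duplicate_threshold Minimum duplicate count that triggers removal.
#' @param duplicate_window_hours Window for duplicate detection.
#' @param max_url_density Maximum fraction of URL tokens.
#' @param max_user_daily Maximum messages per user per day.
#' @return A list of class `noise_rules`.
#' @export
noise_rules <- function(duplicate_threshold = 3, duplicate_window_hours = 1,
                        max_url_density = 0.5, max_user_daily = 50) {
  structure(list(duplicate_threshold = duplicate_threshold,
                 duplicate_window_hours = duplicate_window_hours,
                 max_url_density = max_url_density,
                 max_user_daily = max_user_daily),
            class = "noise_rules")
}

is_url_token <- function(tok) grepl("^(https?://|www\\.)", tok, ignore.case = TRUE)

#' Remove spam, bot, and ad messages
#'
#' Partitions the input into kept and removed messages; every removal is
#' logged with the rule that fired. Kept plus removed always equals the
#' input.
#'
#' @param messages Message tibble (id, text, username, created_at).
#' @param rules A [noise_rules()] object.
#' @return A list with `messages` (kept rows) and `audit` (id, rule, detail).
#' @export
filter_noise <- function(messages, rules = noise_rules()) {
  if (nrow(messages) == 0L) {
    return(list(messages = messages,
                audit = tibble(id = character(), rule = character(),
                               detail = character())))
  }
  drop_rule <- rep(NA_character_, nrow(messages))
  detail <- rep(NA_character_, nrow(messages))

  # ad rule: URL density
  dens <- vapply(strsplit(messages$text, "\\s+"), function(tk) {
    tk <- tk[nzchar(tk)]
    if (!length(tk)) return(0)
    mean(is_url_token(tk))
  }, numeric(1))
  ad <- dens > rules$max_url_density
  drop_rule[ad] <- "ad"
  detail[ad] <- sprintf("url_density=%.2f", dens[ad])

  # spam rule: near-simultaneous duplicates by the same user
  ord <- order(messages$username, messages$text, messages$created_at)
  win <- rules$duplicate_window_hours * 3600
  key <- paste(messages$username[ord], messages$text[ord], sep = "\r")
  for (rows in split(ord, factor(key, levels = unique(key)))) {
    if (length(rows) < rules$duplicate_threshold) next
    t0 <- messages$created_at[rows[1]]
    in_win <- rows[as.numeric(messages$created_at[rows]) - as.numeric(t0) <= win]
    if (length(in_win) >= rules$duplicate_threshold) {
      dup <- setdiff(in_win, in_win[1])
      dup <- dup[is.na(drop_rule[dup])]
      drop_rule[dup] <- "spam"
      detail[dup] <- sprintf("duplicate_of=%s", messages$id[in_win[1]])
    }
  }

  # bot rule: per-user daily rate cap
  day <- as.Date(messages$created_at, tz = "UTC")
  for (rows in split(seq_len(nrow(messages)),
                     list(messages$username, day), drop = TRUE)) {
    rows <- rows[is.na(drop_rule[rows])]
    if (length(rows) > rules$max_user_daily) {
      rows <- rows[order(messages$created_at[rows])]
      excess <- rows[-seq_len(rules$max_user_daily)]
      drop_rule[excess] <- "bot"
      detail[excess] <- sprintf("daily_rate>%d", rules$max_user_daily)
    }
  }

  dropped <- !is.na(drop_rule)
  list(
    messages = messages[!dropped, , drop = FALSE],
    audit = tibble(id = messages$id[dropped], rule = drop_rule[dropped],
                   detail = detail[dropped])
  )
}

#' Segment a hashtag into vocabulary words
#'
#' Greedy longest-match left-to-right segmentation of the case-folded tag
#' body. When no vocabulary word matches at the current position, the
#' remainder is kept as a single lowercased token (so an entirely
#' unsegmentable tag comes back whole).
#'
#' @param tag A hashtag beginning with `#`.
#' @param vocabulary Character vector of known words.
#' @return Character vector of words.
#' @export
segment_hashtag <- function(tag, vocabulary) {
  stopifnot(startsWith(tag, "#"))
  body <- tolower(substring(tag, 2))
  if (!nzchar(body)) return(character(0))
  vocabulary <- tolower(vocabulary)
  out <- character(0)
  pos <- 1L
  nb <- nchar(body)
  while (pos <= nb) {
    hit <- ""
    for (len in seq_len(nb - pos + 1L)) {
      cand <- substr(body, pos, pos + len - 1L)
      if (cand %in% vocabulary) hit <- cand
    }
    if (nzchar(hit)) {
      out <- c(out, hit)
      pos <- pos + nchar(hit)
    } else {
      out <- c(out, substr(body, pos, nb))
      break
    }
  }
  out
}

#' Normalize tokens
#'
#' Lowercases, maps synonyms to their canonical forms, replaces
#' out-of-lexicon tokens that have a unique edit-distance-1 lexicon
#' neighbour (ambiguous or distant tokens are kept as-is), and removes
#' stopwords.
#'
#' @param tokens Character vector.
#' @param synonym_map Named character vector (token -> canonical form).
#' @param spell_lexicon Character vector of known words.
#' @param stopwords Character vector of stopwords to drop.
#' @return Normalized character vector.
#' @export
normalize_tokens <- function(tokens, synonym_map = character(0),
                             spell_lexicon = character(0),
                             stopwords = character(0)) {
  if (!length(tokens)) return(character(0))
  tokens <- tolower(tokens)
  hit <- tokens %in% names(synonym_map)
  tokens[hit] <- unname(synonym_map[tokens[hit]])
  if (length(spell_lexicon)) {
    # correction only targets purely alphabetic out-of-lexicon tokens;
    # one batched edit-distance computation over the unique candidates
    cand <- unique(tokens[!(tokens %in% spell_lexicon |
                              tokens %in% unname(synonym_map)) &
                            grepl("^[a-z]+$", tokens)])
    if (length(cand)) {
      D <- adist(cand, spell_lexicon)
      n1 <- rowSums(D == 1)
      fixable <- which(n1 == 1)
      if (length(fixable)) {
        repl <- setNames(
          spell_lexicon[apply(D[fixable, , drop = FALSE] == 1, 1, which)],
          cand[fixable])
        idx <- tokens %in% names(repl)
        tokens[idx] <- unname(repl[tokens[idx]])
      }
    }
  }
  tokens[!tokens %in% stopwords & nzchar(tokens)]
}

#' Lemmatize tokens by table lookup
#'
#' Unknown words pass through unchanged; applying the operation twice equals
#' applying it once provided the table maps lemmas to themselves (or leaves
#' them out).
#'
#' @param tokens Character vector.
#' @param lemma_table Named character vector (word -> lemma).
#' @return Character vector of lemmas.
#' @export
lemmatize_tokens <- function(tokens, lemma_table = character(0)) {
  hit <- tokens %in% names(lemma_table)
  tokens[hit] <- unname(lemma_table[tokens[hit]])
  tokens
}

#' Load plain-text lexicons
#'
#' Reads `stopwords.txt` (one word per line), `synonyms.tsv` and `lemmas.tsv`
#' (word TAB canonical), and `segment_vocab.txt` (one word per line) from a
#' directory. Missing files yield empty lexicons. The package ships an
#' illustrative English set under `inst/extdata/lexicons`.
#'
#' @param dir Directory path; defaults to the packaged lexicons.
#' @return A list with `stopwords`, `synonyms`, `lemmas`, `segment_vocab`,
#'   `spell_lexicon`.
#' @export
load_lexicons <- function(dir = system.file("extdata", "lexicons", package = "osnevents")) {
  read_lines_safe <- function(f) {
    p <- file.path(dir, f)
    if (file.exists(p)) readr::read_lines(p, progress = FALSE) else character(0)
  }
  read_map <- function(f) {
    p <- file.path(dir, f)
    if (!file.exists(p)) return(character(0))
    d <- readr::read_tsv(p, col_names = c("word", "canonical"),
                         col_types = "cc", progress = FALSE)
    setNames(d$canonical, d$word)
  }
  stopwords <- read_lines_safe("stopwords.txt")
  synonyms <- read_map("synonyms.tsv")
  lemmas <- read_map("lemmas.tsv")
  segment_vocab <- read_lines_safe("segment_vocab.txt")
  list(stopwords = stopwords, synonyms = synonyms, lemmas = lemmas,
       segment_vocab = segment_vocab,
       spell_lexicon = unique(c(segment_vocab, unname(synonyms), names(lemmas),
                                unname(lemmas))))
}

#' Run the full preprocessing chain
#'
#' Fixed stage order: noise filtering, synonym/spelling normalization,
#' hashtag segmentation (segmented words are appended after the text
#' tokens), stopword removal, lemmatization. Messages removed by the noise
#' filter are kept in the output with `dropped = TRUE` and a single drop
#' reason.
#'
#' @param messages Message tibble (id, text, username, created_at, hashtags).
#' @param lexicons A lexicon list as from [load_lexicons()].
#' @param rules A [noise_rules()] object.
#' @return Tibble with id, tokens (list-column), dropped, drop_reason.
#' @export
preprocess_messages <- function(messages, lexicons = load_lexicons(),
                                rules = noise_rules()) {
  filt <- filter_noise(messages, rules)
  kept <- filt$messages
  n <- nrow(kept)

  # corpus-wide vectorized pass; per-message order is preserved throughout
  tk_list <- strsplit(kept$text, "\\s+")
  all_tok <- unlist(tk_list)
  doc <- rep(seq_len(n), lengths(tk_list))
  ok <- nzchar(all_tok) & !is_url_token(all_tok)
  tag_mask <- ok & startsWith(all_tok, "#")
  text_tok <- tolower(all_tok[ok & !tag_mask])
  text_doc <- doc[ok & !tag_mask]

  # synonyms, then batched unique-distance-1 spelling correction
  hit <- text_tok %in% names(lexicons$synonyms)
  text_tok[hit] <- unname(lexicons$synonyms[text_tok[hit]])
  if (length(lexicons$spell_lexicon)) {
    cand <- unique(text_tok[!(text_tok %in% lexicons$spell_lexicon) &
                              grepl("^[a-z]+$", text_tok)])
    if (length(cand)) {
      D <- adist(cand, lexicons$spell_lexicon)
      fixable <- which(rowSums(D == 1) == 1)
      if (length(fixable)) {
        repl <- setNames(
          lexicons$spell_lexicon[apply(D[fixable, , drop = FALSE] == 1, 1, which)],
          cand[fixable])
        idx <- text_tok %in% names(repl)
        text_tok[idx] <- unname(repl[text_tok[idx]])
      }
    }
  }

  # hashtags from text plus the hashtags field, deduplicated per message,
  # segmented once per distinct tag
  tag_tok <- all_tok[tag_mask]
  tag_doc <- doc[tag_mask]
  if ("hashtags" %in% names(kept)) {
    extra <- kept$hashtags
    tag_tok <- c(tag_tok, unlist(extra))
    tag_doc <- c(tag_doc, rep(seq_len(n), lengths(extra)))
  }
  dedup <- !duplicated(paste(tag_doc, tag_tok, sep = "\r"))
  tag_tok <- tag_tok[dedup]; tag_doc <- tag_doc[dedup]
  seg_cache <- lapply(setNames(unique(tag_tok), unique(tag_tok)),
                      segment_hashtag, vocabulary = lexicons$segment_vocab)
  seg_list <- seg_cache[tag_tok]
  seg_tok <- unlist(seg_list, use.names = FALSE)
  seg_doc <- rep(tag_doc, lengths(seg_list))

  # text tokens first, segmented hashtag words appended (stable order)
  comb_tok <- c(text_tok, seg_tok)
  comb_doc <- c(text_doc, seg_doc)
  src <- c(rep(0L, length(text_tok)), rep(1L, length(seg_tok)))
  o <- order(comb_doc, src)
  comb_tok <- comb_tok[o]; comb_doc <- comb_doc[o]

  keep_tok <- !comb_tok %in% lexicons$stopwords
  comb_tok <- lemmatize_tokens(comb_tok[keep_tok], lexicons$lemmas)
  comb_doc <- comb_doc[keep_tok]
  tokens <- unname(split(comb_tok, factor(comb_doc, levels = seq_len(n))))

  out_kept <- tibble(id = kept$id, tokens = tokens,
                     dropped = FALSE, drop_reason = NA_character_)
  out_drop <- tibble(id = filt$audit$id, tokens = rep(list(character(0)),
                                                      nrow(filt$audit)),
                     dropped = TRUE, drop_reason = filt$audit$rule)
  ord <- match(messages$id, c(out_kept$id, out_drop$id))
  bind_rows(out_kept, out_drop)[ord, , drop = FALSE]
}
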