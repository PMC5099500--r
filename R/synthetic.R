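# Seeded generator of labeled tweet corpora with the statistical structure
# the cascade assumes, so every stage is testable without platform access.
#
# Generative story per tweet:
#   * length ~ Poisson(tweet_length_mean), clipped to >= 3 tokens;
#   * each token slot carries a class-specific "topic" token with probability
#     signal_strength, otherwise a background token;
#   * sentiment-bearing tweets additionally receive at most ONE
#     lexicon-valenced "affect" token (probability affect_rate) — explicit
#     sentiment words are sparse in real tweets, which is what limits a
#     lexicon baseline's recall;
#   * positive tweets draw that affect token from an INVERTED set
#     (conventionally negative words used approvingly: "faded", "wasted",
#     "fucked", "lean") with probability inversion_rate — the domain
#     phenomenon where "bad" means "good";
#   * media/retail tweets always carry a URL, personal tweets with
#     probability url_rate_personal; every short URL is an opaque t.co code,
#     and the accompanying resolver table expands it to a host/path that
#     names its class (news-like for media, shop-like for retail) with
#     probability url_signal_strength;
#   * media/retail tweets labeled for sentiment keep their source topic
#     vocabulary, making them noisy for sentiment classifiers — the reason
#     filtering to personal communication helps.
# Only synthetic token strings plus a small curated set of real drug-domain
# words (to exercise tokenizer edge cases) are used; no real user content.

synthetic_vocab <- function(background_vocab_size = 200L) {
  list(
    background = sprintf("w%03d", seq_len(background_vocab_size)),
    source = list(
      personal = c("wanna", "chill", "tonight", "friends", "homie", "blunts",
                   "smoke", "sesh", "vibes", "dab", "joint", "roll"),
      media = c("breaking", "report", "study", "legalization", "policy",
                "lawmakers", "vote", "ballot", "industry", "medical",
                "regulation", "headline"),
      retail = c("sale", "shop", "discount", "order", "shipping", "vape",
                 "store", "deal", "promo", "stock", "gummies", "cartridge")
    ),
    sentiment = list(
      positive = c("dank", "loud", "smooth", "blessed", "relax", "enjoy",
                   "fire", "mellow", "sweet", "prime"),
      negative = c("ban", "arrest", "addiction", "overdose", "penalized",
                   "illegal", "dangerous", "problem", "quit", "regret"),
      neutral = c("today", "weather", "random", "class", "work", "game",
                  "watch", "episode", "tomorrow", "meeting")
    ),
    affect = list(
      positive = c("love", "great", "good", "best", "happy"),
      inverted = c("faded", "wasted", "fucked", "lean"),
      negative = c("hate", "shit", "fake", "ridiculous", "terrible")
    ),
    url = list(
      personal = list(hosts = c("pics.example.net", "myblog.example.org"),
                      words = c("photo", "status", "post", "album", "note", "page")),
      media = list(hosts = c("cannabiswire.example.com", "drugnewsdaily.example.org"),
                   words = c("news", "politics", "legalization", "report",
                             "policy", "marijuana")),
      retail = list(hosts = c("budshop420.example.com", "greenleafstore.example.net"),
                    words = c("shop", "buy", "cannabis", "oil", "discount", "cart"))
    ),
    generic_hosts = c("linkhub.example.com"),
    generic_words = c("page", "item", "view", "entry", "link", "site")
  )
}

#' Generative parameters for a synthetic corpus
#'
#' @param n Corpus size.
#' @param source_counts Named counts over [source_levels()] (optional; tweets
#'   get source labels when present). Must sum to `n`.
#' @param sentiment_counts Named counts over [sentiment_levels()] (optional).
#'   Must sum to `n`.
#' @param signal_strength Probability a token slot carries a class topic
#'   token rather than background noise.
#' @param url_signal_strength Probability an expanded URL names its source
#'   class in host/path words.
#' @param affect_rate Probability a positive/negative tweet carries one
#'   explicit lexicon-valenced affect token.
#' @param inversion_rate Fraction of positive tweets whose affect token comes
#'   from the inverted (conventionally negative) set.
#' @param background_vocab_size Size of the background token vocabulary.
#' @param tweet_length_mean Mean token count (Poisson, clipped at 3).
#' @param url_rate_personal Probability a personal tweet carries a URL.
#' @param all_urls Force a URL onto every tweet (the composition of a
#'   URL-bearing source training sample).
#' @param length_cap Character cap the generated texts must respect (140, the
#'   platform limit of the era being emulated).
#' @param seed Mandatory integer seed.
#' @return A `synthetic_spec`.
#' @export
synthetic_spec <- function(n, source_counts = NULL, sentiment_counts = NULL,
                           signal_strength = 0.8, url_signal_strength = 0.9,
                           affect_rate = 0.6, inversion_rate = 0.3,
                           background_vocab_size = 200L, tweet_length_mean = 12,
                           url_rate_personal = 0.35, all_urls = FALSE,
                           length_cap = 140L, seed) {
  if (missing(seed)) stop_f("a seed is mandatory for synthetic corpora")
  n <- as.integer(n)
  check_counts <- function(counts, levels, what) {
    if (is.null(counts)) return(NULL)
    if (!all(names(counts) %in% levels)) {
      stop_f("%s counts use unknown labels: %s", what,
             paste(setdiff(names(counts), levels), collapse = ", "))
    }
    counts <- counts[counts > 0]
    if (sum(counts) != n) stop_f("%s counts must sum to n = %d (got %d)",
                                 what, n, sum(counts))
    counts
  }
  probs <- c(signal_strength, url_signal_strength, affect_rate,
             inversion_rate, url_rate_personal)
  if (any(probs < 0 | probs > 1)) stop_f("probabilities must lie in [0, 1]")
  structure(list(
    n = n,
    source_counts = check_counts(source_counts, source_levels(), "source"),
    sentiment_counts = check_counts(sentiment_counts, sentiment_levels(), "sentiment"),
    signal_strength = signal_strength,
    url_signal_strength = url_signal_strength,
    affect_rate = affect_rate,
    inversion_rate = inversion_rate,
    background_vocab_size = as.integer(background_vocab_size),
    tweet_length_mean = tweet_length_mean,
    url_rate_personal = url_rate_personal,
    all_urls = isTRUE(all_urls),
    length_cap = as.integer(length_cap),
    seed = as.integer(seed)
  ), class = "synthetic_spec")
}

expand_labels <- function(counts, n) {
  if (is.null(counts)) return(rep(NA_character_, n))
  sample(rep(names(counts), times = counts))
}

short_codes <- function(n) {
  alphabet <- c(letters, 0:9)
  repeat {
    codes <- vapply(seq_len(n), function(i) {
      paste(sample(alphabet, 8, replace = TRUE), collapse = "")
    }, character(1))
    if (!anyDuplicated(codes)) return(codes)
  }
}

#' Generate a labeled synthetic corpus
#'
#' Deterministic given the spec's seed. Returns the corpus together with an
#' offline resolver table for its short URLs and a manifest recording every
#' generating parameter and the per-tweet latent assignments, so any corpus
#' can be regenerated exactly.
#'
#' @param spec A [synthetic_spec()].
#' @return A `synthetic_corpus`: list with `corpus` (a `tweet_corpus`),
#'   `resolver` (a [url_resolver()]), and `manifest`.
#' @export
generate_corpus <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  withr::with_seed(spec$seed, generate_corpus_impl(spec))
}

generate_corpus_impl <- function(spec) {
  n <- spec$n
  vocab <- synthetic_vocab(spec$background_vocab_size)
  src <- expand_labels(spec$source_counts, n)
  sent <- expand_labels(spec$sentiment_counts, n)
  lens <- pmax(3L, stats::rpois(n, spec$tweet_length_mean))
  codes <- short_codes(n)
  texts <- character(n)
  url_lists <- vector("list", n)
  shorts <- character(0)
  expandeds <- character(0)
  inverted <- logical(n)
  has_url <- logical(n)

  for (i in seq_len(n)) {
    topic_class <- if (!is.na(src[i]) && src[i] != "personal") {
      vocab$source[[src[i]]]                       # organizational voice
    } else if (!is.na(sent[i])) {
      vocab$sentiment[[sent[i]]]
    } else if (!is.na(src[i])) {
      vocab$source[[src[i]]]
    } else {
      vocab$background
    }
    len <- lens[i]
    is_signal <- stats::runif(len) < spec$signal_strength
    toks <- character(len)
    toks[is_signal] <- sample(topic_class, sum(is_signal), replace = TRUE)
    toks[!is_signal] <- sample(vocab$background, sum(!is_signal), replace = TRUE)
    if (!is.na(sent[i]) && sent[i] != "neutral" &&
        stats::runif(1) < spec$affect_rate) {
      if (sent[i] == "positive") {
        inverted[i] <- stats::runif(1) < spec$inversion_rate
        aff <- sample(if (inverted[i]) vocab$affect$inverted else
                      vocab$affect$positive, 1)
      } else {
        aff <- sample(vocab$affect$negative, 1)
      }
      at <- sample(len + 1L, 1)
      toks <- append(toks, aff, after = at - 1L)
    }
    if (stats::runif(1) < 0.10) toks <- c(sprintf("@user%04d", sample(9999L, 1)), toks)
    if (stats::runif(1) < 0.15 && any(is_signal)) {
      j <- which(is_signal)[1]
      toks[j] <- paste0("#", sub("^@", "", toks[j]))
    }
    cls <- if (!is.na(src[i])) src[i] else "personal"
    has_url[i] <- spec$all_urls ||
      (cls != "personal") ||
      stats::runif(1) < spec$url_rate_personal
    url <- character(0)
    if (has_url[i]) {
      short <- paste0("https://t.co/", codes[i])
      on_signal <- stats::runif(1) < spec$url_signal_strength
      host <- if (on_signal) sample(vocab$url[[cls]]$hosts, 1) else
        sample(vocab$generic_hosts, 1)
      words <- if (on_signal) sample(vocab$url[[cls]]$words, 2) else
        sample(vocab$generic_words, 2)
      expanded <- paste0("https://", host, "/", paste(words, collapse = "-"))
      shorts <- c(shorts, short)
      expandeds <- c(expandeds, expanded)
      url <- short
    }
    txt <- paste(c(toks, url), collapse = " ")
    while (nchar(txt) > spec$length_cap && length(toks) > 3) {
      toks <- toks[-length(toks)]
      txt <- paste(c(toks, url), collapse = " ")
    }
    texts[i] <- txt
    url_lists[[i]] <- url
  }

  corpus <- as_corpus(
    tibble::tibble(
      id = sprintf("syn%06d", seq_len(n)),
      text = texts,
      urls = url_lists,
      lang = "en",
      source = src,
      sentiment = sent
    ),
    metadata = list(generator = "tweetcascade synthetic", seed = spec$seed,
                    spec = unclass(spec)),
    length_cap = spec$length_cap
  )
  resolver <- url_resolver(stats::setNames(expandeds, shorts))
  manifest <- list(
    spec = unclass(spec),
    latent = tibble::tibble(id = corpus$id, source = src, sentiment = sent,
                            inverted = inverted, has_url = has_url)
  )
  structure(list(corpus = corpus, resolver = resolver, manifest = manifest),
            class = "synthetic_corpus")
}

#' The three benchmark fixture corpora
#'
#' Seeded fixtures whose label compositions equal the printed compositions of
#' the labeled data sets the pipeline was designed around:
#' \describe{
#'   \item{source}{1000 URL-bearing tweets — 330 personal, 330 media, 340
#'     retail (source-classifier training composition).}
#'   \item{sentiment}{3000 tweets — 1292 positive, 921 negative, 787
#'     neutral/unidentifiable, with a latent source composition of 2633
#'     personal / 184 media / 183 retail so the personal-filtering cascade is
#'     exercisable.}
#'   \item{personal_sentiment}{2633 all-personal tweets — 1157 positive, 850
#'     negative, 626 neutral (the composition of a classifier-extracted
#'     personal subset).}
#' }
#'
#' @param seed Base seed (each fixture derives its own from it).
#' @return Named list of `synthetic_corpus` objects.
#' @export
default_fixtures <- function(seed = 2015L) {
  list(
    source = generate_corpus(synthetic_spec(
      1000, source_counts = c(personal = 330, media = 330, retail = 340),
      url_rate_personal = 1, all_urls = TRUE, seed = seed)),
    sentiment = generate_corpus(synthetic_spec(
      3000,
      source_counts = c(personal = 2633, media = 184, retail = 183),
      sentiment_counts = c(positive = 1292, negative = 921, neutral = 787),
      seed = seed + 1L)),
    personal_sentiment = generate_corpus(synthetic_spec(
      2633,
      source_counts = c(personal = 2633),
      sentiment_counts = c(positive = 1157, negative = 850, neutral = 626),
      seed = seed + 2L))
  )
}

#' Write a synthetic corpus bundle to a directory
#'
#' Emits `corpus.jsonl`, `resolver.tsv`, `lexicon.tsv` (the default lexicon)
#' and `manifest.json`.
#'
#' @param synth A `synthetic_corpus`.
#' @param dir Output directory (created if needed).
#' @export
write_synthetic <- function(synth, dir) {
  stopifnot(inherits(synth, "synthetic_corpus"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_corpus(synth$corpus, file.path(dir, "corpus.jsonl"))
  write_resolver_table(synth$resolver, file.path(dir, "resolver.tsv"))
  write_lexicon(default_lexicon(), file.path(dir, "lexicon.tsv"))
  manifest <- synth$manifest
  manifest$latent <- as.data.frame(manifest$latent)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(dir)
}
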