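# Keyword/blacklist relevance filter with co-occurrence rules for ambiguous
# drug slang. Three term sets drive the decision:
#   unambiguous terms  — sufficient alone ("cannabis")
#   ambiguous terms    — slang whose everyday reading dominates ("blunt",
#                        "spice"); each must co-occur with one of its usage
#                        terms ("smoke", "smoked", "smoking") to count
#   blacklist          — phrases that exclude the tweet outright ("emily
#                        blunt", "pumpkin spice latte"); checked first, since
#                        a blacklisted phrase can contain a tracked term
# Matching is case-insensitive on token boundaries ("blunted" never matches
# "blunt"); multiword phrases match as contiguous token sequences.

#' Compile a keyword configuration
#'
#' Normalizes all terms to lowercase and enforces the invariants: the three
#' term sets must be disjoint, phrases non-empty, and the configuration not
#' empty overall.
#'
#' @param unambiguous Character vector of phrases sufficient alone.
#' @param ambiguous Named list: slang phrase -> character vector of required
#'   co-occurring usage terms.
#' @param blacklist Character vector of excluding phrases.
#' @return A `keyword_config` with term counts attached.
#' @export
keyword_config <- function(unambiguous = character(0), ambiguous = list(),
                           blacklist = character(0)) {
  norm <- function(x) tolower(trimws(x))
  unambiguous <- norm(unambiguous)
  blacklist <- norm(blacklist)
  if (length(ambiguous)) {
    names(ambiguous) <- norm(names(ambiguous))
    ambiguous <- lapply(ambiguous, norm)
  }
  amb_terms <- names(ambiguous) %||% character(0)
  all_terms <- c(unambiguous, amb_terms, blacklist)
  if (!length(all_terms)) stop_f("empty keyword configuration")
  if (any(!nzchar(all_terms)) || any(!nzchar(unlist(ambiguous) %||% "x"))) {
    stop_f("keyword configuration contains empty phrases")
  }
  overlap <- c(intersect(unambiguous, blacklist), intersect(unambiguous, amb_terms),
               intersect(amb_terms, blacklist))
  if (length(overlap)) {
    stop_f("term(s) listed in more than one section: %s",
           paste(unique(overlap), collapse = ", "))
  }
  structure(list(unambiguous = unambiguous, ambiguous = ambiguous,
                 blacklist = blacklist),
            class = "keyword_config")
}

#' Read a keyword configuration from YAML
#'
#' Expected sections: `unambiguous` (list of phrases), `ambiguous` (map of
#' phrase -> usage terms), `blacklist` (list of phrases).
#'
#' @param path YAML file.
#' @return A `keyword_config`.
#' @export
read_keyword_config <- function(path) {
  raw <- yaml::read_yaml(path)
  keyword_config(
    unambiguous = as.character(raw$unambiguous %||% character(0)),
    ambiguous = lapply(raw$ambiguous %||% list(), as.character),
    blacklist = as.character(raw$blacklist %||% character(0))
  )
}

phrase_in_tokens <- function(tokens, phrase) {
  pt <- strsplit(phrase, " ", fixed = TRUE)[[1]]
  np <- length(pt)
  nt <- length(tokens)
  if (np == 0 || nt < np) return(FALSE)
  if (np == 1) return(pt %in% tokens)
  for (s in seq_len(nt - np + 1)) {
    if (all(tokens[s:(s + np - 1)] == pt)) return(TRUE)
  }
  FALSE
}

#' Keep/drop decision for one tweet
#'
#' Decision order: non-English language tag -> drop; any blacklist phrase ->
#' drop (blacklist dominates keywords); any unambiguous term -> keep; any
#' ambiguous term together with one of its usage terms -> keep; otherwise
#' drop. Deterministic and independent of config listing order.
#'
#' @param tweet A one-row `tweet_corpus`, a list with `text` (and optional
#'   `lang`), or a bare text string.
#' @param config A [keyword_config()].
#' @return List with `decision` (`"keep"`/`"drop"`), `matched` (terms that
#'   fired) and `reason`.
#' @export
filter_tweet <- function(tweet, config) {
  stopifnot(inherits(config, "keyword_config"))
  if (is.character(tweet)) tweet <- list(text = tweet, lang = NA_character_)
  lang <- tweet$lang %||% NA_character_
  if (length(lang) && !is.na(lang) && !startsWith(tolower(lang), "en")) {
    return(list(decision = "drop", matched = character(0), reason = "language"))
  }
  tokens <- tokenize(as.character(tweet$text))
  bl <- config$blacklist[vapply(config$blacklist, phrase_in_tokens,
                                logical(1), tokens = tokens)]
  if (length(bl)) {
    return(list(decision = "drop", matched = bl, reason = "blacklist"))
  }
  un <- config$unambiguous[vapply(config$unambiguous, phrase_in_tokens,
                                  logical(1), tokens = tokens)]
  if (length(un)) {
    return(list(decision = "keep", matched = un, reason = "unambiguous"))
  }
  for (term in names(config$ambiguous)) {
    if (phrase_in_tokens(tokens, term)) {
      usage <- config$ambiguous[[term]]
      hit <- usage[vapply(usage, phrase_in_tokens, logical(1), tokens = tokens)]
      if (length(hit)) {
        return(list(decision = "keep", matched = c(term, hit),
                    reason = "ambiguous+usage"))
      }
    }
  }
  list(decision = "drop", matched = character(0), reason = "no_keyword")
}

#' Filter a corpus through a keyword configuration
#'
#' @param corpus A `tweet_corpus`.
#' @param config A [keyword_config()].
#' @return The kept subset, with a `filter_report` attribute counting
#'   decisions by reason.
#' @export
filter_corpus <- function(corpus, config) {
  decisions <- lapply(seq_len(nrow(corpus)), function(i) {
    filter_tweet(list(text = corpus$text[i], lang = corpus$lang[i]), config)
  })
  keep <- vapply(decisions, function(d) d$decision == "keep", logical(1))
  reasons <- vapply(decisions, `[[`, character(1), "reason")
  out <- corpus_slice(corpus, keep)
  attr(out, "filter_report") <- list(
    n_in = nrow(corpus), n_kept = sum(keep),
    by_reason = table(reasons)
  )
  out
}

#' An illustrative default keyword configuration
#'
#' The authoritative keyword and blacklist lists used by production
#' surveillance platforms are not public; this default is a small,
#' non-authoritative illustration of the structure (tracked cannabis and
#' synthetic-cannabinoid terms, ambiguous slang bound to usage terms, and a
#' blacklist for common false positives).
#'
#' @return A `keyword_config`.
#' @export
default_keyword_config <- function() {
  keyword_config(
    unambiguous = c("cannabis", "marijuana", "weed", "dabs", "edibles",
                    "synthetic cannabinoid", "k2 spice"),
    ambiguous = list(
      blunt = c("smoke", "smoked", "smoking", "roll", "rolling", "lit"),
      spice = c("smoke", "smoked", "smoking", "high", "synthetic"),
      lean = c("drink", "drank", "drinking", "sip", "sipping"),
      pot = c("smoke", "smoked", "smoking", "high", "stoned")
    ),
    blacklist = c("emily blunt", "pumpkin spice latte", "pumpkin spice",
                  "spice girls", "pot roast", "lean startup")
  )
}
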