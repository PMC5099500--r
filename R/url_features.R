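# URL detection, short-URL expansion and URL-token features. Expanded URLs
# (hosts and path words) carry strong source signal — media articles and
# retail storefronts name themselves in their links — while platform-shortened
# links (t.co) are opaque codes.

#' Extract URLs from text
#'
#' @param text A single character string.
#' @return Character vector of `http(s)` URLs in text order, with trailing
#'   punctuation trimmed.
#' @export
extract_urls <- function(text) {
  if (is.na(text) || !nzchar(text)) return(character(0))
  m <- regmatches(text, gregexpr("https?://[^[:space:]]+", text, perl = TRUE))[[1]]
  sub("[.,;:!?'\"\\)\\]]+$", "", m, perl = TRUE)
}

#' Short-URL resolver
#'
#' Offline mode (the default, and the only mode used in tests) resolves by
#' lookup in a short -> expanded table and never touches the network. Live
#' mode follows redirects through a caller-supplied `fetcher` function (given
#' a URL, return the redirect target or `NA` when the response is final),
#' bounded by `max_redirects`; chains that do not terminate are reported
#' unresolved, never raised as errors.
#'
#' @param table Named character vector (`names` = short URL, values =
#'   expanded) or a two-column data frame `(short, expanded)`.
#' @param mode `"offline"` or `"live"`.
#' @param max_redirects Redirect-following bound for live mode.
#' @param fetcher Function used in live mode; defaults to an error stub so
#'   offline use can never accidentally hit the network.
#' @return A `url_resolver`.
#' @export
url_resolver <- function(table = NULL, mode = c("offline", "live"),
                         max_redirects = 10L, fetcher = NULL) {
  mode <- match.arg(mode)
  if (is.data.frame(table)) {
    table <- stats::setNames(as.character(table[[2]]), as.character(table[[1]]))
  }
  if (mode == "offline" && is.null(table)) table <- character(0)
  structure(list(mode = mode, table = table,
                 max_redirects = as.integer(max_redirects),
                 fetcher = fetcher),
            class = "url_resolver")
}

#' Read a resolver table from TSV
#'
#' @param path Two-column TSV (short, expanded), no header.
#' @return A `url_resolver` in offline mode.
#' @export
read_resolver_table <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE, quote = "",
                          comment.char = "", stringsAsFactors = FALSE,
                          col.names = c("short", "expanded"))
  url_resolver(df)
}

#' Expand a short URL
#'
#' @param url The URL as it appears in the tweet.
#' @param resolver A [url_resolver()].
#' @return The expanded URL, or `NA_character_` when the URL cannot be
#'   resolved (absent from the table, or the live redirect chain exceeded
#'   `max_redirects`).
#' @export
expand_url <- function(url, resolver) {
  stopifnot(inherits(resolver, "url_resolver"))
  if (!grepl("^https?://", url)) stop_f("malformed URL: %s", url)
  if (resolver$mode == "offline") {
    hit <- resolver$table[url]
    return(if (is.na(hit)) NA_character_ else unname(hit))
  }
  if (is.null(resolver$fetcher)) stop_f("live resolver needs a fetcher function")
  cur <- url
  for (i in seq_len(resolver$max_redirects)) {
    nxt <- tryCatch(resolver$fetcher(cur), error = function(e) NA_character_)
    if (is.na(nxt)) return(cur)   # final location reached
    cur <- nxt
  }
  NA_character_                   # still redirecting after the bound
}

url_word_split <- function(x) {
  t <- strsplit(x, "[^a-z0-9]+")[[1]]
  t <- t[nzchar(t)]
  t[nchar(t) >= 2 & !grepl("^[0-9]+$", t)]
}

prefix_url_ngrams <- function(toks) {
  if (!length(toks)) return(character(0))
  uni <- paste0("url:", toks)
  if (length(toks) >= 2) {
    c(uni, paste0("url:", toks[-length(toks)], " ", toks[-1]))
  } else uni
}

#' n-gram features from a URL
#'
#' The (expanded) URL is lowercased, the scheme dropped, and host + path split
#' on non-alphanumeric characters; pure-numeric tokens and tokens shorter than
#' 2 characters are discarded. Unigrams plus adjacent bigrams are emitted,
#' each carrying the reserved `"url:"` prefix so URL-borne words never collide
#' with the same words in tweet text. Unresolved URLs contribute only the host
#' tokens of the original short URL.
#'
#' @param expanded Expanded URL, or `NA` when unresolved.
#' @param original The short URL as it appeared in the tweet (used as the
#'   fallback when `expanded` is `NA`).
#' @return Character vector of prefixed URL n-grams.
#' @export
url_tokens <- function(expanded, original = NULL) {
  if (is.null(expanded) || is.na(expanded)) {
    if (is.null(original) || is.na(original)) return(character(0))
    host <- sub("^https?://", "", tolower(original))
    host <- sub("[/?#].*$", "", host)
    return(prefix_url_ngrams(url_word_split(host)))
  }
  u <- sub("^https?://", "", tolower(expanded))
  prefix_url_ngrams(url_word_split(u))
}

# URL n-grams for one tweet's URL list under a given approach.
# approach 1: host tokens of the short URLs as-is (no expansion); presence of
# a URL and its host are the only signals shortened links offer.
# approach 2: expand, tokenize the full expanded URL; fall back to short-URL
# host tokens when unresolved.
tweet_url_ngrams <- function(urls, approach, resolver = NULL) {
  if (!length(urls)) return(character(0))
  out <- lapply(urls, function(u) {
    if (approach == 1) {
      url_tokens(NA_character_, original = u)
    } else {
      url_tokens(expand_url(u, resolver), original = u)
    }
  })
  unlist(out) %||% character(0)
}

#' Write a resolver table to TSV
#'
#' @param resolver A `url_resolver` (offline) or two-column data frame.
#' @param path Output file.
#' @export
write_resolver_table <- function(resolver, path) {
  tab <- if (inherits(resolver, "url_resolver")) resolver$table else
    stats::setNames(as.character(resolver[[2]]), as.character(resolver[[1]]))
  con <- file(path, open = "w", encoding = "UTF-8")
  writeLines(paste(names(tab), tab, sep = "\t"), con)
  close(con)
  invisible(path)
}
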