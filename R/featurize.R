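# Bag-of-words featurization: lowercase tokenization (stop words retained, no
# stemming), unigram+bigram collection, one-vs-rest chi-square feature
# selection capped at k, and raw-count tf x ln(N/df) weighting.

MENTION_SENTINEL <- "xmentionplaceholderx"

#' Tokenize tweet text
#'
#' Lowercases the text and splits it into maximal runs of letters, digits and
#' apostrophes. URLs are removed from the token stream (they are handled
#' separately as URL features), `#` is stripped from hashtags so the word is
#' kept, and user mentions are replaced by the anonymized placeholder token
#' `"@user"`. Stop words are retained and no stemming is applied: in texts as
#' short as tweets, function words and full word forms carry sentiment signal.
#'
#' @param text A single character string.
#' @return Character vector of tokens in text order.
#' @export
tokenize <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  if (is.na(text) || !nzchar(text)) return(character(0))
  x <- gsub("https?://[^[:space:]]+", " ", text, perl = TRUE)
  x <- gsub("@[A-Za-z0-9_]+", paste0(" ", MENTION_SENTINEL, " "), x, perl = TRUE)
  x <- gsub("#([\\p{L}\\p{N}_])", "\\1", x, perl = TRUE)
  x <- tolower(x)
  toks <- regmatches(x, gregexpr("[\\p{L}\\p{N}'’]+", x, perl = TRUE))[[1]]
  toks <- toks[grepl("[\\p{L}\\p{N}]", toks, perl = TRUE)]
  toks[toks == MENTION_SENTINEL] <- "@user"
  toks
}

#' Collect unigrams and bigrams
#'
#' @param tokens Character vector of tokens (from [tokenize()]).
#' @return Character vector holding every unigram and every adjacent bigram
#'   (two tokens joined by one space), with multiplicities.
#' @export
extract_ngrams <- function(tokens) {
  n <- length(tokens)
  if (n == 0) return(character(0))
  if (n == 1) return(tokens)
  c(tokens, paste(tokens[-n], tokens[-1]))
}

#' Text + URL n-grams for every tweet in a corpus
#'
#' Builds the per-tweet n-gram multisets the classifiers consume: unigrams and
#' bigrams of the tokenized text, plus (optionally) URL-derived tokens. With
#' `approach = 1` each URL contributes the host tokens of the short URL as it
#' appears in the tweet; with `approach = 2` URLs are first expanded through
#' `resolver` and the full expanded URL is tokenized (unresolved URLs fall
#' back to short-URL host tokens). `approach = NULL` adds no URL features
#' (the configuration used for sentiment tasks).
#'
#' @param corpus A `tweet_corpus`.
#' @param approach `NULL`, `1` (short URLs) or `2` (expanded URLs).
#' @param resolver A [url_resolver()]; required for `approach = 2`.
#' @return List (one element per tweet) of n-gram character vectors.
#' @export
corpus_ngrams <- function(corpus, approach = NULL, resolver = NULL) {
  text_ngrams <- lapply(corpus$text, function(t) extract_ngrams(tokenize(t)))
  if (is.null(approach)) return(text_ngrams)
  stopifnot(approach %in% c(1, 2))
  if (approach == 2 && is.null(resolver)) {
    stop_f("approach 2 needs a url_resolver to expand short URLs")
  }
  lapply(seq_len(nrow(corpus)), function(i) {
    c(text_ngrams[[i]], tweet_url_ngrams(corpus$urls[[i]], approach, resolver))
  })
}

#' Chi-square association scores for candidate features
#'
#' For each candidate feature, builds the 2x2 presence/absence x class/rest
#' contingency table for every class and computes the chi-square statistic
#' (no continuity correction); the feature's score is the maximum over
#' classes, the usual reduction for multiclass selection.
#'
#' @param doc_ngrams List of per-document n-gram vectors (or a `tweet_corpus`,
#'   in which case text n-grams are derived and `labels` may name a label
#'   axis).
#' @param labels Class label per document (or axis name when `doc_ngrams` is a
#'   corpus).
#' @param candidates Restrict scoring to these features (default: every n-gram
#'   observed in the documents).
#' @return Named numeric vector of scores.
#' @export
chi_square_scores <- function(doc_ngrams, labels, candidates = NULL) {
  if (inherits(doc_ngrams, "tweet_corpus")) {
    corpus <- doc_ngrams
    if (is.character(labels) && length(labels) == 1 && labels %in% c("source", "sentiment")) {
      labels <- corpus[[labels]]
    }
    doc_ngrams <- corpus_ngrams(corpus)
  }
  stopifnot(length(doc_ngrams) == length(labels))
  if (any(is.na(labels))) stop_f("chi-square scoring needs a label for every document")
  labels <- as.character(labels)
  classes <- unique(labels)
  if (length(classes) < 2) stop_f("chi-square selection needs at least 2 classes")
  uniq <- lapply(doc_ngrams, unique)
  feats <- candidates %||% sort(unique(unlist(uniq)))
  if (!length(feats)) return(stats::setNames(numeric(0), character(0)))
  jj <- match(unlist(uniq), feats)
  ii <- rep.int(seq_along(uniq), lengths(uniq))
  keep <- !is.na(jj)
  P <- Matrix::sparseMatrix(i = ii[keep], j = jj[keep], x = 1,
                            dims = c(length(uniq), length(feats)))
  n <- length(labels)
  df <- Matrix::colSums(P)
  best <- numeric(length(feats))
  for (cl in classes) {
    y <- as.numeric(labels == cl)
    a <- as.vector(Matrix::crossprod(P, y))   # present & class
    nc <- sum(y)
    b <- df - a                               # present & rest
    cc <- nc - a                              # absent & class
    d <- n - nc - b                           # absent & rest
    num <- n * (a * d - b * cc)^2
    den <- (a + b) * (cc + d) * (a + cc) * (b + d)
    s <- ifelse(den > 0, num / den, 0)
    best <- pmax(best, s)
  }
  stats::setNames(best, feats)
}

#' Keep the top-k features by chi-square score
#'
#' Ties at the selection boundary are broken by ascending lexicographic
#' feature string so selection is deterministic and serialized feature spaces
#' are diffable.
#'
#' @param scores Named numeric vector from [chi_square_scores()].
#' @param df Named integer vector of document frequencies (training corpus).
#' @param n Number of training documents.
#' @param k Selection cap (default 500).
#' @return A `feature_space`: list with `features` (ordered by descending
#'   score), `df`, `chi2`, `n`, `k`.
#' @export
select_features <- function(scores, df, n, k = 500L) {
  if (k <= 0) stop_f("k must be positive")
  if (!length(scores)) stop_f("no candidate features to select from")
  ord <- order(-scores, names(scores))
  keep <- utils::head(ord, k)
  feats <- names(scores)[keep]
  if (any(is.na(df[feats])) || any(df[feats] < 1)) {
    stop_f("selected features must have document frequency >= 1")
  }
  structure(list(features = feats,
                 df = stats::setNames(as.integer(df[feats]), feats),
                 chi2 = stats::setNames(as.numeric(scores[keep]), feats),
                 n = as.integer(n), k = as.integer(k)),
            class = "feature_space")
}

#' Build a feature space from training documents
#'
#' Convenience wrapper: candidate n-grams, document frequencies and chi-square
#' scores are computed from the supplied (training) documents and the top-k
#' features retained. Must only ever see training data — inside
#' cross-validation it is re-fit per fold so no information leaks from held-out
#' tweets.
#'
#' @inheritParams chi_square_scores
#' @param k Selection cap.
#' @return A `feature_space`.
#' @export
build_feature_space <- function(doc_ngrams, labels, k = 500L) {
  if (inherits(doc_ngrams, "tweet_corpus")) {
    corpus <- doc_ngrams
    if (is.character(labels) && length(labels) == 1 && labels %in% c("source", "sentiment")) {
      labels <- corpus[[labels]]
    }
    doc_ngrams <- corpus_ngrams(corpus)
  }
  scores <- chi_square_scores(doc_ngrams, labels)
  uniq <- lapply(doc_ngrams, unique)
  df_tab <- table(unlist(uniq))
  df <- stats::setNames(as.integer(df_tab), names(df_tab))
  select_features(scores, df, n = length(doc_ngrams), k = k)
}

#' tf-idf vectors over a feature space
#'
#' Each document is represented by its selected features weighted as
#' `w(i,j) = tf(i,j) * ln(N / df(i))`: `tf` is the raw occurrence count of the
#' feature in the document, `N` the number of training documents and `df` the
#' number of training documents containing the feature. The natural logarithm
#' is used (the base only rescales all weights uniformly); there is no
#' sublinear damping, idf smoothing or vector normalization. Features not in
#' the space are ignored.
#'
#' @param doc_ngrams A single n-gram vector or a list of them.
#' @param space A `feature_space` built on training data.
#' @return Sparse `dgCMatrix`, one row per document, columns named by the
#'   space's features.
#' @export
vectorize <- function(doc_ngrams, space) {
  stopifnot(inherits(space, "feature_space"))
  if (is.character(doc_ngrams)) doc_ngrams <- list(doc_ngrams)
  if (any(space$df < 1)) stop_f("feature space invariant breached: df = 0")
  nf <- length(space$features)
  idf <- log(space$n / space$df)
  per_doc <- lapply(seq_along(doc_ngrams), function(d) {
    j <- match(doc_ngrams[[d]], space$features)
    j <- j[!is.na(j)]
    if (!length(j)) return(NULL)
    tf <- tabulate(j, nbins = nf)
    nz <- which(tf > 0)
    list(i = rep.int(d, length(nz)), j = nz, x = tf[nz] * idf[nz])
  })
  per_doc <- per_doc[!vapply(per_doc, is.null, logical(1))]
  Matrix::sparseMatrix(i = unlist(lapply(per_doc, `[[`, "i")) %||% integer(0),
                       j = unlist(lapply(per_doc, `[[`, "j")) %||% integer(0),
                       x = unlist(lapply(per_doc, `[[`, "x")) %||% numeric(0),
                       dims = c(length(doc_ngrams), nf),
                       dimnames = list(NULL, space$features))
}

#' Serialize / deserialize a feature space as TSV
#'
#' The file starts with a `# n=<N> k=<k>` comment line followed by the columns
#' `feature`, `df`, `chi2` in the space's deterministic order.
#'
#' @param space A `feature_space`.
#' @param path File path.
#' @export
write_feature_space <- function(space, path) {
  stopifnot(inherits(space, "feature_space"))
  con <- file(path, open = "w", encoding = "UTF-8")
  writeLines(sprintf("# n=%d k=%d", space$n, space$k), con)
  writeLines("feature\tdf\tchi2", con)
  writeLines(sprintf("%s\t%d\t%.10g", space$features, space$df, space$chi2), con)
  close(con)
  invisible(path)
}

#' @rdname write_feature_space
#' @export
read_feature_space <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  hdr <- regmatches(lines[1], regexec("^# n=(\\d+) k=(\\d+)$", lines[1]))[[1]]
  if (length(hdr) != 3) stop_f("malformed feature-space header: %s", lines[1])
  body <- lines[-(1:2)]
  parts <- strsplit(body, "\t", fixed = TRUE)
  feats <- vapply(parts, `[[`, character(1), 1)
  structure(list(
    features = feats,
    df = stats::setNames(as.integer(vapply(parts, `[[`, character(1), 2)), feats),
    chi2 = stats::setNames(as.numeric(vapply(parts, `[[`, character(1), 3)), feats),
    n = as.integer(hdr[2]), k = as.integer(hdr[3])),
    class = "feature_space")
}

#' Print method
#' @exportS3Method base::print
#' @keywords internal
print.feature_space <- function(x, ...) {
  cat(sprintf("<feature_space> %d features (cap %d) from %d training tweets\n",
              length(x$features), x$k, x$n))
  cat("  top:", paste(utils::head(x$features, 8), collapse = ", "), "\n")
  invisible(x)
}
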