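# Lexicon-and-rule sentiment baseline: a valence dictionary with negation and
# booster heuristics and a bounded compound score, the comparator family that
# trained classifiers are measured against. Capitalization emphasis,
# punctuation amplification and emoji handling found in full social-media
# lexicon tools are deliberately omitted (the tokenizer lowercases); the
# baseline's role here is the comparison contract, not bit-compatibility with
# any particular tool.

#' Build a sentiment lexicon
#'
#' @param valence Named numeric vector: token -> valence in `[-4, 4]`.
#' @param negators Tokens that invert a following sentiment word.
#' @param boosters Named numeric vector: intensifier token -> increment added
#'   toward the sign of the boosted valence.
#' @param negation_factor Multiplier applied to a valence with a negator in
#'   the preceding window (default -0.74).
#' @param alpha Normalization constant of the compound score (default 15).
#' @param window How many preceding tokens are searched for negators and
#'   boosters (default 3).
#' @return A `sentiment_lexicon`.
#' @export
sentiment_lexicon <- function(valence, negators = character(0),
                              boosters = numeric(0), negation_factor = -0.74,
                              alpha = 15, window = 3L) {
  stopifnot(is.numeric(valence), length(valence) > 0, !is.null(names(valence)))
  names(valence) <- tolower(names(valence))
  negators <- tolower(negators)
  if (length(boosters)) names(boosters) <- tolower(names(boosters))
  structure(list(valence = valence, negators = negators, boosters = boosters,
                 negation_factor = negation_factor, alpha = alpha,
                 window = as.integer(window)),
            class = "sentiment_lexicon")
}

#' A small illustrative lexicon
#'
#' Ships for tests and examples; real deployments should supply a full
#' lexicon file via [read_lexicon()]. Valences follow the conventional (not
#' drug-domain) readings — which is exactly why the baseline degrades on
#' domain-inverted usage such as "faded" or "lean" used approvingly.
#'
#' @return A `sentiment_lexicon`.
#' @export
default_lexicon <- function() {
  sentiment_lexicon(
    valence = c(
      love = 3.2, great = 3.1, good = 1.9, best = 3.2, happy = 2.7,
      amazing = 2.8, win = 2.4,
      bad = -2.5, hate = -2.7, shit = -2.6, fake = -2.1, ridiculous = -1.9,
      terrible = -2.1, ignorant = -1.9, worst = -3.1,
      faded = -1.8, wasted = -2.2, fucked = -2.6, lean = -1.2
    ),
    negators = c("not", "don't", "never", "no", "cannot", "can't", "won't",
                 "ain't", "isn't", "doesn't", "didn't"),
    boosters = c(very = 0.293, really = 0.293, so = 0.293, extremely = 0.293,
                 totally = 0.293)
  )
}

#' Read a lexicon from TSV
#'
#' Columns `token`, `value`, `role` (role one of `valence`, `negator`,
#' `booster`; header row required). Negators ignore `value`; boosters use it
#' as the increment.
#'
#' @param path TSV file.
#' @return A `sentiment_lexicon`.
#' @export
read_lexicon <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, quote = "",
                          comment.char = "", stringsAsFactors = FALSE)
  if (!all(c("token", "value", "role") %in% names(df))) {
    stop_f("lexicon TSV needs token/value/role columns")
  }
  v <- df[df$role == "valence", ]
  ng <- df$token[df$role == "negator"]
  b <- df[df$role == "booster", ]
  sentiment_lexicon(stats::setNames(as.numeric(v$value), v$token),
                    negators = ng,
                    boosters = stats::setNames(as.numeric(b$value), b$token))
}

#' Write a lexicon to TSV
#'
#' @param lexicon A `sentiment_lexicon`.
#' @param path Output file.
#' @export
write_lexicon <- function(lexicon, path) {
  df <- rbind(
    data.frame(token = names(lexicon$valence), value = unname(lexicon$valence),
               role = "valence", stringsAsFactors = FALSE),
    if (length(lexicon$negators))
      data.frame(token = lexicon$negators, value = 0, role = "negator",
                 stringsAsFactors = FALSE),
    if (length(lexicon$boosters))
      data.frame(token = names(lexicon$boosters), value = unname(lexicon$boosters),
                 role = "booster", stringsAsFactors = FALSE)
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Compound sentiment score of a token sequence
#'
#' Valences of lexicon tokens are summed left to right. A negator within the
#' `window` preceding tokens multiplies the valence by `negation_factor`;
#' each booster in the window then adds its increment toward the (possibly
#' negated) valence's sign. The summed valence `S` is squashed to
#' `S / sqrt(S^2 + alpha)`, a strictly increasing map of the sum into
#' `(-1, 1)`; a text with no lexicon tokens scores exactly 0.
#'
#' @param tokens Character vector from [tokenize()] (a bare string is
#'   tokenized first).
#' @param lexicon A `sentiment_lexicon`.
#' @return Compound score in `(-1, 1)`.
#' @export
score_text <- function(tokens, lexicon = default_lexicon()) {
  stopifnot(inherits(lexicon, "sentiment_lexicon"))
  if (length(tokens) == 1 && grepl("\\s", tokens)) tokens <- tokenize(tokens)
  s <- 0
  for (i in seq_along(tokens)) {
    v <- lexicon$valence[tokens[i]]
    if (is.na(v)) next
    v <- unname(v)
    win <- tokens[seq.int(max(1L, i - lexicon$window), length.out = min(i - 1L, lexicon$window))]
    if (any(win %in% lexicon$negators)) v <- v * lexicon$negation_factor
    for (bt in win[win %in% names(lexicon$boosters)]) {
      v <- v + sign(v) * lexicon$boosters[[bt]]
    }
    s <- s + v
  }
  s / sqrt(s^2 + lexicon$alpha)
}

#' Map a compound score to a sentiment label
#'
#' Positive at or above `+threshold`, negative at or below `-threshold`,
#' neutral otherwise — so a tweet in which no sentiment word or pattern is
#' found (compound 0) lands in the neutral category.
#'
#' @param compound Compound score in `[-1, 1]`.
#' @param threshold Decision threshold (default 0.05).
#' @return A sentiment label string.
#' @export
classify_sentiment_lexicon <- function(compound, threshold = 0.05) {
  ifelse(compound >= threshold, "positive",
         ifelse(compound <= -threshold, "negative", "neutral"))
}

#' Lexicon-baseline sentiment labels for a corpus
#'
#' @param corpus A `tweet_corpus`.
#' @param lexicon A `sentiment_lexicon`.
#' @param threshold Decision threshold.
#' @return Character vector of sentiment labels.
#' @export
lexicon_classify <- function(corpus, lexicon = default_lexicon(), threshold = 0.05) {
  compounds <- vapply(corpus$text, function(t) score_text(tokenize(t), lexicon),
                      numeric(1), USE.NAMES = FALSE)
  classify_sentiment_lexicon(compounds, threshold)
}

#' Evaluate the lexicon baseline on the same folds as a trained classifier
#'
#' The baseline needs no training, but scoring it per held-out fold makes its
#' per-fold F-scores directly pairable with cross-validated classifiers in
#' [compare_classifiers()].
#'
#' @param corpus Sentiment-labeled `tweet_corpus`.
#' @param lexicon A `sentiment_lexicon`.
#' @param folds A [make_folds()] assignment (default: fresh 5-fold split with
#'   `seed`).
#' @param k,seed Used when `folds` is not supplied.
#' @param threshold Decision threshold.
#' @return An `eval_report` with algorithm `"lexicon"`.
#' @export
evaluate_lexicon <- function(corpus, lexicon = default_lexicon(), folds = NULL,
                             k = 5L, seed = 1L, threshold = 0.05) {
  labels <- corpus$sentiment
  if (any(is.na(labels))) stop_f("every tweet must carry a sentiment label")
  folds <- folds %||% make_folds(corpus, k = k, seed = seed)
  k <- attr(folds, "k") %||% k
  pred_all <- lexicon_classify(corpus, lexicon, threshold)
  classes <- sort(unique(labels))
  per_class <- vector("list", k)
  macro <- vector("list", k)
  for (f in seq_len(k)) {
    te <- folds == f
    m <- classification_metrics(labels[te], pred_all[te], classes = classes)
    m$fold <- f
    per_class[[f]] <- m[m$class != "macro", ]
    macro[[f]] <- m[m$class == "macro", c("fold", "precision", "recall", "f")]
  }
  new_eval_report(dplyr::bind_rows(per_class), dplyr::bind_rows(macro),
                  "lexicon", "sentiment", k, attr(folds, "seed") %||% seed)
}
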