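# 5-fold cross-validation, per-class and macro precision/recall/F, and paired
# one-tailed t-test comparison of per-fold F-scores.

#' Random fold assignment
#'
#' Uniform (unstratified) random partition into `k` near-equal folds: a seeded
#' permutation chopped into blocks whose sizes differ by at most one.
#'
#' @param x A `tweet_corpus` or an integer number of items.
#' @param k Fold count (default 5).
#' @param seed Seed making the assignment reproducible.
#' @return Integer vector of fold indices in `1..k` (named by tweet id when a
#'   corpus is given), with `k` and `seed` attributes.
#' @export
make_folds <- function(x, k = 5L, seed = 1L) {
  n <- if (inherits(x, "tweet_corpus")) nrow(x) else as.integer(x)
  k <- as.integer(k)
  if (k < 2) stop_f("k must be at least 2")
  if (k > n) stop_f("cannot split %d items into %d folds", n, k)
  perm <- withr::with_seed(seed, sample.int(n))
  sizes <- rep(n %/% k, k)
  r <- n %% k
  if (r > 0) sizes[seq_len(r)] <- sizes[seq_len(r)] + 1L
  fold <- integer(n)
  fold[perm] <- rep(seq_len(k), times = sizes)
  if (inherits(x, "tweet_corpus")) names(fold) <- x$id
  structure(fold, k = k, seed = seed)
}

#' Precision, recall and F for one class
#'
#' `precision = TP/(TP+FP)`, `recall = TP/(TP+FN)`, `F = 2PR/(P+R)` (harmonic
#' mean). Zero-denominator conventions: a metric whose denominator is zero is
#' reported as 0 and the result is flagged.
#'
#' @param gold Gold labels.
#' @param predicted Predicted labels (same length).
#' @param class The class treated as "positive".
#' @return Named numeric `c(precision, recall, f)` with a logical `flagged`
#'   attribute marking zero-denominator conventions.
#' @export
per_class_metrics <- function(gold, predicted, class) {
  if (length(gold) != length(predicted)) stop_f("gold and predicted differ in length")
  if (!length(gold)) stop_f("no predictions to score")
  tp <- sum(gold == class & predicted == class)
  fp <- sum(predicted == class & gold != class)
  fn <- sum(gold == class & predicted != class)
  flagged <- FALSE
  p <- if (tp + fp > 0) tp / (tp + fp) else { flagged <- TRUE; 0 }
  r <- if (tp + fn > 0) tp / (tp + fn) else { flagged <- TRUE; 0 }
  f <- if (p + r > 0) 2 * p * r / (p + r) else { flagged <- TRUE; 0 }
  structure(c(precision = p, recall = r, f = f), flagged = flagged)
}

#' Macro average of per-class metrics
#'
#' Unweighted arithmetic mean of the per-class precision, recall and F values
#' (the standard "macro" reading; the per-class values are averaged, not
#' re-derived from pooled counts).
#'
#' @param metrics A matrix / data frame with columns `precision`, `recall`,
#'   `f` (one row per class), or a list of [per_class_metrics()] results.
#' @return Named numeric `c(precision, recall, f)`.
#' @export
macro_average <- function(metrics) {
  if (is.list(metrics) && !is.data.frame(metrics)) {
    metrics <- do.call(rbind, metrics)
  }
  metrics <- as.data.frame(metrics)
  if (!nrow(metrics)) stop_f("macro average needs at least one class")
  c(precision = mean(metrics$precision),
    recall = mean(metrics$recall),
    f = mean(metrics$f))
}

#' Per-class and macro metrics for one set of predictions
#'
#' @inheritParams per_class_metrics
#' @param classes Classes to score (default: every class present in `gold`).
#' @return Tibble with one row per class plus a `macro` row.
#' @export
classification_metrics <- function(gold, predicted, classes = NULL) {
  classes <- classes %||% sort(unique(gold))
  rows <- lapply(classes, function(cl) {
    m <- per_class_metrics(gold, predicted, cl)
    tibble::tibble(class = cl, precision = m[["precision"]],
                   recall = m[["recall"]], f = m[["f"]],
                   flagged = attr(m, "flagged"))
  })
  per_class <- dplyr::bind_rows(rows)
  mac <- macro_average(per_class[, c("precision", "recall", "f")])
  dplyr::bind_rows(per_class,
                   tibble::tibble(class = "macro", precision = mac[["precision"]],
                                  recall = mac[["recall"]], f = mac[["f"]],
                                  flagged = any(per_class$flagged)))
}

new_eval_report <- function(per_class, macro, algorithm, axis, k, seed, counts = list()) {
  structure(list(per_class = per_class, macro = macro,
                 mean_macro = c(precision = mean(macro$precision),
                                recall = mean(macro$recall),
                                f = mean(macro$f)),
                 fold_f = macro$f,
                 algorithm = algorithm, axis = axis, k = k, seed = seed,
                 counts = counts),
            class = "eval_report")
}

#' Cross-validated evaluation of the bag-of-words pipeline
#'
#' For each fold, chi-square feature selection and tf-idf statistics are
#' re-fit on the training folds only (no information from held-out tweets can
#' leak into the feature space), a classifier is trained and the held-out fold
#' scored. Per-class and macro precision/recall/F are reported per fold and
#' averaged.
#'
#' @param corpus Labeled `tweet_corpus`.
#' @param axis `"source"` or `"sentiment"`.
#' @param algorithm `"nb"`, `"lr"` or `"svm"`.
#' @param k Number of folds.
#' @param seed Seed for the fold assignment (and recorded with the models).
#' @param n_features Feature-selection cap (default 500).
#' @param approach URL-feature approach passed to [corpus_ngrams()] (`NULL`
#'   for text-only features, as used in sentiment tasks).
#' @param resolver [url_resolver()] for `approach = 2`.
#' @param hyper Hyperparameter overrides for the learner.
#' @param folds Optional precomputed [make_folds()] assignment (so different
#'   algorithms can be compared on identical folds).
#' @return An `eval_report`.
#' @export
cross_validate <- function(corpus, axis = c("source", "sentiment"),
                           algorithm = c("svm", "nb", "lr"), k = 5L, seed = 1L,
                           n_features = 500L, approach = NULL, resolver = NULL,
                           hyper = list(), folds = NULL) {
  axis <- match.arg(axis)
  algorithm <- match.arg(algorithm)
  labels <- corpus[[axis]]
  if (any(is.na(labels))) stop_f("every tweet must carry a %s label", axis)
  folds <- folds %||% make_folds(corpus, k = k, seed = seed)
  k <- attr(folds, "k") %||% k
  doc_ngrams <- corpus_ngrams(corpus, approach = approach, resolver = resolver)
  classes <- sort(unique(labels))
  per_class <- vector("list", k)
  macro <- vector("list", k)
  for (f in seq_len(k)) {
    tr <- folds != f
    if (length(unique(labels[tr])) < 2) {
      stop_f("fold %d: training data contains a single class", f)
    }
    space <- build_feature_space(doc_ngrams[tr], labels[tr], k = n_features)
    xtr <- vectorize(doc_ngrams[tr], space)
    xte <- vectorize(doc_ngrams[!tr], space)
    model <- train_classifier(algorithm, xtr, labels[tr], space = space,
                              hyper = hyper, seed = seed)
    pred <- predict(model, xte)
    m <- classification_metrics(labels[!tr], pred, classes = classes)
    m$fold <- f
    per_class[[f]] <- m[m$class != "macro", ]
    macro[[f]] <- m[m$class == "macro", c("fold", "precision", "recall", "f")]
  }
  new_eval_report(dplyr::bind_rows(per_class), dplyr::bind_rows(macro),
                  algorithm, axis, k, seed)
}

#' Paired one-tailed t-test between per-fold F-scores
#'
#' Tests H1: classifier `a` outperforms classifier `b` on average, pairing the
#' F-scores by shared fold (`t = mean(d) / (sd(d)/sqrt(n))`, `df = n - 1`,
#' upper-tail p). Degenerate zero-variance differences are flagged rather than
#' returned as NaN: p is 0, 1 or 0.5 according to the sign of the mean
#' difference (0.5 being the t = 0 convention). An unpaired Welch variant is
#' available via `paired = FALSE`.
#'
#' @param a,b Numeric vectors of per-fold F-scores (or `eval_report`s, whose
#'   `fold_f` is used), paired by position.
#' @param paired Use the paired test (default) or Welch's unpaired test.
#' @return List with `t`, `p`, `df`, `mean_diff`, `degenerate`.
#' @export
compare_classifiers <- function(a, b, paired = TRUE) {
  if (inherits(a, "eval_report")) a <- a$fold_f
  if (inherits(b, "eval_report")) b <- b$fold_f
  if (length(a) != length(b)) stop_f("fold score vectors differ in length")
  if (length(a) < 2) stop_f("need at least 2 folds to compare")
  if (!paired) {
    tt <- stats::t.test(a, b, alternative = "greater", paired = FALSE)
    return(list(t = unname(tt$statistic), p = unname(tt$p.value),
                df = unname(tt$parameter), mean_diff = mean(a) - mean(b),
                degenerate = FALSE))
  }
  d <- a - b
  n <- length(d)
  m <- mean(d)
  s <- stats::sd(d)
  if (s == 0) {
    p <- if (m > 0) 0 else if (m < 0) 1 else 0.5
    t <- if (m > 0) Inf else if (m < 0) -Inf else 0
    return(list(t = t, p = p, df = n - 1, mean_diff = m, degenerate = TRUE))
  }
  t <- m / (s / sqrt(n))
  list(t = t, p = stats::pt(t, df = n - 1, lower.tail = FALSE),
       df = n - 1, mean_diff = m, degenerate = FALSE)
}

#' Print method
#' @exportS3Method base::print
#' @keywords internal
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> %s on %s, %d-fold CV (seed %d)\n",
              x$algorithm, x$axis, x$k, x$seed))
  cat(sprintf("  mean macro: precision %.4f recall %.4f F %.4f\n",
              x$mean_macro[["precision"]], x$mean_macro[["recall"]],
              x$mean_macro[["f"]]))
  if (length(x$counts)) {
    cat("  counts:", paste(sprintf("%s=%s", names(x$counts), unlist(x$counts)),
                           collapse = " "), "\n")
  }
  invisible(x)
}

#' Write an evaluation report as TSV
#'
#' Emits a summary table in the layout of the published results tables (one
#' row per fold plus the mean, columns precision/recall/F) preceded by a
#' comment line recording seed and configuration hash.
#'
#' @param report An `eval_report`.
#' @param path Output file.
#' @param config Optional object hashed into the header for auditability.
#' @export
write_eval_report <- function(report, path, config = NULL) {
  con <- file(path, open = "w", encoding = "UTF-8")
  writeLines(sprintf("# algorithm=%s axis=%s k=%d seed=%d config=%s",
                     report$algorithm, report$axis, report$k, report$seed,
                     if (is.null(config)) "NA" else obj_hash(config)), con)
  writeLines("row\tprecision\trecall\tf", con)
  for (i in seq_len(nrow(report$macro))) {
    writeLines(sprintf("fold%d\t%.6f\t%.6f\t%.6f", report$macro$fold[i],
                       report$macro$precision[i], report$macro$recall[i],
                       report$macro$f[i]), con)
  }
  writeLines(sprintf("mean\t%.6f\t%.6f\t%.6f", report$mean_macro[["precision"]],
                     report$mean_macro[["recall"]], report$mean_macro[["f"]]), con)
  close(con)
  invisible(path)
}
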