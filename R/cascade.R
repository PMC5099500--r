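# End-to-end task assembly: source classification with the no-URL shortcut,
# personal-tweet filtering ahead of sentiment classification, binary task
# construction, and the orchestrating run_pipeline().
#
# The cascade rests on an empirical regularity of drug-related tweet streams:
# media and retail tweets always link out, so a tweet without a URL can be
# assigned to personal communication without consulting a model, and source
# models need only be trained on URL-bearing tweets.

#' Task specification for the pipeline
#'
#' @param task One of `"source_multiclass"`, `"source_binary"`,
#'   `"sentiment_multiclass"`, `"sentiment_binary"`.
#' @param target Target class for `source_binary` (one of
#'   [source_levels()]); the task becomes target-vs-rest.
#' @param approach For source tasks: 1 = short-URL features, 2 = expanded-URL
#'   features. For sentiment tasks: 1 = all tweets, 2 = personal
#'   communication tweets only (as identified by a source classifier).
#' @param algorithm `"nb"`, `"lr"` or `"svm"`.
#' @param n_features Feature-selection cap.
#' @param k Number of CV folds.
#' @param seed Seed for folds and models.
#' @param hyper Learner hyperparameter overrides.
#' @return A `task_spec`.
#' @export
task_spec <- function(task = c("source_multiclass", "source_binary",
                               "sentiment_multiclass", "sentiment_binary"),
                      target = NULL, approach = 2, algorithm = "svm",
                      n_features = 500L, k = 5L, seed = 1L, hyper = list()) {
  task <- match.arg(task)
  if (task == "source_binary") {
    if (is.null(target) || !target %in% source_levels()) {
      stop_f("source_binary needs a target class in {%s}",
             paste(source_levels(), collapse = ", "))
    }
  }
  stopifnot(approach %in% c(1, 2))
  structure(list(task = task, target = target, approach = approach,
                 algorithm = algorithm, n_features = as.integer(n_features),
                 k = as.integer(k), seed = as.integer(seed), hyper = hyper),
            class = "task_spec")
}

#' Fit a source classifier on URL-bearing labeled tweets
#'
#' Trains on the subset of the corpus that has both a source label and at
#' least one URL (the only tweets a source model ever scores, thanks to the
#' no-URL shortcut), using text n-grams plus URL features per `approach`.
#'
#' @param corpus Source-labeled `tweet_corpus`.
#' @param algorithm Learner.
#' @param approach 1 (short URLs) or 2 (expanded URLs).
#' @param resolver [url_resolver()] (required for approach 2).
#' @param n_features Feature cap.
#' @param hyper Learner overrides.
#' @param seed Seed.
#' @return A `tweet_classifier` with `task = "source"` and the approach
#'   stamped on it.
#' @export
fit_source_classifier <- function(corpus, algorithm = "svm", approach = 2,
                                  resolver = NULL, n_features = 500L,
                                  hyper = list(), seed = 1L) {
  keep <- !is.na(corpus$source) & lengths(corpus$urls) > 0
  if (sum(keep) < 2) stop_f("need at least 2 URL-bearing source-labeled tweets")
  sub <- corpus_slice(corpus, keep)
  ng <- corpus_ngrams(sub, approach = approach, resolver = resolver)
  space <- build_feature_space(ng, sub$source, k = n_features)
  x <- vectorize(ng, space)
  model <- train_classifier(algorithm, x, sub$source, space = space,
                            hyper = hyper, seed = seed)
  model$task <- "source"
  model$approach <- approach
  model
}

#' Classify tweets by source with the no-URL shortcut
#'
#' Tweets without URLs are labeled `personal` without invoking the model (all
#' media and retail tweets carry URLs); URL-bearing tweets are featurized
#' (text + URL tokens per the model's approach) and scored. Unresolved URLs
#' fall back to short-URL host tokens, so classification is total — it never
#' raises on a resolver miss.
#'
#' @param corpus A `tweet_corpus` (labels not required).
#' @param model Source classifier from [fit_source_classifier()].
#' @param approach URL-feature approach; must match the model's.
#' @param resolver [url_resolver()] for approach 2.
#' @return Character vector of source labels, one per tweet.
#' @export
classify_source <- function(corpus, model, approach = model$approach,
                            resolver = NULL) {
  stopifnot(inherits(model, "tweet_classifier"))
  if (!identical(model$task, "source")) stop_f("model was not fit as a source classifier")
  if (!identical(approach, model$approach)) {
    stop_f("model was trained with approach %s but approach %s was requested",
           model$approach, approach)
  }
  out <- rep("personal", nrow(corpus))
  has_url <- lengths(corpus$urls) > 0
  if (any(has_url)) {
    sub <- corpus_slice(corpus, has_url)
    ng <- corpus_ngrams(sub, approach = approach, resolver = resolver)
    x <- vectorize(ng, model$space)
    out[has_url] <- predict(model, x)
  }
  out
}

#' Keep only tweets classified as personal communication
#'
#' Applies the source classifier (predicted labels, not gold labels — the
#' subset a deployed cascade would actually see) and returns the personal
#' subset in the original order. The counts removed per predicted class, and
#' the counts that manual labels would have removed when present, are attached
#' for transparency.
#'
#' @inheritParams classify_source
#' @return The filtered `tweet_corpus` with a `filter_report` attribute.
#' @export
filter_personal <- function(corpus, model, approach = model$approach,
                            resolver = NULL) {
  pred <- classify_source(corpus, model, approach = approach, resolver = resolver)
  keep <- pred == "personal"
  out <- corpus_slice(corpus, keep)
  report <- list(
    n_in = nrow(corpus), n_kept = sum(keep),
    removed_predicted = table(factor(pred[!keep], levels = c("media", "retail")))
  )
  if (any(!is.na(corpus$source))) {
    report$removed_gold <- table(factor(corpus$source[!is.na(corpus$source) &
                                                        corpus$source != "personal"],
                                        levels = c("media", "retail")))
  }
  attr(out, "filter_report") <- report
  out
}

#' Recast a corpus for a binary classification task
#'
#' Source tasks keep every tweet and relabel the axis as target-vs-`"rest"`.
#' The sentiment binary task (positive vs negative) removes neutral tweets —
#' the class human coders themselves agree on least — and keeps the labels.
#'
#' @param corpus Labeled `tweet_corpus`.
#' @param spec A [task_spec()] with task `source_binary` or
#'   `sentiment_binary`.
#' @return Relabeled `tweet_corpus`; for sentiment the number of excluded
#'   neutral tweets is attached as the `n_excluded` attribute.
#' @export
make_binary_task <- function(corpus, spec) {
  stopifnot(inherits(spec, "task_spec"))
  if (spec$task == "source_binary") {
    if (all(is.na(corpus$source))) stop_f("corpus carries no source labels")
    meta <- attr(corpus, "metadata") %||% list()
    meta$relabeled_axis <- "source"
    out <- corpus_slice(corpus, seq_len(nrow(corpus)), metadata = meta)
    out$source <- ifelse(out$source == spec$target, spec$target, "rest")
    attr(out, "n_excluded") <- 0L
    return(out)
  }
  if (spec$task == "sentiment_binary") {
    if (all(is.na(corpus$sentiment))) stop_f("corpus carries no sentiment labels")
    keep <- is.na(corpus$sentiment) | corpus$sentiment != "neutral"
    out <- corpus_slice(corpus, keep)
    attr(out, "n_excluded") <- sum(!keep)
    return(out)
  }
  stop_f("make_binary_task applies to binary tasks only")
}

#' Run a full classification task end-to-end
#'
#' Orchestrates the configurations of the study design: subsetting (source
#' tasks use URL-bearing tweets; sentiment approach 2 first filters to
#' predicted-personal tweets; binary tasks relabel or exclude neutral),
#' followed by per-fold feature selection, tf-idf vectorization, training and
#' evaluation under k-fold cross-validation. Optionally writes the report,
#' per-fold feature spaces and a manifest to `output_dir`.
#'
#' @param corpus Labeled `tweet_corpus`.
#' @param spec A [task_spec()].
#' @param resolver [url_resolver()] for URL expansion.
#' @param source_model Trained source classifier; required for sentiment
#'   approach 2 (the recommended choice is an SVM trained with expanded
#'   URLs, but any fitted source model may be injected).
#' @param output_dir Directory for report TSV + manifest JSON (created if
#'   needed); `NULL` skips writing.
#' @return An `eval_report` whose `counts` record the bookkeeping (tweets
#'   used, neutral tweets excluded, personal-filter removals).
#' @export
run_pipeline <- function(corpus, spec, resolver = NULL, source_model = NULL,
                         output_dir = NULL) {
  stopifnot(inherits(spec, "task_spec"))
  counts <- list(n_input = nrow(corpus))
  is_source <- grepl("^source", spec$task)
  work <- corpus
  url_approach <- NULL
  if (is_source) {
    keep <- !is.na(work$source) & lengths(work$urls) > 0
    work <- corpus_slice(work, keep)
    counts$n_url_bearing <- nrow(work)
    url_approach <- spec$approach
  } else if (spec$approach == 2) {
    if (is.null(source_model)) {
      stop_f("sentiment approach 2 needs a fitted source_model to filter personal tweets")
    }
    work <- filter_personal(work, source_model, resolver = resolver)
    fr <- attr(work, "filter_report")
    counts$n_personal <- fr$n_kept
    counts$n_removed_media <- unname(fr$removed_predicted[["media"]])
    counts$n_removed_retail <- unname(fr$removed_predicted[["retail"]])
  }
  if (grepl("binary$", spec$task)) {
    work <- make_binary_task(work, spec)
    counts$n_excluded_neutral <- attr(work, "n_excluded")
  }
  counts$n_evaluated <- nrow(work)
  axis <- if (is_source) "source" else "sentiment"
  report <- cross_validate(work, axis = axis, algorithm = spec$algorithm,
                           k = spec$k, seed = spec$seed,
                           n_features = spec$n_features,
                           approach = url_approach, resolver = resolver,
                           hyper = spec$hyper)
  report$counts <- counts
  report$task <- spec$task
  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    write_eval_report(report, file.path(output_dir, "report.tsv"), config = spec)
    manifest <- list(
      task = spec$task, target = spec$target, approach = spec$approach,
      algorithm = spec$algorithm, n_features = spec$n_features,
      k = spec$k, seed = spec$seed,
      counts = counts,
      config_hash = obj_hash(unclass(spec)),
      corpus_hash = obj_hash(list(corpus$id, corpus$text)),
      mean_macro = as.list(report$mean_macro)
    )
    jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  report
}
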