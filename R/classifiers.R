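# The three supervised learners behind one train/predict contract.
#
# nb  — multinomial naive Bayes with Laplace smoothing (alpha = 1), written
#       here because the installed ecosystem offers only Gaussian NB; tf-idf
#       weights are accepted as fractional counts, the standard practice for
#       text NB over weighted bags of words.
# lr  — L2-regularized logistic regression via glmnet (ridge, single lambda
#       chosen so the penalty matches inverse regularization strength C).
# svm — linear-kernel soft-margin SVM via e1071/libsvm, C = 1.
#
# Multiclass is one-vs-rest for all three (assembled explicitly for lr/svm so
# prediction is literally the argmax of the per-class decision scores).

default_hyper <- function(algorithm, hyper, seed) {
  base <- switch(algorithm,
    nb = list(alpha = 1),
    lr = list(C = 1, tol = 1e-10),
    svm = list(C = 1))
  out <- utils::modifyList(base, hyper)
  out$seed <- seed
  out
}

#' Train a classifier on tf-idf feature vectors
#'
#' @param algorithm `"nb"`, `"lr"` or `"svm"`.
#' @param x Feature matrix (rows = tweets, columns named by the feature
#'   space), as produced by [vectorize()].
#' @param labels Character vector of class labels, one per row; at least two
#'   distinct classes are required. The order of first appearance fixes the
#'   classifier's class order (used for deterministic tie-breaking).
#' @param space The `feature_space` the vectors came from; stored on the model
#'   so prediction can refuse vectors from a different space.
#' @param hyper Named list of hyperparameter overrides (`alpha` for nb; `C`,
#'   `tol` for lr; `C` for svm).
#' @param seed Integer recorded with the hyperparameters; all three learners
#'   are deterministic given the data, so the seed is provenance rather than a
#'   randomness source.
#' @return A `tweet_classifier`.
#' @export
train_classifier <- function(algorithm = c("nb", "lr", "svm"), x, labels,
                             space = NULL, hyper = list(), seed = 1L) {
  algorithm <- match.arg(algorithm)
  labels <- as.character(labels)
  if (nrow(x) != length(labels)) stop_f("x and labels disagree on the number of tweets")
  if (nrow(x) < 2) stop_f("need at least 2 training tweets")
  classes <- unique(labels)
  if (length(classes) < 2) stop_f("training labels contain a single class")
  if (!is.null(space) && !identical(colnames(x), space$features)) {
    stop_f("feature matrix columns do not match the supplied feature space")
  }
  hp <- default_hyper(algorithm, hyper, seed)
  xs <- methods::as(x, "CsparseMatrix")
  fit <- switch(algorithm,
    nb = fit_nb(xs, labels, classes, hp),
    lr = fit_lr(xs, labels, classes, hp),
    svm = fit_svm(as.matrix(x), labels, classes, hp))
  structure(list(algorithm = algorithm, classes = classes, fit = fit,
                 features = colnames(x), space = space, hyper = hp,
                 n_train = nrow(x)),
            class = "tweet_classifier")
}

fit_nb <- function(x, labels, classes, hp) {
  v <- ncol(x)
  ind <- Matrix::sparseMatrix(i = seq_along(labels), j = match(labels, classes),
                              x = 1, dims = c(length(labels), length(classes)))
  S <- as.matrix(Matrix::crossprod(ind, x))          # class x feature weight sums
  log_prior <- log(as.vector(Matrix::colSums(ind)) / length(labels))
  log_prob <- log((S + hp$alpha) / (rowSums(S) + hp$alpha * v))
  list(log_prior = log_prior, log_prob = log_prob)
}

fit_lr <- function(x, labels, classes, hp) {
  n <- nrow(x)
  padded <- ncol(x) < 2
  if (padded) x <- cbind(x, Matrix::Matrix(0, n, 2 - ncol(x), sparse = TRUE))
  lam <- 1 / (n * hp$C)
  models <- lapply(classes, function(cl) {
    y <- as.numeric(labels == cl)
    m <- withCallingHandlers(
      glmnet::glmnet(x, y, family = "binomial", alpha = 0, lambda = lam,
                     standardize = FALSE, thresh = hp$tol, maxit = 1e6),
      warning = function(w) {
        # glmnet advises caution below 8 observations per class; fine for the
        # deliberately tiny corpora used in examples and tests
        if (grepl("fewer than 8", conditionMessage(w))) invokeRestart("muffleWarning")
      })
    beta <- as.numeric(m$beta[, 1])
    if (padded) beta <- beta[1]
    list(intercept = as.numeric(m$a0), beta = beta)
  })
  stats::setNames(models, classes)
}

fit_svm <- function(x, labels, classes, hp) {
  models <- lapply(classes, function(cl) {
    yf <- factor(ifelse(labels == cl, "target", "rest"), levels = c("target", "rest"))
    m <- e1071::svm(x, yf, type = "C-classification", kernel = "linear",
                    cost = hp$C, scale = FALSE)
    # collapse to an explicit hyperplane so prediction is a plain dot product
    w <- as.vector(Matrix::crossprod(m$SV, m$coefs))
    b <- -m$rho
    # libsvm orients the decision value toward whichever label it met first
    # in the data; ask it once and flip so positive always means "target"
    pr <- predict(m, x[1, , drop = FALSE], decision.values = TRUE)
    nm <- colnames(attr(pr, "decision.values"))
    if (identical(nm, "rest/target")) { w <- -w; b <- -b }
    list(w = w, b = b)
  })
  stats::setNames(models, classes)
}

classifier_scores <- function(object, x) {
  xs <- methods::as(x, "CsparseMatrix")
  S <- switch(object$algorithm,
    nb = {
      ll <- as.matrix(xs %*% t(object$fit$log_prob))
      sweep(ll, 2, object$fit$log_prior, `+`)
    },
    lr = vapply(object$fit, function(m) {
      as.vector(xs %*% m$beta) + m$intercept
    }, numeric(nrow(xs))),
    svm = vapply(object$fit, function(m) {
      as.vector(xs %*% m$w) + m$b
    }, numeric(nrow(xs))))
  S <- matrix(S, nrow = nrow(xs), ncol = length(object$classes),
              dimnames = list(NULL, object$classes))
  S
}

#' Predict labels for tf-idf vectors
#'
#' The predicted label is the argmax of the per-class decision scores
#' (log-posterior for nb, linear predictor for lr, signed hyperplane distance
#' for svm); exact ties are broken in favor of the earliest class in the
#' classifier's training-order class list. Vectors must come from the same
#' feature space the model was trained on.
#'
#' @param object A `tweet_classifier`.
#' @param newdata Feature matrix from [vectorize()].
#' @param type `"class"` for labels, `"score"` for the score matrix.
#' @param ... Unused.
#' @return Character vector of labels, or a numeric score matrix.
#' @export
predict.tweet_classifier <- function(object, newdata, type = c("class", "score"), ...) {
  type <- match.arg(type)
  if (!identical(colnames(newdata), object$features)) {
    stop_f("feature space mismatch: vectors were not built on this model's feature space")
  }
  S <- classifier_scores(object, newdata)
  if (type == "score") return(S)
  object$classes[max.col(S, ties.method = "first")]
}

#' Print method
#' @exportS3Method base::print
#' @keywords internal
print.tweet_classifier <- function(x, ...) {
  cat(sprintf("<tweet_classifier> %s over %d features; classes: %s (n_train=%d)\n",
              x$algorithm, length(x$features), paste(x$classes, collapse = ", "),
              x$n_train))
  invisible(x)
}
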