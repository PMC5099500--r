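# separable 2-class vectors over a tiny hand-made feature space
separable_space <- function() {
  structure(list(features = c("fa", "fb", "fc", "fd"),
                 df = c(fa = 10L, fb = 10L, fc = 10L, fd = 10L),
                 chi2 = c(fa = 1, fb = 1, fc = 1, fd = 1),
                 n = 20L, k = 4L), class = "feature_space")
}

separable_xy <- function() {
  sp <- separable_space()
  docs <- c(replicate(10, c("fa", "fb"), simplify = FALSE),
            replicate(10, c("fc", "fd"), simplify = FALSE))
  list(x = vectorize(docs, sp), y = rep(c("A", "B"), each = 10), space = sp)
}

test_that("all three algorithms separate linearly separable classes perfectly", {
  d <- separable_xy()
  for (algo in c("nb", "lr", "svm")) {
    m <- train_classifier(algo, d$x, d$y, space = d$space)
    expect_identical(predict(m, d$x), d$y)
  }
})

test_that("nb posterior matches a hand Bayes computation with Laplace smoothing", {
  sp <- structure(list(features = c("f1", "f2"), df = c(f1 = 1L, f2 = 1L),
                       chi2 = c(f1 = 1, f2 = 1), n = 2L, k = 2L),
                  class = "feature_space")
  # class A: one doc with f1 weight 1; class B: one doc with f2 weight 1
  x <- Matrix::sparseMatrix(i = c(1, 2), j = c(1, 2), x = 1,
                            dims = c(2, 2), dimnames = list(NULL, c("f1", "f2")))
  m <- train_classifier("nb", x, c("A", "B"))
  test_vec <- Matrix::sparseMatrix(i = 1, j = 1, x = 1, dims = c(1, 2),
                                   dimnames = list(NULL, c("f1", "f2")))
  s <- predict(m, test_vec, type = "score")
  # hand computation: P(f1|A) = (1+1)/(1+2), P(f1|B) = (0+1)/(1+2), priors 1/2
  pa <- log(0.5) + 1 * log(2 / 3)
  pb <- log(0.5) + 1 * log(1 / 3)
  expect_equal(unname(s[1, "A"]), pa, tolerance = 1e-9)
  expect_equal(unname(s[1, "B"]), pb, tolerance = 1e-9)
  post_a <- exp(s[1, "A"]) / sum(exp(s[1, ]))
  expect_equal(unname(post_a), 2 / 3, tolerance = 1e-9)
})

test_that("identical conflicting evidence yields equal nb class scores", {
  x <- Matrix::sparseMatrix(i = 1:4, j = rep(1, 4), x = 1, dims = c(4, 2),
                            dimnames = list(NULL, c("f1", "f2")))
  m <- train_classifier("nb", x, c("A", "B", "A", "B"))
  s <- predict(m, x[1, , drop = FALSE], type = "score")
  expect_equal(unname(s[1, "A"]), unname(s[1, "B"]), tolerance = 1e-12)
  # ties resolve to the first class in training order
  expect_identical(predict(m, x[1, , drop = FALSE]), "A")
})

test_that("multiclass lr/svm build one one-vs-rest component per class", {
  d3 <- list()
  sp <- separable_space()
  docs <- c(replicate(5, c("fa"), simplify = FALSE),
            replicate(5, c("fb"), simplify = FALSE),
            replicate(5, c("fc"), simplify = FALSE))
  x <- vectorize(docs, sp)
  y <- rep(c("A", "B", "C"), each = 5)
  for (algo in c("lr", "svm")) {
    m <- train_classifier(algo, x, y, space = sp)
    expect_length(m$fit, 3)
    expect_named(m$fit, c("A", "B", "C"))
    # prediction is the argmax over the one-vs-rest scores
    s <- predict(m, x, type = "score")
    expect_identical(m$classes[max.col(s, ties.method = "first")], predict(m, x))
  }
})

test_that("an all-zero vector falls back to prior/bias-dominant classes", {
  sp <- separable_space()
  # class A sits near the origin, class B far from it, and A dominates the
  # priors: every decision function evaluated at the zero vector favors A
  docs <- c(replicate(12, "fa", simplify = FALSE),
            replicate(4, c("fc", "fc", "fc", "fd", "fd", "fd"), simplify = FALSE))
  x <- vectorize(docs, sp)
  y <- rep(c("A", "B"), c(12, 4))
  zero <- vectorize(list(character(0)), sp)
  m <- train_classifier("nb", x, y)
  expect_identical(predict(m, zero), "A")  # larger prior wins
  for (algo in c("lr", "svm")) {
    m2 <- train_classifier(algo, x, y)
    expect_identical(predict(m2, zero), "A")
  }
})

test_that("training-set permutation leaves nb exactly and lr nearly invariant", {
  d <- separable_xy()
  set.seed(1)
  perm <- sample(nrow(d$x))
  m1 <- train_classifier("nb", d$x, d$y)
  m2 <- train_classifier("nb", d$x[perm, ], d$y[perm])
  expect_equal(m1$fit$log_prob, m2$fit$log_prob, tolerance = 1e-12)
  l1 <- train_classifier("lr", d$x, d$y)
  l2 <- train_classifier("lr", d$x[perm, ], d$y[perm])
  expect_equal(l1$fit$A$beta, l2$fit$A$beta, tolerance = 1e-6)
})

test_that("training and prediction contracts reject invalid inputs", {
  d <- separable_xy()
  expect_error(train_classifier("svm", d$x, rep("A", 20)), "single class")
  expect_error(train_classifier("svm", d$x, d$y[1:5]), "disagree")
  m <- train_classifier("svm", d$x, d$y, space = d$space)
  other <- Matrix::sparseMatrix(i = 1, j = 1, x = 1, dims = c(1, 3),
                                dimnames = list(NULL, c("a", "b", "c")))
  expect_error(predict(m, other), "feature space mismatch")
})
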