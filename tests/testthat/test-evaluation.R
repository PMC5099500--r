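test_that("folds are near-equal, exhaustive, disjoint and seed-deterministic", {
  f <- make_folds(1000, k = 5, seed = 3)
  expect_true(all(table(f) == 200))
  f2 <- make_folds(1002, k = 5, seed = 3)
  expect_setequal(as.integer(table(f2)), c(201L, 201L, 200L, 200L, 200L))
  expect_identical(make_folds(100, 5, seed = 9), make_folds(100, 5, seed = 9))
  expect_false(identical(as.integer(make_folds(100, 5, seed = 9)),
                         as.integer(make_folds(100, 5, seed = 10))))
  # partition: every index in exactly one fold
  expect_equal(sort(unlist(lapply(1:5, function(k) which(f == k)))), 1:1000)
  expect_error(make_folds(3, k = 5), "cannot split")
})

test_that("per-class metrics follow the printed definitions", {
  gold <- c(rep("pos", 10), rep("neg", 10))
  pred <- c(rep("pos", 8), "neg", "neg", rep("neg", 8), "pos", "pos")
  m <- per_class_metrics(gold, pred, "pos")   # TP=8 FP=2 FN=2
  expect_equal(as.numeric(m), c(0.8, 0.8, 0.8))
  # P = R implies F = P (harmonic mean of equal values)
  expect_equal(m[["f"]], m[["precision"]])
  # never-predicted, never-present class: defined as 0 and flagged
  m0 <- per_class_metrics(gold, pred, "neutral")
  expect_equal(as.numeric(m0), c(0, 0, 0))
  expect_true(attr(m0, "flagged"))
  expect_error(per_class_metrics(gold, pred[1:3], "pos"), "length")
})

test_that("macro averaging is the unweighted mean of per-class metrics", {
  m <- data.frame(precision = c(0.5, 0.7, 0.9), recall = c(0.6, 0.8, 1.0),
                  f = c(0.6, 0.8, 1.0))
  expect_equal(unname(macro_average(m)["f"]), 0.8)
  one <- data.frame(precision = 0.7, recall = 0.6, f = 0.65)
  expect_equal(unname(macro_average(one)), c(0.7, 0.6, 0.65))
})

test_that("micro-consistency: per-class TP/FP/FN account for every prediction once", {
  set.seed(8)
  classes <- c("a", "b", "c")
  gold <- sample(classes, 60, replace = TRUE)
  pred <- sample(classes, 60, replace = TRUE)
  tp <- fp <- fn <- 0
  for (cl in classes) {
    tp <- tp + sum(gold == cl & pred == cl)
    fp <- fp + sum(pred == cl & gold != cl)
    fn <- fn + sum(gold == cl & pred != cl)
  }
  expect_equal(tp + fp, 60)
  expect_equal(tp + fn, 60)
  mets <- classification_metrics(gold, pred)
  expect_true(all(mets$precision >= 0 & mets$precision <= 1))
  expect_true(all(mets$f >= 0 & mets$f <= 1))
})

test_that("cross-validation reaches F=1 on a separable corpus and is deterministic", {
  synth <- generate_corpus(synthetic_spec(
    150, source_counts = c(personal = 50, media = 50, retail = 50),
    signal_strength = 1, all_urls = TRUE, seed = 21))
  rep1 <- cross_validate(synth$corpus, "source", "nb", k = 5, seed = 4,
                         n_features = 200, approach = 2, resolver = synth$resolver)
  expect_equal(nrow(rep1$macro), 5)
  expect_gte(rep1$mean_macro[["f"]], 0.99)
  rep2 <- cross_validate(synth$corpus, "source", "nb", k = 5, seed = 4,
                         n_features = 200, approach = 2, resolver = synth$resolver)
  expect_identical(rep1$macro, rep2$macro)
  # mean macro is bracketed by the fold macros
  expect_gte(rep1$mean_macro[["f"]], min(rep1$macro$f))
  expect_lte(rep1$mean_macro[["f"]], max(rep1$macro$f))
})

test_that("paired one-tailed t matches both the hand example and stats::t.test", {
  d <- c(0.01, 0.02, 0.00, 0.01, 0.01)
  b <- c(0.80, 0.81, 0.79, 0.83, 0.78)
  a <- b + d
  got <- compare_classifiers(a, b)
  expect_equal(got$t, 3.1623, tolerance = 1e-4)
  expect_equal(got$p, 0.017, tolerance = 0.01)
  ref <- stats::t.test(a, b, paired = TRUE, alternative = "greater")
  expect_equal(got$t, unname(ref$statistic), tolerance = 1e-9)
  expect_equal(got$p, unname(ref$p.value), tolerance = 1e-9)
  # antisymmetry for non-degenerate inputs
  rev <- compare_classifiers(b, a)
  expect_equal(got$p + rev$p, 1, tolerance = 1e-9)
})

test_that("degenerate t-test cases follow the stated conventions", {
  same <- rep(0.8, 5)
  expect_equal(compare_classifiers(same, same)$p, 0.5)
  up <- compare_classifiers(same + 0.01, same)
  expect_equal(up$p, 0)
  expect_true(up$degenerate)
  down <- compare_classifiers(same - 0.01, same)
  expect_equal(down$p, 1)
})

test_that("evaluation reports serialize with fold rows and the mean", {
  rep0 <- tweetcascade:::new_eval_report(
    per_class = tibble::tibble(),
    macro = tibble::tibble(fold = 1:2, precision = c(0.9, 0.8),
                           recall = c(0.9, 0.8), f = c(0.9, 0.8)),
    algorithm = "svm", axis = "source", k = 2, seed = 1)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_eval_report(rep0, path)
  lines <- readLines(path)
  expect_match(lines[1], "^# algorithm=svm")
  expect_match(lines[length(lines)], "^mean\t0.85", fixed = FALSE)
})
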