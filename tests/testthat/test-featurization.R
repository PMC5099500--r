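test_that("tokenizer lowercases, keeps stop words, strips hashtags and anonymizes mentions", {
  expect_identical(tokenize("Marijuana is GREAT"), c("marijuana", "is", "great"))
  expect_identical(tokenize(""), character(0))
  expect_identical(
    tokenize("@GovChristie very ignorant to not see the value of cannabis"),
    c("@user", "very", "ignorant", "to", "not", "see", "the", "value", "of", "cannabis"))
  expect_identical(tokenize("#blessed don't stop https://t.co/abc123"),
                   c("blessed", "don't", "stop"))
})

test_that("unigram+bigram extraction enumerates adjacent pairs with multiplicity", {
  expect_setequal(extract_ngrams(c("smoking", "dabs")),
                  c("smoking", "dabs", "smoking dabs"))
  expect_identical(extract_ngrams("cannabis"), "cannabis")
  got <- extract_ngrams(c("a", "b", "a", "b"))
  expect_equal(sum(got == "a"), 2)
  expect_equal(sum(got == "a b"), 2)
  expect_equal(sum(got == "b a"), 1)
  expect_identical(extract_ngrams(character(0)), character(0))
})

test_that("chi-square scores match the analytic value for perfect association", {
  docs <- c(replicate(10, c("marker", "filler"), simplify = FALSE),
            replicate(10, list("filler")))
  labels <- rep(c("A", "B"), each = 10)
  s <- chi_square_scores(docs, labels)
  # 10/0/0/10 table on n=20: statistic is exactly n = 20
  expect_equal(unname(s["marker"]), 20, tolerance = 1e-12)
  expect_equal(unname(s["filler"]), 0)
})

test_that("chi-square scores equal an independent contingency-table oracle", {
  set.seed(11)
  vocab <- sprintf("f%02d", 1:30)
  labels <- sample(c("A", "B", "C"), 20, replace = TRUE,
                   prob = c(0.4, 0.3, 0.3))
  docs <- lapply(labels, function(cl) {
    base <- sample(vocab, 5)
    if (cl == "A") base <- c(base, "f01")
    base
  })
  s <- chi_square_scores(docs, labels)
  for (feat in sample(names(s), 10)) {
    expect_equal(unname(s[feat]), oracle_chi2_max(docs, labels, feat),
                 tolerance = 1e-9, label = feat)
  }
})

test_that("chi-square scores are invariant to class renaming and need 2 classes", {
  docs <- list(c("x", "y"), "x", "y", c("y", "y"))
  labels <- c("A", "A", "B", "B")
  s1 <- chi_square_scores(docs, labels)
  s2 <- chi_square_scores(docs, c("B", "B", "A", "A"))
  expect_equal(s1, s2)
  expect_true(all(s1 >= 0))
  expect_error(chi_square_scores(docs, rep("A", 4)), "at least 2 classes")
})

test_that("feature selection caps at k with lexicographic tie-breaking", {
  scores <- stats::setNames(c(5, 5, 3, 1), c("zeta", "beta", "mid", "low"))
  df <- stats::setNames(rep(2L, 4), names(scores))
  sp <- select_features(scores, df, n = 10, k = 2)
  expect_identical(sp$features, c("beta", "zeta"))  # tie broken alphabetically
  sp3 <- select_features(scores, df, n = 10, k = 10)
  expect_equal(length(sp3$features), 4)  # fewer candidates than the cap
  expect_error(select_features(scores, df, n = 10, k = 0), "positive")
})

test_that("tf-idf weights follow w = tf * ln(N/df) exactly", {
  sp <- structure(list(
    features = c("a", "b", "c"),
    df = c(a = 5L, b = 10L, c = 2L),
    chi2 = c(a = 1, b = 1, c = 1), n = 10L, k = 3L), class = "feature_space")
  x <- vectorize(list(c("a", "a", "b", "zzz"), character(0)), sp)
  expect_equal(unname(x[1, "a"]), 2 * log(10 / 5), tolerance = 1e-12)
  expect_equal(unname(x[1, "b"]), 0)           # df = N gives ln(1) = 0
  expect_equal(sum(x[2, ]), 0)         # no selected features -> empty vector
  # linearity in tf
  x2 <- vectorize(list(rep("a", 4)), sp)
  expect_equal(unname(x2[1, "a"]), 2 * unname(x[1, "a"]), tolerance = 1e-12)
})

test_that("tf-idf matches a cell-by-cell oracle on a random corpus", {
  set.seed(5)
  docs <- replicate(12, sample(sprintf("w%d", 1:8), sample(3:6, 1), replace = TRUE),
                    simplify = FALSE)
  labels <- rep(c("A", "B"), 6)
  sp <- build_feature_space(docs, labels, k = 20)
  x <- vectorize(docs, sp)
  for (d in 1:12) {
    for (feat in sp$features) {
      expect_equal(unname(x[d, feat]),
                   oracle_tfidf(docs[[d]], feat, sp$n, sp$df[[feat]]),
                   tolerance = 1e-9)
    }
  }
})

test_that("a corpus with more than k candidates yields exactly k features", {
  synth <- generate_corpus(synthetic_spec(
    120, source_counts = c(personal = 40, media = 40, retail = 40), seed = 99))
  ng <- corpus_ngrams(synth$corpus)
  expect_gt(length(unique(unlist(ng))), 100)
  sp <- build_feature_space(ng, synth$corpus$source, k = 100)
  expect_equal(length(sp$features), 100)
})

test_that("feature spaces round-trip through TSV", {
  docs <- list(c("a", "b"), c("b", "c"), c("a", "a"), "c")
  sp <- build_feature_space(docs, c("A", "B", "A", "B"), k = 3)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_feature_space(sp, path)
  back <- read_feature_space(path)
  expect_identical(back$features, sp$features)
  expect_identical(back$df, sp$df)
  expect_equal(back$chi2, sp$chi2, tolerance = 1e-9)
  expect_identical(back$n, sp$n)
  expect_identical(back$k, sp$k)
})
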