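synth_small <- generate_corpus(synthetic_spec(
  240, source_counts = c(personal = 80, media = 80, retail = 80),
  url_rate_personal = 0.4, seed = 555))

test_that("tweets without URLs are labeled personal without touching the model", {
  src_model <- fit_source_classifier(synth_small$corpus, "svm", approach = 2,
                                     resolver = synth_small$resolver,
                                     n_features = 300)
  corp <- as_corpus(tibble::tibble(id = "x1", text = "no links at all"))
  expect_identical(classify_source(corp, src_model, resolver = synth_small$resolver),
                   "personal")
  # a broken model cannot hurt a no-URL tweet: scores are never consulted
  broken <- src_model
  broken$fit <- NULL
  expect_identical(classify_source(corp, broken, resolver = synth_small$resolver),
                   "personal")
})

test_that("URL-bearing tweets with strong retail URL signal classify as retail", {
  src_model <- fit_source_classifier(synth_small$corpus, "svm", approach = 2,
                                     resolver = synth_small$resolver,
                                     n_features = 300)
  held <- generate_corpus(synthetic_spec(
    60, source_counts = c(personal = 20, media = 20, retail = 20),
    url_rate_personal = 0.5, seed = 556))
  pred <- classify_source(held$corpus, src_model, resolver = held$resolver)
  retail_idx <- held$corpus$source == "retail"
  expect_gt(mean(pred[retail_idx] == "retail"), 0.8)
  # unresolved URLs still classify (host-token fallback), never an exception
  no_table <- url_resolver(character(0))
  expect_silent(pred2 <- classify_source(held$corpus, src_model, resolver = no_table))
  expect_length(pred2, 60)
})

test_that("filter_personal returns an ordered subset and reports removals", {
  src_model <- fit_source_classifier(synth_small$corpus, "svm", approach = 2,
                                     resolver = synth_small$resolver,
                                     n_features = 300)
  kept <- filter_personal(synth_small$corpus, src_model,
                          resolver = synth_small$resolver)
  expect_true(all(kept$id %in% synth_small$corpus$id))
  expect_identical(kept$id,
                   synth_small$corpus$id[synth_small$corpus$id %in% kept$id])
  rep <- attr(kept, "filter_report")
  expect_equal(rep$n_kept + sum(rep$removed_predicted), rep$n_in)
  # no-URL corpora pass through untouched (every tweet shortcuts to personal)
  nourl <- as_corpus(tibble::tibble(id = c("a", "b"), text = c("one", "two")))
  expect_equal(nrow(filter_personal(nourl, src_model,
                                    resolver = synth_small$resolver)), 2)
})

test_that("binary task construction matches the sample bookkeeping", {
  sent <- generate_corpus(synthetic_spec(
    300, sentiment_counts = c(positive = 130, negative = 90, neutral = 80),
    source_counts = c(personal = 300), seed = 77))$corpus
  bin <- make_binary_task(sent, task_spec("sentiment_binary"))
  expect_equal(nrow(bin), 220)
  expect_equal(attr(bin, "n_excluded"), 80)
  expect_setequal(unique(bin$sentiment), c("positive", "negative"))
  # source binary: relabel, keep all tweets
  src_bin <- make_binary_task(synth_small$corpus,
                              task_spec("source_binary", target = "media"))
  expect_equal(nrow(src_bin), nrow(synth_small$corpus))
  expect_setequal(unique(src_bin$source), c("media", "rest"))
  # no neutral tweets: binary output = input
  nn <- generate_corpus(synthetic_spec(
    40, sentiment_counts = c(positive = 25, negative = 15),
    source_counts = c(personal = 40), seed = 78))$corpus
  expect_equal(nrow(make_binary_task(nn, task_spec("sentiment_binary"))), 40)
  expect_error(task_spec("source_binary", target = "positive"), "target class")
})

test_that("run_pipeline produces per-fold reports, bookkeeping and byte-identical reruns", {
  spec <- task_spec("source_multiclass", approach = 2, algorithm = "svm",
                    n_features = 300, seed = 12)
  dir1 <- withr::local_tempdir()
  dir2 <- withr::local_tempdir()
  r1 <- run_pipeline(synth_small$corpus, spec, resolver = synth_small$resolver,
                     output_dir = dir1)
  r2 <- run_pipeline(synth_small$corpus, spec, resolver = synth_small$resolver,
                     output_dir = dir2)
  expect_equal(nrow(r1$macro), 5)
  expect_identical(r1$macro, r2$macro)
  expect_identical(readLines(file.path(dir1, "report.tsv")),
                   readLines(file.path(dir2, "report.tsv")))
  expect_true(file.exists(file.path(dir1, "manifest.json")))
  expect_equal(r1$counts$n_url_bearing,
               sum(lengths(synth_small$corpus$urls) > 0))
})

test_that("sentiment approach 2 records the neutral-exclusion and filter counts", {
  sent <- generate_corpus(synthetic_spec(
    300, sentiment_counts = c(positive = 130, negative = 90, neutral = 80),
    source_counts = c(personal = 240, media = 30, retail = 30), seed = 91))
  src_model <- fit_source_classifier(synth_small$corpus, "svm", approach = 2,
                                     resolver = synth_small$resolver,
                                     n_features = 300)
  rep <- run_pipeline(sent$corpus,
                      task_spec("sentiment_binary", approach = 2,
                                algorithm = "nb", n_features = 300, seed = 5),
                      resolver = sent$resolver, source_model = src_model)
  expect_true(rep$counts$n_personal <= 300)
  expect_true(rep$counts$n_excluded_neutral <= 80)
  expect_equal(rep$counts$n_evaluated,
               rep$counts$n_personal - rep$counts$n_excluded_neutral)
  expect_error(run_pipeline(sent$corpus,
                            task_spec("sentiment_binary", approach = 2),
                            resolver = sent$resolver),
               "source_model")
})
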