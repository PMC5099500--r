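Package: tweetcascade
Title: Cascaded Source and Sentiment Classification of Drug-Related Tweets
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for public-health infoveillance on Twitter: a two-stage
    (cascaded) text-classification pipeline that first labels tweets by
    source/type of communication (personal, official/media, retail) using
    bag-of-words features augmented with tokens from expanded short URLs, and
    then classifies sentiment (positive, negative, neutral) on the personal
    communication subset. Includes keyword/blacklist stream filtering with
    co-occurrence rules for ambiguous drug slang, chi-square n-gram feature
    selection with tf-idf weighting, multinomial Naive Bayes, logistic
    regression and linear SVM learners, 5-fold cross-validated evaluation with
    paired one-tailed t-tests, a lexicon-and-rule sentiment baseline,
    Krippendorff's alpha for intercoder reliability, and a seeded synthetic
    corpus generator that emulates the class structure of labeled drug-related
    tweets (including domain-inverted sentiment vocabulary).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    e1071,
    glmnet,
    jsonlite,
    Matrix,
    methods,
    readr,
    stats,
    tibble,
    tools,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
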