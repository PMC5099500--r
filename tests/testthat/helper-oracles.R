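# Independent brute-force oracles and tiny fixture builders shared by tests.

# chi-square via R's own contingency-table test (no continuity correction);
# independent of the package's vectorized computation
oracle_chi2 <- function(present, in_class) {
  tab <- table(factor(present, levels = c(FALSE, TRUE)),
               factor(in_class, levels = c(FALSE, TRUE)))
  unname(suppressWarnings(stats::chisq.test(tab, correct = FALSE))$statistic)
}

oracle_chi2_max <- function(docs, labels, feature) {
  present <- vapply(docs, function(d) feature %in% d, logical(1))
  max(vapply(unique(labels), function(cl) oracle_chi2(present, labels == cl),
             numeric(1)))
}

# tf-idf by direct evaluation of the printed formula, one cell at a time
oracle_tfidf <- function(doc, feature, n, df) {
  tf <- sum(doc == feature)
  tf * log(n / df)
}

# Krippendorff alpha by explicit enumeration of ordered value pairs within
# units (a different code path from the package's coincidence matrix)
oracle_alpha <- function(df) {
  df <- df[!is.na(df$value), , drop = FALSE]
  by_unit <- split(as.character(df$value), df$unit)
  by_unit <- by_unit[lengths(by_unit) >= 2]
  pair_vals1 <- character(0); pair_vals2 <- character(0); wts <- numeric(0)
  for (vals in by_unit) {
    m <- length(vals)
    for (p in seq_len(m)) for (q in seq_len(m)) {
      if (p == q) next
      pair_vals1 <- c(pair_vals1, vals[p])
      pair_vals2 <- c(pair_vals2, vals[q])
      wts <- c(wts, 1 / (m - 1))
    }
  }
  n <- sum(wts)
  d_o <- sum(wts[pair_vals1 != pair_vals2]) / n
  cats <- unique(c(pair_vals1, pair_vals2))
  n_c <- vapply(cats, function(cat) sum(wts[pair_vals1 == cat]), numeric(1))
  d_e <- (n^2 - sum(n_c^2)) / (n * (n - 1))
  1 - d_o / d_e
}

# small hand-built labeled corpus; word choices make classes separable
toy_corpus <- function() {
  as_corpus(tibble::tibble(
    id = sprintf("t%02d", 1:6),
    text = c("smoking dabs tonight", "dabs are great tonight",
             "breaking news on legalization", "news report on cannabis policy",
             "flash sale on vape carts", "new vape stock in store"),
    source = c("personal", "personal", "media", "media", "retail", "retail"),
    urls = list(character(0), character(0), "https://t.co/m1", "https://t.co/m2",
                "https://t.co/r1", "https://t.co/r2")
  ))
}

toy_resolver <- function() {
  url_resolver(c(
    "https://t.co/m1" = "https://news.example.com/cannabis-legalization",
    "https://t.co/m2" = "https://news.example.com/policy-report",
    "https://t.co/r1" = "https://shop.example.com/vape-sale",
    "https://t.co/r2" = "https://shop.example.com/store-stock"
  ))
}
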