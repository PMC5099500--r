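# Corpus container: a tibble with columns
#   id        chr, non-empty, unique
#   text      chr
#   urls      list of chr (possibly empty character(0))
#   lang      chr or NA (BCP-47-ish tag; only the "en" prefix is interpreted)
#   source    chr or NA, one of source_levels() unless relabeled for a binary task
#   sentiment chr or NA, one of sentiment_levels()
# carrying a free-form `metadata` attribute (provenance: file, seed, generator).

#' Build a tweet corpus
#'
#' Normalizes a data frame of tweets into the corpus container used by every
#' other function in the package. Missing optional columns (`urls`, `lang`,
#' `source`, `sentiment`) are filled; `urls` given as a `"|"`-joined character
#' column is split into a list column.
#'
#' @param x Data frame with at least `id` and `text` columns.
#' @param metadata Named list of provenance information kept as an attribute.
#' @param validate Run [validate_corpus()] before returning?
#' @param length_cap Maximum allowed tweet length in characters (default 280,
#'   the current platform limit; the synthetic generator emits 140-character
#'   tweets matching the era the pipeline was designed for).
#' @return A `tweet_corpus` object (a tibble).
#' @export
as_corpus <- function(x, metadata = list(), validate = TRUE, length_cap = 280L) {
  x <- tibble::as_tibble(x)
  if (!all(c("id", "text") %in% names(x))) {
    stop_f("a corpus needs 'id' and 'text' columns")
  }
  x$id <- as.character(x$id)
  x$text <- as.character(x$text)
  if (!"urls" %in% names(x)) {
    x$urls <- replicate(nrow(x), character(0), simplify = FALSE)
  } else if (is.character(x$urls)) {
    x$urls <- lapply(x$urls, function(u) {
      if (is.na(u) || !nzchar(u)) character(0) else strsplit(u, "|", fixed = TRUE)[[1]]
    })
  } else {
    x$urls <- lapply(x$urls, function(u) as.character(u[!is.na(u) & nzchar(u)]))
  }
  for (col in c("lang", "source", "sentiment")) {
    if (!col %in% names(x)) x[[col]] <- NA_character_
    x[[col]] <- as.character(x[[col]])
    x[[col]][!is.na(x[[col]]) & !nzchar(x[[col]])] <- NA_character_
  }
  x <- x[, c("id", "text", "urls", "lang", "source", "sentiment")]
  out <- structure(x, class = c("tweet_corpus", class(tibble::tibble())))
  attr(out, "metadata") <- metadata
  attr(out, "length_cap") <- as.integer(length_cap)
  if (validate) validate_corpus(out)
  out
}

#' Validate a corpus against its invariants
#'
#' Checks id uniqueness, label values against the closed enumerations, the
#' tweet length cap, that every URL present in the text appears in the `urls`
#' field, and that all media- and retail-labeled tweets carry at least one URL
#' (tweets from those sources always link out; the cascade relies on this).
#'
#' @param corpus A `tweet_corpus`.
#' @param length_cap Override the cap stored on the corpus.
#' @return The corpus, invisibly; errors describe every violation found.
#' @export
validate_corpus <- function(corpus, length_cap = NULL) {
  stopifnot(inherits(corpus, "tweet_corpus"))
  cap <- length_cap %||% attr(corpus, "length_cap") %||% 280L
  probs <- character(0)
  if (any(is.na(corpus$id) | !nzchar(corpus$id))) {
    probs <- c(probs, "empty or missing ids")
  }
  dup <- unique(corpus$id[duplicated(corpus$id)])
  if (length(dup)) {
    probs <- c(probs, sprintf("duplicate ids: %s", paste(utils::head(dup, 5), collapse = ", ")))
  }
  too_long <- sum(nchar(corpus$text) > cap, na.rm = TRUE)
  if (too_long > 0) {
    probs <- c(probs, sprintf("%d tweets exceed the %d-character cap", too_long, cap))
  }
  meta <- attr(corpus, "metadata") %||% list()
  relabeled <- meta$relabeled_axis %||% NA_character_
  bad_lab <- function(vals, levels) {
    v <- vals[!is.na(vals)]
    unique(v[!v %in% levels])
  }
  if (!identical(relabeled, "source")) {
    bad <- bad_lab(corpus$source, source_levels())
    if (length(bad)) probs <- c(probs, sprintf("unknown source label(s): %s", paste(bad, collapse = ", ")))
  }
  if (!identical(relabeled, "sentiment")) {
    bad <- bad_lab(corpus$sentiment, sentiment_levels())
    if (length(bad)) probs <- c(probs, sprintf("unknown sentiment label(s): %s", paste(bad, collapse = ", ")))
  }
  # urls must contain every URL present in the text
  in_text <- lapply(corpus$text, extract_urls)
  missing_url <- vapply(seq_len(nrow(corpus)),
                        function(i) !all(in_text[[i]] %in% corpus$urls[[i]]),
                        logical(1))
  if (any(missing_url)) {
    probs <- c(probs, sprintf("%d tweets have URLs in text missing from the urls field", sum(missing_url)))
  }
  if (!identical(relabeled, "source")) {
    offending <- !is.na(corpus$source) & corpus$source %in% c("media", "retail") &
      lengths(corpus$urls) == 0
    if (any(offending)) {
      probs <- c(probs, sprintf("%d media/retail tweets without a URL", sum(offending)))
    }
  }
  if (length(probs)) stop_f("invalid corpus: %s", paste(probs, collapse = "; "))
  invisible(corpus)
}

check_label_value <- function(value, levels, axis, where) {
  if (is.na(value)) return(NA_character_)
  if (!value %in% levels) {
    stop_f("%s: unknown %s label '%s' (allowed: %s)",
           where, axis, value, paste(levels, collapse = ", "))
  }
  value
}

#' Read a corpus from JSONL or CSV
#'
#' JSONL (canonical) holds one JSON object per line with fields `id`, `text`,
#' `urls` (array, always present even when empty), and optional `lang`,
#' `source`, `sentiment`. CSV (RFC 4180, header row required) uses a
#' `"|"`-joined `urls` column. Malformed records and unknown label strings are
#' rejected with their line numbers.
#'
#' @param path File to read.
#' @param format `"jsonl"` or `"csv"`; guessed from the extension by default.
#' @param validate Validate the resulting corpus?
#' @return A `tweet_corpus`.
#' @export
read_corpus <- function(path, format = c("auto", "jsonl", "csv"), validate = TRUE) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "jsonl"
  }
  if (!file.exists(path)) stop_f("corpus file not found: %s", path)
  if (format == "jsonl") {
    con <- file(path, encoding = "UTF-8")
    lines <- readLines(con, warn = FALSE)
    close(con)
    keep <- nzchar(trimws(lines))
    idx <- which(keep)
    recs <- vector("list", length(idx))
    for (k in seq_along(idx)) {
      ln <- idx[k]
      rec <- tryCatch(jsonlite::fromJSON(lines[ln], simplifyVector = TRUE),
                      error = function(e) stop_f("line %d: malformed JSON (%s)", ln, conditionMessage(e)))
      if (is.null(rec$id) || is.null(rec$text)) {
        stop_f("line %d: record missing id or text", ln)
      }
      where <- sprintf("line %d", ln)
      recs[[k]] <- tibble::tibble(
        id = as.character(rec$id),
        text = as.character(rec$text),
        urls = list(as.character(rec$urls %||% character(0))),
        lang = as.character(rec$lang %||% NA_character_),
        source = check_label_value(as.character(rec$source %||% NA_character_),
                                   source_levels(), "source", where),
        sentiment = check_label_value(as.character(rec$sentiment %||% NA_character_),
                                      sentiment_levels(), "sentiment", where)
      )
    }
    df <- if (length(recs)) dplyr::bind_rows(recs) else
      tibble::tibble(id = character(0), text = character(0))
  } else {
    df <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                          progress = FALSE)
    if (!all(c("id", "text") %in% names(df))) stop_f("CSV is missing id/text columns")
    for (i in seq_len(nrow(df))) {
      where <- sprintf("row %d", i)
      if ("source" %in% names(df)) check_label_value(df$source[i], source_levels(), "source", where)
      if ("sentiment" %in% names(df)) check_label_value(df$sentiment[i], sentiment_levels(), "sentiment", where)
    }
  }
  as_corpus(df, metadata = list(source_file = path, format = format), validate = validate)
}

#' Write a corpus to JSONL or CSV
#'
#' Round-trips with [read_corpus()] item-for-item; an empty `urls` list is
#' serialized as an empty JSON array (or an empty CSV cell), never dropped.
#'
#' @param corpus A `tweet_corpus`.
#' @param path Output file.
#' @param format `"jsonl"` or `"csv"`; guessed from the extension by default.
#' @export
write_corpus <- function(corpus, path, format = c("auto", "jsonl", "csv")) {
  stopifnot(inherits(corpus, "tweet_corpus"))
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "jsonl"
  }
  if (format == "jsonl") {
    lines <- vapply(seq_len(nrow(corpus)), function(i) {
      rec <- list(
        id = corpus$id[i],
        text = corpus$text[i],
        urls = corpus$urls[[i]],
        lang = corpus$lang[i],
        source = corpus$source[i],
        sentiment = corpus$sentiment[i]
      )
      jsonlite::toJSON(rec, auto_unbox = TRUE, na = "null", null = "null")
    }, character(1))
    con <- file(path, open = "wb")
    writeLines(lines, con, useBytes = TRUE)
    close(con)
  } else {
    df <- tibble::tibble(
      id = corpus$id,
      text = corpus$text,
      urls = vapply(corpus$urls, paste, character(1), collapse = "|"),
      lang = corpus$lang,
      source = corpus$source,
      sentiment = corpus$sentiment
    )
    readr::write_csv(df, path, na = "", progress = FALSE)
  }
  invisible(path)
}

#' Count labels on one axis of a corpus
#'
#' @param corpus A `tweet_corpus`.
#' @param axis `"source"` or `"sentiment"`.
#' @return Named integer vector of counts over the axis' label values (all
#'   enumeration values are present, zero-filled), with an `unlabeled`
#'   attribute giving the number of items without a label on that axis.
#' @export
label_counts <- function(corpus, axis = c("source", "sentiment")) {
  axis <- match.arg(axis)
  vals <- corpus[[axis]]
  meta <- attr(corpus, "metadata") %||% list()
  levels <- if (identical(meta$relabeled_axis, axis)) {
    sort(unique(vals[!is.na(vals)]))
  } else if (axis == "source") source_levels() else sentiment_levels()
  counts <- vapply(levels, function(l) sum(vals == l, na.rm = TRUE), integer(1))
  structure(counts, unlabeled = sum(is.na(vals)))
}

# subset rows while keeping corpus class + attributes (tibble subsetting drops them)
corpus_slice <- function(corpus, idx, metadata = NULL) {
  out <- corpus
  attrs <- attributes(corpus)
  out <- tibble::as_tibble(unclass(corpus))[idx, , drop = FALSE]
  out <- structure(out, class = c("tweet_corpus", class(tibble::tibble())))
  attr(out, "metadata") <- metadata %||% attrs$metadata
  attr(out, "length_cap") <- attrs$length_cap
  out
}

#' Print method
#' @exportS3Method base::print
#' @keywords internal
print.tweet_corpus <- function(x, ...) {
  cat(sprintf("<tweet_corpus> %d tweets\n", nrow(x)))
  for (axis in c("source", "sentiment")) {
    if (any(!is.na(x[[axis]]))) {
      lc <- label_counts(x, axis)
      cat(sprintf("  %s: %s (unlabeled %d)\n", axis,
                  paste(sprintf("%s=%d", names(lc), lc), collapse = " "),
                  attr(lc, "unlabeled")))
    }
  }
  NextMethod()
}
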