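`%||%` <- function(x, y) if (is.null(x)) y else x

# md5 of a serialized object; used to stamp run manifests so outputs are auditable
obj_hash <- function(x) {
  f <- tempfile(fileext = ".rds")
  on.exit(unlink(f), add = TRUE)
  saveRDS(x, f, version = 2, compress = FALSE)
  unname(tools::md5sum(f))
}

stop_f <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' Source and sentiment label sets
#'
#' The closed label enumerations used throughout the package: a tweet's
#' source/type of communication is one of `personal`, `media` (official/media
#' content) or `retail` (marketing), and its sentiment is `positive`,
#' `negative` or `neutral` (the neutral value also covers tweets whose
#' sentiment cannot be identified).
#'
#' @return A character vector of allowed label values.
#' @export
source_levels <- function() c("personal", "media", "retail")

#' @rdname source_levels
#' @export
sentiment_levels <- function() c("positive", "negative", "neutral")
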