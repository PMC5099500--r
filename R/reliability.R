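# Krippendorff's alpha for nominal data, computed from the coincidence
# matrix: alpha = 1 - Do/De, where Do is observed and De expected
# disagreement, and the nominal distance is 0 for equal categories and 1
# otherwise. Units rated by fewer than two coders drop out (the
# coincidence-matrix formulation handles missing data naturally).

#' Krippendorff's alpha (nominal)
#'
#' @param data Long-format data frame with columns `unit`, `coder`, `value`
#'   (`NA` = missing coding), or a coders x units matrix.
#' @return List with `alpha` (NA when undefined), `defined` (FALSE when every
#'   coding is a single category, De = 0), `n_units` (units with >= 2
#'   codings), `n_codings`, `categories`.
#' @export
krippendorff_alpha <- function(data) {
  if (is.matrix(data)) {
    data <- data.frame(
      unit = rep(colnames(data) %||% as.character(seq_len(ncol(data))),
                 each = nrow(data)),
      coder = rep(rownames(data) %||% as.character(seq_len(nrow(data))),
                  times = ncol(data)),
      value = as.vector(data),
      stringsAsFactors = FALSE
    )
  }
  stopifnot(all(c("unit", "coder", "value") %in% names(data)))
  data <- data[!is.na(data$value), , drop = FALSE]
  data$value <- as.character(data$value)
  by_unit <- split(data$value, data$unit)
  by_unit <- by_unit[lengths(by_unit) >= 2]
  if (!length(by_unit)) stop_f("no unit has at least 2 codings")
  cats <- sort(unique(unlist(by_unit)))
  nc <- length(cats)
  o <- matrix(0, nc, nc, dimnames = list(cats, cats))
  for (vals in by_unit) {
    m <- length(vals)
    idx <- match(vals, cats)
    for (p in seq_len(m)) {
      for (q in seq_len(m)) {
        if (p != q) o[idx[p], idx[q]] <- o[idx[p], idx[q]] + 1 / (m - 1)
      }
    }
  }
  n_tot <- sum(o)
  n_c <- rowSums(o)
  d_o <- (n_tot - sum(diag(o))) / n_tot
  d_e <- (n_tot^2 - sum(n_c^2)) / (n_tot * (n_tot - 1))
  if (d_e <= 0) {
    return(list(alpha = NA_real_, defined = FALSE, n_units = length(by_unit),
                n_codings = nrow(data), categories = cats))
  }
  list(alpha = 1 - d_o / d_e, defined = TRUE, n_units = length(by_unit),
       n_codings = nrow(data), categories = cats)
}

#' Per-category (binary) alpha
#'
#' Collapses the codings to category-vs-rest for each observed category and
#' reruns [krippendorff_alpha()] — the per-category reporting style used when
#' agreement differs across labels (e.g. agreement on "personal" vs agreement
#' on "retail").
#'
#' @inheritParams krippendorff_alpha
#' @return Named numeric vector of alphas (NA where undefined).
#' @export
per_category_alpha <- function(data) {
  if (is.matrix(data)) {
    full <- krippendorff_alpha(data)   # normalizes input
    cats <- full$categories
    mat <- data
    vals <- vapply(cats, function(cat) {
      collapsed <- ifelse(is.na(mat), NA, ifelse(mat == cat, cat, ".rest"))
      krippendorff_alpha(collapsed)$alpha
    }, numeric(1))
    return(stats::setNames(vals, cats))
  }
  stopifnot(all(c("unit", "coder", "value") %in% names(data)))
  cats <- sort(unique(stats::na.omit(as.character(data$value))))
  vals <- vapply(cats, function(cat) {
    d <- data
    d$value <- ifelse(is.na(d$value), NA,
                      ifelse(as.character(d$value) == cat, cat, ".rest"))
    krippendorff_alpha(d)$alpha
  }, numeric(1))
  stats::setNames(vals, cats)
}

#' Read a reliability table from CSV
#'
#' @param path CSV with columns `unit`, `coder`, `value`.
#' @return Data frame suitable for [krippendorff_alpha()].
#' @export
read_reliability_csv <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                        progress = FALSE)
  if (!all(c("unit", "coder", "value") %in% names(df))) {
    stop_f("reliability CSV needs unit/coder/value columns")
  }
  as.data.frame(df)
}
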