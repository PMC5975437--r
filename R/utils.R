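#' Linear-interpolation percentile
#'
#' All empirical cutoffs in the pipeline (the 3'UTR density cutoff, the
#' coding-metric cutoffs, the catalog thresholds, the trans-lncRNA TS
#' threshold) use the same percentile convention: linear interpolation
#' between order statistics (`stats::quantile()` type 7). The convention is
#' fixed here because cutoff values depend on it.
#'
#' @param x Numeric vector.
#' @param p Percentile in `[0, 100]`.
#' @return A single numeric value.
#' @examples
#' percentile(1:10, 90) # 9.1
#' @export
percentile <- function(x, p) {
  stopifnot(is.numeric(x), length(x) >= 1L, p >= 0, p <= 100)
  if (anyNA(x)) stop("percentile(): NA values in input")
  unname(stats::quantile(x, probs = p / 100, type = 7, names = FALSE))
}

# internal: stop() with a consistent prefix
abort_data <- function(...) stop(..., call. = FALSE)

# internal: check a tibble has the named columns
check_cols <- function(df, cols, what = deparse(substitute(df))) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0L) {
    abort_data(what, " is missing column(s): ", paste(missing, collapse = ", "))
  }
  invisible(df)
}

# internal: reverse complement of an ACGTN character vector (vectorised)
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}
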