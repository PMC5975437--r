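#' One-sided enrichment test on a 2x2 table
#'
#' Tests whether membership in a catalog class is enriched for external
#' support (e.g. mass-spectrometry peptide evidence) with a one-sided
#' Fisher's exact test. The table is
#' `rbind(c(a, b), c(c, d))` = (supported-in-class, unsupported-in-class;
#' supported-elsewhere, unsupported-elsewhere).
#'
#' Two effect-size estimates are reported: `odds_ratio`, the conditional
#' maximum-likelihood odds ratio of the noncentral hypergeometric model
#' (as in [stats::fisher.test()]), and `risk_ratio`,
#' `(a/(a+b)) / (c/(c+d))` — the support-rate ratio between the class and
#' the rest.
#'
#' @param a,b,c,d Non-negative integer cell counts.
#' @param alternative `"greater"` (default; enrichment), `"less"` or
#'   `"two.sided"`.
#' @return A one-row tibble: `a`, `b`, `c`, `d`, `odds_ratio`,
#'   `risk_ratio`, `p_value`. When a margin is zero both estimates are `NA`
#'   and `p_value` is 1.
#' @export
enrichment_test <- function(a, b, c, d, alternative = "greater") {
  counts <- c(a, b, c, d)
  if (any(counts < 0) || any(counts != round(counts))) {
    abort_data("enrichment_test(): cell counts must be non-negative integers")
  }
  if (sum(counts) < 1) abort_data("enrichment_test(): empty table")
  zero_margin <- (a + b) == 0 || (c + d) == 0 || (a + c) == 0 || (b + d) == 0
  if (zero_margin) {
    return(tibble(a = a, b = b, c = c, d = d, odds_ratio = NA_real_,
                  risk_ratio = NA_real_, p_value = 1))
  }
  ft <- stats::fisher.test(matrix(c(a, b, c, d), nrow = 2, byrow = TRUE),
                           alternative = alternative)
  tibble(
    a = a, b = b, c = c, d = d,
    odds_ratio = unname(ft$estimate),
    risk_ratio = (a / (a + b)) / (c / (c + d)),
    p_value = fisher_p(a, b, c, d, alternative)
  )
}

# one-sided / two-sided Fisher p from the hypergeometric distribution;
# vectorised over table cells (used by enrichment_test and the catalog-wide
# enrichment summary)
fisher_p <- function(a, b, c, d, alternative = "greater") {
  switch(alternative,
    greater = phyper(a - 1, a + b, c + d, a + c, lower.tail = FALSE),
    less = phyper(a, a + b, c + d, a + c, lower.tail = TRUE),
    two.sided = purrr::pmap_dbl(list(a, b, c, d), function(a, b, c, d) {
      stats::fisher.test(matrix(c(a, b, c, d), 2, byrow = TRUE))$p.value
    }),
    abort_data("unknown alternative: ", alternative)
  )
}

#' Class-wise support enrichment for a catalog
#'
#' For each catalog class, builds the 2x2 table of supported vs unsupported
#' transcripts inside and outside the class and runs [enrichment_test()].
#'
#' @param catalog A `ribo_catalog` or tibble with `transcript_id` and `cls`.
#' @param supported_ids Transcript IDs with external support.
#' @param classes Classes to test (default all present except
#'   `"unexpressed"`).
#' @param alternative Passed to [enrichment_test()].
#' @return A tibble with one row per class: `cls`, `total`, `supported`,
#'   `odds_ratio`, `risk_ratio`, `p_value`.
#' @export
catalog_enrichment <- function(catalog, supported_ids, classes = NULL,
                               alternative = "greater") {
  check_cols(catalog, c("transcript_id", "cls"))
  cat_tbl <- filter(as_tibble(catalog), .data$cls != "unexpressed")
  classes <- classes %||% sort(unique(cat_tbl$cls))
  supported <- cat_tbl$transcript_id %in% supported_ids
  purrr::map(classes, function(cl) {
    in_cl <- cat_tbl$cls == cl
    enrichment_test(sum(in_cl & supported), sum(in_cl & !supported),
                    sum(!in_cl & supported), sum(!in_cl & !supported),
                    alternative = alternative) |>
      mutate(cls = cl, total = sum(in_cl), supported = sum(in_cl & supported),
             .before = 1L)
  }) |>
    bind_rows() |>
    select("cls", "total", "supported", "odds_ratio", "risk_ratio",
           "p_value")
}

#' Compare a numeric variable between two groups
#'
#' Two-sample t-test, either Welch (unequal variances, default) or pooled.
#' Used for, e.g., comparing expression of associated vs free lncRNAs, or
#' localization / NMD fold changes between classes.
#'
#' @param values_a,values_b Numeric vectors (each `n >= 2`, nonzero
#'   variance).
#' @param method `"welch"` or `"pooled"`.
#' @return A one-row tibble: `statistic`, `p_value`, `mean_a`, `mean_b`,
#'   `df`, `method`.
#' @export
compare_groups <- function(values_a, values_b, method = c("welch", "pooled")) {
  method <- match.arg(method)
  if (length(values_a) < 2L || length(values_b) < 2L) {
    abort_data("compare_groups(): each group needs n >= 2")
  }
  if (stats::var(values_a) == 0 && stats::var(values_b) == 0) {
    abort_data("compare_groups(): both groups are constant")
  }
  tt <- t.test(values_a, values_b, var.equal = (method == "pooled"))
  tibble(
    statistic = unname(tt$statistic),
    p_value = tt$p.value,
    mean_a = mean(values_a),
    mean_b = mean(values_b),
    df = unname(tt$parameter),
    method = method
  )
}
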