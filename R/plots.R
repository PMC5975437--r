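#' Plot the ribosome-density distributions of one dataset
#'
#' Log2 density distributions for lncRNAs and mRNA regions with the 3'UTR
#' cutoff marked. Zero-density transcripts are shown at a small pseudo
#' value (plotting only; classification never uses it).
#'
#' @param density_tbl Output of [density_table()].
#' @param pseudo Pseudo value added before the log transform (default
#'   1e-9).
#' @return A ggplot object.
#' @export
plot_density_distribution <- function(density_tbl, pseudo = 1e-9) {
  cutoff <- attr(density_tbl, "cutoff")
  df <- density_tbl |>
    filter(.data$expressed) |>
    mutate(log2_density = log2(.data$density + pseudo))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$log2_density)) +
    ggplot2::geom_density(fill = "grey80") +
    ggplot2::geom_vline(xintercept = log2(cutoff + pseudo),
                        linetype = "dashed") +
    ggplot2::labs(x = "log2 ribosome density",
                  y = "density",
                  title = "Ribosome density with 3'UTR 90th-percentile cutoff")
}

#' Plot a catalog's composite-score distribution
#'
#' Kernel density of `RAI * (1 - spec)` with the class thresholds, coloured
#' by final class.
#'
#' @param object A `ribo_catalog`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.ribo_catalog <- function(object, ...) {
  df <- filter(as_tibble(object), !is.na(.data$composite_ubiq))
  pct <- attr(object, "catalog_percentiles") %||% c(5, 95)
  lo <- percentile(df$composite_ubiq, pct[1])
  hi <- percentile(df$composite_ubiq, pct[2])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$composite_ubiq,
                                   fill = .data$cls)) +
    ggplot2::geom_histogram(bins = 40, position = "stack") +
    ggplot2::geom_vline(xintercept = c(lo, hi), linetype = "dashed") +
    ggplot2::labs(x = "RAI * (1 - spec)", y = "lncRNAs",
                  fill = "class",
                  title = "Catalog composite scores and class thresholds")
}

#' Plot per-metric coding scores against their cutoffs
#'
#' Violin + jitter of the calibration CDS scores and the assessed lncRNA
#' ORF scores for each coding metric, with the 10th-percentile cutoffs.
#'
#' @param coding_tbl Output of [assess_coding()].
#' @return A ggplot object.
#' @export
plot_coding_scores <- function(coding_tbl) {
  cutoffs <- attr(coding_tbl, "cutoffs")
  cds <- attr(coding_tbl, "cds_scores")
  long <- bind_rows(
    mutate(select(cds, "floss_score", "rrs_scaled", "frame_sim"),
           group = "CDS"),
    mutate(select(filter(coding_tbl, !is.na(.data$orf_start)),
                  "floss_score", "rrs_scaled", "frame_sim"),
           group = "lncRNA ORF")
  ) |>
    tidyr::pivot_longer(c("floss_score", "rrs_scaled", "frame_sim"),
                        names_to = "metric", values_to = "score")
  cut_df <- tibble(
    metric = c("floss_score", "rrs_scaled", "frame_sim"),
    cutoff = unname(cutoffs[c("floss", "rrs", "frame")])
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$group, y = .data$score)) +
    ggplot2::geom_violin() +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.3, size = 0.5) +
    ggplot2::geom_hline(data = cut_df,
                        ggplot2::aes(yintercept = .data$cutoff),
                        linetype = "dashed") +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "score",
                  title = "Coding metrics with CDS-derived cutoffs")
}
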