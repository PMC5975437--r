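#' Ribosome density of a transcript region
#'
#' Density is the weighted Ribo-seq footprint count over a region divided by
#' the transcript's RNA-seq expression (RPKM) and the region length in nt:
#' footprints per nucleotide per expression unit. Expression normalization
#' lets densities be compared across transcripts within a dataset.
#'
#' @param ribo_count Weighted footprint count on the region.
#' @param rpkm Transcript RPKM (must be positive; callers filter to
#'   expressed transcripts first).
#' @param region_length Region length in nt (>= 1).
#' @return A non-negative number.
#' @examples
#' ribosome_density(10, 2, 500) # 0.01
#' @export
ribosome_density <- function(ribo_count, rpkm, region_length) {
  if (any(region_length < 1)) abort_data("region_length must be >= 1")
  if (any(rpkm <= 0)) {
    abort_data("ribosome density undefined at rpkm <= 0; ",
               "filter to expressed transcripts first")
  }
  ribo_count / (rpkm * region_length)
}

#' Expressed-transcript mask
#'
#' A transcript is expressed when its RNA-seq RPKM is at least `threshold`
#' (inclusive; the default threshold of 1 RPKM keeps a transcript at
#' exactly 1).
#'
#' @param expression Expression tibble (`transcript_id`, `rpkm`).
#' @param threshold RPKM threshold (default 1).
#' @return `expression` with a logical `expressed` column added.
#' @export
expressed_mask <- function(expression, threshold = 1.0) {
  check_cols(expression, c("transcript_id", "rpkm"))
  mutate(expression, expressed = .data$rpkm >= threshold)
}

#' Empirical 3'UTR density cutoff
#'
#' The per-dataset association cutoff is the 90th percentile (linear
#' interpolation) of ribosome densities over the 3'UTRs of expressed mRNAs —
#' the 3'UTR lies downstream of the stop codon and approximates the
#' ribosome-free noise floor, so roughly 10% of this empirical null exceeds
#' the cutoff by construction.
#'
#' @param utr3_densities Densities of expressed-mRNA 3'UTRs.
#' @param pct Percentile (default 90).
#' @return The cutoff value.
#' @examples
#' utr3_density_cutoff(1:10) # 9.1
#' @export
utr3_density_cutoff <- function(utr3_densities, pct = 90) {
  if (length(utr3_densities) == 0L) {
    abort_data("utr3_density_cutoff(): no 3'UTR densities")
  }
  percentile(utr3_densities, pct)
}

#' Classify ribosome association against a density cutoff
#'
#' A transcript at or above the cutoff (the cutoff itself included) is
#' ribosome-associated; below it, ribosome-free.
#'
#' @param density Ribosome density values.
#' @param cutoff Cutoff from [utr3_density_cutoff()].
#' @return Logical vector: `TRUE` = associated.
#' @export
classify_association <- function(density, cutoff) {
  density >= cutoff
}

#' Per-dataset density table and association calls
#'
#' Runs the density stage of one dataset end to end: marks expressed
#' transcripts (RPKM >= `rpkm_min`), derives the 3'UTR density cutoff from
#' expressed mRNAs, and classifies every expressed transcript. mRNAs are
#' scored on their CDS density, lncRNAs (and any other non-coding
#' transcripts) on their whole-transcript density; 3'UTRs shorter than
#' `min_utr3_len` are excluded from the cutoff sample.
#'
#' @param ribo_alignments Ribo-seq alignment tibble (weights assigned,
#'   contaminants removed).
#' @param expression RNA-seq expression tibble.
#' @param transcripts Transcript tibble.
#' @param rpkm_min Expression threshold in RPKM (default 1).
#' @param utr3_percentile Cutoff percentile (default 90).
#' @param min_utr3_len Minimum 3'UTR length entering the cutoff sample
#'   (default 30 nt).
#' @return A tibble with `transcript_id`, `rpkm`, `expressed`, `ribo_count`
#'   (on the scored region), `density` and `associated` (`NA` when not
#'   expressed), with the cutoff attached as attribute `cutoff`.
#' @export
density_table <- function(ribo_alignments, expression, transcripts,
                          rpkm_min = 1.0, utr3_percentile = 90,
                          min_utr3_len = 30L) {
  check_cols(transcripts, c("transcript_id", "length", "cds_start",
                            "cds_end", "utr3_start", "utr3_end"))
  expr <- expressed_mask(expression, rpkm_min)

  scored <- transcripts |>
    mutate(
      start = if_else(is.na(.data$cds_start), 0L, .data$cds_start),
      end = if_else(is.na(.data$cds_end), as.integer(.data$length),
                    .data$cds_end)
    ) |>
    select("transcript_id", "start", "end") |>
    region_counts(alignments = ribo_alignments, regions = _) |>
    left_join(select(expr, "transcript_id", "rpkm", "expressed"),
              by = "transcript_id") |>
    mutate(
      density = if_else(.data$expressed,
                        .data$ribo_count / (.data$rpkm * (.data$end - .data$start)),
                        NA_real_)
    )

  utr3_sample <- transcripts |>
    filter(!is.na(.data$utr3_start),
           .data$utr3_end - .data$utr3_start >= min_utr3_len) |>
    select("transcript_id", start = "utr3_start", end = "utr3_end") |>
    region_counts(alignments = ribo_alignments, regions = _) |>
    inner_join(filter(expr, .data$expressed),
               by = "transcript_id") |>
    mutate(density = .data$ribo_count / (.data$rpkm * (.data$end - .data$start)))
  if (nrow(utr3_sample) == 0L) {
    abort_data("no expressed mRNA 3'UTRs available for the density cutoff")
  }
  cutoff <- utr3_density_cutoff(utr3_sample$density, utr3_percentile)

  out <- scored |>
    mutate(associated = if_else(.data$expressed,
                                classify_association(.data$density, cutoff),
                                NA)) |>
    select("transcript_id", "rpkm", "expressed", "ribo_count", "density",
           "associated")
  attr(out, "cutoff") <- cutoff
  attr(out, "utr3_densities") <- utr3_sample$density
  out
}
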