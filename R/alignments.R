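#' Remove contaminant reads
#'
#' Any read with at least one placement on a contaminant transcript (tRNA,
#' rRNA, snoRNA, miRNA, ...) is removed from all transcripts, not just the
#' contaminant ones — a footprint-sized fragment of an abundant structural
#' RNA is noise wherever it multimaps.
#'
#' @param alignments Alignment tibble.
#' @param contaminant_ids Character vector of contaminant transcript IDs.
#' @return The filtered alignment tibble.
#' @export
remove_contaminants <- function(alignments, contaminant_ids) {
  check_cols(alignments, c("read_id", "transcript_id"))
  if (length(contaminant_ids) == 0L) return(alignments)
  bad_reads <- alignments |>
    filter(.data$transcript_id %in% contaminant_ids) |>
    pull("read_id") |>
    unique()
  filter(alignments, !(.data$read_id %in% bad_reads))
}

#' Reads per kilobase per million mapped reads
#'
#' @param counts Numeric vector of (possibly weighted) read counts.
#' @param lengths Transcript lengths in nt, same order as `counts`.
#' @param total_mapped Total weighted mapped reads in the library; must be
#'   positive.
#' @return Numeric vector of RPKM values.
#' @examples
#' compute_rpkm(10, 1000, 1e6) # 10
#' @export
compute_rpkm <- function(counts, lengths, total_mapped) {
  stopifnot(length(counts) == length(lengths))
  if (!is.numeric(total_mapped) || length(total_mapped) != 1L ||
      total_mapped <= 0) {
    abort_data("total_mapped must be a single positive number")
  }
  counts / ((lengths / 1e3) * (total_mapped / 1e6))
}

#' Quantify transcript expression from alignments
#'
#' Sums placement weights per transcript and converts to RPKM using the
#' weighted mapped-read total of the library. Transcripts without any
#' placement get count and RPKM 0.
#'
#' @param alignments Alignment tibble (weights already set; uniform weights
#'   straight from [load_alignments()] give a simple multimap-aware
#'   quantification).
#' @param transcripts Transcript tibble with `transcript_id` and `length`.
#' @return An expression tibble: `transcript_id`, `count`, `rpkm`, with the
#'   library total attached as attribute `total_mapped`.
#' @export
quantify_expression <- function(alignments, transcripts) {
  check_cols(alignments, c("transcript_id", "weight"))
  check_cols(transcripts, c("transcript_id", "length"))
  counts <- alignments |>
    group_by(.data$transcript_id) |>
    summarise(count = sum(.data$weight), .groups = "drop")
  total <- sum(counts$count)
  if (total <= 0) abort_data("no mapped reads to quantify")
  expr <- transcripts |>
    select("transcript_id", "length") |>
    left_join(counts, by = "transcript_id") |>
    mutate(count = dplyr::coalesce(.data$count, 0),
           rpkm = compute_rpkm(.data$count, .data$length, total)) |>
    select("transcript_id", "count", "rpkm")
  attr(expr, "total_mapped") <- total
  expr
}

#' Expression-proportional multimapping weights
#'
#' For one read with placements on transcripts with expression values
#' `rpkms`, the weight of placement i is `rpkms[i] / sum(rpkms)`. When every
#' candidate transcript has zero expression the ratio is undefined and
#' weights fall back to uniform.
#'
#' @param rpkms Non-negative expression values, one per placement.
#' @return A weight vector summing to 1.
#' @examples
#' multimap_weights(c(3, 1)) # 0.75 0.25
#' @export
multimap_weights <- function(rpkms) {
  if (length(rpkms) == 0L) abort_data("multimap_weights(): empty RPKM vector")
  if (any(rpkms < 0)) abort_data("multimap_weights(): negative RPKM")
  s <- sum(rpkms)
  if (s == 0) rep(1 / length(rpkms), length(rpkms)) else rpkms / s
}

#' Reallocate multimapped reads by transcript expression
#'
#' Replaces the uniform placement weights with expression-proportional ones:
#' each read's placements are weighted by the RPKM of their target
#' transcripts (RNA-seq-derived expression, precomputed once — no
#' iteration).
#'
#' @param alignments Alignment tibble.
#' @param expression Expression tibble from [quantify_expression()] (RNA-seq).
#' @return The alignment tibble with updated `weight`.
#' @export
assign_multimap_weights <- function(alignments, expression) {
  check_cols(alignments, c("read_id", "transcript_id"))
  check_cols(expression, c("transcript_id", "rpkm"))
  alignments |>
    left_join(select(expression, "transcript_id", "rpkm"),
              by = "transcript_id") |>
    mutate(rpkm = dplyr::coalesce(.data$rpkm, 0)) |>
    group_by(.data$read_id) |>
    mutate(weight = multimap_weights(.data$rpkm)) |>
    ungroup() |>
    select(-"rpkm")
}

#' Weighted footprint count over a transcript region
#'
#' Sums the weights of placements whose 5' end falls in the half-open region
#' `[region_start, region_end)` of `transcript_id`.
#'
#' @param alignments Alignment tibble.
#' @param transcript_id Transcript to count on.
#' @param region_start,region_end 0-based half-open region bounds.
#' @return A single non-negative number.
#' @export
weighted_region_count <- function(alignments, transcript_id, region_start,
                                  region_end) {
  if (region_end < region_start) {
    abort_data("inverted region [", region_start, ", ", region_end, ")")
  }
  alignments |>
    filter(.data$transcript_id == .env$transcript_id,
           .data$five_prime >= .env$region_start,
           .data$five_prime < .env$region_end) |>
    pull("weight") |>
    sum()
}

# vectorised weighted 5'-end counts over many regions.
# regions: tibble(transcript_id, start, end) plus any id columns; returns the
# regions tibble with a `ribo_count` column appended.
region_counts <- function(alignments, regions) {
  check_cols(regions, c("transcript_id", "start", "end"))
  regions$.row <- seq_len(nrow(regions))
  hits <- alignments |>
    inner_join(regions, by = "transcript_id", relationship = "many-to-many") |>
    filter(.data$five_prime >= .data$start, .data$five_prime < .data$end) |>
    group_by(.data$.row) |>
    summarise(ribo_count = sum(.data$weight), .groups = "drop")
  regions |>
    left_join(hits, by = ".row") |>
    mutate(ribo_count = dplyr::coalesce(.data$ribo_count, 0)) |>
    select(-".row")
}

#' Write an expression table as TSV
#'
#' @param expression Expression tibble.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_expression_table <- function(expression, path) {
  readr::write_tsv(expression, path)
  invisible(path)
}
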