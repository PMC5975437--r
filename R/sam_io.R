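#' Read transcriptome alignments from SAM or BAM
#'
#' Reads alignment records against transcript references into the tidy
#' alignment representation used throughout the package: one row per kept
#' read-to-transcript placement. Unmapped records are skipped; only
#' sense-strand (forward) placements are kept, matching a strand-specific
#' ribosome-profiling protocol; reads with more than `max_hits` distinct
#' placements are dropped entirely. Placement weights are initialised
#' uniformly (`1 / n_hits`); see [assign_multimap_weights()] for
#' expression-weighted reallocation.
#'
#' @param path SAM or BAM file of alignments to transcript references.
#' @param transcripts Transcript tibble (`transcript_id`, `length`); any
#'   reference name absent from it is an error.
#' @param max_hits Maximum number of distinct placements per read
#'   (default 100).
#' @return A tibble with `read_id`, `transcript_id`, `five_prime` (0-based
#'   transcript position of the 5' end), `read_length`, `n_hits`, `weight`.
#' @export
load_alignments <- function(path, transcripts, max_hits = 100L) {
  check_cols(transcripts, c("transcript_id", "length"))
  bam <- as_bam(path)
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "qwidth"),
    tag = "NH",
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE)
  )
  rec <- Rsamtools::scanBam(bam, param = p)[[1]]
  aln <- tibble(
    read_id = rec$qname,
    flag = rec$flag,
    transcript_id = as.character(rec$rname),
    five_prime = rec$pos - 1L,
    read_length = rec$qwidth,
    nh = if (is.null(rec$tag$NH)) NA_integer_ else rec$tag$NH
  )
  unknown <- setdiff(unique(aln$transcript_id), transcripts$transcript_id)
  if (length(unknown) > 0L) {
    abort_data("alignment reference(s) not in transcript table: ",
               paste(head(unknown, 5), collapse = ", "))
  }
  aln <- filter(aln, bitwAnd(.data$flag, 16L) == 0L) # sense strand only
  if (nrow(aln) == 0L) {
    return(tibble(read_id = character(), transcript_id = character(),
                  five_prime = integer(), read_length = integer(),
                  n_hits = integer(), weight = double()))
  }
  aln <- aln |>
    group_by(.data$read_id) |>
    mutate(n_hits = if (all(is.na(.data$nh))) n() else max(.data$nh, n())) |>
    ungroup() |>
    filter(.data$n_hits <= max_hits) |>
    group_by(.data$read_id) |>
    # placements may have been lost to the strand filter; weights are uniform
    # over the placements actually kept
    mutate(weight = 1 / n()) |>
    ungroup() |>
    select("read_id", "transcript_id", "five_prime", "read_length",
           "n_hits", "weight")
  aln
}

# SAM paths are converted to BAM in tempdir; BAM paths pass through
as_bam <- function(path) {
  if (grepl("\\.bam$", path, ignore.case = TRUE)) return(path)
  dest <- tempfile(fileext = "")
  Rsamtools::asBam(path, destination = dest, overwrite = TRUE,
                   indexDestination = FALSE, format = "sam")
}

#' Write alignments as SAM
#'
#' Emits a plain-text SAM file with one `@SQ` header line per transcript and
#' one record per placement (CIGAR `<len>M`, NH tag, flag 16 for antisense
#' placements when a `strand` column is present). Read sequences are taken
#' from the transcript.
#'
#' @param alignments Alignment tibble (`read_id`, `transcript_id`,
#'   `five_prime`, `read_length`; optional `strand` with values `"+"`/`"-"`).
#' @param transcripts Transcript tibble with `transcript_id`, `length`,
#'   `sequence`.
#' @param path Output SAM path.
#' @return `path`, invisibly.
#' @export
write_sam <- function(alignments, transcripts, path) {
  check_cols(alignments, c("read_id", "transcript_id", "five_prime",
                           "read_length"))
  check_cols(transcripts, c("transcript_id", "length", "sequence"))
  hdr <- c(
    "@HD\tVN:1.6\tSO:unknown",
    sprintf("@SQ\tSN:%s\tLN:%d", transcripts$transcript_id,
            as.integer(transcripts$length))
  )
  seq_of <- setNames(transcripts$sequence, transcripts$transcript_id)
  aln <- alignments |>
    group_by(.data$read_id) |>
    mutate(.nh = n()) |>
    ungroup()
  strand <- if ("strand" %in% names(aln)) aln$strand else rep("+", nrow(aln))
  strand[is.na(strand)] <- "+"
  seqs <- substring(seq_of[aln$transcript_id], aln$five_prime + 1L,
                    aln$five_prime + aln$read_length)
  seqs <- ifelse(strand == "-", revcomp(seqs), seqs)
  recs <- sprintf("%s\t%d\t%s\t%d\t255\t%dM\t*\t0\t0\t%s\t*\tNH:i:%d",
                  aln$read_id, ifelse(strand == "-", 16L, 0L),
                  aln$transcript_id, aln$five_prime + 1L,
                  as.integer(aln$read_length), seqs, aln$.nh)
  writeLines(c(hdr, recs), path)
  invisible(path)
}
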