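#' Transformed fragment length organization similarity score
#'
#' Compares a transcript's footprint-length histogram to the pooled CDS
#' reference. Both histograms are first restricted to the footprint length
#' window and renormalized; the score is `1 - dist(P, Q)` (total-variation
#' complement), so 1 means CDS-like footprint lengths and 0 means none of
#' the length mass overlaps the reference.
#'
#' @param transcript_hist Length histogram of the transcript's footprints.
#' @param cds_reference_hist Pooled CDS length histogram.
#' @param length_window Footprint length window in nt, inclusive
#'   (default `c(25, 35)`).
#' @return A number in `[0, 1]`.
#' @export
floss <- function(transcript_hist, cds_reference_hist,
                  length_window = c(25L, 35L)) {
  p <- restrict_hist(transcript_hist, length_window)
  q <- restrict_hist(cds_reference_hist, length_window)
  if (is.null(p)) {
    abort_data("floss(): transcript has no footprints in the length window")
  }
  if (is.null(q)) {
    abort_data("floss(): CDS reference has no mass in the length window")
  }
  1 - distribution_distance(p, q)
}

# restrict a length histogram to [lo, hi] and renormalize; NULL if empty
restrict_hist <- function(h, window) {
  check_cols(h, c("length", "freq"), "histogram")
  h <- filter(h, .data$length >= window[1], .data$length <= window[2])
  if (nrow(h) == 0L || sum(h$freq) <= 0) return(NULL)
  mutate(h, freq = .data$freq / sum(.data$freq))
}

#' Scaled ribosome release score
#'
#' The raw ribosome release score is the ratio of in-ORF to downstream
#' ribosome footprint density, normalized by the same ratio in RNA-seq to
#' control for library and coverage biases; a translating ORF shows a sharp
#' drop of ribosome occupancy past its stop codon, hence a large raw score.
#' One pseudo-read is added to each of the four counts, and the unbounded
#' raw ratio is mapped to `[0, 1)` by `x / (1 + x)`.
#'
#' For an mRNA CDS the downstream region is the annotated 3'UTR; for a
#' lncRNA ORF it is the stop-to-transcript-end stretch.
#'
#' @param ribo_orf,ribo_down Weighted Ribo-seq counts on the ORF and
#'   downstream regions.
#' @param rna_orf,rna_down Weighted RNA-seq counts on the same regions.
#' @param orf_len,down_len Region lengths in nt; `down_len < 1` is an error
#'   (the ORF is unassessable).
#' @param pseudocount Reads added to each count (default 1).
#' @return The scaled score in `[0, 1)`.
#' @examples
#' rrs(100, 10, 50, 50, 300, 150) # ~ 10/11
#' @export
rrs <- function(ribo_orf, ribo_down, rna_orf, rna_down, orf_len, down_len,
                pseudocount = 1) {
  if (any(down_len < 1) || any(orf_len < 1)) {
    abort_data("rrs(): zero-length region; ORF unassessable")
  }
  ribo_ratio <- ((ribo_orf + pseudocount) / orf_len) /
    ((ribo_down + pseudocount) / down_len)
  rna_ratio <- ((rna_orf + pseudocount) / orf_len) /
    ((rna_down + pseudocount) / down_len)
  raw <- ribo_ratio / rna_ratio
  raw / (1 + raw)
}

#' Footprint frame distribution of an ORF
#'
#' Weighted counts of footprint 5' ends falling inside the ORF, binned by
#' frame relative to the ORF start (`(five_prime - start) %% 3`), with one
#' pseudo-read added per frame and normalized. The pseudocounts guarantee a
#' strictly positive triple even for ORFs without any footprint (which then
#' yields the uninformative uniform distribution).
#'
#' @param alignments Ribo-seq alignment tibble.
#' @param transcript_id Transcript carrying the ORF.
#' @param orf_start,orf_end ORF bounds, 0-based half-open.
#' @param pseudocount Reads added per frame (default 1).
#' @return A numeric triple (frames 0, 1, 2) summing to 1.
#' @export
frame_distribution <- function(alignments, transcript_id, orf_start, orf_end,
                               pseudocount = 1) {
  hits <- alignments |>
    filter(.data$transcript_id == .env$transcript_id,
           .data$five_prime >= .env$orf_start,
           .data$five_prime < .env$orf_end)
  counts <- c(0, 0, 0)
  if (nrow(hits) > 0L) {
    fr <- (hits$five_prime - orf_start) %% 3L
    for (f in 0:2) counts[f + 1L] <- sum(hits$weight[fr == f])
  }
  counts <- counts + pseudocount
  counts / sum(counts)
}

#' Frame-periodicity score (Kullback-Leibler divergence)
#'
#' `framescore(P, Q) = sum_i P(i) * log(P(i) / Q(i))` (natural log) between
#' an ORF's frame distribution `P` and the pooled CDS reference `Q`. Zero
#' means the ORF's three-nucleotide periodicity matches translating CDSs
#' exactly; the score grows with dissimilarity. `Q` must be strictly
#' positive (it is add-one smoothed by construction).
#'
#' @param p,q Frame distributions (numeric triples summing to 1).
#' @return A non-negative number (nats).
#' @export
framescore <- function(p, q) {
  stopifnot(length(p) == 3L, length(q) == 3L)
  if (any(q <= 0)) abort_data("framescore(): reference frame distribution must be strictly positive (smooth it)")
  terms <- ifelse(p > 0, p * log(p / q), 0)
  sum(terms)
}

#' Frame similarity
#'
#' Monotone transform `exp(-framescore)` mapping the KL divergence to
#' `(0, 1]` so that, like the transformed FLOSS and scaled RRS, higher
#' means more CDS-like and the shared "10th-percentile, pass if at or
#' above" cutoff rule applies.
#'
#' @param frame_kl Kullback-Leibler divergence from [framescore()].
#' @return A value in `(0, 1]`.
#' @export
frame_sim <- function(frame_kl) exp(-frame_kl)

#' Coding-metric cutoffs from translating CDSs
#'
#' Each metric's cutoff is the 10th percentile (linear interpolation) of
#' the scores obtained on expressed, ribosome-associated mRNA CDSs, so that
#' 90% of calibration mRNAs are identified as coding. A score at or above
#' the cutoff (cutoff included) passes.
#'
#' @param cds_scores Tibble with columns `floss_score`, `rrs_scaled`,
#'   `frame_sim` over calibration CDSs (>= 10 rows).
#' @param pct Cutoff percentile (default 10).
#' @return Named numeric vector `c(floss=, rrs=, frame=)`.
#' @export
coding_cutoffs <- function(cds_scores, pct = 10) {
  check_cols(cds_scores, c("floss_score", "rrs_scaled", "frame_sim"))
  if (nrow(cds_scores) < 10L) {
    abort_data("coding_cutoffs(): need at least 10 CDS calibration scores, got ",
               nrow(cds_scores))
  }
  c(floss = percentile(cds_scores$floss_score, pct),
    rrs = percentile(cds_scores$rrs_scaled, pct),
    frame = percentile(cds_scores$frame_sim, pct))
}

#' Translation level of a transcript
#'
#' The number of coding filters (FLOSS, RRS, Framescore) passed, maximized
#' over the transcript's putative ORFs; 0 when the transcript has no
#' putative ORF. Levels 0-3 are reported as "A0"-"A3".
#'
#' @param pass_floss,pass_rrs,pass_frame Logical vectors, one element per
#'   ORF (`NA` counts as a fail).
#' @return Integer in 0-3.
#' @export
translation_level <- function(pass_floss, pass_rrs, pass_frame) {
  if (length(pass_floss) == 0L) return(0L)
  n_pass <- (!is.na(pass_floss) & pass_floss) +
    (!is.na(pass_rrs) & pass_rrs) +
    (!is.na(pass_frame) & pass_frame)
  as.integer(max(n_pass))
}

#' Assess coding potential of ribosome-associated lncRNAs in one dataset
#'
#' Builds the pooled CDS reference histograms (footprint lengths and frame
#' distribution) from expressed mRNAs, calibrates the three coding-metric
#' cutoffs on expressed, ribosome-associated mRNA CDSs, scores every
#' putative ORF of every ribosome-associated lncRNA, and assigns each
#' lncRNA its translation level A0-A3.
#'
#' FLOSS is computed per transcript (whole-transcript footprints) and
#' attached to each of its ORFs; RRS and the frame score are per ORF, with
#' the lncRNA downstream region running from the ORF stop to the transcript
#' 3' end.
#'
#' @param ribo_alignments,rna_alignments Alignment tibbles (weights
#'   assigned, contaminants removed).
#' @param transcripts Transcript tibble.
#' @param density_tbl Output of [density_table()] for this dataset.
#' @param lncrna_ids IDs of lncRNA transcripts.
#' @param orfs Putative ORFs from [putative_orfs()] (lncRNAs only).
#' @param length_window FLOSS footprint length window (default 25-35 nt).
#' @param cutoff_percentile Coding cutoff percentile (default 10).
#' @return A per-transcript tibble: `transcript_id`, best ORF bounds,
#'   scores, pass flags and `level`, with attributes `cutoffs`,
#'   `cds_scores` and `orf_scores` (the full per-ORF table).
#' @export
assess_coding <- function(ribo_alignments, rna_alignments, transcripts,
                          density_tbl, lncrna_ids, orfs,
                          length_window = c(25L, 35L),
                          cutoff_percentile = 10) {
  expr_assoc <- density_tbl |>
    filter(.data$expressed)
  mrna <- transcripts |>
    filter(!is.na(.data$cds_start)) |>
    semi_join(expr_assoc, by = "transcript_id")

  # pooled CDS references over expressed mRNAs
  cds_regions <- select(mrna, "transcript_id", start = "cds_start",
                        end = "cds_end")
  ref_hist <- restrict_hist(length_distribution(ribo_alignments, cds_regions),
                            length_window)
  if (is.null(ref_hist)) {
    abort_data("no CDS footprints in the FLOSS length window; cannot build reference")
  }
  ref_frame <- pooled_frame_reference(ribo_alignments, cds_regions)

  # calibration: expressed AND associated mRNAs, scored on their own CDS
  calib_ids <- expr_assoc |>
    filter(!is.na(.data$associated), .data$associated) |>
    semi_join(x = mrna, y = _, by = "transcript_id") |>
    pull("transcript_id")
  calib <- mrna |>
    filter(.data$transcript_id %in% calib_ids,
           .data$utr3_end - .data$utr3_start >= 1L) |>
    mutate(start = .data$cds_start, end = .data$cds_end,
           down_start = .data$utr3_start, down_end = .data$utr3_end)
  cds_scores <- score_orf_table(calib, ribo_alignments, rna_alignments,
                                ref_hist, ref_frame, length_window,
                                floss_region = "cds")
  cutoffs <- coding_cutoffs(cds_scores, cutoff_percentile)

  # lncRNA ORFs on associated lncRNAs
  assoc_lnc <- expr_assoc |>
    filter(.data$transcript_id %in% lncrna_ids, !is.na(.data$associated),
           .data$associated) |>
    pull("transcript_id")
  lnc_orfs <- orfs |>
    filter(.data$transcript_id %in% assoc_lnc) |>
    left_join(select(transcripts, "transcript_id", "length"),
              by = "transcript_id") |>
    mutate(down_start = .data$end, down_end = as.integer(.data$length))
  orf_scores <- score_orf_table(lnc_orfs, ribo_alignments, rna_alignments,
                                ref_hist, ref_frame, length_window,
                                floss_region = "transcript") |>
    mutate(
      pass_floss = !is.na(.data$floss_score) &
        .data$floss_score >= cutoffs[["floss"]],
      pass_rrs = !is.na(.data$rrs_scaled) &
        .data$rrs_scaled >= cutoffs[["rrs"]],
      pass_frame = !is.na(.data$frame_sim) &
        .data$frame_sim >= cutoffs[["frame"]],
      n_pass = .data$pass_floss + .data$pass_rrs + .data$pass_frame
    )

  per_tx <- tibble(transcript_id = assoc_lnc) |>
    left_join(
      orf_scores |>
        group_by(.data$transcript_id) |>
        arrange(dplyr::desc(.data$n_pass), .data$start) |>
        dplyr::slice(1) |>
        ungroup(),
      by = "transcript_id"
    ) |>
    mutate(level = if_else(is.na(.data$n_pass), 0L, as.integer(.data$n_pass))) |>
    select("transcript_id", orf_start = "start", orf_end = "end",
           "floss_score", "rrs_scaled", "frame_kl", "frame_sim",
           "pass_floss", "pass_rrs", "pass_frame", "level")
  attr(per_tx, "cutoffs") <- cutoffs
  attr(per_tx, "cds_scores") <- cds_scores
  attr(per_tx, "orf_scores") <- orf_scores
  per_tx
}

# pooled, add-one-smoothed frame distribution over CDS regions
pooled_frame_reference <- function(ribo_alignments, cds_regions,
                                   pseudocount = 1) {
  hits <- ribo_alignments |>
    inner_join(cds_regions, by = "transcript_id",
               relationship = "many-to-many") |>
    filter(.data$five_prime >= .data$start, .data$five_prime < .data$end)
  counts <- c(0, 0, 0)
  if (nrow(hits) > 0L) {
    fr <- (hits$five_prime - hits$start) %% 3L
    for (f in 0:2) counts[f + 1L] <- sum(hits$weight[fr == f])
  }
  counts <- counts + pseudocount
  counts / sum(counts)
}

# score a table of ORF-like regions (columns transcript_id, start, end,
# down_start, down_end): FLOSS on the transcript or CDS, RRS, framescore
score_orf_table <- function(regions, ribo_alignments, rna_alignments,
                            ref_hist, ref_frame, length_window,
                            floss_region = c("transcript", "cds")) {
  floss_region <- match.arg(floss_region)
  if (nrow(regions) == 0L) {
    return(tibble(transcript_id = character(), start = integer(),
                  end = integer(), floss_score = double(),
                  rrs_scaled = double(), frame_kl = double(),
                  frame_sim = double()))
  }
  # FLOSS: one histogram per transcript
  tx_ids <- unique(regions$transcript_id)
  floss_regions <- if (floss_region == "transcript") {
    tibble(transcript_id = tx_ids, start = 0L, end = .Machine$integer.max)
  } else {
    regions |>
      distinct(.data$transcript_id, .keep_all = TRUE) |>
      select("transcript_id", "start", "end")
  }
  floss_by_tx <- floss_per_transcript(ribo_alignments, floss_regions,
                                      ref_hist, length_window)

  # RRS: weighted counts on ORF and downstream regions, both assays
  orf_r <- region_counts(ribo_alignments,
                         select(regions, "transcript_id", "start", "end"))
  down_r <- region_counts(ribo_alignments,
                          select(regions, "transcript_id",
                                 start = "down_start", end = "down_end"))
  orf_n <- region_counts(rna_alignments,
                         select(regions, "transcript_id", "start", "end"))
  down_n <- region_counts(rna_alignments,
                          select(regions, "transcript_id",
                                 start = "down_start", end = "down_end"))
  down_len <- regions$down_end - regions$down_start
  orf_len <- regions$end - regions$start
  rrs_scaled <- rep(NA_real_, nrow(regions))
  ok <- down_len >= 1L
  rrs_scaled[ok] <- rrs(orf_r$ribo_count[ok], down_r$ribo_count[ok],
                        orf_n$ribo_count[ok], down_n$ribo_count[ok],
                        orf_len[ok], down_len[ok])

  # frame score per region (vectorised equivalent of frame_distribution()
  # + framescore() over every region)
  frame_kl <- frame_kl_batch(ribo_alignments, regions, ref_frame)

  regions |>
    select("transcript_id", "start", "end") |>
    mutate(
      floss_score = floss_by_tx[.data$transcript_id],
      rrs_scaled = rrs_scaled,
      frame_kl = frame_kl,
      frame_sim = frame_sim(frame_kl)
    )
}

# batched per-region frame KL against the pooled reference; add-one
# smoothing per frame, natural-log KL (identical to frame_distribution()
# followed by framescore(), but joined in one pass)
frame_kl_batch <- function(ribo_alignments, regions, ref_frame,
                           pseudocount = 1) {
  reg <- regions |>
    select("transcript_id", "start", "end") |>
    mutate(.row = dplyr::row_number())
  hits <- ribo_alignments |>
    inner_join(reg, by = "transcript_id", relationship = "many-to-many") |>
    filter(.data$five_prime >= .data$start, .data$five_prime < .data$end) |>
    mutate(frame = (.data$five_prime - .data$start) %% 3L) |>
    group_by(.data$.row, .data$frame) |>
    summarise(w = sum(.data$weight), .groups = "drop")
  counts <- matrix(0, nrow = nrow(reg), ncol = 3L)
  if (nrow(hits) > 0L) {
    counts[cbind(hits$.row, hits$frame + 1L)] <- hits$w
  }
  counts <- counts + pseudocount
  p <- counts / rowSums(counts)
  rowSums(p * log(p / matrix(ref_frame, nrow(reg), 3, byrow = TRUE)))
}

# per-transcript FLOSS against a prepared (already window-restricted,
# renormalized) reference histogram
floss_per_transcript <- function(ribo_alignments, regions, ref_hist,
                                 length_window) {
  hits <- ribo_alignments |>
    inner_join(regions, by = "transcript_id") |>
    filter(.data$five_prime >= .data$start, .data$five_prime < .data$end,
           .data$read_length >= length_window[1],
           .data$read_length <= length_window[2])
  out <- setNames(rep(NA_real_, nrow(regions)), regions$transcript_id)
  if (nrow(hits) == 0L) return(out)
  per_len <- hits |>
    group_by(.data$transcript_id, length = .data$read_length) |>
    summarise(freq = sum(.data$weight), .groups = "drop_last") |>
    mutate(freq = .data$freq / sum(.data$freq)) |>
    ungroup()
  ref <- rename(ref_hist, ref_freq = "freq")
  tv <- per_len |>
    dplyr::full_join(
      tidyr::crossing(transcript_id = unique(per_len$transcript_id),
                      select(ref, "length", "ref_freq")),
      by = c("transcript_id", "length")
    ) |>
    mutate(freq = dplyr::coalesce(.data$freq, 0),
           ref_freq = dplyr::coalesce(.data$ref_freq, 0)) |>
    group_by(.data$transcript_id) |>
    summarise(tv = 0.5 * sum(abs(.data$freq - .data$ref_freq)),
              .groups = "drop")
  out[tv$transcript_id] <- 1 - tv$tv
  out
}
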