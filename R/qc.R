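#' Footprint length distribution over a region set
#'
#' Builds the normalized, weight-aware histogram of read lengths over the
#' placements whose 5' end falls inside one of the given regions. Used both
#' for dataset QC (lncRNA vs CDS footprint length similarity) and as the
#' FLOSS reference/query histograms.
#'
#' @param alignments Alignment tibble.
#' @param regions Region tibble (`transcript_id`, `start`, `end`,
#'   0-based half-open).
#' @return A length histogram: tibble with `length` (nt) and `freq` summing
#'   to 1.
#' @export
length_distribution <- function(alignments, regions) {
  if (nrow(regions) == 0L) abort_data("length_distribution(): empty region set")
  hits <- alignments |>
    inner_join(select(regions, "transcript_id", "start", "end"),
               by = "transcript_id", relationship = "many-to-many") |>
    filter(.data$five_prime >= .data$start, .data$five_prime < .data$end)
  if (nrow(hits) == 0L) {
    abort_data("no footprints fall inside the region set")
  }
  hits |>
    group_by(length = .data$read_length) |>
    summarise(freq = sum(.data$weight), .groups = "drop") |>
    mutate(freq = .data$freq / sum(.data$freq)) |>
    arrange(.data$length)
}

#' Total-variation distance between two length histograms
#'
#' `dist(P, Q) = 0.5 * sum_l |P(l) - Q(l)|` over the union of supports
#' (missing lengths count as 0). Ranges from 0 (identical) to 1 (disjoint
#' supports). Used to compare the footprint length distribution on lncRNAs
#' against the one on CDSs when selecting datasets, and (as `1 - dist`) as
#' the transformed FLOSS score.
#'
#' @param p,q Length histograms (tibbles with `length`, `freq`, each summing
#'   to 1 within `1e-6`).
#' @return A number in `[0, 1]`.
#' @export
distribution_distance <- function(p, q) {
  check_cols(p, c("length", "freq"), "p")
  check_cols(q, c("length", "freq"), "q")
  if (abs(sum(p$freq) - 1) > 1e-6 || abs(sum(q$freq) - 1) > 1e-6) {
    abort_data("distribution_distance(): histograms must be normalized")
  }
  joined <- dplyr::full_join(p, q, by = "length", suffix = c("_p", "_q")) |>
    mutate(freq_p = dplyr::coalesce(.data$freq_p, 0),
           freq_q = dplyr::coalesce(.data$freq_q, 0))
  0.5 * sum(abs(joined$freq_p - joined$freq_q))
}

#' Select one representative dataset per tissue
#'
#' Applies the three dataset-selection criteria: (i) RNA-seq and Ribo-seq
#' mapping rates both strictly greater than `rate_min`; (ii) footprint
#' length-distribution distance between lncRNAs and CDSs strictly below
#' `dist_max`; (iii) among passing datasets of the same tissue, only the one
#' with the smallest `dist_value` is selected (ties broken by `dataset_id`).
#'
#' @param profiles Tibble with `dataset_id`, `tissue`, `mapping_rate_rna`,
#'   `mapping_rate_ribo`, `dist_value`.
#' @param rate_min Minimum mapping rate (default 0.30, strict).
#' @param dist_max Maximum dist value (default 0.15, strict).
#' @return `profiles` with logical columns `passes` and `selected` added.
#' @export
select_datasets <- function(profiles, rate_min = 0.30, dist_max = 0.15) {
  check_cols(profiles, c("dataset_id", "tissue", "mapping_rate_rna",
                         "mapping_rate_ribo", "dist_value"))
  pick_best <- function(passes, dist_value, dataset_id) {
    sel <- rep(FALSE, length(passes))
    ok <- which(passes)
    if (length(ok) > 0L) {
      sel[ok[order(dist_value[ok], dataset_id[ok])][1]] <- TRUE
    }
    sel
  }
  profiles |>
    mutate(passes = .data$mapping_rate_rna > rate_min &
             .data$mapping_rate_ribo > rate_min &
             .data$dist_value < dist_max) |>
    group_by(.data$tissue) |>
    mutate(selected = pick_best(.data$passes, .data$dist_value,
                                .data$dataset_id)) |>
    ungroup()
}

#' QC profile of one dataset
#'
#' Computes the lncRNA-vs-CDS footprint length-distribution distance for a
#' dataset's Ribo-seq alignments, packaging it with externally supplied
#' mapping rates into the profile row consumed by [select_datasets()].
#'
#' @param alignments Ribo-seq alignment tibble (contaminants removed).
#' @param transcripts Transcript tibble.
#' @param lncrna_ids IDs of lncRNA transcripts.
#' @param dataset_id,tissue Identifiers for the profile row.
#' @param mapping_rate_rna,mapping_rate_ribo Mapping rates in `[0, 1]`,
#'   taken from aligner logs.
#' @return A one-row profile tibble.
#' @export
dataset_profile <- function(alignments, transcripts, lncrna_ids, dataset_id,
                            tissue, mapping_rate_rna, mapping_rate_ribo) {
  cds_regions <- transcripts |>
    filter(!is.na(.data$cds_start)) |>
    select("transcript_id", start = "cds_start", end = "cds_end")
  lnc_regions <- transcripts |>
    filter(.data$transcript_id %in% lncrna_ids) |>
    mutate(start = 0L, end = as.integer(.data$length)) |>
    select("transcript_id", "start", "end")
  d <- distribution_distance(
    length_distribution(alignments, cds_regions),
    length_distribution(alignments, lnc_regions)
  )
  tibble(dataset_id = dataset_id, tissue = tissue,
         mapping_rate_rna = mapping_rate_rna,
         mapping_rate_ribo = mapping_rate_ribo,
         dist_value = d)
}
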