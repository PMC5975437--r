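#' Enumerate putative ORFs in a transcript sequence
#'
#' A putative ORF is a run of codons starting with ATG and ending with the
#' first in-frame stop codon (TGA, TAA or TAG), with total length (stop
#' included) of at least `min_len` nucleotides. One ORF is reported per
#' (frame, stop codon): the longest one, i.e. anchored at the most 5'
#' in-frame ATG that is not preceded by another in-frame stop. Codons
#' containing N never count as start or stop codons.
#'
#' @param sequence A single DNA string over `{A,C,G,T,N}`.
#' @param min_len Minimum ORF length in nt, stop codon included (default 30).
#' @return A tibble with 0-based half-open `start`, `end`, plus `frame`
#'   (`start %% 3`) and `orf_len`, sorted by `start`.
#' @examples
#' find_putative_orfs(paste0("ATG", strrep("AAA", 8), "TAG"))
#' @export
find_putative_orfs <- function(sequence, min_len = 30L) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  n <- nchar(sequence)
  out <- vector("list", 3L)
  stops <- c("TGA", "TAA", "TAG")
  for (f in 0:2) {
    starts_nt <- seq.int(f + 1L, by = 3L, length.out = max(0L, (n - f) %/% 3L))
    if (length(starts_nt) == 0L) next
    codons <- substring(sequence, starts_nt, starts_nt + 2L)
    is_atg <- codons == "ATG"
    is_stop <- codons %in% stops
    if (!any(is_stop) || !any(is_atg)) next
    stop_idx <- which(is_stop)
    prev_stop <- c(0L, stop_idx[-length(stop_idx)])
    atg_idx <- which(is_atg)
    orf <- purrr::map2(stop_idx, prev_stop, function(s, ps) {
      cand <- atg_idx[atg_idx > ps & atg_idx < s]
      if (length(cand) == 0L) return(NULL)
      a <- cand[1]
      c(start = starts_nt[a] - 1L, end = starts_nt[s] + 2L) # 0-based half-open
    })
    out[[f + 1L]] <- purrr::compact(orf)
  }
  orfs <- unlist(out, use.names = FALSE)
  if (is.null(orfs)) {
    return(tibble(start = integer(), end = integer(),
                  frame = integer(), orf_len = integer()))
  }
  m <- matrix(orfs, ncol = 2L, byrow = TRUE)
  res <- tibble(start = as.integer(m[, 1]), end = as.integer(m[, 2])) |>
    mutate(frame = .data$start %% 3L, orf_len = .data$end - .data$start) |>
    filter(.data$orf_len >= min_len) |>
    arrange(.data$start)
  res
}

#' Enumerate putative ORFs for every transcript in a table
#'
#' @param transcripts Transcript tibble with `transcript_id` and `sequence`.
#' @param min_len Minimum ORF length in nt (stop included).
#' @return A tibble with `transcript_id`, `start`, `end`, `frame`, `orf_len`.
#' @export
putative_orfs <- function(transcripts, min_len = 30L) {
  check_cols(transcripts, c("transcript_id", "sequence"))
  purrr::map2(transcripts$transcript_id, transcripts$sequence, function(id, s) {
    mutate(find_putative_orfs(s, min_len = min_len), transcript_id = id,
           .before = 1L)
  }) |>
    bind_rows()
}
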