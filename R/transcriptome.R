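#' GENCODE lncRNA biotypes used as the default whitelist
#'
#' The twelve transcript biotypes treated as long non-coding RNA when
#' selecting lncRNAs from an annotation. Matching is case-insensitive.
#'
#' @export
lnc_biotypes_default <- c(
  "lincRNA", "antisense", "TEC", "sense_intronic", "retained_intron",
  "processed_transcript", "sense_overlapping", "3prime_overlapping_ncRNA",
  "pseudogene", "bidirectional_promoter_lncRNA", "non_coding", "macro_lncRNA"
)

#' Build transcript models from a GTF annotation and a genome
#'
#' Parses exon and CDS records, splices exons 5' to 3' (reverse-complementing
#' minus-strand transcripts), and projects CDS coordinates into transcript
#' coordinates. The result is one row per transcript with its full spliced
#' sequence and, for protein-coding transcripts, the 5'UTR/CDS/3'UTR spans.
#'
#' All transcript-coordinate spans are 0-based half-open. Stop-codon records,
#' when present in the GTF, are merged into the CDS span so that the CDS ends
#' with its stop codon.
#'
#' @param gtf Path to a GTF file (GENCODE dialect: attributes `transcript_id`,
#'   `gene_id` and `transcript_type` or `transcript_biotype`), or a
#'   `GRanges` already imported from one.
#' @param genome Path to a genome FASTA, a `Biostrings::DNAStringSet`, or a
#'   named character vector of chromosome sequences.
#' @return A tibble with columns `transcript_id`, `gene_id`, `biotype`,
#'   `length`, `sequence`, and integer columns `utr5_start`, `utr5_end`,
#'   `cds_start`, `cds_end`, `utr3_start`, `utr3_end` (`NA` for
#'   non-coding transcripts).
#' @export
parse_annotation <- function(gtf, genome) {
  gr <- if (inherits(gtf, "GRanges")) gtf else rtracklayer::import(gtf, format = "gtf")
  genome <- as_genome(genome)

  md <- S4Vectors::mcols(gr)
  biotype_col <- intersect(c("transcript_type", "transcript_biotype", "gene_type"),
                           names(md))[1]
  if (is.na(biotype_col)) md$transcript_type <- NA_character_ else
    md$transcript_type <- as.character(md[[biotype_col]])

  feat <- tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),  # 1-based inclusive (GTF)
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    type = as.character(md$type),
    transcript_id = as.character(md$transcript_id),
    gene_id = as.character(md$gene_id),
    biotype = md$transcript_type
  )

  exons <- filter(feat, .data$type == "exon")
  if (nrow(exons) == 0L) abort_data("annotation contains no exon records")
  cds <- filter(feat, .data$type %in% c("CDS", "stop_codon"))

  bad_chrom <- setdiff(unique(exons$chrom), names(genome))
  if (length(bad_chrom) > 0L) {
    tx <- unique(exons$transcript_id[exons$chrom %in% bad_chrom])
    abort_data("chromosome(s) ", paste(bad_chrom, collapse = ", "),
               " absent from genome (transcript(s) ",
               paste(head(tx, 5), collapse = ", "), ")")
  }
  chrom_len <- setNames(Biostrings::width(genome), names(genome))
  oob <- exons$start < 1L | exons$end > chrom_len[exons$chrom]
  if (any(oob)) {
    abort_data("exon outside chromosome bounds for transcript(s) ",
               paste(unique(exons$transcript_id[oob]), collapse = ", "))
  }

  exons <- arrange(exons, .data$transcript_id, .data$start)
  exon_seq <- as.character(Biostrings::subseq(
    genome[exons$chrom], start = exons$start, end = exons$end))

  tx <- exons |>
    mutate(exon_seq = exon_seq, exon_len = .data$end - .data$start + 1L) |>
    group_by(.data$transcript_id, .data$gene_id, .data$biotype, .data$strand) |>
    summarise(
      sequence = if (.data$strand[1] == "-") {
        revcomp(paste0(.data$exon_seq, collapse = ""))
      } else {
        paste0(.data$exon_seq, collapse = "")
      },
      length = sum(.data$exon_len),
      exon_starts = list(.data$start),
      exon_ends = list(.data$end),
      .groups = "drop"
    )

  # project CDS (incl. stop codon) into transcript coordinates
  cds_span <- if (nrow(cds) == 0L) {
    tibble(transcript_id = character(), g5 = integer(), g3 = integer())
  } else {
    cds |>
      group_by(.data$transcript_id) |>
      summarise(g5 = min(.data$start), g3 = max(.data$end), .groups = "drop")
  }
  tx <- left_join(tx, cds_span, by = "transcript_id")

  span <- purrr::pmap(
    list(tx$exon_starts, tx$exon_ends, tx$strand, tx$g5, tx$g3, tx$length,
         tx$transcript_id),
    function(es, ee, strand, g5, g3, len, id) {
      if (is.na(g5)) {
        return(c(NA_integer_, NA_integer_))
      }
      lo <- genomic_to_tx(g5, es, ee, strand)
      hi <- genomic_to_tx(g3, es, ee, strand)
      if (is.na(lo) || is.na(hi)) {
        abort_data("CDS of transcript ", id, " falls outside its exons")
      }
      c(min(lo, hi), max(lo, hi) + 1L) # 0-based half-open
    }
  )
  cds_start <- purrr::map_int(span, 1)
  cds_end <- purrr::map_int(span, 2)

  out <- tx |>
    mutate(
      cds_start = cds_start,
      cds_end = cds_end,
      utr5_start = if_else(is.na(cds_start), NA_integer_, 0L),
      utr5_end = cds_start,
      utr3_start = cds_end,
      utr3_end = if_else(is.na(cds_end), NA_integer_, as.integer(.data$length))
    ) |>
    select("transcript_id", "gene_id", "biotype", "length", "sequence",
           "utr5_start", "utr5_end", "cds_start", "cds_end",
           "utr3_start", "utr3_end") |>
    arrange(.data$transcript_id)
  out
}

# map one genomic position (1-based) to a 0-based transcript coordinate.
# exon starts/ends are 1-based inclusive genomic coordinates, sorted.
genomic_to_tx <- function(g, exon_starts, exon_ends, strand) {
  widths <- exon_ends - exon_starts + 1L
  idx <- which(g >= exon_starts & g <= exon_ends)
  if (length(idx) == 0L) return(NA_integer_)
  idx <- idx[1]
  plus_coord <- sum(widths[seq_len(idx - 1L)]) + (g - exon_starts[idx])
  if (strand == "-") sum(widths) - 1L - plus_coord else as.integer(plus_coord)
}

# accept a genome as path / DNAStringSet / named character vector
as_genome <- function(genome) {
  if (inherits(genome, "DNAStringSet")) return(genome)
  if (is.character(genome) && length(genome) == 1L && file.exists(genome)) {
    g <- Biostrings::readDNAStringSet(genome)
    names(g) <- sub("\\s.*$", "", names(g))
    return(g)
  }
  if (is.character(genome) && !is.null(names(genome))) {
    return(Biostrings::DNAStringSet(genome))
  }
  abort_data("genome must be a FASTA path, DNAStringSet, or named character vector")
}

#' Select lncRNA transcripts
#'
#' Keeps transcripts whose biotype belongs to the lncRNA whitelist and whose
#' gene is not a known protein-coding gene. The latter excludes, e.g., a
#' retained-intron transcript of a protein-coding gene.
#'
#' @param transcripts Transcript tibble from [parse_annotation()].
#' @param lnc_biotypes Character vector of biotypes to keep
#'   (default [lnc_biotypes_default]; matched case-insensitively).
#' @param coding_gene_ids Gene IDs with at least one protein-coding
#'   transcript. Defaults to genes carrying a `protein_coding` biotype in
#'   `transcripts` itself.
#' @return The filtered transcript tibble.
#' @export
select_lncrnas <- function(transcripts,
                           lnc_biotypes = lnc_biotypes_default,
                           coding_gene_ids = NULL) {
  check_cols(transcripts, c("transcript_id", "gene_id", "biotype"))
  if (is.null(coding_gene_ids)) {
    coding_gene_ids <- transcripts |>
      filter(tolower(.data$biotype) == "protein_coding") |>
      pull("gene_id") |>
      unique()
  }
  transcripts |>
    filter(tolower(.data$biotype) %in% tolower(lnc_biotypes),
           !(.data$gene_id %in% coding_gene_ids))
}

#' Write transcript sequences as FASTA
#'
#' @param transcripts Transcript tibble with `transcript_id` and `sequence`.
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_transcriptome_fasta <- function(transcripts, path) {
  check_cols(transcripts, c("transcript_id", "sequence"))
  seqs <- Biostrings::DNAStringSet(setNames(transcripts$sequence,
                                            transcripts$transcript_id))
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Read transcript sequences from FASTA
#'
#' @param path FASTA path.
#' @return A tibble with `transcript_id`, `length` and `sequence`.
#' @export
read_transcriptome_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  tibble(
    transcript_id = sub("\\s.*$", "", names(seqs)),
    length = Biostrings::width(seqs),
    sequence = unname(as.character(seqs))
  )
}

#' Write the transcript table as TSV
#'
#' Sequence is omitted; spans are kept so the table can be re-joined with a
#' transcriptome FASTA by [read_transcriptome_fasta()].
#'
#' @param transcripts Transcript tibble.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_transcript_table <- function(transcripts, path) {
  readr::write_tsv(select(transcripts, -dplyr::any_of("sequence")), path)
  invisible(path)
}
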