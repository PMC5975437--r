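write_gtf_lines <- function(lines, path = tempfile(fileext = ".gtf")) {
  writeLines(lines, path)
  path
}

gtf_row <- function(chrom, type, start, end, strand, tx, gene,
                    biotype = "protein_coding") {
  sprintf(
    '%s\ttest\t%s\t%d\t%d\t.\t%s\t.\tgene_id "%s"; transcript_id "%s"; transcript_type "%s";',
    chrom, type, start, end, strand, gene, tx, biotype)
}

test_that("exons are spliced 5' to 3' and minus strands reverse-complemented", {
  genome <- c(chr1 = "AAATTTCCC")
  gtf <- write_gtf_lines(c(
    gtf_row("chr1", "exon", 1, 3, "+", "tx_plus", "g1", "lincRNA"),
    gtf_row("chr1", "exon", 7, 9, "+", "tx_plus", "g1", "lincRNA"),
    gtf_row("chr1", "exon", 1, 3, "-", "tx_minus", "g2", "lincRNA")
  ))
  tx <- parse_annotation(gtf, genome)
  plus <- tx[tx$transcript_id == "tx_plus", ]
  expect_equal(plus$sequence, "AAACCC")
  expect_equal(plus$length, 6)
  minus <- tx[tx$transcript_id == "tx_minus", ]
  expect_equal(minus$sequence, "TTT")
})

test_that("CDS spans project into transcript coordinates and partition the mRNA", {
  # 3-exon transcript; CDS (with stop codon) covers the middle exon
  genome <- c(chr1 = paste0(strrep("A", 10), "ATGAAATAA", strrep("C", 10)))
  gtf <- write_gtf_lines(c(
    gtf_row("chr1", "exon", 1, 10, "+", "tx1", "g1"),
    gtf_row("chr1", "exon", 11, 19, "+", "tx1", "g1"),
    gtf_row("chr1", "exon", 20, 29, "+", "tx1", "g1"),
    gtf_row("chr1", "CDS", 11, 16, "+", "tx1", "g1"),
    gtf_row("chr1", "stop_codon", 17, 19, "+", "tx1", "g1")
  ))
  tx <- parse_annotation(gtf, genome)
  expect_equal(tx$utr5_start, 0L)
  expect_equal(tx$utr5_end, 10L)
  expect_equal(tx$cds_start, 10L)
  expect_equal(tx$cds_end, 19L)
  expect_equal(tx$utr3_start, 19L)
  expect_equal(tx$utr3_end, 29L)
  expect_equal((tx$cds_end - tx$cds_start) %% 3L, 0L)
  expect_equal(substr(tx$sequence, tx$cds_start + 1, tx$cds_start + 3), "ATG")
})

test_that("minus-strand CDS projection respects transcript orientation", {
  # minus-strand: transcript sequence is the reverse complement
  genome <- c(chr1 = "TTATTTCATGGG") # revcomp = CCCATGAAATAA
  gtf <- write_gtf_lines(c(
    gtf_row("chr1", "exon", 1, 12, "-", "txm", "g1"),
    gtf_row("chr1", "CDS", 4, 9, "-", "txm", "g1"),
    gtf_row("chr1", "stop_codon", 1, 3, "-", "txm", "g1")
  ))
  tx <- parse_annotation(gtf, genome)
  expect_equal(tx$sequence, "CCCATGAAATAA")
  expect_equal(tx$cds_start, 3L)
  expect_equal(tx$cds_end, 12L)
})

test_that("missing chromosomes and out-of-bounds exons are hard errors", {
  genome <- c(chr1 = "AAATTTCCC")
  bad_chrom <- write_gtf_lines(
    gtf_row("chrX", "exon", 1, 3, "+", "tx1", "g1"))
  expect_error(parse_annotation(bad_chrom, genome), "chrX")
  oob <- write_gtf_lines(
    gtf_row("chr1", "exon", 5, 50, "+", "tx2", "g1"))
  expect_error(parse_annotation(oob, genome), "bounds")
})

test_that("lncRNA selection honours the biotype whitelist and coding genes", {
  tx <- tibble::tibble(
    transcript_id = c("t1", "t2", "t3", "t4"),
    gene_id = c("gA", "gB", "gB", "gC"),
    biotype = c("lincRNA", "protein_coding", "retained_intron", "miRNA")
  )
  kept <- select_lncrnas(tx)
  # the retained_intron transcript of protein-coding gene gB is excluded,
  # as is the miRNA (not whitelisted)
  expect_equal(kept$transcript_id, "t1")
  # explicit coding set overrides detection
  kept2 <- select_lncrnas(tx, coding_gene_ids = character())
  expect_setequal(kept2$transcript_id, c("t1", "t3"))
  expect_equal(nrow(select_lncrnas(tx[0, ])), 0L)
})

test_that("FASTA round trip preserves sequences byte-exactly", {
  tx <- tiny_transcripts()
  fa <- tempfile(fileext = ".fa")
  write_transcriptome_fasta(tx, fa)
  back <- read_transcriptome_fasta(fa)
  expect_equal(back$transcript_id, tx$transcript_id)
  expect_identical(back$sequence, tx$sequence)
  expect_equal(back$length, tx$length)
})
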