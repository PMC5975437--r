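# small in-code fixtures and independent oracles shared across tests

# quick alignment-tibble builder: one row per placement
aln_tbl <- function(transcript_id, five_prime, read_length = 30L,
                    read_id = NULL, weight = 1, n_hits = 1L) {
  n <- max(length(transcript_id), length(five_prime))
  tibble::tibble(
    read_id = read_id %||% sprintf("r%03d", seq_len(n)),
    transcript_id = rep_len(transcript_id, n),
    five_prime = as.integer(rep_len(five_prime, n)),
    read_length = as.integer(rep_len(read_length, n)),
    n_hits = as.integer(rep_len(n_hits, n)),
    weight = rep_len(weight, n)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# length histogram from a lengths/freqs pair
hist_tbl <- function(lengths, freqs) {
  tibble::tibble(length = as.integer(lengths), freq = freqs)
}

# exhaustive ORF oracle: tests every (ATG, stop) pair per frame and keeps,
# per stop, the most 5' ATG with no intervening in-frame stop
orf_scan_oracle <- function(seq, min_len = 30L) {
  n <- nchar(seq)
  stops <- c("TGA", "TAA", "TAG")
  found <- list()
  for (f in 0:2) {
    starts <- seq.int(f + 1L, by = 3L, length.out = max(0L, (n - f) %/% 3L))
    if (length(starts) == 0L) next
    codons <- substring(seq, starts, starts + 2L)
    for (si in which(codons %in% stops)) {
      best <- NA_integer_
      for (ai in seq_len(si - 1L)) {
        if (codons[ai] %in% stops) best <- NA_integer_ # reset past a stop
        else if (codons[ai] == "ATG" && is.na(best)) best <- ai
      }
      if (!is.na(best)) {
        len <- (si - best + 1L) * 3L
        if (len >= min_len) {
          found[[length(found) + 1L]] <-
            c(start = starts[best] - 1L, end = starts[si] + 2L)
        }
      }
    }
  }
  if (length(found) == 0L) {
    return(tibble::tibble(start = integer(), end = integer()))
  }
  m <- do.call(rbind, found)
  tibble::tibble(start = as.integer(m[, "start"]),
                 end = as.integer(m[, "end"])) |>
    dplyr::arrange(start)
}

# brute-force one-sided (greater) Fisher tail: explicit binomial-coefficient
# sum over tables at least as extreme, vectorised over tables
fisher_tail_oracle <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c; n <- r1 + r2
  denom <- lchoose(n, c1)
  p <- numeric(length(a))
  for (k in 0:max(c1)) {
    ok <- k >= a & k <= pmin(r1, c1)
    p[ok] <- p[ok] + exp(lchoose(r1[ok], k) + lchoose(r2[ok], c1[ok] - k) -
                           denom[ok])
  }
  p
}

# random normalized length histogram
random_hist <- function(k = 5, lengths = 25:35) {
  l <- sort(sample(lengths, k))
  w <- runif(k)
  hist_tbl(l, w / sum(w))
}

# a tiny deterministic transcript table: two mRNAs and two lncRNAs
tiny_transcripts <- function() {
  mk <- function(id, biotype, utr5, cds_codons, utr3, gene = paste0("G", id)) {
    set.seed(nchar(id) * 7 + utr5)
    sense <- setdiff(apply(expand.grid(c("A", "C", "G", "T"),
                                       c("A", "C", "G", "T"),
                                       c("A", "C", "G", "T")),
                           1, paste, collapse = ""),
                     c("TGA", "TAA", "TAG"))
    rand <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                              collapse = "")
    if (biotype == "protein_coding") {
      cds <- paste0("ATG", paste(sample(sense, cds_codons - 2, replace = TRUE),
                                 collapse = ""), "TAA")
      seq <- paste0(rand(utr5), cds, rand(utr3))
      tibble::tibble(transcript_id = id, gene_id = gene, biotype = biotype,
                     length = nchar(seq), sequence = seq,
                     utr5_start = 0L, utr5_end = utr5,
                     cds_start = utr5, cds_end = utr5 + 3L * cds_codons,
                     utr3_start = utr5 + 3L * cds_codons,
                     utr3_end = nchar(seq))
    } else {
      seq <- paste0(rand(utr5), "ATG",
                    paste(sample(sense, cds_codons - 2, replace = TRUE),
                          collapse = ""), "TAA", rand(utr3))
      tibble::tibble(transcript_id = id, gene_id = gene, biotype = biotype,
                     length = nchar(seq), sequence = seq,
                     utr5_start = NA_integer_, utr5_end = NA_integer_,
                     cds_start = NA_integer_, cds_end = NA_integer_,
                     utr3_start = NA_integer_, utr3_end = NA_integer_)
    }
  }
  dplyr::bind_rows(
    mk("M1", "protein_coding", 60L, 100L, 120L),
    mk("M2", "protein_coding", 80L, 150L, 200L),
    mk("L1", "lincRNA", 100L, 40L, 150L),
    mk("L2", "antisense", 120L, 50L, 100L)
  )
}
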