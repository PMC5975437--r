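#' Simulation configuration
#'
#' Defaults describe a small but realistic ribosome-profiling study: four
#' transcript classes (mRNAs, translated lncRNAs, ribosome-associated but
#' untranslated lncRNAs, ribosome-free lncRNAs) plus a few abundant
#' contaminant RNAs; footprints on translating ORFs are ~29 nt with strong
#' frame-0 periodicity and a sharp coverage drop past the stop codon, while
#' untranslated/background footprints are broader in length and aperiodic.
#' Background (ribosome-free) coverage follows the same law as mRNA 3'UTRs,
#' which is what gives the 90th-percentile 3'UTR cutoff its intended
#' operating point.
#'
#' @param n_mrna,n_lnc_translated,n_lnc_associated,n_lnc_free Class sizes.
#' @param n_contaminant Number of contaminant (rRNA-like) transcripts.
#' @param n_datasets Number of datasets (tissues) to simulate.
#' @param footprint_mean,footprint_sd Footprint length law (nt) for
#'   translating ribosomes, clipped to 25-35.
#' @param bg_footprint_mean,bg_footprint_sd Length law for background /
#'   untranslated footprints, clipped to 22-38.
#' @param periodicity_strength Fraction of in-ORF 5' ends forced to frame 0.
#' @param stop_dropoff Downstream-to-ORF coverage ratio past the stop.
#' @param rna_depth,ribo_depth Expected reads per kb per RPKM unit on
#'   covered regions.
#' @param rna_read_length RNA-seq read length (nt).
#' @param rpkm_meanlog,rpkm_sdlog Log-normal law of transcript abundance.
#' @param dataset_rpkm_sdlog Per-dataset log-normal jitter of abundance.
#' @param dropout_prob Per-dataset probability that an mRNA is unexpressed
#'   (RPKM pushed below 1).
#' @param lnc_dropout_prob Per-dataset dropout probability for lncRNAs;
#'   higher than for mRNAs because lncRNA expression is typically
#'   tissue-specific.
#' @param assoc_strength_meanlog,assoc_strength_sdlog Log-normal law of the
#'   per-transcript ribosome-association strength of associated-untranslated
#'   lncRNAs, as a fraction of the translating-ORF footprint rate. The law
#'   straddles well above the 3'UTR noise floor but leaves a minority of
#'   borderline transcripts whose association calls flip across datasets,
#'   as observed in real multi-tissue studies.
#' @param utr3_noise_sdlog Log-normal spread of per-transcript background
#'   rates (3'UTRs and free lncRNAs).
#' @param contaminant_fraction Contaminant reads as a fraction of the
#'   Ribo-seq library.
#' @param multimap_rate Fraction of RNA-seq reads duplicated onto a decoy
#'   transcript.
#' @param seed Integer seed; every simulation draw is derived from it.
#' @return A `sim_config` list.
#' @export
simulation_config <- function(n_mrna = 60L, n_lnc_translated = 60L,
                              n_lnc_associated = 60L, n_lnc_free = 60L,
                              n_contaminant = 4L, n_datasets = 10L,
                              footprint_mean = 29, footprint_sd = 1.2,
                              bg_footprint_mean = 31, bg_footprint_sd = 3,
                              periodicity_strength = 0.85,
                              stop_dropoff = 0.05,
                              rna_depth = 6, ribo_depth = 6,
                              rna_read_length = 36L,
                              rpkm_meanlog = 2, rpkm_sdlog = 1,
                              dataset_rpkm_sdlog = 0.3,
                              dropout_prob = 0.10,
                              lnc_dropout_prob = 0.35,
                              assoc_strength_meanlog = log(0.6),
                              assoc_strength_sdlog = 0.6,
                              utr3_noise_sdlog = 0.6,
                              contaminant_fraction = 0.03,
                              multimap_rate = 0.05,
                              seed = 20260101L) {
  cfg <- as.list(environment())
  stopifnot(cfg$periodicity_strength >= 0, cfg$periodicity_strength <= 1,
            cfg$stop_dropoff >= 0, cfg$stop_dropoff <= 1,
            cfg$dropout_prob >= 0, cfg$dropout_prob <= 1,
            cfg$lnc_dropout_prob >= 0, cfg$lnc_dropout_prob <= 1,
            cfg$contaminant_fraction >= 0, cfg$contaminant_fraction <= 1,
            cfg$multimap_rate >= 0, cfg$multimap_rate <= 1,
            cfg$rna_depth > 0, cfg$ribo_depth > 0)
  structure(cfg, class = "sim_config")
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# a run of n_codons sense codons (no in-frame stop), ATG first, stop last
random_orf_seq <- function(n_codons) {
  codons <- apply(expand.grid(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                              c("A", "C", "G", "T")), 1, paste, collapse = "")
  sense <- setdiff(codons, c("TGA", "TAA", "TAG"))
  paste0("ATG",
         paste(sample(sense, n_codons - 2L, replace = TRUE), collapse = ""),
         sample(c("TGA", "TAA", "TAG"), 1L))
}

#' Simulate a transcriptome with ground truth
#'
#' Generates mRNAs with 5'UTR/CDS/3'UTR partitions, lncRNAs each carrying
#' at least one embedded putative ORF, and contaminant transcripts, along
#' with per-transcript truth labels. Deterministic given `config$seed`.
#'
#' @param config A [simulation_config()].
#' @return A list with `transcripts` (same shape as [parse_annotation()]
#'   output) and `truth` (tibble: `transcript_id`, `class`, `is_mrna`,
#'   `is_associated`, `is_translated`, `orf_start`, `orf_end`,
#'   `base_rpkm`).
#' @export
simulate_transcriptome <- function(config = simulation_config()) {
  set.seed(config$seed)
  classes <- c(rep("mrna", config$n_mrna),
               rep("lnc_translated", config$n_lnc_translated),
               rep("lnc_associated", config$n_lnc_associated),
               rep("lnc_free", config$n_lnc_free),
               rep("contaminant", config$n_contaminant))
  n <- length(classes)
  ids <- sprintf("TX%04d", seq_len(n))

  rows <- purrr::map2(ids, classes, function(id, cl) {
    if (cl == "mrna") {
      utr5 <- sample(60:200, 1)
      n_codons <- sample(80:260, 1)
      utr3 <- sample(150:1200, 1)
      cds_seq <- random_orf_seq(n_codons)
      seq <- paste0(random_dna(utr5), cds_seq, random_dna(utr3))
      len <- nchar(seq)
      tibble(transcript_id = id, gene_id = paste0("G_", id),
             biotype = "protein_coding", length = len, sequence = seq,
             utr5_start = 0L, utr5_end = utr5,
             cds_start = utr5, cds_end = utr5 + 3L * n_codons,
             utr3_start = utr5 + 3L * n_codons, utr3_end = len,
             orf_start = utr5, orf_end = utr5 + 3L * n_codons)
    } else if (cl == "contaminant") {
      len <- sample(100:160, 1)
      tibble(transcript_id = id, gene_id = paste0("G_", id),
             biotype = "rRNA", length = len, sequence = random_dna(len),
             utr5_start = NA_integer_, utr5_end = NA_integer_,
             cds_start = NA_integer_, cds_end = NA_integer_,
             utr3_start = NA_integer_, utr3_end = NA_integer_,
             orf_start = NA_integer_, orf_end = NA_integer_)
    } else {
      left <- sample(60:200, 1)
      n_codons <- sample(60:160, 1)
      right <- sample(60:300, 1)
      seq <- paste0(random_dna(left), random_orf_seq(n_codons),
                    random_dna(right))
      len <- nchar(seq)
      tibble(transcript_id = id, gene_id = paste0("G_", id),
             biotype = "lincRNA", length = len, sequence = seq,
             utr5_start = NA_integer_, utr5_end = NA_integer_,
             cds_start = NA_integer_, cds_end = NA_integer_,
             utr3_start = NA_integer_, utr3_end = NA_integer_,
             orf_start = left, orf_end = left + 3L * n_codons)
    }
  })
  tx <- bind_rows(rows)

  truth <- tibble(
    transcript_id = ids,
    class = classes,
    is_mrna = classes == "mrna",
    is_associated = classes %in% c("mrna", "lnc_translated", "lnc_associated"),
    is_translated = classes %in% c("mrna", "lnc_translated"),
    orf_start = tx$orf_start,
    orf_end = tx$orf_end,
    base_rpkm = if_else(classes == "contaminant", 50,
                        rlnorm(n, config$rpkm_meanlog, config$rpkm_sdlog)),
    assoc_strength = if_else(
      classes == "lnc_associated",
      rlnorm(n, config$assoc_strength_meanlog, config$assoc_strength_sdlog),
      NA_real_)
  )
  list(transcripts = select(tx, -"orf_start", -"orf_end"), truth = truth)
}

# draw footprint lengths from a clipped normal law
draw_lengths <- function(n, mean, sd, lo, hi) {
  pmin(pmax(round(rnorm(n, mean, sd)), lo), hi)
}

# uniform 5' positions within [start, end), keeping the read on-transcript
draw_positions <- function(n, start, end, read_len, tx_len) {
  hi <- pmin(end, tx_len - read_len + 1L)
  lo <- pmin(start, hi - 1L)
  lo + floor(runif(n) * pmax(hi - lo, 1L))
}

#' Simulate Ribo-seq alignments for one dataset
#'
#' Translated transcripts receive footprints whose 5' ends fall inside the
#' active ORF, with a frame-0 excess set by `periodicity_strength` and
#' downstream coverage suppressed to `stop_dropoff` of the in-ORF rate.
#' Associated-untranslated lncRNAs receive uniform aperiodic coverage over
#' the whole transcript. Free lncRNAs receive only background coverage
#' drawn from the same per-transcript rate law as mRNA 3'UTRs. Contaminant
#' reads are emitted with a second placement on a random lncRNA.
#'
#' @param transcripts,truth From [simulate_transcriptome()].
#' @param rpkm Named per-transcript RPKM values for this dataset.
#' @param config A [simulation_config()].
#' @param seed Dataset-level seed.
#' @return An alignment tibble (uniform placement weights).
#' @export
simulate_ribo_reads <- function(transcripts, truth, rpkm, config, seed) {
  set.seed(seed)
  lnc_ids <- truth$transcript_id[startsWith(truth$class, "lnc")]
  cont_ids <- truth$transcript_id[truth$class == "contaminant"]
  chunks <- list()
  for (k in seq_len(nrow(truth))) {
    tr <- truth[k, ]
    len <- transcripts$length[k]
    r <- unname(rpkm[tr$transcript_id])
    if (r <= 0) next
    if (tr$is_translated) {
      orf_len <- tr$orf_end - tr$orf_start
      n_orf <- rpois(1, r * orf_len / 1e3 * config$ribo_depth)
      down_len <- len - tr$orf_end
      noise <- rlnorm(1, 0, config$utr3_noise_sdlog)
      n_down <- if (down_len > 0) {
        rpois(1, r * down_len / 1e3 * config$ribo_depth *
                config$stop_dropoff * noise)
      } else 0L
      if (n_orf > 0) {
        rl <- draw_lengths(n_orf, config$footprint_mean, config$footprint_sd,
                           25L, 35L)
        periodic <- runif(n_orf) < config$periodicity_strength
        pos <- draw_positions(n_orf, tr$orf_start, tr$orf_end, rl, len)
        # snap periodic reads to frame 0 of the active ORF
        pos[periodic] <- pos[periodic] -
          (pos[periodic] - tr$orf_start) %% 3L
        chunks[[length(chunks) + 1L]] <- tibble(
          transcript_id = tr$transcript_id, five_prime = as.integer(pos),
          read_length = as.integer(rl))
      }
      if (n_down > 0) {
        rl <- draw_lengths(n_down, config$bg_footprint_mean,
                           config$bg_footprint_sd, 22L, 38L)
        pos <- draw_positions(n_down, tr$orf_end, len, rl, len)
        chunks[[length(chunks) + 1L]] <- tibble(
          transcript_id = tr$transcript_id, five_prime = as.integer(pos),
          read_length = as.integer(rl))
      }
    } else if (tr$is_associated || tr$class == "contaminant") {
      # uniform aperiodic coverage over the whole transcript, scaled by the
      # transcript's association strength (contaminants at full rate)
      strength <- if (tr$class == "contaminant") 1 else
        tr$assoc_strength * rlnorm(1, 0, config$dataset_rpkm_sdlog)
      n_reads <- rpois(1, r * len / 1e3 * config$ribo_depth * strength)
      if (n_reads > 0) {
        rl <- draw_lengths(n_reads, config$bg_footprint_mean,
                           config$bg_footprint_sd, 22L, 38L)
        pos <- draw_positions(n_reads, 0L, len, rl, len)
        chunks[[length(chunks) + 1L]] <- tibble(
          transcript_id = tr$transcript_id, five_prime = as.integer(pos),
          read_length = as.integer(rl))
      }
    } else {
      # free lncRNA: background at the 3'UTR noise-floor law
      noise <- rlnorm(1, 0, config$utr3_noise_sdlog)
      n_reads <- rpois(1, r * len / 1e3 * config$ribo_depth *
                         config$stop_dropoff * noise)
      if (n_reads > 0) {
        rl <- draw_lengths(n_reads, config$bg_footprint_mean,
                           config$bg_footprint_sd, 22L, 38L)
        pos <- draw_positions(n_reads, 0L, len, rl, len)
        chunks[[length(chunks) + 1L]] <- tibble(
          transcript_id = tr$transcript_id, five_prime = as.integer(pos),
          read_length = as.integer(rl))
      }
    }
  }
  aln <- bind_rows(chunks)
  if (nrow(aln) == 0L) {
    return(tibble(read_id = character(), transcript_id = character(),
                  five_prime = integer(), read_length = integer(),
                  n_hits = integer(), weight = double()))
  }
  aln$read_id <- sprintf("ribo_%06d", seq_len(nrow(aln)))
  aln$n_hits <- 1L
  aln$weight <- 1

  # contaminant reads multimapping onto lncRNAs
  n_cont <- round(config$contaminant_fraction * nrow(aln))
  lnc_expressed <- lnc_ids[rpkm[lnc_ids] > 0]
  if (n_cont > 0 && length(cont_ids) > 0 && length(lnc_expressed) > 0) {
    cont_tx <- sample(cont_ids, n_cont, replace = TRUE)
    decoy_tx <- sample(lnc_expressed, n_cont, replace = TRUE)
    cont_len <- setNames(transcripts$length, transcripts$transcript_id)
    rl <- draw_lengths(n_cont, config$bg_footprint_mean,
                       config$bg_footprint_sd, 22L, 38L)
    ids <- sprintf("cont_%06d", seq_len(n_cont))
    cont_aln <- bind_rows(
      tibble(read_id = ids, transcript_id = cont_tx,
             five_prime = as.integer(draw_positions(
               n_cont, 0L, cont_len[cont_tx], rl, cont_len[cont_tx])),
             read_length = as.integer(rl), n_hits = 2L, weight = 0.5),
      tibble(read_id = ids, transcript_id = decoy_tx,
             five_prime = as.integer(draw_positions(
               n_cont, 0L, cont_len[decoy_tx], rl, cont_len[decoy_tx])),
             read_length = as.integer(rl), n_hits = 2L, weight = 0.5)
    )
    aln <- bind_rows(aln, cont_aln)
  }
  select(aln, "read_id", "transcript_id", "five_prime", "read_length",
         "n_hits", "weight")
}

#' Simulate RNA-seq alignments for one dataset
#'
#' Uniform positional coverage with expected counts proportional to
#' transcript RPKM and length; a `multimap_rate` fraction of reads gains a
#' second placement on a random decoy transcript.
#'
#' @inheritParams simulate_ribo_reads
#' @return An alignment tibble (uniform placement weights).
#' @export
simulate_rna_reads <- function(transcripts, truth, rpkm, config, seed) {
  set.seed(seed)
  rl <- config$rna_read_length
  counts <- rpois(nrow(transcripts),
                  unname(rpkm[transcripts$transcript_id]) *
                    transcripts$length / 1e3 * config$rna_depth)
  chunks <- purrr::map(which(counts > 0), function(k) {
    len <- transcripts$length[k]
    r <- min(rl, len)
    tibble(transcript_id = transcripts$transcript_id[k],
           five_prime = as.integer(draw_positions(counts[k], 0L, len, r, len)),
           read_length = as.integer(r))
  })
  aln <- bind_rows(chunks)
  if (nrow(aln) == 0L) {
    return(tibble(read_id = character(), transcript_id = character(),
                  five_prime = integer(), read_length = integer(),
                  n_hits = integer(), weight = double()))
  }
  aln$read_id <- sprintf("rna_%06d", seq_len(nrow(aln)))
  aln$n_hits <- 1L
  aln$weight <- 1

  n_multi <- round(config$multimap_rate * nrow(aln))
  expressed_ids <- names(rpkm)[rpkm > 0]
  if (n_multi > 0 && length(expressed_ids) > 1L) {
    pick <- sample(nrow(aln), n_multi)
    # homologous decoys are themselves expressed transcripts
    decoy <- sample(expressed_ids, n_multi, replace = TRUE)
    len_of <- setNames(transcripts$length, transcripts$transcript_id)
    dup <- aln[pick, ]
    dup$transcript_id <- decoy
    dup$read_length <- pmin(dup$read_length, len_of[decoy])
    dup$five_prime <- as.integer(draw_positions(
      n_multi, 0L, len_of[decoy], dup$read_length, len_of[decoy]))
    aln$n_hits[pick] <- 2L
    aln$weight[pick] <- 0.5
    dup$n_hits <- 2L
    dup$weight <- 0.5
    aln <- bind_rows(aln, dup)
  }
  select(aln, "read_id", "transcript_id", "five_prime", "read_length",
         "n_hits", "weight")
}

#' Simulate a full multi-dataset study
#'
#' Generates one transcriptome and `n_datasets` paired Ribo-seq/RNA-seq
#' libraries with per-dataset abundance jitter and expression dropout.
#' Dataset seeds are derived from `config$seed`.
#'
#' @param config A [simulation_config()].
#' @return A list: `transcripts`, `truth`, `contaminant_ids`, `lncrna_ids`
#'   and `datasets` — a named list (one per tissue) of
#'   `list(ribo =, rna =, rpkm =)`.
#' @export
simulate_study <- function(config = simulation_config()) {
  sim <- simulate_transcriptome(config)
  tissues <- paste0("tissue", seq_len(config$n_datasets))
  datasets <- purrr::map(seq_len(config$n_datasets), function(i) {
    seed_i <- (config$seed + 7919L * i) %% .Machine$integer.max
    set.seed(seed_i)
    jitter <- rlnorm(nrow(sim$truth), 0, config$dataset_rpkm_sdlog)
    p_drop <- ifelse(startsWith(sim$truth$class, "lnc"),
                     config$lnc_dropout_prob, config$dropout_prob)
    drop <- runif(nrow(sim$truth)) < p_drop &
      sim$truth$class != "contaminant"
    rpkm <- sim$truth$base_rpkm * jitter
    rpkm[drop] <- 0
    rpkm <- setNames(rpkm, sim$truth$transcript_id)
    list(
      ribo = simulate_ribo_reads(sim$transcripts, sim$truth, rpkm, config,
                                 seed = seed_i + 1L),
      rna = simulate_rna_reads(sim$transcripts, sim$truth, rpkm, config,
                               seed = seed_i + 2L),
      rpkm = rpkm
    )
  })
  names(datasets) <- tissues
  list(
    transcripts = sim$transcripts,
    truth = sim$truth,
    contaminant_ids = sim$truth$transcript_id[sim$truth$class == "contaminant"],
    lncrna_ids = sim$truth$transcript_id[startsWith(sim$truth$class, "lnc")],
    datasets = datasets
  )
}

#' Write a simulated study to disk
#'
#' Emits the transcriptome FASTA, the transcript table, per-dataset SAM
#' files, the contaminant ID list and the truth table — the on-disk layout
#' consumed by [run_pipeline()].
#'
#' @param study From [simulate_study()].
#' @param outdir Output directory (created if needed).
#' @return `outdir`, invisibly.
#' @export
write_simulation <- function(study, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  write_transcriptome_fasta(study$transcripts,
                            file.path(outdir, "transcripts.fa"))
  write_transcript_table(study$transcripts,
                         file.path(outdir, "transcripts.tsv"))
  writeLines(study$contaminant_ids, file.path(outdir, "contaminants.txt"))
  readr::write_tsv(study$truth, file.path(outdir, "truth.tsv"))
  for (tissue in names(study$datasets)) {
    d <- study$datasets[[tissue]]
    write_sam(d$ribo, study$transcripts,
              file.path(outdir, paste0(tissue, ".ribo.sam")))
    write_sam(d$rna, study$transcripts,
              file.path(outdir, paste0(tissue, ".rna.sam")))
  }
  invisible(outdir)
}
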