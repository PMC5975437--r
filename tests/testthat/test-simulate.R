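small_cfg <- function(seed = 7, ...) {
  simulation_config(n_mrna = 20L, n_lnc_translated = 10L,
                    n_lnc_associated = 10L, n_lnc_free = 10L,
                    n_datasets = 2L, seed = seed, ...)
}

test_that("the simulator is deterministic given a seed", {
  s1 <- simulate_study(small_cfg())
  s2 <- simulate_study(small_cfg())
  expect_identical(s1$transcripts$sequence, s2$transcripts$sequence)
  expect_identical(s1$datasets[[1]]$ribo, s2$datasets[[1]]$ribo)
  expect_identical(s1$datasets[[2]]$rna, s2$datasets[[2]]$rna)
  s3 <- simulate_study(small_cfg(seed = 8))
  expect_false(identical(s1$transcripts$sequence, s3$transcripts$sequence))
})

test_that("generated mRNA CDSs are well-formed and lncRNAs carry a putative ORF", {
  sim <- simulate_transcriptome(small_cfg())
  tx <- sim$transcripts
  mrna <- dplyr::filter(tx, biotype == "protein_coding")
  for (k in seq_len(nrow(mrna))) {
    s <- mrna$cds_start[k]; e <- mrna$cds_end[k]
    expect_equal((e - s) %% 3L, 0L)
    expect_equal(substr(mrna$sequence[k], s + 1, s + 3), "ATG")
    expect_true(substr(mrna$sequence[k], e - 2, e) %in% c("TGA", "TAA", "TAG"))
    expect_equal(mrna$utr5_end[k], s)
    expect_equal(mrna$utr3_start[k], e)
    expect_equal(mrna$utr3_end[k], mrna$length[k])
  }
  lnc <- dplyr::filter(tx, biotype == "lincRNA")
  orfs <- putative_orfs(lnc)
  expect_true(all(lnc$transcript_id %in% orfs$transcript_id))
  # an mRNA-free transcriptome is allowed
  only_lnc <- simulate_transcriptome(simulation_config(
    n_mrna = 0L, n_lnc_translated = 5L, n_lnc_associated = 0L,
    n_lnc_free = 0L, n_contaminant = 0L, seed = 3))
  expect_true(all(only_lnc$transcripts$biotype == "lincRNA"))
})

test_that("emitted alignments stay within transcript bounds and survive SAM round trip", {
  study <- simulate_study(small_cfg())
  len_of <- setNames(study$transcripts$length, study$transcripts$transcript_id)
  for (d in study$datasets) {
    for (aln in list(d$ribo, d$rna)) {
      expect_true(all(aln$five_prime >= 0))
      expect_true(all(aln$five_prime < len_of[aln$transcript_id]))
      expect_true(all(aln$five_prime + aln$read_length <=
                        len_of[aln$transcript_id]))
    }
  }
  sam <- tempfile(fileext = ".sam")
  write_sam(study$datasets[[1]]$ribo, study$transcripts, sam)
  back <- load_alignments(sam, study$transcripts)
  expect_equal(nrow(back), nrow(study$datasets[[1]]$ribo))
  a <- dplyr::arrange(study$datasets[[1]]$ribo, read_id, transcript_id,
                      five_prime)
  b <- dplyr::arrange(back, read_id, transcript_id, five_prime)
  expect_equal(b$five_prime, a$five_prime)
  expect_equal(b$read_length, a$read_length)
  expect_equal(b$transcript_id, a$transcript_id)
})

test_that("periodicity and stop-dropoff limit cases hold", {
  cfg <- simulation_config(n_mrna = 0L, n_lnc_translated = 5L,
                           n_lnc_associated = 0L, n_lnc_free = 0L,
                           n_contaminant = 0L, n_datasets = 2L,
                           periodicity_strength = 1, stop_dropoff = 0,
                           seed = 19)
  sim <- simulate_transcriptome(cfg)
  rpkm <- setNames(sim$truth$base_rpkm, sim$truth$transcript_id)
  ribo <- simulate_ribo_reads(sim$transcripts, sim$truth, rpkm, cfg, seed = 5)
  j <- dplyr::inner_join(ribo, sim$truth, by = "transcript_id")
  # no reads downstream of the active ORF stop
  expect_true(all(j$five_prime < j$orf_end))
  inorf <- dplyr::filter(j, five_prime >= orf_start)
  expect_true(all((inorf$five_prime - inorf$orf_start) %% 3L == 0L))
})

test_that("read counts are Poisson-consistent with the configured depth", {
  cfg <- simulation_config(n_mrna = 0L, n_lnc_translated = 0L,
                           n_lnc_associated = 10L, n_lnc_free = 0L,
                           n_contaminant = 0L, contaminant_fraction = 0,
                           seed = 29)
  sim <- simulate_transcriptome(cfg)
  rpkm <- setNames(sim$truth$base_rpkm, sim$truth$transcript_id)
  # associated-untranslated coverage rate: rpkm * len/1e3 * depth * strength
  lambda <- sum(rpkm * sim$transcripts$length / 1e3 * cfg$ribo_depth *
                  sim$truth$assoc_strength)
  counts <- purrr::map_dbl(1:20, function(s) {
    nrow(simulate_ribo_reads(sim$transcripts, sim$truth, rpkm, cfg, seed = s))
  })
  # dataset-level lognormal jitter widens the spread; check the mean count
  # against the Poisson mixture expectation within 3 standard errors
  expected <- lambda * exp(0.5 * cfg$dataset_rpkm_sdlog^2)
  se <- sd(counts) / sqrt(length(counts))
  expect_lt(abs(mean(counts) - expected), 3 * se + 0.05 * expected)
})

test_that("recovered RNA-seq expression tracks the simulated abundances", {
  for (s in 1:3) {
    cfg <- small_cfg(seed = 100 + s)
    study <- simulate_study(cfg)
    d <- study$datasets[[1]]
    expr <- quantify_expression(d$rna, study$transcripts)
    truth_rpkm <- d$rpkm[expr$transcript_id]
    keep <- truth_rpkm > 0
    rho <- cor(expr$rpkm[keep], truth_rpkm[keep], method = "spearman")
    expect_gte(rho, 0.95)
  }
})

test_that("zero depth yields an empty library", {
  cfg <- small_cfg()
  sim <- simulate_transcriptome(cfg)
  rpkm <- setNames(rep(0, nrow(sim$truth)), sim$truth$transcript_id)
  expect_equal(nrow(simulate_rna_reads(sim$transcripts, sim$truth, rpkm,
                                       cfg, seed = 1)), 0L)
})
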