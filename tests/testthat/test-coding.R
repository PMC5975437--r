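test_that("transformed FLOSS is 1 minus the length-histogram distance", {
  ref <- hist_tbl(28:30, c(0.25, 0.5, 0.25))
  expect_equal(floss(ref, ref), 1)
  expect_equal(floss(hist_tbl(25, 1), hist_tbl(35, 1)), 0)
  # half-overlapping: TV = 0.5
  p <- hist_tbl(28:30, c(0.5, 0.5, 0))
  q <- hist_tbl(28:30, c(0.25, 0.25, 0.5))
  expect_equal(floss(p, q), 0.5)
  # lengths outside the window are excluded before renormalizing
  p2 <- hist_tbl(c(28, 50), c(0.5, 0.5))
  expect_equal(floss(p2, hist_tbl(28, 1)), 1)
  expect_error(floss(hist_tbl(50, 1), ref), "length window")
})

test_that("scaled RRS maps the coverage-drop ratio to [0, 1)", {
  # equal ribo and RNA ratios: raw = 1, scaled = 0.5
  expect_equal(rrs(9, 4, 9, 4, 300, 150), 0.5)
  # raw ratio 10: pick counts so pseudocounted ratios are exact
  expect_equal(rrs(99, 9, 9, 9, 300, 300), (10 / 1) / (1 + 10 / 1))
  # zero ribo ORF coverage without pseudocount: raw 0, scaled 0
  expect_equal(rrs(0, 10, 10, 10, 300, 300, pseudocount = 0), 0)
  expect_error(rrs(1, 1, 1, 1, 300, 0), "unassessable")
})

test_that("frame distributions are add-one smoothed over ORF-relative frames", {
  aln <- aln_tbl("L1", 100 + 3 * (0:29)) # 30 reads, all frame 0
  expect_equal(frame_distribution(aln, "L1", 100, 250),
               c(31, 1, 1) / 33)
  expect_equal(frame_distribution(aln[0, ], "L1", 100, 250), rep(1 / 3, 3))
  bal <- aln_tbl("L1", 100 + 0:29) # 10 reads per frame
  expect_equal(frame_distribution(bal, "L1", 100, 250), rep(1 / 3, 3))
})

test_that("the frame score is the KL divergence in nats", {
  q <- rep(1 / 3, 3)
  expect_equal(framescore(q, q), 0)
  p <- c(0.5, 0.25, 0.25)
  expect_equal(framescore(p, q),
               0.5 * log(1.5) + 2 * 0.25 * log(0.75), tolerance = 1e-12)
  expect_equal(round(framescore(p, q), 4), 0.0589)
  expect_error(framescore(p, c(1, 0, 0)), "strictly positive")
  set.seed(3)
  for (i in 1:20) {
    a <- runif(3); a <- a / sum(a)
    b <- runif(3) + 0.01; b <- b / sum(b)
    expect_gte(framescore(a, b), -1e-12)
  }
})

test_that("frame_sim is a strictly decreasing bijection preserving pass calls", {
  kl <- sort(runif(50, 0, 3))
  fs <- frame_sim(kl)
  expect_true(all(diff(fs) < 0))
  # pass under a frame_sim cutoff == pass under the matching KL cutoff
  cut_kl <- 0.7
  expect_equal(fs >= frame_sim(cut_kl), kl <= cut_kl)
})

test_that("coding cutoffs pass 90% of the calibration CDSs, cutoff inclusive", {
  scores <- tibble::tibble(floss_score = 1:10 / 10, rrs_scaled = 1:10 / 10,
                           frame_sim = 1:10 / 10)
  cuts <- coding_cutoffs(scores)
  expect_equal(unname(cuts["floss"]), 0.19)
  expect_equal(sum(scores$floss_score >= cuts["floss"]), 9L)
  same <- tibble::tibble(floss_score = rep(0.4, 12), rrs_scaled = rep(0.4, 12),
                         frame_sim = rep(0.4, 12))
  cuts2 <- coding_cutoffs(same)
  expect_equal(unname(cuts2["rrs"]), 0.4)
  expect_true(all(same$rrs_scaled >= cuts2["rrs"])) # score == cutoff passes
  expect_error(coding_cutoffs(scores[1:5, ]), "at least 10")
})

test_that("translation level is the best filter count over ORFs", {
  expect_equal(translation_level(TRUE, TRUE, TRUE), 3L)
  expect_equal(translation_level(c(TRUE, TRUE), c(FALSE, TRUE), c(FALSE, TRUE)),
               3L)
  expect_equal(translation_level(logical(), logical(), logical()), 0L)
  expect_equal(translation_level(NA, TRUE, FALSE), 1L)
})

test_that("assess_coding assigns A3 to a clean periodic lncRNA ORF", {
  tx <- tiny_transcripts()
  orfs <- putative_orfs(dplyr::filter(tx, startsWith(transcript_id, "L")))
  l1 <- orfs[orfs$transcript_id == "L1", ][1, ]

  cds_reads <- function(row) {
    s <- row$cds_start; e <- row$cds_end
    aln_tbl(row$transcript_id, s + 3 * (0:((e - s) %/% 3 - 1)),
            read_length = 29)
  }
  ribo <- dplyr::bind_rows(
    cds_reads(tx[1, ]), cds_reads(tx[2, ]),
    # L1: periodic 29-mers confined to its ORF
    aln_tbl("L1", l1$start + 3 * (0:(l1$orf_len %/% 3 - 1)), read_length = 29),
    # light 3'UTR background on the mRNAs
    aln_tbl("M1", tx$utr3_start[1] + c(2, 30), read_length = 31),
    aln_tbl("M2", tx$utr3_start[2] + c(2, 30, 60), read_length = 31)
  )
  rna <- dplyr::bind_rows(purrr::map(1:4, function(k) {
    aln_tbl(tx$transcript_id[k], seq(0, tx$length[k] - 40, 10))
  }))
  expr <- quantify_expression(rna, tx)
  # calibration needs >= 10 CDS scores: replicate the two mRNAs
  tx_big <- tx
  ribo_big <- ribo
  rna_big <- rna
  for (i in 1:5) {
    ext <- dplyr::mutate(tx[1:2, ],
                         transcript_id = paste0(transcript_id, "_", i),
                         gene_id = paste0(gene_id, "_", i))
    tx_big <- dplyr::bind_rows(tx_big, ext)
    # clones get progressively sparser footprint coverage so the calibration
    # CDS scores span a realistic coverage range
    clone_ribo <- ribo[ribo$transcript_id %in% c("M1", "M2"), ] |>
      dplyr::group_by(transcript_id) |>
      dplyr::slice(seq(1, dplyr::n(), by = i + 1)) |>
      dplyr::ungroup() |>
      dplyr::mutate(transcript_id = paste0(transcript_id, "_", i),
                    read_id = paste0(read_id, "_", i))
    ribo_big <- dplyr::bind_rows(ribo_big, clone_ribo)
    rna_big <- dplyr::bind_rows(
      rna_big,
      dplyr::mutate(rna[rna$transcript_id %in% c("M1", "M2"), ],
                    transcript_id = paste0(transcript_id, "_", i),
                    read_id = paste0(read_id, "_", i)))
  }
  expr_big <- quantify_expression(rna_big, tx_big)
  dens <- density_table(ribo_big, expr_big, tx_big)
  orfs_big <- putative_orfs(dplyr::filter(tx_big, startsWith(transcript_id, "L")))
  out <- assess_coding(ribo_big, rna_big, tx_big, dens,
                       c("L1", "L2"), orfs_big)
  l1row <- out[out$transcript_id == "L1", ]
  expect_equal(l1row$level, 3L)
  # L2 has no footprints at all: if associated it could only be level 0
  if ("L2" %in% out$transcript_id) {
    expect_equal(out$level[out$transcript_id == "L2"], 0L)
  }
})
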