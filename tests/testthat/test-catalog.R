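test_that("tissue specificity spans 0 (ubiquitous) to 1 (specific)", {
  expect_equal(tissue_specificity(10, 10), 0)
  expect_equal(tissue_specificity(1, 10), 1)
  expect_equal(tissue_specificity(4, 10), 2 / 3, tolerance = 1e-4)
  expect_error(tissue_specificity(0, 10), "undefined")
  expect_error(tissue_specificity(1, 1), "M >= 2")
})

test_that("RAI is the mean association sign over expressed datasets", {
  expect_equal(rai_score(rep(TRUE, 4), c(TRUE, TRUE, TRUE, FALSE)), 0.5)
  expect_equal(rai_score(rep(TRUE, 5), rep(TRUE, 5)), 1)
  expect_equal(rai_score(rep(TRUE, 3), rep(FALSE, 3)), -1)
  # unexpressed datasets are ignored entirely
  expect_equal(rai_score(c(TRUE, FALSE, TRUE), c(TRUE, NA, FALSE)), 0)
  expect_error(rai_score(rep(FALSE, 3), rep(NA, 3)), "unexpressed")
})

test_that("composite scores multiply RAI by the specificity split and sum to RAI", {
  cs <- composite_scores(1, 0)
  expect_equal(c(cs$composite_ubiq, cs$composite_spec), c(1, 0))
  cs2 <- composite_scores(0.5, 2 / 3)
  expect_equal(cs2$composite_ubiq, 0.5 * (1 / 3))
  expect_equal(cs2$composite_spec, 0.5 * (2 / 3))
  cs3 <- composite_scores(-1, 0)
  expect_equal(cs3$composite_ubiq, -1)
  set.seed(9)
  rai <- runif(100, -1, 1); spec <- runif(100)
  cc <- composite_scores(rai, spec)
  expect_equal(cc$composite_ubiq + cc$composite_spec, rai)
})

test_that("catalog classing uses strict 5th/95th percentile thresholds", {
  cls <- classify_catalog(1:20)
  expect_equal(cls[1], "noribo")   # 1 < 1.95
  expect_equal(cls[20], "ribo")    # 20 > 19.05
  expect_equal(cls[10], "other")
  expect_true(all(classify_catalog(rep(0.3, 25)) == "other"))
  # a value exactly at a threshold is not extreme: with a tied maximum the
  # 95th percentile equals that maximum, so neither tied value is "ribo"
  x <- c(1:18, 20, 20)
  expect_equal(classify_catalog(x)[19:20], c("other", "other"))
  expect_error(classify_catalog(1:19), "at least 20")
})

test_that("class fractions match the percentile construction on continuous scores", {
  set.seed(13)
  for (i in 1:10) {
    x <- rnorm(sample(40:400, 1))
    cls <- classify_catalog(x)
    expect_lte(mean(cls == "noribo"), 0.05 + 1 / length(x))
    expect_lte(mean(cls == "ribo"), 0.05 + 1 / length(x))
  }
})

test_that("the translation score applies the level weights over associated datasets", {
  expect_equal(translation_score(c(3, 3)), 2)
  expect_equal(translation_score(0), -1)
  expect_equal(translation_score(c(rep(3, 9), 2)), 9.5)
  expect_equal(translation_score(c(0, 1, 2, 3)), -1 - 0.5 + 0.5 + 1)
  expect_true(is.na(translation_score(integer())))
  expect_error(translation_score(4), "0..3")
})

test_that("trans selection takes the strict top 5% of ribo-class TS values", {
  cls <- rep("ribo", 100)
  out <- select_trans(cls, 1:100)
  expect_equal(which(out == "trans"), 96:100)
  expect_true(all(select_trans(rep("ribo", 10), rep(2, 10)) == "ribo"))
  expect_equal(select_trans("ribo", 5), "ribo") # single member stays
  mixed <- select_trans(c("noribo", "ribo", "other"), c(NA, 4, NA))
  expect_equal(mixed, c("noribo", "ribo", "other"))
})

test_that("build_catalog integrates states into spec, RAI, TS and classes", {
  # 3 datasets, transcripts designed to hit known values
  grid <- tidyr::crossing(transcript_id = sprintf("L%02d", 1:24),
                          dataset_id = c("d1", "d2", "d3"))
  set.seed(41)
  states <- grid |>
    dplyr::mutate(
      expressed = TRUE,
      associated = runif(dplyr::n()) < 0.5,
      level = ifelse(associated, sample(0:3, dplyr::n(), replace = TRUE),
                     NA_integer_)
    )
  # pin one transcript: expressed everywhere, associated everywhere at A3
  states[states$transcript_id == "L01", "associated"] <- TRUE
  states[states$transcript_id == "L01", "level"] <- 3L
  # and one expressed only in d1, free there
  states[states$transcript_id == "L02", "expressed"] <-
    c(TRUE, FALSE, FALSE)
  states[states$transcript_id == "L02", "associated"] <- c(FALSE, NA, NA)
  states[states$transcript_id == "L02", "level"] <- NA_integer_

  cat <- build_catalog(states)
  l1 <- cat[cat$transcript_id == "L01", ]
  expect_equal(l1$spec, 0)
  expect_equal(l1$rai, 1)
  expect_equal(l1$composite_ubiq, 1)
  expect_equal(l1$ts, 3)
  expect_equal(l1$state, "A3,A3,A3")
  l2 <- cat[cat$transcript_id == "L02", ]
  expect_equal(l2$spec, 1)
  expect_equal(l2$rai, -1)
  expect_equal(l2$composite_ubiq, 0) # rai * (1 - spec) with spec = 1
  expect_true(is.na(l2$ts))
  expect_equal(l2$state, "F,N,N")
  expect_equal(cat$composite_ubiq + cat$composite_spec, cat$rai)
})

test_that("RAI and TS ignore datasets where the transcript is unexpressed", {
  base <- tibble::tibble(
    transcript_id = "L1", dataset_id = c("d1", "d2", "d3"),
    expressed = TRUE, associated = c(TRUE, TRUE, FALSE),
    level = c(3L, 2L, NA))
  filler <- tidyr::crossing(transcript_id = sprintf("F%02d", 1:20),
                            dataset_id = c("d1", "d2", "d3", "d4")) |>
    dplyr::mutate(expressed = TRUE, associated = FALSE, level = NA_integer_)
  cat3 <- build_catalog(dplyr::bind_rows(
    base, dplyr::filter(filler, dataset_id != "d4")))
  extra <- tibble::tibble(transcript_id = "L1", dataset_id = "d4",
                          expressed = FALSE, associated = NA, level = NA_integer_)
  cat4 <- build_catalog(dplyr::bind_rows(base, extra, filler))
  l3 <- cat3[cat3$transcript_id == "L1", ]
  l4 <- cat4[cat4$transcript_id == "L1", ]
  expect_equal(l3$rai, l4$rai) # unchanged by the unexpressed dataset
  expect_equal(l3$ts, l4$ts)
  # spec changes exactly as (M - x)/(M - 1) dictates
  expect_equal(l3$spec, 0)
  expect_equal(l4$spec, (4 - 3) / (4 - 1))
})

test_that("catalog construction demands at least two datasets", {
  states <- tibble::tibble(transcript_id = sprintf("L%02d", 1:25),
                           dataset_id = "d1", expressed = TRUE,
                           associated = TRUE, level = 1L)
  expect_error(build_catalog(states), "at least 2 datasets")
})

test_that("tidy and glance summarise the catalog", {
  grid <- tidyr::crossing(transcript_id = sprintf("L%02d", 1:30),
                          dataset_id = c("d1", "d2"))
  set.seed(2)
  states <- dplyr::mutate(grid, expressed = TRUE,
                          associated = runif(dplyr::n()) < 0.5,
                          level = ifelse(associated, 3L, NA_integer_))
  cat <- build_catalog(states)
  g <- glance(cat)
  expect_equal(g$n_lncrna, 30)
  expect_equal(g$n_noribo + g$n_ribo + g$n_trans + g$n_other +
                 g$n_unexpressed, 30)
  td <- tidy(cat)
  expect_false(inherits(td, "ribo_catalog"))
  expect_equal(nrow(td), 30)
})
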