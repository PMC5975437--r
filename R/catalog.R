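#' Expression tissue specificity
#'
#' `spec = (M - x) / (M - 1)` where `x` is the number of datasets (tissues /
#' cell types) in which the transcript is expressed out of `M` datasets:
#' 0 means ubiquitous, 1 means expressed in a single dataset.
#'
#' @param x Number of datasets with expression (1 <= x <= M).
#' @param m Total number of datasets (M >= 2).
#' @return A number in `[0, 1]`.
#' @examples
#' tissue_specificity(4, 10) # 0.667
#' @export
tissue_specificity <- function(x, m) {
  if (any(m < 2)) abort_data("tissue_specificity(): needs M >= 2 datasets")
  if (any(x < 1) || any(x > m)) {
    abort_data("tissue_specificity(): x must be in [1, M] (undefined for unexpressed transcripts)")
  }
  (m - x) / (m - 1)
}

#' Ribosomal association index
#'
#' The mean association sign over the datasets in which a transcript is
#' expressed: `RAI = sum(x_i * y_i) / sum(x_i)` with `x_i` the expression
#' indicator and `y_i = +1` (ribosome-associated) or `-1` (ribosome-free).
#' Ranges from -1 (consistently free) to +1 (consistently associated).
#'
#' @param expressed Logical vector over datasets.
#' @param associated Logical vector over datasets; only entries where
#'   `expressed` is `TRUE` are used.
#' @return A number in `[-1, 1]`.
#' @examples
#' rai_score(rep(TRUE, 4), c(TRUE, TRUE, TRUE, FALSE)) # 0.5
#' @export
rai_score <- function(expressed, associated) {
  stopifnot(length(expressed) == length(associated))
  n_expr <- sum(expressed)
  if (n_expr == 0L) {
    abort_data("rai_score(): transcript unexpressed in every dataset")
  }
  y <- ifelse(associated[expressed], 1, -1)
  if (anyNA(y)) abort_data("rai_score(): association undefined in an expressed dataset")
  sum(y) / n_expr
}

#' Composite RAI-by-specificity scores
#'
#' `RAI * (1 - spec)` favours transcripts whose association evidence is
#' replicated across broadly expressed datasets (the catalog's primary
#' ranking score); `RAI * spec` highlights association among
#' tissue-specific transcripts. The two sum to RAI.
#'
#' @param rai RAI values.
#' @param spec Specificity values.
#' @return A tibble with `composite_ubiq` and `composite_spec`.
#' @export
composite_scores <- function(rai, spec) {
  tibble(composite_ubiq = rai * (1 - spec), composite_spec = rai * spec)
}

#' Classify lncRNAs by the composite score percentiles
#'
#' Transcripts whose `RAI * (1 - spec)` falls strictly below the lower
#' percentile are noribo-lncRNAs; strictly above the upper percentile,
#' ribo-lncRNAs; all others (thresholds included) are left unclassified
#' ("other").
#'
#' @param composite_ubiq Numeric vector of `RAI * (1 - spec)` scores
#'   (>= 20 values).
#' @param lower,upper Percentiles (defaults 5 and 95).
#' @return Character vector of `"noribo"`, `"ribo"`, `"other"`.
#' @export
classify_catalog <- function(composite_ubiq, lower = 5, upper = 95) {
  if (length(composite_ubiq) < 20L) {
    abort_data("classify_catalog(): need at least 20 scored lncRNAs, got ",
               length(composite_ubiq))
  }
  lo <- percentile(composite_ubiq, lower)
  hi <- percentile(composite_ubiq, upper)
  dplyr::case_when(
    composite_ubiq < lo ~ "noribo",
    composite_ubiq > hi ~ "ribo",
    TRUE ~ "other"
  )
}

#' Translation score across datasets
#'
#' A weighted sum over the datasets in which a transcript is
#' ribosome-associated, with per-dataset translation levels A0-A3 mapped to
#' weights -1, -0.5, 0.5 and 1. A positive TS indicates translation
#' evidence replicated across datasets.
#'
#' @param levels Integer vector of translation levels (0-3), one per
#'   associated dataset; empty means TS is undefined (`NA`).
#' @param weights Level weights (default `c(-1, -0.5, 0.5, 1)` for levels
#'   0-3).
#' @return A single number, or `NA` when `levels` is empty.
#' @examples
#' translation_score(c(3, 3)) # 2
#' translation_score(0) # -1
#' @export
translation_score <- function(levels, weights = c(-1, -0.5, 0.5, 1)) {
  if (length(levels) == 0L) return(NA_real_)
  if (any(is.na(levels)) || any(!levels %in% 0:3)) {
    abort_data("translation_score(): levels must be integers in 0..3")
  }
  sum(weights[levels + 1L])
}

#' Promote top-TS ribo-lncRNAs to trans-lncRNAs
#'
#' Within the ribo class, transcripts whose TS lies strictly above the
#' `pct`-th percentile of ribo-class TS values are relabelled as
#' trans-lncRNAs (putatively translated).
#'
#' @param cls Character class vector (`"noribo"`, `"ribo"`, `"other"`).
#' @param ts TS values aligned with `cls` (`NA` allowed outside the ribo
#'   class).
#' @param pct Percentile within the ribo class (default 95, i.e. top 5%).
#' @return The class vector with `"trans"` labels applied.
#' @export
select_trans <- function(cls, ts, pct = 95) {
  stopifnot(length(cls) == length(ts))
  ribo <- which(cls == "ribo" & !is.na(ts))
  if (length(ribo) == 0L) return(cls)
  thr <- percentile(ts[ribo], pct)
  cls[ribo[ts[ribo] > thr]] <- "trans"
  cls
}

#' Build the cross-dataset lncRNA catalog
#'
#' Integrates per-dataset expression, association and translation-level
#' calls into the final catalog: per-dataset states (N = not expressed,
#' F = ribosome-free, A0-A3 = associated at translation level 0-3), spec,
#' RAI, the composite scores, TS, and the noribo / ribo / trans / other
#' class. Transcripts expressed in no dataset are reported with `NA` scores
#' and class `"unexpressed"`.
#'
#' @param states Long tibble with one row per (transcript, dataset):
#'   columns `transcript_id`, `dataset_id`, `expressed` (logical),
#'   `associated` (logical, `NA` when not expressed), `level` (integer 0-3,
#'   `NA` when not associated). Every transcript must appear for every
#'   dataset.
#' @param catalog_percentiles Lower/upper composite percentiles
#'   (default `c(5, 95)`).
#' @param trans_percentile TS percentile within the ribo class (default 95).
#' @param min_datasets Minimum number of expressed datasets for a transcript
#'   to be scored (default 1).
#' @return An object of class `ribo_catalog`: a tibble with per-transcript
#'   `state` string, `n_expressed`, `n_associated`, `spec`, `rai`,
#'   `composite_ubiq`, `composite_spec`, `ts` and `cls`.
#' @export
build_catalog <- function(states, catalog_percentiles = c(5, 95),
                          trans_percentile = 95, min_datasets = 1L) {
  check_cols(states, c("transcript_id", "dataset_id", "expressed",
                       "associated", "level"))
  m <- dplyr::n_distinct(states$dataset_id)
  if (m < 2L) {
    abort_data("build_catalog(): spec needs at least 2 datasets (M - 1 ",
               "denominator); got ", m)
  }

  per_tx <- states |>
    arrange(.data$transcript_id, .data$dataset_id) |>
    group_by(.data$transcript_id) |>
    summarise(
      state = paste(state_code(.data$expressed, .data$associated, .data$level),
                    collapse = ","),
      n_expressed = sum(.data$expressed),
      n_associated = sum(.data$expressed & !is.na(.data$associated) &
                           .data$associated),
      rai = if (sum(.data$expressed) >= 1L) {
        rai_score(.data$expressed, .data$associated)
      } else NA_real_,
      ts = translation_score(
        .data$level[.data$expressed & !is.na(.data$associated) &
                      .data$associated]),
      .groups = "drop"
    ) |>
    mutate(
      spec = if_else(.data$n_expressed >= 1L,
                     tissue_specificity(pmax(.data$n_expressed, 1L), m),
                     NA_real_)
    )

  per_tx <- dplyr::bind_cols(per_tx, composite_scores(per_tx$rai, per_tx$spec))

  scored <- !is.na(per_tx$rai) & per_tx$n_expressed >= min_datasets
  cls <- rep("unexpressed", nrow(per_tx))
  cls[!is.na(per_tx$rai) & !scored] <- "other"
  cls[scored] <- classify_catalog(per_tx$composite_ubiq[scored],
                                  catalog_percentiles[1],
                                  catalog_percentiles[2])
  cls[scored] <- select_trans(cls[scored], per_tx$ts[scored],
                              trans_percentile)
  per_tx$cls <- cls

  out <- select(per_tx, "transcript_id", "state", "n_expressed",
                "n_associated", "spec", "rai", "composite_ubiq",
                "composite_spec", "ts", "cls")
  class(out) <- c("ribo_catalog", class(out))
  attr(out, "n_datasets") <- m
  attr(out, "catalog_percentiles") <- catalog_percentiles
  attr(out, "trans_percentile") <- trans_percentile
  out
}

# per-dataset state code: N (unexpressed), F (free), A0-A3 (associated)
state_code <- function(expressed, associated, level) {
  dplyr::case_when(
    !expressed ~ "N",
    is.na(associated) | !associated ~ "F",
    TRUE ~ paste0("A", dplyr::coalesce(level, 0L))
  )
}

#' @export
print.ribo_catalog <- function(x, ...) {
  cat("Ribosome-association catalog:", nrow(x), "lncRNAs over",
      attr(x, "n_datasets"), "datasets\n")
  print(table(x$cls))
  NextMethod()
}

#' Summarise a catalog
#'
#' @param x A `ribo_catalog`.
#' @param ... Unused.
#' @return A one-row tibble with class counts and dataset number.
#' @exportS3Method generics::glance
glance.ribo_catalog <- function(x, ...) {
  tibble(
    n_lncrna = nrow(x),
    n_datasets = attr(x, "n_datasets"),
    n_noribo = sum(x$cls == "noribo"),
    n_ribo = sum(x$cls == "ribo"),
    n_trans = sum(x$cls == "trans"),
    n_other = sum(x$cls == "other"),
    n_unexpressed = sum(x$cls == "unexpressed")
  )
}

#' Tidy a catalog
#'
#' @param x A `ribo_catalog`.
#' @param ... Unused.
#' @return The catalog as a plain tibble.
#' @exportS3Method generics::tidy
tidy.ribo_catalog <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "ribo_catalog")
  as_tibble(out)
}

#' Write a catalog as TSV
#'
#' @param catalog A `ribo_catalog` (or plain tibble).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_catalog <- function(catalog, path) {
  readr::write_tsv(as_tibble(catalog), path)
  invisible(path)
}
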