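#' Read a transcripts-by-tissues FPKM matrix
#'
#' Reads a tab-delimited expression table whose first column holds transcript
#' ids and remaining columns hold per-tissue FPKM values. Values must be
#' complete and nonnegative; tissue labels must be unique.
#'
#' @param path Path to a TSV with a header line.
#' @return Tibble: `transcript_id` plus one numeric column per tissue.
#' @export
read_fpkm <- function(path) {
  tb <- readr::read_tsv(path, show_col_types = FALSE)
  names(tb)[1] <- "transcript_id"
  tb$transcript_id <- as.character(tb$transcript_id)
  validate_fpkm(tb)
}

#' Validate an FPKM expression tibble
#' @param expr Tibble: `transcript_id` plus numeric tissue columns.
#' @return The input, invisibly usable; errors on violation.
#' @export
validate_fpkm <- function(expr) {
  .assert("transcript_id" %in% names(expr), "expression table needs transcript_id")
  tissues <- setdiff(names(expr), "transcript_id")
  .assert(length(tissues) >= 1, "expression table has no tissue columns")
  .assert(!anyDuplicated(tissues), "duplicate tissue labels")
  vals <- as.matrix(expr[tissues])
  .assert(!anyNA(vals), "missing FPKM values")
  .assert(all(vals >= 0), "negative FPKM values")
  expr
}

#' Convert an FPKM tibble to a numeric matrix
#' @inheritParams validate_fpkm
#' @return Numeric matrix, rownames = transcript ids.
#' @export
fpkm_matrix <- function(expr) {
  tissues <- setdiff(names(expr), "transcript_id")
  m <- as.matrix(expr[tissues])
  rownames(m) <- expr$transcript_id
  m
}

.EXPR_CLASSES <- c("very_low", "low", "moderate", "high", "very_high")

#' Classify FPKM values into five expression levels
#'
#' Bins: very_low `[0,2)`, low `[2,5)`, moderate `[5,10)`, high `[10,20]`,
#' very_high `(20, Inf)`. Only the outer bounds (<2 = very low, >20 = very
#' high) are canonical; the interior boundaries are the package's convention
#' and configurable via `breaks`.
#'
#' @param fpkm Numeric vector of nonnegative FPKM values.
#' @param breaks Interior bin boundaries `c(low, moderate, high, very_high)`.
#' @return Factor with levels very_low < low < moderate < high < very_high.
#' @examples
#' classify_expression(c(1.9, 5, 25))
#' @export
classify_expression <- function(fpkm, breaks = c(2, 5, 10, 20)) {
  .assert(all(fpkm >= 0, na.rm = TRUE), "negative FPKM value")
  .assert(length(breaks) == 4 && !is.unsorted(breaks), "need 4 sorted breaks")
  idx <- findInterval(fpkm, breaks, left.open = FALSE) + 1L
  # findInterval puts fpkm == breaks[4] into bin 5; the high bin is closed at 20
  idx[fpkm == breaks[4]] <- 4L
  factor(.EXPR_CLASSES[idx], levels = .EXPR_CLASSES, ordered = TRUE)
}

#' Per-transcript expression class from maximal tissue expression
#'
#' Assigns each transcript the class of its maximum FPKM across tissues,
#' summarising how strongly it is expressed anywhere in the panel.
#'
#' @inheritParams validate_fpkm
#' @param breaks Passed to [classify_expression()].
#' @return Tibble: `transcript_id`, `max_fpkm`, `expression_class`.
#' @export
expression_classes <- function(expr, breaks = c(2, 5, 10, 20)) {
  m <- fpkm_matrix(expr)
  mx <- apply(m, 1, max)
  tibble(transcript_id = rownames(m), max_fpkm = unname(mx),
         expression_class = classify_expression(unname(mx), breaks))
}

#' Tissue-specificity index (tau)
#'
#' For an expression vector x over N tissues the index is
#' `sum(1 - x_i / max(x)) / (N - 1)`: 0 for perfectly uniform (housekeeping)
#' expression, 1 for expression confined to a single tissue. Rows with all-zero
#' expression have no defined index and are flagged (`defined = FALSE`,
#' `tsi = NA`).
#'
#' @inheritParams validate_fpkm
#' @return Tibble: `transcript_id`, `tsi`, `max_tissue` (first tissue in
#'   column order on ties), `max_fpkm`, `defined`.
#' @export
compute_tsi <- function(expr) {
  m <- fpkm_matrix(expr)
  .assert(ncol(m) >= 2, "TSI needs at least two tissues")
  mx <- apply(m, 1, max)
  n <- ncol(m)
  tsi <- ifelse(mx > 0, rowSums(1 - m / mx) / (n - 1), NA_real_)
  which_max <- apply(m, 1, which.max)   # first argmax on ties
  tibble(
    transcript_id = rownames(m),
    tsi = unname(tsi),
    max_tissue = unname(ifelse(mx > 0, colnames(m)[which_max],
                               NA_character_)),
    max_fpkm = unname(mx),
    defined = unname(mx > 0)
  )
}

#' Call tissue-specific transcripts
#'
#' A transcript is called specific to its maximal tissue when its
#' tissue-specificity index reaches `tsi_threshold` (default 0.9). Undefined
#' (all-zero) rows are never called.
#'
#' @inheritParams validate_fpkm
#' @param tsi_threshold Inclusive tau threshold.
#' @param tsi Optional precomputed [compute_tsi()] result.
#' @return Tibble of specific transcripts: `transcript_id`, `tissue`, `tsi`.
#' @export
call_tissue_specific <- function(expr, tsi_threshold = 0.9, tsi = NULL) {
  tsi <- tsi %||% compute_tsi(expr)
  tsi %>%
    filter(.data$defined, .data$tsi >= tsi_threshold) %>%
    select("transcript_id", tissue = "max_tissue", "tsi")
}

#' Count tissue-specific transcripts per tissue
#' @param calls Result of [call_tissue_specific()].
#' @return Tibble: `tissue`, `n_specific`.
#' @export
count_specific_per_tissue <- function(calls) {
  calls %>% count(.data$tissue, name = "n_specific")
}

#' Row z-score an expression matrix for heatmap display
#'
#' Centres and scales each row over tissues (mean 0, sd 1); constant rows map
#' to 0.
#'
#' @inheritParams validate_fpkm
#' @param ids Optional subset of transcript ids (e.g. the specific set).
#' @return Numeric matrix of z-scores.
#' @export
zscore_rows <- function(expr, ids = NULL) {
  m <- fpkm_matrix(expr)
  if (!is.null(ids)) m <- m[ids, , drop = FALSE]
  mu <- rowMeans(m)
  sdv <- apply(m, 1, stats::sd)
  z <- (m - mu) / ifelse(sdv > 0, sdv, 1)
  z[sdv == 0, ] <- 0
  z
}

#' Call stage-specific transcripts by on/off thresholds
#'
#' A transcript is stage-specific to a target tissue set when it is expressed
#' in at least one target tissue at or above `on_min` FPKM and shows no
#' expression (at most `off_max` FPKM) in every non-target tissue.
#'
#' @inheritParams validate_fpkm
#' @param target_tissues Character vector of target tissue labels.
#' @param on_min Minimum FPKM in some target tissue.
#' @param off_max Maximum FPKM tolerated in every other tissue.
#' @return Tibble: `transcript_id`, `max_target_fpkm`, `max_other_fpkm`.
#' @export
call_stage_specific <- function(expr, target_tissues, on_min = 3,
                                off_max = 0.1) {
  tissues <- setdiff(names(expr), "transcript_id")
  .assert(length(target_tissues) >= 1, "empty target tissue set")
  .assert(all(target_tissues %in% tissues),
          "target tissue not in expression matrix")
  m <- fpkm_matrix(expr)
  others <- setdiff(tissues, target_tissues)
  on <- apply(m[, target_tissues, drop = FALSE], 1, max)
  off <- if (length(others)) apply(m[, others, drop = FALSE], 1, max) else 0
  keep <- on >= on_min & off <= off_max
  tibble(transcript_id = rownames(m)[keep],
         max_target_fpkm = unname(on[keep]),
         max_other_fpkm = unname(off[keep]))
}

#' Count transcripts expressed in each tissue
#'
#' @inheritParams validate_fpkm
#' @param min_fpkm Inclusive FPKM threshold for calling a transcript
#'   expressed in a tissue.
#' @return Tibble: `tissue`, `n_expressed`.
#' @export
count_expressed_per_tissue <- function(expr, min_fpkm = 1) {
  .assert(min_fpkm >= 0, "min_fpkm must be nonnegative")
  m <- fpkm_matrix(expr)
  tibble(tissue = colnames(m),
         n_expressed = unname(colSums(m >= min_fpkm)))
}
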