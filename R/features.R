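#' Characteristic features of a lincRNA set
#'
#' Computes the per-transcript features used to characterise lincRNA catalogs
#' (spliced length, exon count, GC/AU base composition) plus the set-level
#' summary: mean length, mean exon length (total exonic length over total exon
#' count), mean exon count, fraction of single-exon transcripts,
#' per-chromosome counts, and the cumulative AU-frequency curve. When an mRNA
#' comparison set is supplied its curve is computed with the same machinery so
#' the AU enrichment of lincRNAs can be contrasted.
#'
#' @param records LincRNA tibble (the `lincrnas` element of a
#'   [run_discovery()] result, or any tibble with `linc_id`/`transcript_id`,
#'   `chrom`, `length_nt`, `exon_count`).
#' @param sequences Named character vector of spliced sequences keyed by
#'   `transcript_id`.
#' @param mrna_records,mrna_sequences Optional comparison set (same layout).
#' @return Object of class `linc_features`: list with `features` (per-record
#'   tibble adding `gc_fraction` and `au_fraction`), `summary` (one-row
#'   tibble), `per_chromosome` and `au_curve` (columns `set`, `au_fraction`,
#'   `cumulative_fraction`).
#' @export
linc_features <- function(records, sequences,
                          mrna_records = NULL, mrna_sequences = NULL) {
  feat <- .feature_table(records, sequences, set = "lincRNA")
  curves <- .au_curve(feat)
  if (!is.null(mrna_records)) {
    mfeat <- .feature_table(mrna_records, mrna_sequences, set = "mRNA")
    curves <- bind_rows(curves, .au_curve(mfeat))
  }
  summary <- tibble(
    n = nrow(feat),
    mean_length = mean(feat$length_nt),
    mean_exon_count = mean(feat$exon_count),
    mean_exon_length = sum(feat$length_nt) / sum(feat$exon_count),
    fraction_single_exon = mean(feat$exon_count == 1),
    mean_gc = mean(feat$gc_fraction, na.rm = TRUE),
    mean_au = mean(feat$au_fraction, na.rm = TRUE)
  )
  per_chrom <- feat %>% count(.data$chrom, name = "n_lincrnas")
  structure(list(features = feat, summary = summary,
                 per_chromosome = per_chrom, au_curve = curves),
            class = "linc_features")
}

.feature_table <- function(records, sequences, set) {
  id_col <- if ("transcript_id" %in% names(records)) "transcript_id" else "linc_id"
  seqs <- sequences[records[[id_col]]]
  .assert(length(seqs) == nrow(records) && !anyNA(names(seqs)),
          "missing sequence for a record")
  records %>%
    mutate(
      gc_fraction = unname(map_dbl(seqs, .gc_fraction)),
      au_fraction = 1 - .data$gc_fraction,
      set = set
    )
}

.au_curve <- function(feat) {
  au <- sort(feat$au_fraction)
  tibble(set = feat$set[1], au_fraction = au,
         cumulative_fraction = seq_along(au) / length(au))
}

#' @export
print.linc_features <- function(x, ...) {
  cat("lincRNA feature summary\n")
  print(x$summary)
  invisible(x)
}

#' @describeIn linc_features `tidy()` returns the per-record feature table.
#' @param x A `linc_features` object.
#' @param ... Unused.
#' @export
tidy.linc_features <- function(x, ...) x$features

#' @describeIn linc_features `glance()` returns the one-row summary.
#' @export
glance.linc_features <- function(x, ...) x$summary
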