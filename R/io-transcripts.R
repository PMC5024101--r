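#' Read assembled transcript models from a GTF file
#'
#' Parses exon features from a GTF produced by an assembler/comparison tool and
#' returns one row per transcript. GTF 1-based inclusive coordinates are
#' converted to the package's internal 0-based half-open convention. The
#' assembly comparison class code (e.g. `"u"` for intergenic) is taken from the
#' `class_code` attribute when present; alternatively a two-column
#' `transcript_id` / `class_code` table may be supplied.
#'
#' @param path Path to a GTF file containing `exon` features.
#' @param class_code_table Optional data frame with columns `transcript_id` and
#'   `class_code`, used when the GTF does not carry a `class_code` attribute.
#' @return A tibble with one row per transcript: `transcript_id`, `gene_id`,
#'   `chrom`, `strand` (`"+"`, `"-"` or `"*"` when unknown), `class_code`,
#'   `start`, `end` (transcript span, 0-based half-open), `n_exons`,
#'   `spliced_length`, and a list-column `exons` of per-exon
#'   `tibble(start, end)` sorted by start.
#' @export
read_transcripts <- function(path, class_code_table = NULL) {
  .assert(file.exists(path), "GTF file not found: %s", path)
  .validate_gtf_lines(path)
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[!is.na(gr$type) & as.character(gr$type) == "exon"]
  .assert(length(gr) > 0, "no exon features in %s", path)
  tx_id <- as.character(gr$transcript_id %||% rep(NA_character_, length(gr)))
  if (anyNA(tx_id) || any(tx_id == "")) {
    stop("exon feature without transcript_id in ", path, call. = FALSE)
  }
  exon_tbl <- tibble(
    transcript_id = tx_id,
    gene_id = as.character(gr$gene_id %||% tx_id),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    strand = as.character(GenomicRanges::strand(gr)),
    class_code = if (!is.null(gr$class_code)) as.character(gr$class_code) else NA_character_,
    start = GenomicRanges::start(gr) - 1L,  # to 0-based half-open
    end = GenomicRanges::end(gr)
  )
  tx <- exon_tbl %>%
    group_by(.data$transcript_id) %>%
    arrange(.data$start, .by_group = TRUE) %>%
    summarise(
      gene_id = .data$gene_id[1],
      chrom = .data$chrom[1],
      strand = .data$strand[1],
      class_code = .data$class_code[1],
      exons = list(as_tibble(dplyr::pick("start", "end"))),
      .groups = "drop"
    ) %>%
    mutate(
      start = map_int(.data$exons, ~ min(.x$start)),
      end = map_int(.data$exons, ~ max(.x$end)),
      n_exons = map_int(.data$exons, nrow),
      spliced_length = map_int(.data$exons, ~ sum(.x$end - .x$start))
    ) %>%
    select("transcript_id", "gene_id", "chrom", "strand", "class_code",
           "start", "end", "n_exons", "spliced_length", "exons")
  if (!is.null(class_code_table)) {
    cc <- as_tibble(class_code_table)
    .assert(all(c("transcript_id", "class_code") %in% names(cc)),
            "class_code_table needs columns transcript_id, class_code")
    tx <- tx %>%
      select(-"class_code") %>%
      left_join(cc[, c("transcript_id", "class_code")], by = "transcript_id") %>%
      select("transcript_id", "gene_id", "chrom", "strand", "class_code",
             dplyr::everything())
  }
  validate_transcripts(tx)
  tx
}

# cheap structural scan so malformed lines are reported with their line number
.validate_gtf_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  body <- which(!grepl("^#", lines) & nzchar(lines))
  nf <- vapply(strsplit(lines[body], "\t", fixed = TRUE), length, integer(1))
  bad <- body[nf < 9]
  if (length(bad)) {
    stop(sprintf("malformed GTF line %d in %s (expected 9 tab-separated fields)",
                 bad[1], path), call. = FALSE)
  }
  invisible(TRUE)
}

#' Validate the invariants of a transcript table
#'
#' Checks that every transcript has at least one exon, exons are sorted and
#' non-overlapping, and the cached spliced length matches the exon intervals.
#'
#' @param transcripts Transcript tibble as returned by [read_transcripts()].
#' @return The input, invisibly; errors if an invariant fails.
#' @export
validate_transcripts <- function(transcripts) {
  for (i in seq_len(nrow(transcripts))) {
    ex <- transcripts$exons[[i]]
    id <- transcripts$transcript_id[i]
    .assert(nrow(ex) >= 1, "transcript %s has no exons", id)
    .assert(all(ex$end > ex$start), "transcript %s has an empty exon", id)
    .assert(!is.unsorted(ex$start, strictly = FALSE),
            "transcript %s exons unsorted", id)
    if (nrow(ex) > 1) {
      .assert(all(ex$start[-1] >= ex$end[-nrow(ex)]),
              "transcript %s has overlapping exons", id)
    }
    .assert(sum(ex$end - ex$start) == transcripts$spliced_length[i],
            "transcript %s spliced_length inconsistent", id)
  }
  invisible(transcripts)
}

#' Read coding-gene loci from a GFF3 or GTF annotation
#'
#' Extracts `gene` features (falling back to `mRNA`/`transcript` when no gene
#' features exist) as simple genomic spans used by the flanking-distance filter.
#'
#' @param path Path to a GFF3 (`.gff`/`.gff3`) or GTF annotation file.
#' @param biotype_default Biotype assigned when the file carries none.
#' @return Tibble: `gene_id`, `chrom`, `strand`, `start`, `end` (0-based
#'   half-open span) and `biotype`.
#' @export
read_gene_loci <- function(path, biotype_default = "coding") {
  .assert(file.exists(path), "annotation file not found: %s", path)
  fmt <- if (grepl("\\.gtf$", path, ignore.case = TRUE)) "gtf" else "gff3"
  gr <- rtracklayer::import(path, format = fmt)
  types <- as.character(gr$type)
  keep <- types == "gene"
  if (!any(keep)) keep <- types %in% c("mRNA", "transcript")
  gr <- gr[keep]
  .assert(length(gr) > 0, "no gene features in %s", path)
  ids <- as.character(gr$ID %||% gr$gene_id %||% paste0("gene", seq_along(gr)))
  bt <- as.character(gr$biotype %||% gr$gene_biotype %||%
                       rep(biotype_default, length(gr)))
  out <- tibble(
    gene_id = ids,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    strand = as.character(GenomicRanges::strand(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    biotype = bt
  )
  .assert(all(out$end > out$start), "gene span with end <= start in %s", path)
  out
}

#' Write transcript models to GTF
#'
#' Emits one `exon` feature per exon with `gene_id`, `transcript_id` and
#' `class_code` attributes; internal 0-based half-open coordinates are written
#' back as GTF 1-based inclusive.
#'
#' @param transcripts Transcript tibble ([read_transcripts()] layout).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_transcript_gtf <- function(transcripts, path) {
  rows <- purrr::pmap(transcripts, function(transcript_id, gene_id, chrom,
                                            strand, class_code, exons, ...) {
    attr_str <- sprintf(
      'gene_id "%s"; transcript_id "%s"; class_code "%s";',
      gene_id, transcript_id, class_code %||% "."
    )
    gtf_strand <- if (strand %in% c("+", "-")) strand else "."
    sprintf("%s\tlinctools\texon\t%d\t%d\t.\t%s\t.\t%s",
            chrom, exons$start + 1L, exons$end, gtf_strand, attr_str)
  })
  writeLines(unlist(rows), path)
  invisible(path)
}

#' Write transcripts as BED12
#'
#' One BED12 line per transcript; blocks mirror the exon structure. BED uses
#' the same 0-based half-open convention as the internal model, so coordinates
#' pass through unchanged.
#'
#' @inheritParams write_transcript_gtf
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed12 <- function(transcripts, path) {
  lines <- purrr::pmap_chr(transcripts, function(transcript_id, chrom, strand,
                                                 start, end, exons, ...) {
    sizes <- exons$end - exons$start
    starts <- exons$start - start
    paste(chrom, start, end, transcript_id, 0L,
          if (strand %in% c("+", "-")) strand else ".",
          start, end, "0",
          nrow(exons),
          paste0(paste(sizes, collapse = ","), ","),
          paste0(paste(starts, collapse = ","), ","),
          sep = "\t")
  })
  writeLines(lines, path)
  invisible(path)
}
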