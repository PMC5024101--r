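#' Read external coding-evidence tables
#'
#' The cascade consumes precomputed homology and coding-potential evidence as
#' plain tab-delimited tables rather than invoking search tools: a BLASTX-style
#' protein-hit table (`transcript_id`, best e-value), a domain-hit table
#' (`transcript_id`, best e-value) and a coding-potential score table
#' (`transcript_id`, score; positive means predicted coding). Transcripts
#' absent from a hit table simply have no hit.
#'
#' @param protein_path,domain_path,cpc_path Paths to two-column TSVs with a
#'   header line (`transcript_id` plus `evalue` or `score`). Any may be `NULL`.
#' @return Tibble: `transcript_id`, `protein_hit_evalue`, `domain_hit_evalue`,
#'   `cpc_score` (NA where absent).
#' @export
read_evidence <- function(protein_path = NULL, domain_path = NULL,
                          cpc_path = NULL) {
  read_two <- function(path, col) {
    if (is.null(path)) {
      return(tibble(transcript_id = character(), !!col := numeric()))
    }
    tb <- readr::read_tsv(path, show_col_types = FALSE)
    .assert(ncol(tb) >= 2, "evidence table %s needs two columns", path)
    tibble(transcript_id = as.character(tb[[1]]), !!col := as.numeric(tb[[2]]))
  }
  ev <- read_two(protein_path, "protein_hit_evalue") %>%
    dplyr::full_join(read_two(domain_path, "domain_hit_evalue"),
                     by = "transcript_id") %>%
    dplyr::full_join(read_two(cpc_path, "cpc_score"), by = "transcript_id")
  for (col in c("protein_hit_evalue", "domain_hit_evalue", "cpc_score")) {
    if (!col %in% names(ev)) ev[[col]] <- NA_real_
  }
  bad <- !is.na(ev$protein_hit_evalue) & ev$protein_hit_evalue < 0 |
    !is.na(ev$domain_hit_evalue) & ev$domain_hit_evalue < 0
  .assert(!any(bad), "negative e-value in evidence tables")
  ev
}

#' Extract intergenic transcripts by assembly class code
#'
#' Keeps exactly the transcripts whose assembly-comparison class code is `"u"`
#' (entirely intergenic relative to the reference annotation); this is the
#' entry stage of the discovery cascade.
#'
#' @param transcripts Transcript tibble ([read_transcripts()] layout).
#' @param code Class code treated as intergenic.
#' @return List with tibbles `retained` and `removed`.
#' @export
extract_intergenic <- function(transcripts, code = "u") {
  keep <- !is.na(transcripts$class_code) & transcripts$class_code == code
  list(retained = transcripts[keep, ], removed = transcripts[!keep, ])
}

#' Remove short transcripts
#'
#' Retains transcripts with spliced length strictly greater than
#' `min_exclusive` (default 200 nt: transcripts of 200 nt or shorter are
#' removed, the operational definition of "long").
#'
#' @inheritParams extract_intergenic
#' @param min_exclusive Exclusive lower bound on spliced length (nt).
#' @return List with tibbles `retained` and `removed`.
#' @export
filter_length <- function(transcripts, min_exclusive = 200L) {
  keep <- transcripts$spliced_length > min_exclusive
  list(retained = transcripts[keep, ], removed = transcripts[!keep, ])
}

#' Remove transcripts with long open reading frames
#'
#' Transcripts whose longest ORF exceeds `max_orf` nucleotides (stop codon
#' included) are discarded as potentially protein-coding; an ORF of exactly
#' `max_orf` is retained, as is the absence of any ORF.
#'
#' @inheritParams extract_intergenic
#' @param orfs Tibble from [longest_orfs()]; must cover every transcript.
#' @param max_orf Inclusive upper bound on ORF length (nt).
#' @return List with tibbles `retained` and `removed`.
#' @export
filter_orf <- function(transcripts, orfs, max_orf = 300L) {
  m <- match(transcripts$transcript_id, orfs$transcript_id)
  if (anyNA(m)) {
    stop("missing ORF result for transcript: ",
         transcripts$transcript_id[is.na(m)][1], call. = FALSE)
  }
  keep <- orfs$orf_length[m] <= max_orf
  list(retained = transcripts[keep, ], removed = transcripts[!keep, ])
}

#' Remove transcripts with protein or domain homology
#'
#' Sequential two-step homology filter: transcripts with a protein hit at or
#' below the e-value cutoff are removed first; among the remainder, those with
#' a domain hit at or below the cutoff are removed. The two removal sets are
#' therefore disjoint.
#'
#' @inheritParams extract_intergenic
#' @param evidence Evidence tibble ([read_evidence()] layout).
#' @param evalue_cutoff Inclusive e-value threshold for calling a hit.
#' @return List with tibbles `retained`, `removed_protein`, `removed_domain`.
#' @export
filter_evidence <- function(transcripts, evidence, evalue_cutoff = 1e-3) {
  m <- match(transcripts$transcript_id, evidence$transcript_id)
  pe <- evidence$protein_hit_evalue[m]
  de <- evidence$domain_hit_evalue[m]
  .assert(!any(pe < 0, na.rm = TRUE) && !any(de < 0, na.rm = TRUE),
          "negative e-value in evidence")
  prot <- !is.na(pe) & pe <= evalue_cutoff
  dom <- !prot & !is.na(de) & de <= evalue_cutoff
  list(retained = transcripts[!prot & !dom, ],
       removed_protein = transcripts[prot, ],
       removed_domain = transcripts[dom, ])
}

#' Remove transcripts predicted coding by coding-potential score
#'
#' Transcripts with a positive coding-potential score (strictly greater than
#' `coding_threshold`) are discarded; a score of exactly the threshold is
#' retained. Every transcript reaching this stage must have a score.
#'
#' @inheritParams filter_evidence
#' @param coding_threshold Scores strictly above this are called coding.
#' @return List with tibbles `retained` and `removed`.
#' @export
filter_cpc <- function(transcripts, evidence, coding_threshold = 0) {
  m <- match(transcripts$transcript_id, evidence$transcript_id)
  sc <- evidence$cpc_score[m]
  if (anyNA(sc)) {
    stop("missing coding-potential score for transcript: ",
         transcripts$transcript_id[is.na(sc)][1], call. = FALSE)
  }
  keep <- sc <= coding_threshold
  list(retained = transcripts[keep, ], removed = transcripts[!keep, ])
}

# minimum genomic gap between a span and any gene span on the same chromosome
.min_gene_gap <- function(chrom, start, end, genes) {
  g <- genes[genes$chrom == chrom, ]
  if (!nrow(g)) return(Inf)
  gap <- pmax(g$start - end, start - g$end)   # negative => overlap
  max(0, min(pmax(gap, 0)))
}

#' Remove transcripts near coding genes
#'
#' A transcript is removed when the minimum genomic gap between its span and
#' any coding gene span on the same chromosome is at most `window` nucleotides
#' (overlap counts as gap 0). The rule is strand-agnostic: it guards against
#' unannotated transcription-start extensions of coding genes on either strand.
#'
#' @inheritParams extract_intergenic
#' @param genes Gene-locus tibble ([read_gene_loci()] layout); only rows with
#'   `biotype == "coding"` are considered.
#' @param window Inclusive flanking distance (nt).
#' @return List with tibbles `retained` and `removed`.
#' @export
filter_flanking <- function(transcripts, genes, window = 500L) {
  genes <- genes[genes$biotype == "coding", ]
  gaps <- purrr::pmap_dbl(
    transcripts[, c("chrom", "start", "end")],
    function(chrom, start, end) .min_gene_gap(chrom, start, end, genes)
  )
  keep <- gaps > window
  list(retained = transcripts[keep, ], removed = transcripts[!keep, ])
}

.gc_fraction <- function(seq) {
  bases <- strsplit(seq, "", fixed = TRUE)[[1]]
  acgt <- bases[bases %in% c("A", "C", "G", "T")]
  if (!length(acgt)) return(NA_real_)
  mean(acgt %in% c("G", "C"))
}

#' Run the full lincRNA discovery cascade
#'
#' Applies, in order: intergenic class-code extraction, length filter (>
#' `min_len` nt), longest-ORF filter (<= `max_orf` nt), protein-homology
#' filter, domain-homology filter, coding-potential filter and the
#' coding-gene flanking filter. Survivors are designated lincRNAs and assigned
#' identifiers `Ca_linc_0001`, `Ca_linc_0002`, ... in genomic coordinate order
#' (chromosome, start, transcript id).
#'
#' @param transcripts Transcript tibble ([read_transcripts()] layout).
#' @param sequences Named character vector of spliced sequences.
#' @param evidence Evidence tibble ([read_evidence()] layout).
#' @param genes Gene-locus tibble ([read_gene_loci()] layout).
#' @param min_len Exclusive minimum spliced length (nt).
#' @param max_orf Inclusive maximum ORF length (nt).
#' @param evalue_cutoff Homology e-value threshold.
#' @param cpc_threshold Coding-potential threshold.
#' @param flank Flanking window around coding genes (nt).
#' @param id_prefix Prefix of assigned lincRNA identifiers.
#' @return Object of class `linc_discovery`: list with `lincrnas` (tibble:
#'   `linc_id`, `transcript_id`, `chrom`, `strand`, `start`, `end`,
#'   `length_nt`, `exon_count`, `gc_fraction`), `ledger` (a [filter_ledger()]),
#'   `orfs`, and `params`.
#' @export
run_discovery <- function(transcripts, sequences, evidence, genes,
                          min_len = 200L, max_orf = 300L,
                          evalue_cutoff = 1e-3, cpc_threshold = 0,
                          flank = 500L, id_prefix = "Ca_linc_") {
  ledger <- filter_ledger()
  ids <- function(tb) tb$transcript_id

  s1 <- extract_intergenic(transcripts)
  ledger <- .ledger_add(ledger, "class_code_u", ids(transcripts),
                        ids(s1$removed), "class code not u")

  s2 <- filter_length(s1$retained, min_exclusive = min_len)
  ledger <- .ledger_add(ledger, "length_gt_200", ids(s1$retained),
                        ids(s2$removed),
                        sprintf("length <= %d nt", min_len))

  seqs2 <- sequences[ids(s2$retained)]
  .assert(!anyNA(names(seqs2)) && length(seqs2) == nrow(s2$retained),
          "missing sequence for a transcript entering the ORF filter")
  strands <- setNames(s2$retained$strand, s2$retained$transcript_id)
  orfs <- longest_orfs(seqs2, strands = strands)
  s3 <- filter_orf(s2$retained, orfs, max_orf = max_orf)
  ledger <- .ledger_add(ledger, "orf_le_300", ids(s2$retained),
                        ids(s3$removed), sprintf("ORF > %d nt", max_orf))

  s4 <- filter_evidence(s3$retained, evidence, evalue_cutoff = evalue_cutoff)
  ledger <- .ledger_add(ledger, "protein_hit", ids(s3$retained),
                        ids(s4$removed_protein), "protein similarity hit")
  after_prot <- bind_rows(s4$retained, s4$removed_domain) %>%
    arrange(match(.data$transcript_id, ids(s3$retained)))
  ledger <- .ledger_add(ledger, "domain_hit", ids(after_prot),
                        ids(s4$removed_domain), "protein domain hit")

  s5 <- filter_cpc(s4$retained, evidence, coding_threshold = cpc_threshold)
  ledger <- .ledger_add(ledger, "cpc_coding", ids(s4$retained),
                        ids(s5$removed), "coding potential score > 0")

  s6 <- filter_flanking(s5$retained, genes, window = flank)
  ledger <- .ledger_add(ledger, "gene_flanking", ids(s5$retained),
                        ids(s6$removed),
                        sprintf("within %d nt of a coding gene", flank))
  validate_ledger(ledger)

  final <- s6$retained %>%
    arrange(.data$chrom, .data$start, .data$transcript_id)
  width <- max(4L, nchar(as.character(nrow(final))))
  lincs <- final %>%
    mutate(
      linc_id = sprintf(paste0(id_prefix, "%0", width, "d"), row_number()),
      length_nt = .data$spliced_length,
      exon_count = .data$n_exons,
      gc_fraction = unname(map_dbl(sequences[.data$transcript_id],
                                   .gc_fraction))
    ) %>%
    select("linc_id", "transcript_id", "chrom", "strand", "start", "end",
           "length_nt", "exon_count", "gc_fraction")

  structure(list(
    lincrnas = lincs, ledger = ledger, orfs = orfs,
    params = list(min_len = min_len, max_orf = max_orf,
                  evalue_cutoff = evalue_cutoff,
                  cpc_threshold = cpc_threshold, flank = flank)
  ), class = "linc_discovery")
}

#' @export
print.linc_discovery <- function(x, ...) {
  cat(sprintf("lincRNA discovery: %d candidates -> %d lincRNAs\n",
              if (nrow(x$ledger$stages)) x$ledger$stages$input_count[1] else 0L,
              nrow(x$lincrnas)))
  print(x$ledger$stages, n = Inf)
  invisible(x)
}

#' @describeIn run_discovery `tidy()` returns the per-stage ledger.
#' @param x A `linc_discovery` object.
#' @param ... Unused.
#' @export
tidy.linc_discovery <- function(x, ...) x$ledger$stages

#' @describeIn run_discovery `glance()` returns a one-row cascade summary.
#' @export
glance.linc_discovery <- function(x, ...) {
  glance(x$ledger) %>%
    mutate(n_lincrnas = nrow(x$lincrnas),
           mean_length = mean(x$lincrnas$length_nt),
           mean_exon_count = mean(x$lincrnas$exon_count))
}
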