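#' Pipeline configuration with canonical thresholds
#'
#' Collects every tunable threshold of the workflow with its canonical
#' default: minimum lincRNA length (>200 nt), maximum ORF length (300 nt),
#' homology e-value (1e-3), coding-potential threshold (0), coding-gene
#' flanking window (500 nt), tissue-specificity index cutoff (0.9),
#' stage-specific on/off FPKM thresholds (3 / 0.1), co-expression percentile
#' (top 0.5%), propagation weight alpha (0.8), per-term annotation rank
#' (100), enrichment significance threshold (1e-10), and the miRNA target
#' cutoffs (expectation 3, unpairing energy 25).
#'
#' @param seed Integer seed driving every random step.
#' @param sim A [sim_config()] describing the synthetic study to generate
#'   (set individual fields via `sim = sim_config(...)`).
#' @param min_len,max_orf,evalue_cutoff,cpc_threshold,flank Discovery
#'   thresholds.
#' @param tsi_threshold,on_min,off_max,min_expr_fpkm Expression thresholds.
#' @param percentile,alpha,tol,top_rank,p_threshold Annotation thresholds.
#' @param max_expectation,max_upe,max_gaps miRNA-target thresholds.
#' @param out_dir Optional directory for result files (TSV/GraphML/JSON).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 42L,
                            sim = NULL,
                            min_len = 200L, max_orf = 300L,
                            evalue_cutoff = 1e-3, cpc_threshold = 0,
                            flank = 500L,
                            tsi_threshold = 0.9, on_min = 3, off_max = 0.1,
                            min_expr_fpkm = 1,
                            percentile = 0.5, alpha = 0.8, tol = 1e-6,
                            top_rank = 100L, p_threshold = 1e-10,
                            max_expectation = 3, max_upe = 25, max_gaps = 1L,
                            out_dir = NULL) {
  sim <- sim %||% sim_config(seed = seed)
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full lincRNA workflow end-to-end on a synthetic study
#'
#' Generates the synthetic study for `config$sim`, then executes the four
#' analysis stages in order: discovery cascade, expression analysis
#' (tissue-specificity, expression classes, per-tissue counts,
#' co-expression), network-propagation GO annotation with enrichment of the
#' tissue-specific set, and miRNA target scanning with interaction-network
#' classification. Returns a machine-readable report whose counts come
#' straight from the stage results (the discovery ledger is the single
#' source of truth for cascade counts).
#'
#' @param config A [pipeline_config()].
#' @param quiet Suppress progress messages.
#' @return Object of class `linc_pipeline`: list with `discovery`,
#'   `expression`, `annotation`, `mirna`, `study` (the generated fixtures)
#'   and `report` (named list of headline numbers).
#' @export
run_lincrna_pipeline <- function(config = pipeline_config(), quiet = FALSE) {
  say <- function(...) if (!quiet) message(...)
  study <- simulate_lincrna_study(config$sim)

  say("stage 1/4: discovery cascade")
  disc <- run_discovery(
    study$discovery$transcripts, study$discovery$sequences,
    study$discovery$evidence, study$discovery$genes,
    min_len = config$min_len, max_orf = config$max_orf,
    evalue_cutoff = config$evalue_cutoff,
    cpc_threshold = config$cpc_threshold, flank = config$flank
  )
  feat <- linc_features(disc$lincrnas, study$discovery$sequences)

  say("stage 2/4: expression analysis")
  id_map <- setNames(disc$lincrnas$linc_id, disc$lincrnas$transcript_id)
  linc_expr <- study$expression$linc_expr %>%
    filter(.data$transcript_id %in% names(id_map)) %>%
    mutate(transcript_id = unname(id_map[.data$transcript_id]))
  mrna_expr <- study$expression$mrna_expr
  tsi <- compute_tsi(linc_expr)
  specific <- call_tissue_specific(linc_expr, config$tsi_threshold, tsi = tsi)
  classes <- expression_classes(linc_expr)
  per_tissue <- count_expressed_per_tissue(linc_expr, config$min_expr_fpkm)
  pairs <- coexpression_pair_universe(linc_expr, mrna_expr)

  say("stage 3/4: network propagation annotation")
  edges <- suppressWarnings(
    build_coexpression_edges(pairs, percentile = config$percentile)
  )
  network <- combine_network(edges, study$network$ppi,
                             linc_ids = linc_expr$transcript_id,
                             mrna_ids = mrna_expr$transcript_id)
  propagation <- propagate_annotations(network, study$network$go,
                                       alpha = config$alpha,
                                       tol = config$tol)
  assignments <- assign_annotations(propagation, top_rank = config$top_rank)
  first_degree <- seed_first_degree(network, study$network$go)
  coverage <- annotation_coverage(assignments, linc_expr$transcript_id)
  enrichment <- if (nrow(specific)) {
    enrich_go(study = intersect(specific$transcript_id,
                                linc_expr$transcript_id),
              population = linc_expr$transcript_id,
              go_annotations = bind_rows(
                assignments %>% select(gene_id = "linc_id", "term"),
                first_degree %>% select(gene_id = "linc_id", "term")
              ),
              p_threshold = config$p_threshold)
  } else NULL

  say("stage 4/4: miRNA interaction screening")
  linc_seq_map <- study$mirna$linc_seqs
  names(linc_seq_map) <- unname(id_map[names(linc_seq_map)])
  linc_seq_map <- linc_seq_map[!is.na(names(linc_seq_map))]
  hits <- scan_targets(study$mirna$mirnas, linc_seq_map,
                       max_expectation = config$max_expectation,
                       max_upe = config$max_upe, max_gaps = config$max_gaps,
                       quiet = TRUE)
  inet <- build_interaction_network(hits)

  report <- list(
    seed = config$seed,
    n_input_transcripts = nrow(study$discovery$transcripts),
    cascade = disc$ledger$stages,
    n_lincrnas = nrow(disc$lincrnas),
    mean_length = feat$summary$mean_length,
    mean_exon_count = feat$summary$mean_exon_count,
    fraction_single_exon = feat$summary$fraction_single_exon,
    n_tissue_specific = nrow(specific),
    n_annotated = coverage$n_annotated,
    annotation_pct = coverage$pct,
    n_mirna_pairs = inet$summary$n_pairs,
    n_target_lincs = inet$summary$n_lincs,
    n_targeting_mirnas = inet$summary$n_mirnas
  )

  result <- structure(list(
    discovery = disc, features = feat,
    expression = list(linc_expr = linc_expr, mrna_expr = mrna_expr,
                      tsi = tsi, specific = specific, classes = classes,
                      per_tissue = per_tissue),
    annotation = list(network = network, propagation = propagation,
                      assignments = assignments,
                      first_degree = first_degree, coverage = coverage,
                      enrichment = enrichment, edges = edges),
    mirna = list(hits = hits, network = inet),
    study = study, report = report, config = config
  ), class = "linc_pipeline")

  if (!is.null(config$out_dir)) .write_pipeline_outputs(result, config$out_dir)
  result
}

.write_pipeline_outputs <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_tsv(result$discovery$ledger$stages,
                   file.path(dir, "filter_ledger.tsv"))
  readr::write_tsv(result$discovery$lincrnas,
                   file.path(dir, "lincrnas.tsv"))
  readr::write_tsv(result$expression$tsi, file.path(dir, "tsi.tsv"))
  readr::write_tsv(result$expression$specific,
                   file.path(dir, "tissue_specific.tsv"))
  readr::write_tsv(result$annotation$assignments,
                   file.path(dir, "go_annotations.tsv"))
  if (!is.null(result$annotation$enrichment)) {
    readr::write_tsv(result$annotation$enrichment,
                     file.path(dir, "go_enrichment.tsv"))
  }
  readr::write_tsv(result$mirna$hits %>%
                     select(-dplyr::starts_with("aln_")),
                   file.path(dir, "mirna_hits.tsv"))
  write_network_graphml(result$annotation$network,
                        file.path(dir, "bicolor_network.graphml"))
  if (nrow(result$mirna$network$edges)) {
    write_interaction_graphml(result$mirna$network,
                              file.path(dir, "mirna_network.graphml"))
  }
  rep <- result$report
  rep$cascade <- NULL
  jsonlite::write_json(rep, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @export
print.linc_pipeline <- function(x, ...) {
  r <- x$report
  cat("lincRNA pipeline run (seed ", r$seed, ")\n", sep = "")
  cat(sprintf("  %d transcripts -> %d lincRNAs\n",
              r$n_input_transcripts, r$n_lincrnas))
  cat(sprintf("  tissue-specific: %d; annotated: %d (%d%%)\n",
              r$n_tissue_specific, r$n_annotated, r$annotation_pct))
  cat(sprintf("  miRNA interactions: %d pairs (%d lincRNAs x %d miRNAs)\n",
              r$n_mirna_pairs, r$n_target_lincs, r$n_targeting_mirnas))
  invisible(x)
}

#' @describeIn run_lincrna_pipeline `glance()` returns the headline report as
#'   a one-row tibble.
#' @param x A `linc_pipeline` object.
#' @param ... Unused.
#' @export
glance.linc_pipeline <- function(x, ...) {
  r <- x$report
  as_tibble(r[setdiff(names(r), "cascade")])
}
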