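test_that("intergenic extraction keeps exactly the class-code-u transcripts", {
  tx <- dplyr::bind_rows(
    make_tx("a", class_code = "u"), make_tx("b", class_code = "="),
    make_tx("c", class_code = "j"), make_tx("d", class_code = "u")
  )
  res <- extract_intergenic(tx)
  expect_equal(res$retained$transcript_id, c("a", "d"))
  expect_equal(res$removed$transcript_id, c("b", "c"))
  none <- extract_intergenic(tx[tx$class_code != "u", ])
  expect_equal(nrow(none$retained), 0L)
})

test_that("length filter removes at 200 nt and retains at 201 nt", {
  tx <- dplyr::bind_rows(
    make_tx("len200", exons = list(c(0L, 200L))),
    make_tx("len201", exons = list(c(0L, 201L)))
  )
  res <- filter_length(tx)
  expect_equal(res$retained$transcript_id, "len201")
  expect_equal(res$removed$transcript_id, "len200")
})

test_that("longest ORF finder handles forced and degenerate cases", {
  expect_equal(find_longest_orf("CCCCCC")$orf_length, 0L)
  hit <- find_longest_orf("ATGAAATAG", strand_mode = "sense_only")
  expect_equal(hit$orf_length, 9L)      # stop codon counted
  expect_equal(hit$frame, 1L)
  expect_equal(c(hit$orf_start, hit$orf_end), c(0L, 9L))
  # reverse-strand ORF is only seen in both-strand mode
  rc <- "CTATTTCAT"                     # revcomp of ATGAAATAG
  expect_equal(find_longest_orf(rc, "sense_only")$orf_length, 0L)
  both <- find_longest_orf(rc, "both")
  expect_equal(both$orf_length, 9L)
  expect_lt(both$frame, 0L)
  # N never completes a start or stop codon
  expect_equal(find_longest_orf("ATNAAATAG")$orf_length, 0L)
  expect_error(find_longest_orf(""), "non-empty")
})

test_that("longest ORF finder matches the brute-force all-frame scan", {
  set.seed(101)
  for (r in 1:60) {
    gc <- runif(1, 0.3, 0.6)
    s <- paste(sample(c("A", "C", "G", "T"), 600, replace = TRUE,
                      prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
               collapse = "")
    expect_equal(find_longest_orf(s, "both")$orf_length,
                 brute_orf_length(s, both = TRUE))
    expect_equal(find_longest_orf(s, "sense_only")$orf_length,
                 brute_orf_length(s, both = FALSE))
  }
})

test_that("ORF filter boundary is >300 removed, 300 retained", {
  tx <- dplyr::bind_rows(make_tx("ok"), make_tx("edge"), make_tx("coding"))
  orfs <- tibble::tibble(transcript_id = c("ok", "edge", "coding"),
                         orf_length = c(0L, 300L, 301L),
                         frame = c(NA, 1L, 1L),
                         orf_start = c(NA, 0L, 0L), orf_end = c(NA, 300L, 301L))
  res <- filter_orf(tx, orfs)
  expect_setequal(res$retained$transcript_id, c("ok", "edge"))
  expect_equal(res$removed$transcript_id, "coding")
  expect_error(filter_orf(tx, orfs[1:2, ]), "missing ORF")
})

test_that("homology filter removes protein then domain hits sequentially", {
  tx <- dplyr::bind_rows(make_tx("p"), make_tx("d"), make_tx("clean"))
  ev <- tibble::tibble(
    transcript_id = c("p", "d"),
    protein_hit_evalue = c(1e-5, 0.01),    # 0.01 above the 1e-3 cutoff
    domain_hit_evalue = c(NA, 1e-4),
    cpc_score = NA_real_
  )
  res <- filter_evidence(tx, ev)
  expect_equal(res$removed_protein$transcript_id, "p")
  expect_equal(res$removed_domain$transcript_id, "d")
  expect_equal(res$retained$transcript_id, "clean")
  expect_length(intersect(res$removed_protein$transcript_id,
                          res$removed_domain$transcript_id), 0)
  ev$protein_hit_evalue[1] <- -1
  expect_error(filter_evidence(tx, ev), "negative")
})

test_that("coding-potential filter removes only strictly positive scores", {
  tx <- dplyr::bind_rows(make_tx("pos"), make_tx("zero"), make_tx("neg"))
  ev <- tibble::tibble(transcript_id = c("pos", "zero", "neg"),
                       protein_hit_evalue = NA_real_,
                       domain_hit_evalue = NA_real_,
                       cpc_score = c(0.01, 0, -1.3))
  res <- filter_cpc(tx, ev)
  expect_equal(res$removed$transcript_id, "pos")
  expect_setequal(res$retained$transcript_id, c("zero", "neg"))
  expect_error(filter_cpc(tx, ev[1:2, ]), "neg")
})

test_that("flanking filter measures the span gap inclusively", {
  genes <- tibble::tibble(gene_id = "g", chrom = "chr1", strand = "+",
                          start = 100L, end = 600L, biotype = "coding")
  near <- make_tx("near", exons = list(c(1000L, 1500L)))   # gap 400
  res <- filter_flanking(near, genes)
  expect_equal(res$removed$transcript_id, "near")
  far_genes <- dplyr::mutate(genes, end = 499L)            # gap 501
  expect_equal(filter_flanking(near, far_genes)$retained$transcript_id, "near")
  edge_genes <- dplyr::mutate(genes, end = 500L)           # gap exactly 500
  expect_equal(filter_flanking(near, edge_genes)$removed$transcript_id, "near")
  overlap <- make_tx("ov", exons = list(c(500L, 900L)))    # overlap, gap 0
  expect_equal(filter_flanking(overlap, genes)$removed$transcript_id, "ov")
  other_chrom <- make_tx("oc", chrom = "chr2", exons = list(c(100L, 400L)))
  expect_equal(filter_flanking(other_chrom, genes)$retained$transcript_id, "oc")
})

test_that("full cascade recovers the planted lincRNA set with a conserving ledger", {
  fix <- generate_discovery_fixture(sim_config(seed = 31L))
  disc <- run_discovery(fix$transcripts, fix$sequences, fix$evidence,
                        fix$genes)
  truth <- fix$manifest$transcript_id[fix$manifest$is_true_linc]
  expect_setequal(disc$lincrnas$transcript_id, truth)

  st <- disc$ledger$stages
  expect_equal(st$input_count, st$removed_count + st$retained_count)
  expect_equal(st$input_count[-1], st$retained_count[-nrow(st)])
  # every planted category is removed at exactly its designed stage
  cat_counts <- table(fix$manifest$category)
  expected_removed <- c(cat_counts[["non_u"]], cat_counts[["short"]],
                        cat_counts[["long_orf"]], cat_counts[["protein_hit"]],
                        cat_counts[["domain_hit"]],
                        cat_counts[["cpc_positive"]], cat_counts[["flanking"]])
  expect_equal(st$removed_count, expected_removed)

  # identifiers are zero-padded, unique and consecutive in coordinate order
  expect_equal(disc$lincrnas$linc_id,
               sprintf("Ca_linc_%04d", seq_len(nrow(disc$lincrnas))))
  ord <- order(disc$lincrnas$chrom, disc$lincrnas$start,
               disc$lincrnas$transcript_id)
  expect_equal(ord, seq_len(nrow(disc$lincrnas)))

  # post hoc re-verification of the defining properties
  expect_true(all(disc$lincrnas$length_nt > 200))
  orf_again <- vapply(fix$sequences[disc$lincrnas$transcript_id],
                      function(s) find_longest_orf(s, "both")$orf_length,
                      integer(1))
  expect_true(all(orf_again <= 300))
})

test_that("final retained set is invariant to swapping the CPC and flanking stages", {
  fix <- generate_discovery_fixture(sim_config(seed = 33L))
  u <- extract_intergenic(fix$transcripts)$retained
  long <- filter_length(u)$retained
  orfs <- longest_orfs(fix$sequences[long$transcript_id],
                       strands = setNames(long$strand, long$transcript_id))
  kept <- filter_orf(long, orfs)$retained
  kept <- filter_evidence(kept, fix$evidence)$retained
  a <- filter_flanking(filter_cpc(kept, fix$evidence)$retained, fix$genes)
  b <- filter_cpc(filter_flanking(kept, fix$genes)$retained, fix$evidence)
  expect_setequal(a$retained$transcript_id, b$retained$transcript_id)
})

test_that("feature summary matches direct recomputation", {
  recs <- tibble::tibble(
    transcript_id = c("a", "b", "c", "d"), chrom = "chr1",
    length_nt = c(4L, 300L, 500L, 700L), exon_count = c(1L, 1L, 1L, 2L)
  )
  seqs <- c(a = "ATAT", b = strrep("GC", 150), c = strrep("AT", 250),
            d = strrep("ACGT", 175))
  feat <- linc_features(recs, seqs)
  expect_equal(feat$features$gc_fraction, c(0, 1, 0, 0.5))
  expect_equal(feat$summary$fraction_single_exon, 0.75)
  expect_equal(feat$summary$mean_exon_count, 1.25)
  expect_equal(feat$summary$mean_length, mean(c(4, 300, 500, 700)))
  expect_equal(feat$summary$mean_exon_length, sum(recs$length_nt) / 5)
  expect_equal(max(feat$au_curve$cumulative_fraction), 1)

  # synthetic set: summary equals brute-force recomputation from raw inputs
  fix <- generate_discovery_fixture(sim_config(seed = 35L))
  disc <- run_discovery(fix$transcripts, fix$sequences, fix$evidence,
                        fix$genes)
  feat2 <- linc_features(disc$lincrnas, fix$sequences)
  man <- fix$manifest[fix$manifest$is_true_linc, ]
  expect_equal(feat2$summary$n, nrow(man))
  expect_equal(feat2$summary$mean_length, mean(man$spliced_length))
  gc_brute <- vapply(fix$sequences[man$transcript_id], function(s) {
    b <- strsplit(s, "")[[1]]
    mean(b %in% c("G", "C"))
  }, numeric(1))
  expect_equal(sort(feat2$features$gc_fraction), sort(unname(gc_brute)))
})

test_that("cascade arithmetic utility chains removals correctly", {
  cc <- cascade_counts(100L, c(10L, 20L, 5L))
  expect_equal(cc$retained_count, c(90L, 70L, 65L))
  expect_equal(cc$input_count, c(100L, 90L, 70L))
  expect_error(cascade_counts(10L, c(20L)), "more than available")
})
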