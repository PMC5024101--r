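# Seeded synthetic-data generators with planted ground truth.
#
# The generators emulate the shape of a multi-tissue plant RNA-seq lincRNA
# study: an assembled transcript set containing planted members of every
# discovery filter category, an 11-tissue FPKM matrix with housekeeping,
# tissue-specific and co-regulated profiles, a modular PPI/GO structure, and
# miRNAs with binding sites of designed expectation scores.

#' Configuration for the synthetic study generators
#'
#' Defaults define the reference synthetic study: two chromosomes, ~90 coding
#' genes, one hundred assembled transcripts spread over all discovery filter
#' categories, the 11-tissue panel, 20 planted tissue-specific profiles with
#' 20% multiplicative noise, three co-regulated GO modules and six miRNAs
#' with planted sites at designed expectations 0, 0.5, 2, 3 and 3.5.
#'
#' @param seed Integer seed; the same config yields byte-identical fixtures.
#' @param n_chromosomes Number of chromosomes.
#' @param counts Named integer vector of planted transcript categories:
#'   `true_linc`, `short`, `long_orf`, `protein_hit`, `domain_hit`,
#'   `cpc_positive`, `flanking`, `non_u`.
#' @param tissues Tissue labels of the expression panel.
#' @param n_specific Planted tissue-specific lincRNA profiles.
#' @param noise_cv Coefficient of variation of the multiplicative
#'   (lognormal) expression noise.
#' @param n_blocks,block_mrnas,block_lincs Co-regulated module structure:
#'   number of modules and mRNA/lincRNA members per module.
#' @param n_background_mrnas Additional unstructured mRNAs.
#' @param n_mirnas Number of 21-nt miRNAs.
#' @param site_expectations Designed expectation scores of planted miRNA
#'   sites (one site per value, each on a distinct lincRNA).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 42L,
                       n_chromosomes = 2L,
                       counts = c(true_linc = 40L, short = 15L,
                                  long_orf = 10L, protein_hit = 8L,
                                  domain_hit = 3L, cpc_positive = 5L,
                                  flanking = 8L, non_u = 15L),
                       tissues = default_tissues(),
                       n_specific = 20L,
                       noise_cv = 0.2,
                       n_blocks = 3L, block_mrnas = 10L, block_lincs = 4L,
                       n_background_mrnas = 15L,
                       n_mirnas = 6L,
                       site_expectations = c(0, 0, 0.5, 0.5, 2, 2,
                                             3, 3, 3.5, 3.5)) {
  .assert(all(counts >= 0) && noise_cv >= 0, "invalid config")
  .assert(length(tissues) >= 2, "need at least two tissues")
  structure(list(seed = as.integer(seed), n_chromosomes = n_chromosomes,
                 counts = counts, tissues = tissues,
                 n_specific = n_specific, noise_cv = noise_cv,
                 n_blocks = n_blocks, block_mrnas = block_mrnas,
                 block_lincs = block_lincs,
                 n_background_mrnas = n_background_mrnas,
                 n_mirnas = n_mirnas,
                 site_expectations = site_expectations),
            class = "sim_config")
}

# random sequence at a given GC fraction
.rand_seq <- function(n, gc = 0.35) {
  paste(sample(c("A", "T", "G", "C"), n, replace = TRUE,
               prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2)),
        collapse = "")
}

# random sequence rejected until its longest 6-frame ORF is <= max_orf
.rand_noncoding_seq <- function(n, gc = 0.35, max_orf = 300L) {
  for (i in 1:100) {
    s <- .rand_seq(n, gc)
    if (find_longest_orf(s, "both")$orf_length <= max_orf) return(s)
  }
  stop("could not generate a noncoding sequence of length ", n, call. = FALSE)
}

# sequence whose longest ORF is exactly orf_len (a multiple of 3 >= 6).
# Flanks use a C/T alphabet and the ORF interior pyrimidine-only codons, so
# no ATG or stop codon can arise outside the planted frame on either strand.
.planted_orf_seq <- function(orf_len, flank5 = 40L, flank3 = 40L) {
  .assert(orf_len %% 3 == 0 && orf_len >= 6, "ORF length must be 3k >= 6")
  py_codons <- c("CTT", "CCT", "TCT", "TTC", "CTC", "CCC")
  n_mid <- orf_len / 3 - 2
  mid <- paste(sample(py_codons, n_mid, replace = TRUE), collapse = "")
  flank <- function(n) paste(sample(c("C", "T"), n, replace = TRUE),
                             collapse = "")
  paste0(flank(flank5), "ATG", mid, "TAA", flank(flank3))
}

# draw k permutations of 1..n whose pairwise Spearman correlations are all
# near zero (deterministic under the active RNG state)
.orthogonal_permutations <- function(k, n, max_abs_rho = 0.15,
                                     max_tries = 5000L) {
  for (i in seq_len(max_tries)) {
    ps <- map(seq_len(k), ~ sample.int(n))
    ok <- TRUE
    for (a in seq_len(k - 1)) {
      for (b in (a + 1):k) {
        if (abs(stats::cor(ps[[a]], ps[[b]], method = "spearman")) >
              max_abs_rho) {
          ok <- FALSE
          break
        }
      }
      if (!ok) break
    }
    if (ok) return(ps)
  }
  stop("could not draw mutually uncorrelated tissue permutations",
       call. = FALSE)
}

# lognormal multiplicative noise with unit mean and given CV
.lnoise <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Generate the discovery fixture: transcripts, sequences, genes, evidence
#'
#' Plants one transcript per configured category: intergenic (`"u"`) true
#' lincRNAs passing every filter; short (<= 200 nt) transcripts; transcripts
#' carrying a constructed ORF longer than 300 nt; transcripts tagged in the
#' protein / domain evidence tables; transcripts with positive
#' coding-potential score; transcripts placed within 500 nt of a coding gene;
#' and non-`"u"` transcripts overlapping genes. True lincRNAs are AU-rich
#' relative to mRNA-like GC content. All placements guarantee that each
#' planted transcript is removed at exactly its designed stage.
#'
#' @param config A [sim_config()].
#' @param dir Optional directory: when given, writes `transcripts.gtf`,
#'   `transcripts.fa`, `genes.gff3`, `protein.tsv`, `domain.tsv`, `cpc.tsv`
#'   and `manifest.json` there.
#' @return List: `transcripts` (tibble), `sequences` (named character),
#'   `genes` (tibble), `evidence` (tibble), `manifest` (tibble with planted
#'   `category` and `is_true_linc` per transcript), `paths` (or NULL).
#' @export
generate_discovery_fixture <- function(config, dir = NULL) {
  set.seed(.derive_seed(config$seed, 1L))
  cnt <- config$counts
  u_cats <- c("true_linc", "short", "long_orf", "protein_hit",
              "domain_hit", "cpc_positive", "flanking")
  n_slots <- sum(cnt[u_cats])
  n_genes_per_chrom <- ceiling(n_slots / config$n_chromosomes) + 1L
  pitch <- 3400L

  genes <- list()
  slots <- list()
  for (ch in seq_len(config$n_chromosomes)) {
    chrom <- paste0("chr", ch)
    for (gi in seq_len(n_genes_per_chrom)) {
      gs <- (gi - 1L) * pitch + 500L + sample.int(200L, 1L)
      glen <- 800L + sample.int(300L, 1L)
      genes[[length(genes) + 1L]] <- tibble(
        gene_id = sprintf("gene_%s_%03d", chrom, gi), chrom = chrom,
        strand = sample(c("+", "-"), 1L), start = gs, end = gs + glen,
        biotype = "coding"
      )
      slots[[length(slots) + 1L]] <- list(chrom = chrom, gene_end = gs + glen,
                                          gene_start = gs)
    }
  }
  genes <- bind_rows(genes)
  .assert(length(slots) >= max(n_slots, cnt[["non_u"]]),
          "impossible geometry: too many transcripts for the gene grid")

  cats <- rep(u_cats, times = cnt[u_cats])
  cats <- sample(cats)                       # interleave categories
  tx <- list(); seqs <- character(0); man <- list()
  ev_protein <- list(); ev_domain <- list(); ev_cpc <- list()
  orf_planted <- 0L

  for (k in seq_along(cats)) {
    cat_k <- cats[k]
    slot <- slots[[k]]
    id <- sprintf("TCONS_%05d", k)
    near <- cat_k == "flanking"
    seq_len_k <- switch(cat_k,
      short = 120L + sample.int(80L, 1L),        # <= 200 nt
      long_orf = NA_integer_,                    # set by construction
      250L + sample.int(450L, 1L)                # 251..700 nt
    )
    if (cat_k == "long_orf") {
      orf_planted <- orf_planted + 1L
      orf_len <- if (orf_planted == 1L) 303L else 303L + 3L * sample.int(30L, 1L)
      s <- .planted_orf_seq(orf_len)
      seq_len_k <- nchar(s)
    } else {
      s <- .rand_noncoding_seq(seq_len_k, gc = 0.33)
    }
    offset <- if (near) 100L + sample.int(300L, 1L) else 600L + sample.int(100L, 1L)
    t_start <- slot$gene_end + offset
    # ~20% of multi-exon-capable transcripts get two exons
    two_exon <- cat_k != "short" && runif(1) < 0.2
    if (two_exon) {
      e1 <- floor(seq_len_k / 2)
      intron <- 80L + sample.int(60L, 1L)
      exons <- tibble(start = c(t_start, t_start + e1 + intron),
                      end = c(t_start + e1, t_start + seq_len_k + intron))
    } else {
      exons <- tibble(start = t_start, end = t_start + seq_len_k)
    }
    tx[[k]] <- tibble(
      transcript_id = id, gene_id = paste0("XLOC_", id),
      chrom = slot$chrom, strand = "*", class_code = "u",
      start = min(exons$start), end = max(exons$end),
      n_exons = nrow(exons), spliced_length = sum(exons$end - exons$start),
      exons = list(exons)
    )
    seqs[id] <- s
    man[[k]] <- tibble(transcript_id = id, category = cat_k,
                       is_true_linc = cat_k == "true_linc",
                       chrom = slot$chrom, start = min(exons$start),
                       end = max(exons$end),
                       spliced_length = sum(exons$end - exons$start))
    if (cat_k == "protein_hit") {
      ev_protein[[id]] <- 10^-(4 + runif(1) * 8)
    }
    if (cat_k == "domain_hit") {
      ev_domain[[id]] <- 10^-(4 + runif(1) * 6)
    }
    ev_cpc[[id]] <- if (cat_k == "cpc_positive") 0.5 + runif(1) * 2 else
      -0.5 - runif(1) * 2
  }

  # non-"u" transcripts overlap a gene body
  non_u_codes <- c("=", "j", "o", "x")
  for (j in seq_len(cnt[["non_u"]])) {
    slot <- slots[[j]]
    id <- sprintf("TCONS_%05d", length(cats) + j)
    glen2 <- 300L + sample.int(200L, 1L)
    t_start <- slot$gene_start + 50L
    exons <- tibble(start = t_start, end = t_start + glen2)
    tx[[length(cats) + j]] <- tibble(
      transcript_id = id, gene_id = paste0("XLOC_", id),
      chrom = slot$chrom, strand = sample(c("+", "-"), 1L),
      class_code = sample(non_u_codes, 1L),
      start = t_start, end = t_start + glen2,
      n_exons = 1L, spliced_length = glen2, exons = list(exons)
    )
    seqs[id] <- .rand_seq(glen2, gc = 0.45)
    man[[length(cats) + j]] <- tibble(transcript_id = id, category = "non_u",
                                      is_true_linc = FALSE,
                                      chrom = slot$chrom, start = t_start,
                                      end = t_start + glen2,
                                      spliced_length = glen2)
    ev_cpc[[id]] <- 1 + runif(1)
  }

  transcripts <- bind_rows(tx)
  manifest <- bind_rows(man)
  evidence <- tibble(
    transcript_id = names(ev_cpc),
    protein_hit_evalue = unname(map_dbl(names(ev_cpc),
                                        ~ ev_protein[[.x]] %||% NA_real_)),
    domain_hit_evalue = unname(map_dbl(names(ev_cpc),
                                       ~ ev_domain[[.x]] %||% NA_real_)),
    cpc_score = unname(unlist(ev_cpc))
  )

  paths <- NULL
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    paths <- list(
      gtf = file.path(dir, "transcripts.gtf"),
      fasta = file.path(dir, "transcripts.fa"),
      genes = file.path(dir, "genes.gff3"),
      protein = file.path(dir, "protein.tsv"),
      domain = file.path(dir, "domain.tsv"),
      cpc = file.path(dir, "cpc.tsv"),
      manifest = file.path(dir, "manifest.json")
    )
    write_transcript_gtf(transcripts, paths$gtf)
    write_fasta(seqs, paths$fasta)
    .write_gff3_genes(genes, paths$genes)
    ev_write <- function(tb, path) {
      readr::write_tsv(tb, path)
    }
    ev_write(evidence %>% filter(!is.na(.data$protein_hit_evalue)) %>%
               select("transcript_id", evalue = "protein_hit_evalue"),
             paths$protein)
    ev_write(evidence %>% filter(!is.na(.data$domain_hit_evalue)) %>%
               select("transcript_id", evalue = "domain_hit_evalue"),
             paths$domain)
    ev_write(evidence %>% select("transcript_id", score = "cpc_score"),
             paths$cpc)
    jsonlite::write_json(manifest, paths$manifest, dataframe = "rows",
                         digits = NA)
  }
  list(transcripts = transcripts, sequences = seqs, genes = genes,
       evidence = evidence, manifest = manifest, paths = paths)
}

.write_gff3_genes <- function(genes, path) {
  lines <- c("##gff-version 3", purrr::pmap_chr(genes, function(gene_id, chrom,
                                                               strand, start,
                                                               end, biotype) {
    sprintf("%s\tsim\tgene\t%d\t%d\t.\t%s\t.\tID=%s;biotype=%s",
            chrom, start + 1L, end, strand, gene_id, biotype)
  }))
  writeLines(lines, path)
  invisible(path)
}

#' Generate the expression fixture: FPKM matrix with planted profiles
#'
#' Builds an 11-tissue FPKM matrix over the supplied lincRNA and mRNA ids.
#' Planted profiles: tissue-specific rows (high in one assigned tissue, near
#' zero elsewhere), housekeeping rows (constant mean with multiplicative
#' lognormal noise), and co-regulated blocks of mRNAs plus lincRNAs sharing a
#' strong latent tissue gradient (a distinct tissue permutation per block).
#' Baseline expression levels keep the five-class histogram dominated by the
#' very-low class, as typical of lincRNA catalogs.
#'
#' @param config A [sim_config()].
#' @param linc_ids LincRNA row ids. The first `n_specific` become specific
#'   profiles, the next `n_blocks * block_lincs` become block members, the
#'   remainder housekeeping.
#' @param mrna_ids mRNA row ids; the first `n_blocks * block_mrnas` are block
#'   members, the rest background.
#' @return List: `linc_expr`, `mrna_expr` (FPKM tibbles), `manifest` (tibble:
#'   `id`, `role`, `profile`, `tissue`, `block`).
#' @export
generate_expression_fixture <- function(config, linc_ids, mrna_ids) {
  set.seed(.derive_seed(config$seed, 2L))
  tissues <- config$tissues
  nt <- length(tissues)
  cv <- config$noise_cv
  .assert(length(linc_ids) >= config$n_specific +
            config$n_blocks * config$block_lincs,
          "not enough lincRNA ids for the configured profiles")
  .assert(length(mrna_ids) >= config$n_blocks * config$block_mrnas,
          "not enough mRNA ids for the configured blocks")

  # block latent profiles: permuted geometric gradient across tissues;
  # ratio 1.5 between adjacent ranks keeps tau below the specific threshold.
  # Modules are disjoint, so their profiles must be mutually uncorrelated:
  # permutation sets are rejected until all pairwise |rank correlations| are
  # small.
  perms <- .orthogonal_permutations(config$n_blocks, nt)
  block_profiles <- map(seq_len(config$n_blocks), function(b) {
    base <- 1.5^(seq_len(nt) - 1)
    base <- base / max(base) * 12      # top tissue ~12 FPKM
    setNames(base[perms[[b]]], tissues)
  })

  rows <- list(); man <- list()
  add_row <- function(id, role, profile, tissue = NA_character_,
                      block = NA_integer_, values) {
    rows[[length(rows) + 1L]] <<- tibble(transcript_id = id,
                                         !!!as.list(values))
    man[[length(man) + 1L]] <<- tibble(id = id, role = role,
                                       profile = profile, tissue = tissue,
                                       block = block)
  }

  li <- 0L
  for (i in seq_len(config$n_specific)) {
    li <- li + 1L
    tis <- tissues[(i - 1L) %% nt + 1L]
    v <- setNames(rep(0.02, nt), tissues) * .lnoise(nt, cv)
    v[tis] <- (12 + runif(1) * 8) * .lnoise(1, cv)
    add_row(linc_ids[li], "lincRNA", "specific", tis, values = v)
  }
  for (b in seq_len(config$n_blocks)) {
    for (j in seq_len(config$block_lincs)) {
      li <- li + 1L
      v <- block_profiles[[b]] * .lnoise(nt, cv)
      add_row(linc_ids[li], "lincRNA", "block", block = b, values = v)
    }
  }
  while (li < length(linc_ids)) {
    li <- li + 1L
    mean_fpkm <- rlnorm(1, meanlog = log(0.8), sdlog = 0.6)  # mostly very low
    v <- setNames(rep(mean_fpkm, nt), tissues) * .lnoise(nt, cv)
    add_row(linc_ids[li], "lincRNA", "housekeeping", values = v)
  }
  linc_expr <- bind_rows(rows)
  linc_man <- bind_rows(man)

  rows <- list(); man <- list()
  mi <- 0L
  for (b in seq_len(config$n_blocks)) {
    for (j in seq_len(config$block_mrnas)) {
      mi <- mi + 1L
      v <- block_profiles[[b]] * .lnoise(nt, cv)
      add_row(mrna_ids[mi], "mRNA", "block", block = b, values = v)
    }
  }
  while (mi < length(mrna_ids)) {
    mi <- mi + 1L
    mean_fpkm <- rlnorm(1, meanlog = log(3), sdlog = 1)
    v <- setNames(rep(mean_fpkm, nt), tissues) * .lnoise(nt, cv)
    add_row(mrna_ids[mi], "mRNA", "housekeeping", values = v)
  }
  mrna_expr <- bind_rows(rows)
  mrna_man <- bind_rows(man)

  list(linc_expr = validate_fpkm(linc_expr),
       mrna_expr = validate_fpkm(mrna_expr),
       manifest = bind_rows(linc_man, mrna_man))
}

#' Generate the network fixture: modular PPI edges and GO annotations
#'
#' Partitions the block mRNAs into GO modules matching the expression blocks:
#' dense high-score PPI edges inside modules, sparse low-score edges between
#' them, and one GO term per module annotating its member mRNAs.
#'
#' @param config A [sim_config()].
#' @param mrna_ids mRNA ids; the first `n_blocks * block_mrnas` are module
#'   members in block order (as in [generate_expression_fixture()]).
#' @return List: `ppi` (tibble `protein_a`, `protein_b`, `score`),
#'   `go` (tibble `gene_id`, `term`), `manifest` (tibble `gene_id`, `block`,
#'   `term`).
#' @export
generate_network_fixture <- function(config, mrna_ids) {
  set.seed(.derive_seed(config$seed, 3L))
  nb <- config$n_blocks
  bm <- config$block_mrnas
  .assert(length(mrna_ids) >= nb * bm, "module sizes exceed mRNA count")
  members <- map(seq_len(nb), function(b) mrna_ids[((b - 1) * bm + 1):(b * bm)])
  terms <- sprintf("GO:MOD%04d", seq_len(nb))

  ppi <- list()
  for (b in seq_len(nb)) {
    ids <- members[[b]]
    prs <- utils::combn(ids, 2)
    keep <- runif(ncol(prs)) < 0.6
    if (any(keep)) {
      ppi[[length(ppi) + 1L]] <- tibble(protein_a = prs[1, keep],
                                        protein_b = prs[2, keep],
                                        score = 0.7 + runif(sum(keep)) * 0.3)
    }
  }
  for (b1 in seq_len(nb - 1)) {
    for (b2 in (b1 + 1):nb) {
      grid <- expand.grid(a = members[[b1]], b = members[[b2]],
                          stringsAsFactors = FALSE)
      keep <- runif(nrow(grid)) < 0.05
      if (any(keep)) {
        ppi[[length(ppi) + 1L]] <- tibble(protein_a = grid$a[keep],
                                          protein_b = grid$b[keep],
                                          score = 0.05 + runif(sum(keep)) * 0.2)
      }
    }
  }
  ppi <- bind_rows(ppi)
  go <- bind_rows(map(seq_len(nb), function(b) {
    tibble(gene_id = members[[b]], term = terms[b])
  }))
  manifest <- go %>% mutate(block = match(.data$term, terms)) %>%
    rename(gene_id = "gene_id")
  list(ppi = ppi, go = go, manifest = manifest)
}

#' Generate the miRNA fixture: miRNAs and lincRNAs with planted sites
#'
#' Draws random 21-nt miRNAs and splices into chosen lincRNA sequences target
#' sites constructed by exact penalty arithmetic: each site starts from the
#' perfect reverse complement of its miRNA and receives mismatches (penalty 1,
#' doubled in the seed) and G:U wobbles (penalty 0.5) at fixed positions so
#' its designed expectation is exactly the configured value. Designed cases
#' cover perfect sites (0), a non-seed wobble (0.5), a seed mismatch (2),
#' seed plus non-seed mismatches (3) and sites just beyond the reporting
#' cutoff (3.5).
#'
#' @param config A [sim_config()].
#' @param linc_seqs Named character vector of lincRNA sequences; sites are
#'   planted into the first `length(site_expectations)` sequences.
#' @return List: `mirnas` (tibble `mirna_id`, `sequence`), `linc_seqs`
#'   (modified sequences), `manifest` (tibble `linc_id`, `mirna_id`,
#'   `target_start`, `designed_expectation`).
#' @export
generate_mirna_fixture <- function(config, linc_seqs) {
  set.seed(.derive_seed(config$seed, 4L))
  n_sites <- length(config$site_expectations)
  .assert(length(linc_seqs) >= n_sites,
          "need at least one lincRNA per planted site")
  M <- 21L
  mirnas <- tibble(
    mirna_id = sprintf("car-miR%03d", seq_len(config$n_mirnas)),
    sequence = map_chr(seq_len(config$n_mirnas), function(i) {
      s <- strsplit(.rand_seq(M, gc = 0.5), "", fixed = TRUE)[[1]]
      s[20] <- "G"              # guarantees a wobble-capable non-seed position
      paste(chartr("T", "U", s), collapse = "")
    })
  )

  # positions (miRNA coordinates) used by each designed modification set
  design_mods <- function(e) {
    switch(as.character(e),
      "0" = list(),
      "0.5" = list(list(pos = 20L, type = "wobble")),
      "2" = list(list(pos = 5L, type = "mismatch")),
      "3" = list(list(pos = 5L, type = "mismatch"),
                 list(pos = 18L, type = "mismatch")),
      "3.5" = list(list(pos = 5L, type = "mismatch"),
                   list(pos = 18L, type = "mismatch"),
                   list(pos = 20L, type = "wobble")),
      stop("no designed modification set for expectation ", e, call. = FALSE)
    )
  }

  host_ids <- names(linc_seqs)[seq_len(n_sites)]
  man <- list()
  for (i in seq_len(n_sites)) {
    e <- config$site_expectations[i]
    mi <- (i - 1L) %% config$n_mirnas + 1L
    m <- strsplit(chartr("U", "T", mirnas$sequence[mi]), "", fixed = TRUE)[[1]]
    # perfect site: reverse complement of the miRNA (DNA)
    site <- rev(chartr("ACGT", "TGCA", m))
    for (mod in design_mods(e)) {
      j <- M - mod$pos + 1L                   # site position paired to pos
      site[j] <- if (mod$type == "wobble") "T" else m[mod$pos]
    }
    host <- linc_seqs[[host_ids[i]]]
    L <- nchar(host)
    .assert(L >= M + 40L, "host lincRNA too short for a planted site")
    off <- 20L + sample.int(L - M - 40L, 1L)  # 0-based target start
    linc_seqs[[host_ids[i]]] <- paste0(
      substr(host, 1L, off),
      paste(site, collapse = ""),
      substr(host, off + M + 1L, L)
    )
    man[[i]] <- tibble(linc_id = host_ids[i], mirna_id = mirnas$mirna_id[mi],
                       target_start = off, designed_expectation = e)
  }
  list(mirnas = mirnas, linc_seqs = linc_seqs, manifest = bind_rows(man))
}

#' Generate the full synthetic study
#'
#' Runs all four generators with sub-seeds derived from the config seed and
#' wires them together: the expression fixture covers the planted true
#' lincRNAs and the module mRNAs, the network fixture shares the expression
#' blocks, and the miRNA fixture plants sites into true-lincRNA sequences.
#'
#' @param config A [sim_config()].
#' @param dir Optional output directory for the discovery fixture files.
#' @return List with elements `discovery`, `expression`, `network`, `mirna`
#'   and the `config`.
#' @export
simulate_lincrna_study <- function(config = sim_config(), dir = NULL) {
  disc <- generate_discovery_fixture(config, dir = dir)
  true_lincs <- disc$manifest$transcript_id[disc$manifest$is_true_linc]
  n_mrna <- config$n_blocks * config$block_mrnas + config$n_background_mrnas
  mrna_ids <- sprintf("CaMRNA_%04d", seq_len(n_mrna))
  expr <- generate_expression_fixture(config, linc_ids = true_lincs,
                                      mrna_ids = mrna_ids)
  net <- generate_network_fixture(config, mrna_ids = mrna_ids)
  mir <- generate_mirna_fixture(config, linc_seqs = disc$sequences[true_lincs])
  list(discovery = disc, expression = expr, network = net, mirna = mir,
       config = config)
}
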