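test_that("expression classes bin FPKM at the documented boundaries", {
  got <- classify_expression(c(0, 1.9, 2, 4.9, 5, 9.9, 10, 20, 20.1, 100))
  expect_equal(as.character(got),
               c("very_low", "very_low", "low", "low", "moderate", "moderate",
                 "high", "high", "very_high", "very_high"))
  expect_error(classify_expression(-1), "negative")
})

test_that("tau is 0 for uniform, 1 for single-tissue, 0.95 for the hand example", {
  expr <- tibble::tibble(
    transcript_id = c("hk", "strict", "hand"),
    !!!stats::setNames(as.list(as.data.frame(rbind(
      rep(5, 11),
      c(8, rep(0, 10)),
      c(10, 5, rep(0, 9))
    ))), default_tissues())
  )
  tsi <- compute_tsi(expr)
  expect_equal(tsi$tsi[tsi$transcript_id == "hk"], 0)
  expect_equal(tsi$tsi[tsi$transcript_id == "strict"], 1)
  # direct evaluation of sum(1 - x/xmax)/(N-1) on (10,5,0x9):
  # (0 + 0.5 + 9) / 10 = 0.95
  expect_equal(tsi$tsi[tsi$transcript_id == "hand"], 0.95)
  expect_equal(tsi$max_tissue[tsi$transcript_id == "hand"], "GS")
})

test_that("tau is scale-invariant, bounded and monotone", {
  set.seed(202)
  for (r in 1:50) {
    x <- runif(11, 0, 50)
    expr <- tibble::tibble(transcript_id = "t",
                           !!!stats::setNames(as.list(x), default_tissues()))
    t1 <- compute_tsi(expr)$tsi
    expect_gte(t1, 0)
    expect_lte(t1, 1)
    c_ <- runif(1, 0.1, 10)
    expr2 <- tibble::tibble(transcript_id = "t",
                            !!!stats::setNames(as.list(c_ * x),
                                               default_tissues()))
    expect_equal(compute_tsi(expr2)$tsi, t1, tolerance = 1e-12)
    # raising a non-maximal tissue (below the max) never increases tau
    i <- which(x < max(x))[1]
    x3 <- x
    x3[i] <- x3[i] + runif(1) * (max(x) - x3[i])
    expr3 <- tibble::tibble(transcript_id = "t",
                            !!!stats::setNames(as.list(x3),
                                               default_tissues()))
    expect_lte(compute_tsi(expr3)$tsi, t1 + 1e-12)
  }
  # all-zero rows are flagged undefined and never called specific
  zero <- tibble::tibble(transcript_id = "z",
                         !!!stats::setNames(as.list(rep(0, 11)),
                                            default_tissues()))
  tz <- compute_tsi(zero)
  expect_false(tz$defined)
  expect_true(is.na(tz$tsi))
  expect_equal(nrow(call_tissue_specific(zero)), 0L)
})

test_that("specificity calling recovers planted profiles with no housekeeping calls", {
  cfg <- sim_config(seed = 41L)
  ex <- generate_expression_fixture(cfg, sprintf("L%03d", 1:40),
                                    sprintf("M%03d", 1:45))
  calls <- call_tissue_specific(ex$linc_expr)
  man <- ex$manifest[ex$manifest$role == "lincRNA", ]
  spec <- man[man$profile == "specific", ]
  hit <- merge(calls, spec, by.x = c("transcript_id", "tissue"),
               by.y = c("id", "tissue"))
  expect_gte(nrow(hit), ceiling(0.95 * nrow(spec)))
  expect_equal(sum(calls$transcript_id %in%
                     man$id[man$profile == "housekeeping"]), 0L)
  # boundary behaviour of the threshold itself
  tsi <- tibble::tibble(transcript_id = c("a", "b"), tsi = c(0.95, 0.89),
                        max_tissue = "GS", max_fpkm = 5, defined = TRUE)
  out <- call_tissue_specific(ex$linc_expr, tsi = tsi)
  expect_equal(out$transcript_id, "a")
})

test_that("stage-specific calling enforces on/off thresholds", {
  mk <- function(vals) {
    tibble::tibble(transcript_id = "t",
                   !!!stats::setNames(as.list(vals), default_tissues()))
  }
  fb <- c("FB1", "FB2", "FB3", "FB4")
  on <- rep(0, 11); on[4] <- 4                  # FB1 = 4, rest 0
  expect_equal(call_stage_specific(mk(on), fb)$transcript_id, "t")
  leaky <- on; leaky[2] <- 0.2                  # YL = 0.2 > 0.1
  expect_equal(nrow(call_stage_specific(mk(leaky), fb)), 0L)
  weak <- rep(0, 11); weak[4] <- 2.9            # below the on threshold
  expect_equal(nrow(call_stage_specific(mk(weak), fb)), 0L)
  expect_error(call_stage_specific(mk(on), character(0)), "empty")
  expect_error(call_stage_specific(mk(on), "NOPE"), "not in")
})

test_that("Spearman co-expression matches the rank-then-Pearson oracle", {
  tissues <- default_tissues()
  idc <- tibble::tibble(transcript_id = "a",
                        !!!stats::setNames(as.list(1:11), tissues))
  rev_ <- tibble::tibble(transcript_id = "b",
                         !!!stats::setNames(as.list(11:1), tissues))
  expect_equal(spearman_coexpression(idc, idc)$pairs$rho, 1)
  expect_equal(spearman_coexpression(idc, rev_)$pairs$rho, -1)

  set.seed(77)
  A <- matrix(rlnorm(20 * 11), 20, dimnames = list(paste0("L", 1:20), tissues))
  B <- matrix(rlnorm(15 * 11), 15, dimnames = list(paste0("M", 1:15), tissues))
  ta <- tibble::as_tibble(cbind(data.frame(transcript_id = rownames(A)), A))
  tb <- tibble::as_tibble(cbind(data.frame(transcript_id = rownames(B)), B))
  co <- spearman_coexpression(ta, tb)
  for (r in sample(nrow(co$pairs), 40)) {
    p <- co$pairs[r, ]
    expect_equal(p$rho, spearman_manual(A[p$linc_id, ], B[p$mrna_id, ]),
                 tolerance = 1e-12)
  }
  # zero-variance rows are flagged and forced to rho 0
  flat <- tibble::tibble(transcript_id = "flat",
                         !!!stats::setNames(as.list(rep(2, 11)), tissues))
  cf <- spearman_coexpression(flat, tb)
  expect_true(all(cf$pairs$flagged))
  expect_true(all(cf$pairs$rho == 0))
  # mismatched tissue panels are rejected
  expect_error(spearman_coexpression(ta, tb[, 1:6]), "differ")
})

test_that("top co-expressed mRNA lists rank by rho with lexicographic ties", {
  co <- structure(list(pairs = tibble::tibble(
    linc_id = "L1",
    mrna_id = c("Mb", "Ma", "Mc", "Md", "Me"),
    rho = c(0.9, 0.9, 0.5, 0.2, -0.3),
    flagged = FALSE
  ), tissues = default_tissues()), class = "coexpression")
  top <- top_coexpressed(co, "L1", k = 10)
  expect_equal(nrow(top), 5L)                     # fewer available than k
  expect_equal(top$mrna_id[1:2], c("Ma", "Mb"))   # tie broken by id
  expect_error(top_coexpressed(co, "L999"), "unknown")

  # planted co-regulated block occupies the top ranks
  cfg <- sim_config(seed = 43L)
  ex <- generate_expression_fixture(cfg, sprintf("L%03d", 1:40),
                                    sprintf("M%03d", 1:45))
  co2 <- spearman_coexpression(ex$linc_expr, ex$mrna_expr)
  man <- ex$manifest
  bl <- man[man$role == "lincRNA" & man$profile == "block" & man$block == 1, ]
  bm <- man[man$role == "mRNA" & man$profile == "block" & man$block == 1, ]
  top2 <- top_coexpressed(co2, bl$id[1], k = nrow(bm))
  expect_gte(mean(top2$mrna_id %in% bm$id), 0.9)
})

test_that("per-tissue expressed counts match a brute-force tally", {
  tissues <- default_tissues()
  one <- tibble::tibble(transcript_id = "t",
                        !!!stats::setNames(as.list(c(0, 0.5, rep(0, 9))),
                                           tissues))
  cnt <- count_expressed_per_tissue(one, min_fpkm = 0.1)
  expect_equal(cnt$n_expressed[cnt$tissue == "YL"], 1L)
  expect_equal(sum(cnt$n_expressed), 1L)
  expect_true(all(count_expressed_per_tissue(one, 0)$n_expressed == 1L))

  cfg <- sim_config(seed = 47L)
  ex <- generate_expression_fixture(cfg, sprintf("L%03d", 1:40),
                                    sprintf("M%03d", 1:45))
  got <- count_expressed_per_tissue(ex$linc_expr, min_fpkm = 1)
  m <- fpkm_matrix(ex$linc_expr)
  expect_equal(got$n_expressed, unname(colSums(m >= 1)))
})

test_that("row z-scoring centres and scales for the heatmap", {
  tissues <- default_tissues()
  expr <- tibble::tibble(transcript_id = c("a", "flat"),
                         !!!stats::setNames(as.list(as.data.frame(rbind(
                           1:11, rep(3, 11)
                         ))), tissues))
  z <- zscore_rows(expr)
  expect_equal(unname(rowMeans(z)), c(0, 0))
  expect_equal(unname(apply(z, 1, stats::sd)), c(1, 0))
})
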