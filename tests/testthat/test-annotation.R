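test_that("min-max normalization maps endpoints and degenerate input", {
  expect_equal(minmax_normalize(c(2, 4, 6)), c(0, 0.5, 1))
  expect_equal(minmax_normalize(rep(7, 5)), rep(0, 5))
  set.seed(303)
  x <- rnorm(50)
  nx <- minmax_normalize(x)
  expect_equal(nx[which.min(x)], 0)
  expect_equal(nx[which.max(x)], 1)
  expect_true(all(nx >= 0 & nx <= 1))
})

test_that("percentile edge threshold equals the sort-and-cut oracle", {
  set.seed(304)
  # distinct magnitudes with random signs, so the top-|rho| set is unambiguous
  rho <- sample(seq(0.0005, 0.9995, length.out = 1000)) *
    sample(c(-1, 1), 1000, replace = TRUE)
  pairs <- tibble::tibble(node_a = paste0("L", 1:1000),
                          node_b = paste0("M", 1:1000), rho = rho)
  edges <- build_coexpression_edges(pairs, percentile = 0.5)
  top5 <- pairs[order(-abs(pairs$rho)), ][1:5, ]       # 0.5% of 1000 = 5
  expect_setequal(edges$node_a, top5$node_a)
  expect_equal(sort(edges$weight), sort(abs(top5$rho)))

  # degenerate tie: all correlations equal -> every pair kept
  same <- tibble::tibble(node_a = paste0("L", 1:300),
                         node_b = paste0("M", 1:300), rho = 0.7)
  expect_equal(nrow(build_coexpression_edges(same)), 300L)

  small <- pairs[1:50, ]
  expect_warning(build_coexpression_edges(small), "unstable")
})

test_that("bicolor network combines evidence by max and rejects bad PPI edges", {
  co <- tibble::tibble(node_a = c("L1", "m1"), node_b = c("m1", "m2"),
                       weight = c(0.7, 0.4))
  ppi <- tibble::tibble(protein_a = c("m1", "m1"), protein_b = c("m2", "m3"),
                        score = c(0.9, 0.1))
  net <- combine_network(co, ppi, linc_ids = "L1",
                         mrna_ids = c("m1", "m2", "m3"))
  # PPI scores are min-max normalized: 0.9 -> 1, 0.1 -> 0
  expect_equal(net$W["m1", "m2"], max(0.4, 1))
  expect_equal(net$W["L1", "m1"], 0.7)
  expect_true(isSymmetric(net$W))
  expect_true(all(diag(net$W) == 0))
  expect_equal(unname(net$color[c("L1", "m1")]), c("lincRNA", "mRNA"))

  bad_ppi <- tibble::tibble(protein_a = "L1", protein_b = "m1", score = 1)
  expect_error(combine_network(co, bad_ppi, "L1", c("m1", "m2", "m3")),
               "lincRNA")
})

test_that("first-degree seeding takes the union of neighbour annotations", {
  co <- tibble::tibble(node_a = c("L1", "L1"), node_b = c("m1", "m2"),
                       weight = c(0.9, 0.8))
  net <- combine_network(co, NULL, linc_ids = c("L1", "L2"),
                         mrna_ids = c("m1", "m2"))
  go <- tibble::tibble(gene_id = c("m1", "m1", "m2"),
                       term = c("GO:a", "GO:b", "GO:b"))
  seeded <- seed_first_degree(net, go)
  expect_setequal(seeded$term[seeded$linc_id == "L1"], c("GO:a", "GO:b"))
  expect_equal(sum(seeded$linc_id == "L2"), 0L)   # isolated lincRNA
})

test_that("propagation closed forms hold for empty and isolated seeds", {
  net <- combine_network(
    tibble::tibble(node_a = character(), node_b = character(),
                   weight = numeric()),
    NULL, linc_ids = "L1", mrna_ids = c("m1", "m2")
  )
  Y <- matrix(c(1, 0, 0, 0, 0, 0), nrow = 3,
              dimnames = list(c("m1", "m2", "L1"), c("GO:seed", "GO:empty")))
  prop <- propagate_annotations(net, Y, alpha = 0.8)
  # empty prior column stays identically zero
  expect_true(all(prop$F[, "GO:empty"] == 0))
  # isolated seeded node: F = (1 - alpha) * Y
  expect_equal(prop$F["m1", "GO:seed"], 0.2, tolerance = 1e-9)
  expect_equal(prop$F["m2", "GO:seed"], 0)
  expect_true(all(prop$converged))
})

test_that("propagation matches the direct linear solve on a 3-node path", {
  co <- tibble::tibble(node_a = c("m1", "m2"), node_b = c("m2", "L1"),
                       weight = c(1, 1))
  net <- combine_network(co, NULL, linc_ids = "L1", mrna_ids = c("m1", "m2"))
  go <- tibble::tibble(gene_id = "m1", term = "GO:x")
  prop <- propagate_annotations(net, go, alpha = 0.8, tol = 1e-9)
  Y <- matrix(c(1, 0, 0), 3, dimnames = list(c("m1", "m2", "L1"), "GO:x"))
  direct <- propagation_solve(net$W, Y, alpha = 0.8)
  expect_equal(prop$F[, "GO:x"], direct[, "GO:x"], tolerance = 1e-5)
})

test_that("propagation equals the oracle solve on random networks up to 200 nodes", {
  set.seed(305)
  for (n in c(20L, 80L, 200L)) {
    nodes <- paste0("n", seq_len(n))
    W <- matrix(0, n, n, dimnames = list(nodes, nodes))
    idx <- which(upper.tri(W))
    on <- sample(idx, size = round(0.05 * length(idx)))
    W[on] <- runif(length(on))
    W <- W + t(W)
    n_mrna <- floor(n / 2)
    net <- structure(list(
      W = W,
      color = stats::setNames(c(rep("mRNA", n_mrna),
                                rep("lincRNA", n - n_mrna)), nodes),
      nodes = nodes
    ), class = "bicolor_network")
    Y <- matrix(0, n, 2, dimnames = list(nodes, c("GO:1", "GO:2")))
    Y[sample(seq_len(n_mrna), 5), "GO:1"] <- 1
    Y[sample(seq_len(n_mrna), 8), "GO:2"] <- 1
    prop <- propagate_annotations(net, Y, alpha = 0.8, tol = 1e-9)
    direct <- propagation_solve(W, Y, alpha = 0.8)
    expect_equal(prop$F, direct, tolerance = 1e-5)
    expect_true(all(prop$converged))
    # fixed-point residual below the tolerance
    resid <- sum(abs(prop$F - (0.8 * prop$Wnorm %*% prop$F + 0.2 * Y)))
    expect_lt(resid, 1e-6 * ncol(Y) + 1e-9)
  }
})

test_that("connecting a lincRNA to a seed mRNA never lowers its score", {
  set.seed(306)
  for (r in 1:20) {
    nodes <- c(paste0("m", 1:6), paste0("L", 1:3))
    W <- matrix(0, 9, 9, dimnames = list(nodes, nodes))
    for (i in 1:8) for (j in (i + 1):9) {
      linc_pair <- startsWith(nodes[i], "L") && startsWith(nodes[j], "L")
      if (!linc_pair && runif(1) < 0.3) {
        W[i, j] <- W[j, i] <- runif(1)
      }
    }
    net <- structure(list(
      W = W,
      color = stats::setNames(c(rep("mRNA", 6), rep("lincRNA", 3)), nodes),
      nodes = nodes
    ), class = "bicolor_network")
    go <- tibble::tibble(gene_id = "m1", term = "GO:x")
    before <- propagate_annotations(net, go, alpha = 0.8, tol = 1e-9)
    l <- sample(paste0("L", 1:3), 1)
    if (W[l, "m1"] > 0) next
    net$W[l, "m1"] <- net$W["m1", l] <- runif(1)
    after <- propagate_annotations(net, go, alpha = 0.8, tol = 1e-9)
    expect_gte(after$F[l, "GO:x"], before$F[l, "GO:x"] - 1e-9)
  }
})

test_that("term assignment respects the rank cap and the positive-score guard", {
  co <- tibble::tibble(node_a = c("L1", "L2"), node_b = c("m1", "m1"),
                       weight = c(0.9, 0.5))
  net <- combine_network(co, NULL, linc_ids = c("L1", "L2", "L3"),
                         mrna_ids = "m1")
  go <- tibble::tibble(gene_id = "m1", term = "GO:x")
  prop <- propagate_annotations(net, go)
  asg_all <- assign_annotations(prop, top_rank = 100)
  # the isolated lincRNA has score 0 and is never annotated
  expect_false("L3" %in% asg_all$linc_id)
  expect_lte(nrow(asg_all), 3L)
  asg_one <- assign_annotations(prop, top_rank = 1)
  expect_equal(asg_one$linc_id, "L1")   # stronger edge ranks first
  cov <- annotation_coverage(asg_all, c("L1", "L2", "L3"))
  expect_equal(cov$n_annotated, 2L)
  expect_equal(cov$n_total, 3L)
})

test_that("planted GO modules propagate to their lincRNAs without crosstalk", {
  cfg <- sim_config(seed = 51L)
  study <- simulate_lincrna_study(cfg)
  ex <- study$expression
  pairs <- coexpression_pair_universe(ex$linc_expr, ex$mrna_expr)
  # fixture-scale percentile: keep roughly the planted coherent-pair mass
  edges <- build_coexpression_edges(pairs, percentile = 15)
  net <- combine_network(edges, study$network$ppi,
                         linc_ids = ex$linc_expr$transcript_id,
                         mrna_ids = ex$mrna_expr$transcript_id)
  prop <- propagate_annotations(net, study$network$go, alpha = 0.8)
  expect_true(all(prop$converged))
  asg <- assign_annotations(prop, top_rank = cfg$block_lincs)
  man <- ex$manifest[ex$manifest$role == "lincRNA" &
                       ex$manifest$profile == "block", ]
  truth <- tibble::tibble(linc_id = man$id,
                          term = sprintf("GO:MOD%04d", man$block))
  correct <- merge(asg, truth)
  expect_gte(nrow(correct), ceiling(0.9 * nrow(truth)))
  crossed <- merge(asg, truth, by = "linc_id")
  expect_equal(sum(crossed$term.x != crossed$term.y), 0L)
})

test_that("hypergeometric enrichment is exact and flags by threshold", {
  # fully selective draw: study of 5 hits all 5 term genes out of 20
  pop <- paste0("g", 1:20)
  go <- tibble::tibble(gene_id = paste0("g", 1:5), term = "GO:t")
  res <- enrich_go(paste0("g", 1:5), pop, go, p_threshold = 1e-3)
  expect_equal(res$p_value, 1 / choose(20, 5), tolerance = 1e-12)
  expect_equal(res$k, 5L)
  expect_equal(res$K, 5L)
  expect_true(res$significant)    # 6.45e-5 is below the 1e-3 threshold
  expect_false(any(enrich_go(paste0("g", 1:5), pop, go)$significant))
})

test_that("enrichment p is 1 for a universal term and errors on empty study", {
  pop <- paste0("g", 1:12)
  go <- tibble::tibble(gene_id = pop, term = "GO:all")
  res <- enrich_go(pop[1:4], pop, go)
  expect_equal(res$p_value, 1)
  expect_error(enrich_go(character(0), pop, go), "empty")
  expect_error(enrich_go("not_there", pop, go), "contained")
})

test_that("enrichment p-values are uniform under the null", {
  # discrete hypergeometric p-values are made exactly uniform with the
  # standard randomization U = P(X > k) + V * P(X = k), V ~ U(0,1)
  set.seed(307)
  pop <- paste0("g", 1:60)
  go <- tibble::tibble(gene_id = paste0("g", 1:20), term = "GO:t")
  u <- replicate(1000, {
    study <- sample(pop, 15)
    res <- enrich_go(study, pop, go, p_threshold = 1e-10)
    k <- res$k
    p_ge <- res$p_value
    p_eq <- stats::dhyper(k, 20, 40, 15)
    p_ge - runif(1) * p_eq
  })
  ks <- stats::ks.test(u, "punif")
  expect_gt(ks$p.value, 0.01)
})
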