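#' Min-max linear normalization
#'
#' Maps values linearly onto `[0,1]`; a constant vector maps to all zeros
#' (degenerate rule, so constant evidence carries no weight).
#'
#' @param x Numeric vector with at least one value.
#' @return Numeric vector in `[0,1]`.
#' @export
minmax_normalize <- function(x) {
  .assert(length(x) >= 1, "need at least one value")
  rng <- range(x)
  if (rng[1] == rng[2]) return(rep(0, length(x)))
  (x - rng[1]) / (rng[2] - rng[1])
}

#' Build the candidate pair universe for co-expression edges
#'
#' Collects the node pairs whose rank correlations compete for network edges:
#' all lincRNA-mRNA pairs and all mRNA-mRNA pairs (lincRNA-lincRNA pairs are
#' excluded by default; enable with `include_linc_linc`).
#'
#' @param linc_expr,mrna_expr FPKM tibbles with identical tissue columns.
#' @param include_linc_linc Also include lincRNA-lincRNA pairs.
#' @return Tibble: `node_a`, `node_b`, `rho`, `flagged`.
#' @export
coexpression_pair_universe <- function(linc_expr, mrna_expr,
                                       include_linc_linc = FALSE) {
  lm <- spearman_coexpression(linc_expr, mrna_expr)$pairs %>%
    rename(node_a = "linc_id", node_b = "mrna_id")
  mm <- spearman_coexpression(mrna_expr, mrna_expr)$pairs %>%
    rename(node_a = "linc_id", node_b = "mrna_id") %>%
    filter(.data$node_a < .data$node_b)   # upper triangle, no self pairs
  out <- bind_rows(lm, mm)
  if (include_linc_linc) {
    ll <- spearman_coexpression(linc_expr, linc_expr)$pairs %>%
      rename(node_a = "linc_id", node_b = "mrna_id") %>%
      filter(.data$node_a < .data$node_b)
    out <- bind_rows(out, ll)
  }
  out
}

#' Threshold co-expression pairs at a top-percentile cutoff
#'
#' Keeps the pairs whose absolute rank correlation lies in the top
#' `percentile` percent of the candidate universe: the threshold is the
#' `(100 - percentile)`-th percentile of `|rho|` and a pair is kept when
#' `|rho| >= t`. Edge weight is `|rho|`.
#'
#' @param pairs Tibble with columns `node_a`, `node_b`, `rho` (e.g. from
#'   [coexpression_pair_universe()]).
#' @param percentile Top percentage of pairs to keep (default 0.5, i.e. the
#'   top 0.5% of absolute correlations).
#' @return Tibble: `node_a`, `node_b`, `weight`; attribute `threshold` holds
#'   the cutoff used.
#' @export
build_coexpression_edges <- function(pairs, percentile = 0.5) {
  .assert(percentile > 0 && percentile < 100, "percentile must be in (0,100)")
  if (nrow(pairs) < 200) {
    warning("fewer than 200 candidate pairs; percentile threshold is unstable",
            call. = FALSE)
  }
  a <- abs(pairs$rho)
  t <- unname(stats::quantile(a, 1 - percentile / 100))
  edges <- pairs %>%
    filter(abs(.data$rho) >= t) %>%
    mutate(weight = abs(.data$rho)) %>%
    select("node_a", "node_b", "weight")
  attr(edges, "threshold") <- t
  edges
}

#' Combine co-expression and protein-interaction edges into a bicolor network
#'
#' Builds the weighted bicolor graph over mRNA and lincRNA nodes: PPI scores
#' are min-max normalized to `[0,1]` and merged with co-expression edge
#' weights (already `|rho| <= 1`); where both evidence types cover a pair the
#' weights are combined by `max` (default) or `mean`. PPI edges may only
#' connect mRNA nodes.
#'
#' @param coexpr_edges Tibble `node_a`, `node_b`, `weight` from
#'   [build_coexpression_edges()].
#' @param ppi_edges Tibble `protein_a`, `protein_b`, `score`; may be empty.
#' @param linc_ids,mrna_ids Node identity vectors (disjoint).
#' @param combine `"max"` or `"mean"`.
#' @return Object of class `bicolor_network`: list with `W` (symmetric
#'   weighted adjacency, zero diagonal), `color` (named `"mRNA"`/`"lincRNA"`)
#'   and `nodes`.
#' @export
combine_network <- function(coexpr_edges, ppi_edges, linc_ids, mrna_ids,
                            combine = c("max", "mean")) {
  combine <- match.arg(combine)
  .assert(!length(intersect(linc_ids, mrna_ids)),
          "lincRNA and mRNA id sets overlap")
  nodes <- c(mrna_ids, linc_ids)
  color <- setNames(c(rep("mRNA", length(mrna_ids)),
                      rep("lincRNA", length(linc_ids))), nodes)
  if (!is.null(ppi_edges) && nrow(ppi_edges)) {
    touch_linc <- ppi_edges$protein_a %in% linc_ids |
      ppi_edges$protein_b %in% linc_ids
    if (any(touch_linc)) {
      stop("PPI edge touches a lincRNA node: ",
           ppi_edges$protein_a[touch_linc][1], call. = FALSE)
    }
    ppi <- tibble(node_a = ppi_edges$protein_a, node_b = ppi_edges$protein_b,
                  weight = minmax_normalize(ppi_edges$score))
  } else {
    ppi <- tibble(node_a = character(), node_b = character(),
                  weight = numeric())
  }
  all_edges <- bind_rows(coexpr_edges, ppi)
  bad <- !(all_edges$node_a %in% nodes) | !(all_edges$node_b %in% nodes)
  .assert(!any(bad), "edge references a node outside the node set")

  n <- length(nodes)
  W <- matrix(0, n, n, dimnames = list(nodes, nodes))
  if (nrow(all_edges)) {
    ia <- match(all_edges$node_a, nodes)
    ib <- match(all_edges$node_b, nodes)
    for (k in seq_len(nrow(all_edges))) {
      i <- ia[k]; j <- ib[k]
      if (i == j) next
      w <- all_edges$weight[k]
      cur <- W[i, j]
      new <- if (cur == 0) w else if (combine == "max") max(cur, w) else {
        # mean of the two evidence weights when both cover the pair
        (cur + w) / 2
      }
      W[i, j] <- new
      W[j, i] <- new
    }
  }
  diag(W) <- 0
  structure(list(W = W, color = color, nodes = nodes),
            class = "bicolor_network")
}

#' @export
print.bicolor_network <- function(x, ...) {
  cat(sprintf("bicolor network: %d mRNA + %d lincRNA nodes, %d edges\n",
              sum(x$color == "mRNA"), sum(x$color == "lincRNA"),
              sum(x$W > 0) / 2))
  invisible(x)
}

#' Binary GO prior matrix of a bicolor network
#'
#' Builds the node-by-term prior `Y`: 1 where an mRNA node carries the GO
#' annotation, 0 elsewhere (lincRNA rows are all zero). Terms with no
#' annotated node in the network are dropped.
#'
#' @param network A [combine_network()] result.
#' @param go_annotations Tibble with columns `gene_id`, `term`.
#' @return Binary matrix (nodes x terms).
#' @export
go_priors <- function(network, go_annotations) {
  ann <- go_annotations %>%
    filter(.data$gene_id %in% names(network$color)[network$color == "mRNA"]) %>%
    distinct(.data$gene_id, .data$term)
  terms <- sort(unique(ann$term))
  .assert(length(terms) >= 1, "no GO term annotates any network mRNA")
  Y <- matrix(0, length(network$nodes), length(terms),
              dimnames = list(network$nodes, terms))
  Y[cbind(ann$gene_id, ann$term)] <- 1
  Y
}

#' First-degree-neighbour GO annotation of lincRNAs
#'
#' Annotates every lincRNA node with the union of GO terms of the mRNA nodes
#' it is directly connected to. This direct transfer is recorded separately
#' from the propagation-based annotation.
#'
#' @inheritParams go_priors
#' @return Tibble: `linc_id`, `term`.
#' @export
seed_first_degree <- function(network, go_annotations) {
  lincs <- names(network$color)[network$color == "lincRNA"]
  ann <- go_annotations %>% distinct(.data$gene_id, .data$term)
  out <- map(lincs, function(l) {
    nb <- colnames(network$W)[network$W[l, ] > 0]
    terms <- sort(unique(ann$term[ann$gene_id %in% nb]))
    if (!length(terms)) return(NULL)
    tibble(linc_id = l, term = terms)
  })
  res <- bind_rows(out)
  if (!nrow(res)) res <- tibble(linc_id = character(), term = character())
  res
}

# symmetric degree normalization W' = D^{-1/2} W D^{-1/2}; isolated rows -> 0
.normalize_adjacency <- function(W) {
  d <- rowSums(W)
  s <- ifelse(d > 0, 1 / sqrt(d), 0)
  W * outer(s, s)
}

#' Propagate GO annotations over the bicolor network
#'
#' Global label propagation: with the symmetrically degree-normalized
#' adjacency `W'`, each term's score vector is iterated
#' `F <- alpha W' F + (1 - alpha) Y` from `F = Y` until the L1 change drops
#' below `tol` (or `max_iter` is hit, in which case the term is flagged
#' non-converged). The fixed point trades smoothness over the network against
#' fidelity to the mRNA GO priors and ranks lincRNAs for each term.
#'
#' @inheritParams go_priors
#' @param alpha Propagation weight in (0,1); higher spreads information
#'   further along the network.
#' @param tol L1 convergence tolerance per term.
#' @param max_iter Iteration cap.
#' @return Object of class `go_propagation`: list with `F` (node-by-term
#'   scores), `Y`, `color`, `alpha`, `tol`, `iterations`, `converged`
#'   (named logical per term) and `Wnorm`.
#' @export
propagate_annotations <- function(network, go_annotations, alpha = 0.8,
                                  tol = 1e-6, max_iter = 1000L) {
  .assert(alpha > 0 && alpha < 1, "alpha must be in (0,1)")
  Y <- if (is.matrix(go_annotations)) go_annotations
       else go_priors(network, go_annotations)
  Wn <- .normalize_adjacency(network$W)
  F_ <- Y
  active <- rep(TRUE, ncol(Y))
  iters <- integer(ncol(Y))
  for (it in seq_len(max_iter)) {
    Fn <- alpha * (Wn %*% F_[, active, drop = FALSE]) +
      (1 - alpha) * Y[, active, drop = FALSE]
    delta <- colSums(abs(Fn - F_[, active, drop = FALSE]))
    F_[, active] <- Fn
    iters[active] <- it
    done <- delta < tol
    if (any(done)) active[which(active)[done]] <- FALSE
    if (!any(active)) break
  }
  converged <- setNames(!active, colnames(Y))
  if (any(active)) {
    warning("propagation did not converge for ", sum(active),
            " term(s) within ", max_iter, " iterations", call. = FALSE)
  }
  structure(list(F = F_, Y = Y, color = network$color, alpha = alpha,
                 tol = tol, iterations = setNames(iters, colnames(Y)),
                 converged = converged, Wnorm = Wn),
            class = "go_propagation")
}

#' @export
print.go_propagation <- function(x, ...) {
  cat(sprintf("GO propagation: %d nodes x %d terms, alpha = %g (%s)\n",
              nrow(x$F), ncol(x$F), x$alpha,
              if (all(x$converged)) "all terms converged"
              else paste(sum(!x$converged), "terms not converged")))
  invisible(x)
}

#' @describeIn propagate_annotations `tidy()` returns long per-node scores.
#' @param x A `go_propagation` object.
#' @param ... Unused.
#' @export
tidy.go_propagation <- function(x, ...) {
  as_tibble(as.data.frame.table(x$F, responseName = "score",
                                stringsAsFactors = FALSE)) %>%
    rename(node = "Var1", term = "Var2") %>%
    mutate(color = unname(x$color[.data$node]))
}

#' @describeIn propagate_annotations `glance()` summarises convergence.
#' @export
glance.go_propagation <- function(x, ...) {
  tibble(n_nodes = nrow(x$F), n_terms = ncol(x$F), alpha = x$alpha,
         all_converged = all(x$converged),
         max_iterations = max(x$iterations))
}

#' Assign GO terms to lincRNAs from propagation scores
#'
#' For each term, lincRNA nodes are ranked by propagation score (descending,
#' ties broken by node id) and the `top_rank` best with a strictly positive
#' score receive the term.
#'
#' @param propagation A [propagate_annotations()] result.
#' @param top_rank Number of top-ranked lincRNAs annotated per term.
#' @return Tibble: `linc_id`, `term`, `score`, `rank`.
#' @export
assign_annotations <- function(propagation, top_rank = 100L) {
  lincs <- names(propagation$color)[propagation$color == "lincRNA"]
  Fl <- propagation$F[lincs, , drop = FALSE]
  out <- map(colnames(Fl), function(term) {
    sc <- Fl[, term]
    ord <- order(-sc, names(sc))
    ranked <- tibble(linc_id = names(sc)[ord], term = term,
                     score = unname(sc[ord])) %>%
      mutate(rank = row_number()) %>%
      filter(.data$rank <= top_rank, .data$score > 0)
    if (nrow(ranked)) ranked else NULL
  })
  res <- bind_rows(out)
  if (!nrow(res)) {
    res <- tibble(linc_id = character(), term = character(),
                  score = numeric(), rank = integer())
  }
  res
}

#' Fraction of lincRNAs with at least one assigned term
#'
#' @param assignments Result of [assign_annotations()] (or
#'   [seed_first_degree()]).
#' @param linc_ids All lincRNA identifiers in the analysis.
#' @return One-row tibble: `n_annotated`, `n_total`, `pct` (rounded) and
#'   `pct_floor`.
#' @export
annotation_coverage <- function(assignments, linc_ids) {
  n_ann <- length(intersect(unique(assignments$linc_id), linc_ids))
  tibble(n_annotated = n_ann, n_total = length(linc_ids),
         pct = percent_of(n_ann, length(linc_ids), "round"),
         pct_floor = percent_of(n_ann, length(linc_ids), "floor"))
}

#' Hypergeometric GO term enrichment
#'
#' For every term annotated in the population, computes the upper-tail
#' hypergeometric probability of observing at least the study's hit count:
#' with population size `N`, `K` population genes carrying the term, study
#' size `n` and `k` study hits, `p = P(X >= k)`. Benjamini-Hochberg adjusted
#' p-values are reported alongside.
#'
#' @param study Character vector of study gene ids (must be a subset of the
#'   population, non-empty).
#' @param population Character vector of population gene ids.
#' @param go_annotations Tibble `gene_id`, `term`.
#' @param p_threshold Significance threshold on the raw p-value.
#' @return Tibble sorted by `p_value`: `term`, `k`, `n`, `K`, `N`, `p_value`,
#'   `p_adjust`, `significant`.
#' @export
enrich_go <- function(study, population, go_annotations,
                      p_threshold = 1e-10) {
  study <- unique(study)
  population <- unique(population)
  .assert(length(study) >= 1, "empty study set")
  .assert(all(study %in% population), "study set not contained in population")
  ann <- go_annotations %>%
    filter(.data$gene_id %in% population) %>%
    distinct(.data$gene_id, .data$term)
  .assert(nrow(ann) > 0, "no annotation covers the population")
  Npop <- length(population)
  n <- length(study)
  per_term <- ann %>%
    group_by(.data$term) %>%
    summarise(K = dplyr::n_distinct(.data$gene_id),
              k = sum(unique(.data$gene_id) %in% study), .groups = "drop")
  per_term %>%
    mutate(
      n = n, N = Npop,
      p_value = phyper(.data$k - 1, .data$K, Npop - .data$K, n,
                       lower.tail = FALSE),
      p_adjust = p.adjust(.data$p_value, method = "BH"),
      significant = .data$p_value < p_threshold
    ) %>%
    arrange(.data$p_value) %>%
    select("term", "k", "n", "K", "N", "p_value", "p_adjust", "significant")
}

#' Export a bicolor network to GraphML
#'
#' @param network A [combine_network()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_network_graphml <- function(network, path) {
  g <- igraph::graph_from_adjacency_matrix(network$W, mode = "undirected",
                                           weighted = TRUE)
  igraph::V(g)$color_class <- unname(network$color[igraph::V(g)$name])
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
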