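# Plant-style miRNA-target complementarity scoring.
#
# The miRNA (5'->3') is aligned antiparallel to a target window: miRNA
# position i pairs with the i-th base of the reversed window. Per-position
# penalties: Watson-Crick pair 0, G:U wobble 0.5, mismatch 1, bulge 2; all
# penalties are doubled at miRNA positions 2-13 (the seed, counted from the
# miRNA 5' end). The expectation score of a duplex is the penalty total; at
# most one bulge (on either strand) is allowed per duplex.

.MIRNA_BASES <- c("A", "C", "G", "U")
.TARGET_BASES <- c("A", "C", "G", "T", "N")

# pair penalty lookup: rows miRNA base, cols target base (target in DNA, T==U)
.pair_cost_matrix <- function(match = 0, wobble = 0.5, mismatch = 1) {
  pc <- matrix(mismatch, 4, 5, dimnames = list(.MIRNA_BASES, .TARGET_BASES))
  pc["A", "T"] <- match
  pc["C", "G"] <- match
  pc["G", "C"] <- match
  pc["U", "A"] <- match
  pc["G", "T"] <- wobble   # G:U wobble
  pc["U", "G"] <- wobble
  pc[, "N"] <- mismatch
  pc
}

.seed_weights <- function(M, seed_start = 2L, seed_end = 13L, seed_factor = 2) {
  w <- rep(1, M)
  idx <- seq_len(M) >= seed_start & seq_len(M) <= seed_end
  w[idx] <- seed_factor
  w
}

.encode_target <- function(seq) {
  x <- match(strsplit(seq, "", fixed = TRUE)[[1]], .TARGET_BASES)
  .assert(!anyNA(x), "invalid character in target sequence")
  x
}

.encode_mirna <- function(seq) {
  seq <- chartr("T", "U", toupper(seq))
  x <- match(strsplit(seq, "", fixed = TRUE)[[1]], .MIRNA_BASES)
  .assert(!anyNA(x), "invalid character in miRNA sequence")
  x
}

# per-window duplex scores along a whole target sequence.
# Works in reversed-target coordinates: U = rev(target); a duplex anchored at
# U-position u pairs m[i] with U[u+i-1] (gapless). Returns, for every u, the
# best score over the allowed duplex variants and which variant/bulge it used.
.scan_duplexes <- function(mirna_enc, target_enc, pc, w, max_gaps = 1L,
                           gap_penalty = 2) {
  M <- length(mirna_enc)
  L <- length(target_enc)
  if (L < M - max_gaps) {
    return(tibble(u = integer(), score = numeric(), window_len = integer(),
                  bulge = character(), bulge_pos = integer()))
  }
  Urev <- rev(target_enc)
  # cost of pairing m[i] with U[u + i - 1 + shift]; Inf outside the sequence
  cost_at <- function(shift) {
    mat <- matrix(Inf, M, L)
    for (i in seq_len(M)) {
      pos <- seq_len(L) + i - 1L + shift
      ok <- pos >= 1L & pos <= L
      mat[i, ok] <- pc[cbind(mirna_enc[i], Urev[pos[ok]])] * w[i]
    }
    mat
  }
  c0 <- cost_at(0L)
  P0 <- apply(c0, 2, cumsum)                      # prefix sums over i
  res <- list()
  # gapless: valid u where the whole duplex fits
  u_ok <- seq_len(max(0L, L - M + 1L))
  if (length(u_ok)) {
    res$none <- tibble(u = u_ok, score = P0[M, u_ok],
                       window_len = M, bulge = "none", bulge_pos = NA_integer_)
  }
  if (max_gaps >= 1L && M >= 3L) {
    # miRNA bulge at internal position k: m[k] unpaired, window length M-1
    cm <- cost_at(-1L)
    Sm <- apply(cm[M:1, , drop = FALSE], 2, cumsum)[M:1, , drop = FALSE]
    u_ok <- seq_len(max(0L, L - (M - 1L) + 1L))
    if (length(u_ok)) {
      ks <- 2:(M - 1)
      sc <- vapply(ks, function(k) {
        P0[k - 1L, u_ok] + gap_penalty * w[k] + Sm[k + 1L, u_ok]
      }, numeric(length(u_ok)))
      sc <- matrix(sc, nrow = length(u_ok))
      best_k <- max.col(-sc, ties.method = "first")
      res$mirna <- tibble(u = u_ok,
                          score = sc[cbind(seq_along(u_ok), best_k)],
                          window_len = M - 1L, bulge = "mirna",
                          bulge_pos = ks[best_k])
    }
    # target bulge between miRNA positions k and k+1: window length M+1
    cp <- cost_at(1L)
    Sp <- apply(cp[M:1, , drop = FALSE], 2, cumsum)[M:1, , drop = FALSE]
    u_ok <- seq_len(max(0L, L - (M + 1L) + 1L))
    if (length(u_ok)) {
      ks <- 1:(M - 1)
      sc <- vapply(ks, function(k) {
        P0[k, u_ok] + gap_penalty * w[k + 1L] + Sp[k + 1L, u_ok]
      }, numeric(length(u_ok)))
      sc <- matrix(sc, nrow = length(u_ok))
      best_k <- max.col(-sc, ties.method = "first")
      res$target <- tibble(u = u_ok,
                           score = sc[cbind(seq_along(u_ok), best_k)],
                           window_len = M + 1L, bulge = "target",
                           bulge_pos = ks[best_k])
    }
  }
  bind_rows(res)
}

#' Score one miRNA-target duplex
#'
#' Aligns a miRNA (5'->3') against a single candidate target window and
#' returns the expectation score: the penalty total with match 0, G:U wobble
#' 0.5, mismatch 1, bulge 2, doubled at miRNA seed positions 2-13. The window
#' length must equal the miRNA length (gapless), one less (miRNA bulge) or
#' one more (target bulge) when `max_gaps = 1`. Lower scores mean better
#' complementarity; 0 is a perfect duplex.
#'
#' @param mirna miRNA sequence (RNA or DNA alphabet, 5'->3').
#' @param target_window Target subsequence (DNA alphabet, 5'->3').
#' @param max_gaps Maximum bulges in the duplex (0 or 1).
#' @param match,wobble,mismatch,gap_penalty Penalty constants.
#' @param seed_start,seed_end,seed_factor Seed window (miRNA positions,
#'   1-based from the 5' end) and penalty multiplier inside it.
#' @return One-row tibble: `expectation`, `window_len`, `bulge`
#'   (`"none"`/`"mirna"`/`"target"`), `bulge_pos`, and the aligned strings
#'   `aln_mirna` (5'->3'), `aln_pairs`, `aln_target` (3'->5').
#' @examples
#' score_site("UGGAAGCUA", "TAGCTTCCA")  # perfect duplex, expectation 0
#' @export
score_site <- function(mirna, target_window, max_gaps = 1L,
                       match = 0, wobble = 0.5, mismatch = 1,
                       gap_penalty = 2, seed_start = 2L, seed_end = 13L,
                       seed_factor = 2) {
  m <- .encode_mirna(mirna)
  t <- .encode_target(toupper(chartr("uU", "tT", target_window)))
  M <- length(m); L <- length(t)
  .assert(abs(L - M) <= max_gaps,
          "window length %d incompatible with miRNA length %d", L, M)
  pc <- .pair_cost_matrix(match, wobble, mismatch)
  w <- .seed_weights(M, seed_start, seed_end, seed_factor)
  cand <- .scan_duplexes(m, t, pc, w, max_gaps = max_gaps,
                         gap_penalty = gap_penalty)
  cand <- cand[cand$window_len == L & cand$u == 1L, ]
  .assert(nrow(cand) > 0, "no admissible duplex for this window")
  best <- cand[which.min(cand$score), ]
  aln <- .duplex_alignment(m, t, best$bulge, best$bulge_pos, pc)
  tibble(expectation = best$score, window_len = L, bulge = best$bulge,
         bulge_pos = best$bulge_pos,
         aln_mirna = aln$mirna, aln_pairs = aln$pairs, aln_target = aln$target)
}

# build display strings for a duplex (miRNA 5'->3' on top, target 3'->5')
.duplex_alignment <- function(m, t, bulge, bulge_pos, pc) {
  Urev <- rev(t)
  mi <- .MIRNA_BASES[m]
  M <- length(m)
  if (bulge == "none") {
    tgt <- .TARGET_BASES[Urev]
    top <- mi
  } else if (bulge == "mirna") {
    k <- bulge_pos
    tgt <- .TARGET_BASES[Urev]
    tgt <- append(tgt, "-", after = k - 1L)
    top <- mi
  } else {
    k <- bulge_pos
    tgt <- .TARGET_BASES[Urev]
    top <- append(mi, "-", after = k)
  }
  sym <- vapply(seq_along(top), function(i) {
    if (top[i] == "-" || tgt[i] == "-") return(" ")
    cost <- pc[top[i], tgt[i]]
    if (cost == 0) "|" else if (cost < 1) ":" else " "
  }, character(1))
  list(mirna = paste(top, collapse = ""),
       pairs = paste(sym, collapse = ""),
       target = paste(tgt, collapse = ""))
}

#' Scan lincRNA sequences for miRNA target sites
#'
#' Slides every miRNA over every lincRNA, scoring each candidate duplex
#' (gapless plus single-bulge variants) with the expectation score of
#' [score_site()], and reports sites with expectation at or below
#' `max_expectation`. Overlapping hits of the same miRNA-lincRNA pair are
#' collapsed greedily: the best-scoring site is primary; worse
#' non-overlapping sites are kept as secondary. If a precomputed target-site
#' accessibility table (`upe`) is supplied, hits whose matched energy exceeds
#' `max_upe` are removed; without a table the accessibility filter is skipped
#' with a notice.
#'
#' @param mirnas Tibble from [read_mirnas()] (`mirna_id`, `sequence`).
#' @param linc_seqs Named character vector of lincRNA sequences (DNA).
#' @param max_expectation Inclusive reporting cutoff on the expectation score.
#' @param upe Optional tibble `linc_id`, `mirna_id`, `target_start`, `upe`.
#' @param max_upe Inclusive cutoff on the unpairing energy.
#' @param max_gaps Maximum bulges per duplex (0 or 1).
#' @param quiet Suppress the skipped-accessibility notice.
#' @inheritParams score_site
#' @return Tibble of hits: `linc_id`, `mirna_id`, `target_start` (0-based on
#'   the transcript), `target_end`, `expectation`, `bulge`, `primary`, `upe`,
#'   `aln_mirna`, `aln_pairs`, `aln_target`.
#' @export
scan_targets <- function(mirnas, linc_seqs, max_expectation = 3,
                         upe = NULL, max_upe = 25, max_gaps = 1L,
                         match = 0, wobble = 0.5, mismatch = 1,
                         gap_penalty = 2, seed_start = 2L, seed_end = 13L,
                         seed_factor = 2, quiet = FALSE) {
  if (!nrow(mirnas) || !length(linc_seqs)) {
    return(.empty_hits())
  }
  pc <- .pair_cost_matrix(match, wobble, mismatch)
  hits <- list()
  for (mi in seq_len(nrow(mirnas))) {
    m <- .encode_mirna(mirnas$sequence[mi])
    w <- .seed_weights(length(m), seed_start, seed_end, seed_factor)
    for (lid in names(linc_seqs)) {
      t_enc <- .encode_target(linc_seqs[[lid]])
      L <- length(t_enc)
      cand <- .scan_duplexes(m, t_enc, pc, w, max_gaps = max_gaps,
                             gap_penalty = gap_penalty)
      cand <- cand[cand$score <= max_expectation, ]
      if (!nrow(cand)) next
      cand <- cand %>%
        mutate(target_start = L - (.data$u + .data$window_len - 1L),
               target_end = L - .data$u + 1L) %>%
        arrange(.data$score,
                map_int(.data$bulge, ~ if (.x == "none") 0L else 1L),
                .data$target_start)
      # greedy collapse of overlapping sites: best kept, overlaps dropped
      kept <- integer(0)
      for (r in seq_len(nrow(cand))) {
        ov <- any(cand$target_start[r] < cand$target_end[kept] &
                    cand$target_end[r] > cand$target_start[kept])
        if (!length(kept) || !ov) kept <- c(kept, r)
      }
      sel <- cand[kept, ]
      for (r in seq_len(nrow(sel))) {
        aln <- .duplex_alignment(
          m,
          t_enc[(sel$target_start[r] + 1L):sel$target_end[r]],
          sel$bulge[r], sel$bulge_pos[r], pc
        )
        hits[[length(hits) + 1L]] <- tibble(
          linc_id = lid, mirna_id = mirnas$mirna_id[mi],
          target_start = sel$target_start[r], target_end = sel$target_end[r],
          expectation = sel$score[r], bulge = sel$bulge[r],
          primary = r == 1L, upe = NA_real_,
          aln_mirna = aln$mirna, aln_pairs = aln$pairs,
          aln_target = aln$target
        )
      }
    }
  }
  out <- bind_rows(hits)
  if (!nrow(out)) return(.empty_hits())
  if (!is.null(upe)) {
    out <- out %>%
      select(-"upe") %>%
      left_join(upe[, c("linc_id", "mirna_id", "target_start", "upe")],
                by = c("linc_id", "mirna_id", "target_start")) %>%
      filter(is.na(.data$upe) | .data$upe <= max_upe)
  } else if (!quiet) {
    message("no target-site accessibility (UPE) table supplied; ",
            "accessibility filter skipped")
  }
  out
}

.empty_hits <- function() {
  tibble(linc_id = character(), mirna_id = character(),
         target_start = integer(), target_end = integer(),
         expectation = numeric(), bulge = character(), primary = logical(),
         upe = numeric(), aln_mirna = character(), aln_pairs = character(),
         aln_target = character())
}

#' Build the lincRNA-miRNA interaction network
#'
#' Collapses target hits to distinct (lincRNA, miRNA) pairs, builds the
#' bipartite interaction graph and classifies every connected component's
#' interaction pattern: `one_to_one` (one lincRNA, one miRNA), `one_to_many`
#' (one lincRNA targeted by several miRNAs), `many_to_one` (one miRNA
#' targeting several lincRNAs) and `many_to_many`.
#'
#' @param hits Hit tibble from [scan_targets()].
#' @return Object of class `interaction_network`: list with `edges`
#'   (`linc_id`, `mirna_id`), `nodes` (`node`, `type`, `degree`, `component`,
#'   `pattern`), `components` and `summary` (`n_lincs`, `n_mirnas`,
#'   `n_pairs` plus one count per pattern).
#' @export
build_interaction_network <- function(hits) {
  edges <- hits %>% distinct(.data$linc_id, .data$mirna_id)
  if (!nrow(edges)) {
    empty <- tibble(node = character(), type = character(),
                    degree = integer(), component = integer(),
                    pattern = character())
    return(structure(list(edges = edges, nodes = empty,
                          components = tibble(component = integer(),
                                              n_lincs = integer(),
                                              n_mirnas = integer(),
                                              pattern = character()),
                          summary = tibble(n_lincs = 0L, n_mirnas = 0L,
                                           n_pairs = 0L)),
                     class = "interaction_network"))
  }
  g <- igraph::graph_from_data_frame(edges, directed = FALSE)
  type <- ifelse(igraph::V(g)$name %in% edges$linc_id, "lincRNA", "miRNA")
  comp <- igraph::components(g)
  nodes <- tibble(node = igraph::V(g)$name, type = type,
                  degree = unname(igraph::degree(g)),
                  component = unname(comp$membership))
  comps <- nodes %>%
    group_by(.data$component) %>%
    summarise(n_lincs = sum(.data$type == "lincRNA"),
              n_mirnas = sum(.data$type == "miRNA"), .groups = "drop") %>%
    mutate(pattern = dplyr::case_when(
      .data$n_lincs == 1 & .data$n_mirnas == 1 ~ "one_to_one",
      .data$n_lincs == 1 & .data$n_mirnas > 1 ~ "one_to_many",
      .data$n_lincs > 1 & .data$n_mirnas == 1 ~ "many_to_one",
      TRUE ~ "many_to_many"
    ))
  nodes <- nodes %>% left_join(comps[, c("component", "pattern")],
                               by = "component")
  pattern_counts <- comps %>% count(.data$pattern) %>%
    tidyr::pivot_wider(names_from = "pattern", values_from = "n",
                       names_prefix = "n_")
  summary <- tibble(n_lincs = dplyr::n_distinct(edges$linc_id),
                    n_mirnas = dplyr::n_distinct(edges$mirna_id),
                    n_pairs = nrow(edges)) %>%
    dplyr::bind_cols(pattern_counts)
  structure(list(edges = edges, nodes = nodes, components = comps,
                 summary = summary, graph = g),
            class = "interaction_network")
}

#' @export
print.interaction_network <- function(x, ...) {
  cat("lincRNA-miRNA interaction network\n")
  print(x$summary)
  invisible(x)
}

#' @describeIn build_interaction_network `tidy()` returns the edge list.
#' @param x An `interaction_network` object.
#' @param ... Unused.
#' @export
tidy.interaction_network <- function(x, ...) x$edges

#' @describeIn build_interaction_network `glance()` returns the summary row.
#' @export
glance.interaction_network <- function(x, ...) x$summary

#' Export the interaction network to GraphML
#' @param network An `interaction_network` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_interaction_graphml <- function(network, path) {
  g <- network$graph
  igraph::V(g)$type_class <- network$nodes$type[
    match(igraph::V(g)$name, network$nodes$node)]
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
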