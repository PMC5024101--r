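# Independent oracles used to validate the package implementations.
# These deliberately reimplement each computation in the most direct way
# possible (exhaustive scans, textbook formulas, linear solves) and share no
# code with the package internals.

# exhaustive longest-ORF scan: every ATG in every frame, walk to first stop
brute_orf_length <- function(seq, both = TRUE) {
  seq <- toupper(seq)
  stops <- c("TAA", "TAG", "TGA")
  scan1 <- function(s) {
    L <- nchar(s)
    best <- 0L
    for (i in seq_len(max(0L, L - 2L))) {
      if (substr(s, i, i + 2L) != "ATG") next
      j <- i
      while (j + 5L <= L) {
        j <- j + 3L
        if (substr(s, j, j + 2L) %in% stops) {
          best <- max(best, j + 2L - i + 1L)
          break
        }
      }
    }
    best
  }
  rc <- function(s) {
    paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "", fixed = TRUE)[[1]]),
          collapse = "")
  }
  if (both) max(scan1(seq), scan1(rc(seq))) else scan1(seq)
}

# textbook Spearman: average ranks, then the Pearson product-moment formula
spearman_manual <- function(x, y) {
  rx <- rank(x)
  ry <- rank(y)
  dx <- rx - mean(rx)
  dy <- ry - mean(ry)
  sum(dx * dy) / sqrt(sum(dx^2) * sum(dy^2))
}

# direct linear solve of the propagation fixed point
# F = (1 - alpha) (I - alpha W')^{-1} Y  with W' = D^{-1/2} W D^{-1/2}
propagation_solve <- function(W, Y, alpha) {
  d <- rowSums(W)
  s <- ifelse(d > 0, 1 / sqrt(d), 0)
  Wn <- W * outer(s, s)
  solve(diag(nrow(W)) - alpha * Wn, (1 - alpha) * Y)
}

# position-wise penalty sum for a gapless miRNA duplex (miRNA 5'->3' against
# the reversed target window), rebuilt from the scoring rules
brute_duplex_score <- function(mirna, window) {
  m <- strsplit(chartr("T", "U", toupper(mirna)), "", fixed = TRUE)[[1]]
  t <- rev(strsplit(toupper(window), "", fixed = TRUE)[[1]])
  stopifnot(length(m) == length(t))
  wc <- c(A = "T", C = "G", G = "C", U = "A")
  total <- 0
  for (i in seq_along(m)) {
    cost <- if (wc[[m[i]]] == t[i]) 0
    else if ((m[i] == "G" && t[i] == "T") || (m[i] == "U" && t[i] == "G")) 0.5
    else 1
    if (i >= 2 && i <= 13) cost <- cost * 2
    total <- total + cost
  }
  total
}

# one-row transcript tibble for inline fixtures
make_tx <- function(id, chrom = "chr1", exons = list(c(0L, 300L)),
                    strand = "*", class_code = "u", gene_id = id) {
  ex <- tibble::tibble(start = vapply(exons, `[`, integer(1), 1L),
                       end = vapply(exons, `[`, integer(1), 2L))
  tibble::tibble(
    transcript_id = id, gene_id = gene_id, chrom = chrom, strand = strand,
    class_code = class_code, start = min(ex$start), end = max(ex$end),
    n_exons = nrow(ex), spliced_length = sum(ex$end - ex$start),
    exons = list(ex)
  )
}
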