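.STOP_CODONS <- c("TAA", "TAG", "TGA")

# split one frame of a sequence into codons (character vector)
.frame_codons <- function(seq, frame) {
  L <- nchar(seq)
  n <- (L - frame + 1L) %/% 3L
  if (n <= 0L) return(character(0))
  starts <- frame + 3L * (seq_len(n) - 1L)
  substring(seq, starts, starts + 2L)
}

# longest ATG..stop ORF in one frame; returns codon indices or NULL
.frame_longest <- function(cods) {
  is_atg <- cods == "ATG"           # codons containing N never match
  is_stop <- cods %in% .STOP_CODONS
  stops <- which(is_stop)
  atgs <- which(is_atg)
  if (!length(stops) || !length(atgs)) return(NULL)
  best <- NULL
  seg_start <- 1L
  for (s in stops) {
    a <- atgs[atgs >= seg_start & atgs < s]
    if (length(a)) {
      len <- (s - a[1] + 1L) * 3L
      if (is.null(best) || len > best$len) {
        best <- list(len = len, atg = a[1], stop = s)
      }
    }
    seg_start <- s + 1L
  }
  best
}

.revcomp <- function(seq) {
  chartr("ACGTN", "TGCAN", paste(rev(strsplit(seq, "", fixed = TRUE)[[1]]),
                                 collapse = ""))
}

#' Find the longest open reading frame of a transcript
#'
#' Scans for the longest ATG-to-stop ORF; the stop codon is counted in the
#' length. With `strand_mode = "sense_only"` the three forward frames of the
#' supplied (sense-oriented) sequence are scanned; with `"both"` all six frames
#' are scanned, which is the appropriate mode for unstranded intergenic
#' assemblies. Codons containing `N` never match ATG or a stop. Ties are broken
#' by the 5'-most start on the forward strand, then forward over reverse.
#' Stretches starting with ATG but lacking an in-frame stop before the
#' transcript end are not counted as ORFs unless `include_open_ended = TRUE`.
#'
#' @param sequence Nucleotide string over `A`,`C`,`G`,`T`,`N`.
#' @param strand_mode `"sense_only"` or `"both"`.
#' @param include_open_ended Count stop-less ATG-to-end stretches as ORFs.
#' @return One-row tibble: `orf_length` (nt, 0 if none), `frame` (+1..+3 /
#'   -1..-3, `NA` if none), `orf_start`, `orf_end` (0-based half-open interval
#'   in transcript coordinates, `NA` if none).
#' @examples
#' find_longest_orf("ATGAAATAG")   # 9 nt, frame +1
#' find_longest_orf("CCCCCC")      # no ORF
#' @export
find_longest_orf <- function(sequence,
                             strand_mode = c("both", "sense_only"),
                             include_open_ended = FALSE) {
  strand_mode <- match.arg(strand_mode)
  .assert(is.character(sequence) && length(sequence) == 1 && nzchar(sequence),
          "sequence must be a non-empty string")
  sequence <- toupper(sequence)
  .assert(!grepl("[^ACGTN]", sequence), "sequence has non-ACGTN characters")
  L <- nchar(sequence)

  candidates <- list()
  scan_strand <- function(seq, sign) {
    for (f in 1:3) {
      cods <- .frame_codons(seq, f)
      if (include_open_ended) {
        cods2 <- c(cods, "TAA")  # sentinel stop at transcript end
        hit <- .frame_longest(cods2)
        if (!is.null(hit) && hit$stop > length(cods)) {
          hit$len <- hit$len - 3L  # sentinel not part of the sequence
          hit$stop <- length(cods)
          if (hit$len == 0L) hit <- NULL
          else hit$open <- TRUE
        }
      } else {
        hit <- .frame_longest(cods)
      }
      if (!is.null(hit)) {
        # codon index -> 0-based interval on this strand's sequence
        s0 <- (f - 1L) + (hit$atg - 1L) * 3L
        e0 <- (f - 1L) + hit$stop * 3L
        e0 <- min(e0, nchar(seq))
        if (sign > 0) {
          iv <- c(s0, e0)
        } else {
          iv <- c(L - e0, L - s0)   # map reverse-strand interval back
        }
        candidates[[length(candidates) + 1L]] <<- list(
          len = hit$len, frame = sign * f, start = iv[1], end = iv[2]
        )
      }
    }
  }
  scan_strand(sequence, +1L)
  if (strand_mode == "both") scan_strand(.revcomp(sequence), -1L)

  if (!length(candidates)) {
    return(tibble(orf_length = 0L, frame = NA_integer_,
                  orf_start = NA_integer_, orf_end = NA_integer_))
  }
  lens <- map_int(candidates, ~ as.integer(.x$len))
  top <- which(lens == max(lens))
  if (length(top) > 1) {
    # prefer forward strand, then 5'-most start
    sgn <- map_int(candidates[top], ~ as.integer(sign(.x$frame)))
    top <- top[order(-sgn, map_int(candidates[top], ~ as.integer(.x$start)))]
  }
  b <- candidates[[top[1]]]
  tibble(orf_length = as.integer(b$len), frame = as.integer(b$frame),
         orf_start = as.integer(b$start), orf_end = as.integer(b$end))
}

#' Longest ORFs for a set of transcripts
#'
#' Vectorised wrapper over [find_longest_orf()]: transcripts with a known
#' strand are scanned sense-only (their sequences are sense-oriented), those
#' with unknown strand over all six frames.
#'
#' @param sequences Named character vector of spliced transcript sequences.
#' @param strands Optional named character vector of strands (`"+"`, `"-"`,
#'   `"*"`); unknown/missing entries are scanned in both orientations.
#' @param include_open_ended Passed to [find_longest_orf()].
#' @return Tibble: `transcript_id`, `orf_length`, `frame`, `orf_start`,
#'   `orf_end`.
#' @export
longest_orfs <- function(sequences, strands = NULL, include_open_ended = FALSE) {
  ids <- names(sequences)
  .assert(!is.null(ids), "sequences must be named by transcript_id")
  res <- map(ids, function(id) {
    st <- if (is.null(strands)) "*" else (strands[[id]] %||% "*")
    mode <- if (st %in% c("+", "-")) "sense_only" else "both"
    find_longest_orf(sequences[[id]], strand_mode = mode,
                     include_open_ended = include_open_ended)
  })
  bind_rows(res) %>% mutate(transcript_id = ids, .before = 1)
}
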