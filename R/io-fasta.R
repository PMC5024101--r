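#' Read transcript sequences from FASTA
#'
#' Loads a nucleotide FASTA into a named character vector keyed by the header
#' token before the first whitespace. Sequences are uppercased and `U` is
#' stored as `T`, so downstream code works in a single DNA alphabet
#' (`A`,`C`,`G`,`T`,`N`).
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  .assert(file.exists(path), "FASTA file not found: %s", path)
  ss <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(ids)) {
    stop("duplicate FASTA id: ", ids[duplicated(ids)][1], call. = FALSE)
  }
  seqs <- chartr("uU", "tT", as.character(ss))
  seqs <- toupper(seqs)
  if (any(!nzchar(seqs))) {
    stop("empty sequence for FASTA id: ", ids[!nzchar(seqs)][1], call. = FALSE)
  }
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) {
    stop("non-nucleotide characters in FASTA record: ", ids[bad][1],
         call. = FALSE)
  }
  setNames(seqs, ids)
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param width Line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  .assert(!is.null(names(seqs)) && all(nzchar(names(seqs))),
          "sequences must be named")
  ss <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(ss, path, width = width)
  invisible(path)
}

#' Read mature miRNA sequences
#'
#' Reads a mature-miRNA FASTA; sequences are stored in the RNA alphabet
#' (`T` converted to `U`) and must be 18-26 nt, the length range of plant
#' mature miRNAs.
#'
#' @param path Path to a miRNA FASTA file.
#' @param min_len,max_len Accepted mature-sequence length bounds.
#' @return Tibble: `mirna_id`, `sequence` (RNA alphabet), `length`.
#' @export
read_mirnas <- function(path, min_len = 18L, max_len = 26L) {
  seqs <- read_fasta(path)              # normalises to DNA alphabet
  rna <- chartr("T", "U", seqs)
  len <- nchar(rna)
  bad <- len < min_len | len > max_len
  if (any(bad)) {
    stop("miRNA length out of range (", min_len, "-", max_len, " nt): ",
         names(rna)[bad][1], call. = FALSE)
  }
  tibble(mirna_id = names(rna), sequence = unname(rna), length = unname(len))
}
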