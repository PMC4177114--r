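## Sequence file I/O. All heavy lifting is delegated to Biostrings; this
## file only adapts to and from the package's plain-data containers.

#' Construct a set of read pairs
#'
#' The package's paired-end container: a data.frame with one row per
#' fragment and columns `id`, `seq1`, `qual1`, `seq2`, `qual2` (sequences
#' over {A,C,G,T,N}; qualities as Phred+33 strings of matching length).
#'
#' @param id fragment identifiers (without the `/1`, `/2` mate suffix).
#' @param seq1,seq2 mate sequences.
#' @param qual1,qual2 Phred+33 quality strings; default constant Q40.
#' @return a `read_pairs` data.frame.
#' @export
read_pairs <- function(id, seq1, seq2, qual1 = NULL, qual2 = NULL) {
  q40 <- function(s) vapply(nchar(s), function(n) strrep("I", n), "")
  if (is.null(qual1)) qual1 <- q40(seq1)
  if (is.null(qual2)) qual2 <- q40(seq2)
  stopifnot(length(id) == length(seq1), length(seq1) == length(seq2),
            all(nchar(seq1) == nchar(qual1)), all(nchar(seq2) == nchar(qual2)))
  structure(
    data.frame(id = as.character(id), seq1 = seq1, qual1 = qual1,
               seq2 = seq2, qual2 = qual2, stringsAsFactors = FALSE),
    class = c("read_pairs", "data.frame")
  )
}

empty_read_pairs <- function() {
  read_pairs(character(0), character(0), character(0))
}

#' Read paired FASTQ files
#'
#' @param fq1,fq2 FASTQ file paths (Phred+33; gzip-transparent). Mates must
#'   be in matching order; `/1`, `/2` suffixes are stripped from ids.
#' @return a [read_pairs()] data.frame.
#' @export
read_fastq_pairs <- function(fq1, fq2) {
  r1 <- Biostrings::readDNAStringSet(fq1, format = "fastq", with.qualities = TRUE)
  r2 <- Biostrings::readDNAStringSet(fq2, format = "fastq", with.qualities = TRUE)
  if (length(r1) != length(r2)) stop("parse error: mate files differ in record count")
  ids <- sub("/[12]$", "", sub("\\s.*$", "", names(r1)))
  ids2 <- sub("/[12]$", "", sub("\\s.*$", "", names(r2)))
  if (!identical(ids, ids2)) stop("parse error: mate ids are not in matching order")
  read_pairs(ids,
             as.character(r1), as.character(r2),
             as.character(S4Vectors::mcols(r1)$qualities),
             as.character(S4Vectors::mcols(r2)$qualities))
}

#' Write paired FASTQ files
#'
#' @param pairs a [read_pairs()] data.frame.
#' @param fq1,fq2 output paths; mates are named `<id>/1` and `<id>/2`.
#' @export
write_fastq_pairs <- function(pairs, fq1, fq2) {
  wr <- function(seqs, quals, ids, path) {
    x <- Biostrings::DNAStringSet(seqs)
    names(x) <- ids
    Biostrings::writeXStringSet(x, path, format = "fastq",
                                qualities = Biostrings::BStringSet(quals))
  }
  wr(pairs$seq1, pairs$qual1, paste0(pairs$id, "/1"), fq1)
  wr(pairs$seq2, pairs$qual2, paste0(pairs$id, "/2"), fq2)
  invisible(c(fq1, fq2))
}

#' Read FASTA into a named character vector
#' @param path FASTA file path.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

#' Write a named character vector as FASTA
#' @param seqs named character vector.
#' @param path output path.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

## BED (0-based half-open) writers for interval tables.
write_bed <- function(intervals, chrom, path) {
  df <- data.frame(chrom = chrom, start = intervals$start0, end = intervals$end0)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
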