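## Small sequence and numeric helpers shared across modules.

#' Reverse complement of DNA strings
#'
#' Vectorised reverse complement over plain character vectors. IUPAC
#' ambiguity codes (including N) are complemented by Biostrings rules.
#'
#' @param x character vector of DNA sequences over {A,C,G,T,N}.
#' @return character vector of the same length.
#' @export
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

## Round half away from zero (the convention that reproduces the printed
## integer copy folds; base round() is round-half-even).
round_half_away <- function(x, digits = 0L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

## Canonical form of kmers: lexicographic min of the kmer and its reverse
## complement. `rc` may be supplied when already computed.
canonical_kmer <- function(x, rc = NULL) {
  if (is.null(rc)) rc <- revcomp(x)
  ifelse(x <= rc, x, rc)
}

## All kmers of every sequence, as one character vector (N-containing
## kmers are retained; callers drop them where the semantics demand it).
extract_kmers <- function(seqs, k) {
  n <- nchar(seqs)
  keep <- which(n >= k)
  if (length(keep) == 0L) return(character(0))
  reps <- n[keep] - k + 1L
  starts <- sequence(reps)
  owner <- rep(seqs[keep], reps)
  substring(owner, starts, starts + k - 1L)
}

## Positions (0-based) and kmers for one sequence.
kmer_positions <- function(seq, k) {
  L <- nchar(seq)
  if (L < k) return(data.table::data.table(pos0 = integer(0), kmer = character(0)))
  starts <- seq_len(L - k + 1L)
  data.table::data.table(pos0 = starts - 1L, kmer = substring(seq, starts, starts + k - 1L))
}

#' Test equality of two sequences up to rotation and strand
#'
#' Circular molecules have no distinguished origin or strand; two assembled
#' sequences are the same genome when one is a rotation of the other or of
#' its reverse complement.
#'
#' @param a,b DNA sequences as single character strings.
#' @return `TRUE` or `FALSE`.
#' @export
same_up_to_rotation <- function(a, b) {
  if (nchar(a) != nchar(b)) return(FALSE)
  if (nchar(a) == 0L) return(TRUE)
  bb <- paste0(b, b)
  grepl(a, bb, fixed = TRUE) || grepl(revcomp(a), bb, fixed = TRUE)
}

#' Rotate a circular sequence into a reference frame
#'
#' Finds an exact `k`-mer of the reference that occurs exactly once in the
#' (doubled) sequence and rotates/flips the sequence so that position 0
#' corresponds to the reference origin. Returns the input unchanged when
#' no anchoring kmer is found.
#'
#' @param seq circular sequence to normalise (single string).
#' @param ref reference sequence defining the frame.
#' @param k anchor length (default 31).
#' @return rotated (and possibly reverse-complemented) sequence.
#' @export
normalize_rotation <- function(seq, ref, k = 31L) {
  L <- nchar(seq)
  if (L < k || nchar(ref) < k) return(seq)
  dbl <- paste0(seq, seq)
  for (off in seq(0L, min(nchar(ref) - k, 5000L), by = 97L)) {
    probe <- substring(ref, off + 1L, off + k)
    for (flip in c(FALSE, TRUE)) {
      target <- if (flip) revcomp(dbl) else dbl
      hits <- gregexpr(probe, target, fixed = TRUE)[[1L]]
      if (hits[1L] == -1L) next
      hits <- hits[hits <= L]              # one representative per rotation
      if (length(hits) != 1L) next
      rot <- (hits - 1L - off) %% L
      s2 <- if (flip) revcomp(seq) else seq
      return(paste0(substring(s2, rot + 1L, L), substring(s2, 1L, rot)))
    }
  }
  seq
}

## Hamming distance between equal-length strings (NA if unequal length).
hamming <- function(a, b) {
  if (nchar(a) != nchar(b)) return(NA_integer_)
  sum(charToRaw(a) != charToRaw(b))
}

## Decode Phred+33 quality strings to integer lists.
phred_decode <- function(qual) {
  lapply(qual, function(q) utf8ToInt(q) - 33L)
}

## Random DNA of length n from the current RNG stream.
random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

## Run code under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

## Maximal runs of N in a sequence; 0-based half-open intervals.
n_runs <- function(seq) {
  r <- rle(strsplit(seq, "", fixed = TRUE)[[1]] == "N")
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- r$values
  data.frame(start0 = starts[keep], end0 = ends[keep])
}
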