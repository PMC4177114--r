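## Exact and near-exact full-length read placement by seed-and-verify.
## With at most m mismatches permitted over a read of length L, splitting
## the read into m+1 non-overlapping blocks guarantees (pigeonhole) that
## at least one block is an exact match, so seeding each block start with
## a kmer lookup and verifying candidates by full-length Hamming
## comparison misses no placement. No indels, no clipping: the filters
## this module serves ("at least one end mapped exactly") are exact-match
## semantics. N never matches any base, including N.

#' Build a seed index over reference sequences
#'
#' Indexes every position of every reference by its canonical `seed_k`-mer
#' (so both strands are retrievable through one lookup). Kmers containing
#' N (e.g. gap runs in a draft) are not indexed.
#'
#' @param refs named character vector of reference sequences, or a single
#'   unnamed sequence (named `"ref"`).
#' @param seed_k seed kmer size; odd (default 21) and at most the shortest
#'   read to be mapped.
#' @return an object of class `seed_index`.
#' @export
build_index <- function(refs, seed_k = 21L) {
  seed_k <- as.integer(seed_k)
  if (seed_k %% 2L == 0L) stop("seed_k must be odd")
  if (is.null(names(refs))) names(refs) <- if (length(refs) == 1L) "ref" else
    sprintf("ref%d", seq_along(refs))
  tabs <- lapply(names(refs), function(nm) {
    kp <- kmer_positions(refs[[nm]], seed_k)
    kp <- kp[!grepl("N", kp$kmer, fixed = TRUE)]
    if (nrow(kp) == 0L) return(NULL)
    canon <- canonical_kmer(kp$kmer)
    data.table::data.table(kmer = canon, ref = nm, pos0 = kp$pos0,
                           fwd_is_canon = kp$kmer == canon)
  })
  seeds <- data.table::rbindlist(tabs)
  if (nrow(seeds) > 0L) data.table::setkey(seeds, kmer)
  structure(list(refs = refs, ref_len = nchar(refs), seed_k = seed_k,
                 seeds = seeds),
            class = "seed_index")
}

#' @export
print.seed_index <- function(x, ...) {
  cat(sprintf("<seed_index> %d reference(s), %d seed positions, seed_k=%d\n",
              length(x$refs), nrow(x$seeds), x$seed_k))
  invisible(x)
}

#' Query a seed kmer against the index
#'
#' @param index a [build_index()] object.
#' @param kmer a `seed_k`-length kmer (either strand).
#' @return data.frame of `ref`, `pos0` (0-based forward-strand position),
#'   `fwd` (TRUE when the indexed strand matches the query orientation).
#' @export
query_seeds <- function(index, kmer) {
  stopifnot(inherits(index, "seed_index"), nchar(kmer) == index$seed_k)
  canon <- canonical_kmer(kmer)
  hits <- index$seeds[list(canon), nomatch = NULL]
  data.frame(ref = hits$ref, pos0 = hits$pos0,
             fwd = hits$fwd_is_canon == (kmer == canon))
}

## Hamming distance where N matches nothing (not even N).
.mismatch_count <- function(a, b) {
  ra <- charToRaw(a); rb <- charToRaw(b)
  sum(ra != rb | ra == as.raw(78L) | rb == as.raw(78L))
}

#' Map reads by seed-and-verify
#'
#' Returns every placement of every read with at most `max_mismatch`
#' mismatches over the full read length, on either strand of any indexed
#' reference.
#'
#' @param reads character vector of read sequences (ids from names, else
#'   positional).
#' @param index a [build_index()] object.
#' @param max_mismatch maximum Hamming mismatches (default 0, the
#'   exact-match semantics of the pipeline's filters).
#' @return data.frame: `read_id`, `ref`, `start0` (0-based), `strand`
#'   (`"+"`/`"-"`), `mismatches`. Zero rows when nothing places.
#' @export
map_reads <- function(reads, index, max_mismatch = 0L) {
  stopifnot(inherits(index, "seed_index"))
  mm <- as.integer(max_mismatch)
  ids <- if (!is.null(names(reads))) names(reads) else as.character(seq_along(reads))
  empty <- data.frame(read_id = character(0), ref = character(0),
                      start0 = integer(0), strand = character(0),
                      mismatches = integer(0), stringsAsFactors = FALSE)
  if (length(reads) == 0L || nrow(index$seeds) == 0L) return(empty)
  sk <- index$seed_k
  Lr <- nchar(reads)
  if (any(Lr %/% (mm + 1L) < sk)) {
    stop("parameter error: seed_k exceeds read_length/(max_mismatch+1); ",
         "the pigeonhole guarantee would be lost")
  }

  cand <- vector("list", mm + 1L)
  for (b in 0:mm) {
    off <- b * (Lr %/% (mm + 1L))                 # 0-based block start per read
    seed <- substring(reads, off + 1L, off + sk)
    canon <- canonical_kmer(seed)
    q <- data.table::data.table(read_idx = seq_along(reads), off = off,
                                Lr = Lr, kmer = canon,
                                q_is_canon = seed == canon)
    hits <- index$seeds[q, on = "kmer", nomatch = NULL, allow.cartesian = TRUE]
    if (nrow(hits) == 0L) next
    same <- hits$fwd_is_canon == hits$q_is_canon
    start0 <- ifelse(same, hits$pos0 - hits$off,
                     hits$pos0 - (hits$Lr - hits$off - sk))
    cand[[b + 1L]] <- data.table::data.table(
      read_idx = hits$read_idx, ref = hits$ref, start0 = as.integer(start0),
      strand = ifelse(same, "+", "-"), Lr = hits$Lr)
  }
  cand <- data.table::rbindlist(cand)
  if (nrow(cand) == 0L) return(empty)
  cand <- unique(cand)
  ok <- cand$start0 >= 0L & cand$start0 + cand$Lr <= index$ref_len[cand$ref]
  cand <- cand[ok]
  if (nrow(cand) == 0L) return(empty)

  refsub <- substring(index$refs[cand$ref], cand$start0 + 1L, cand$start0 + cand$Lr)
  qseq <- reads[cand$read_idx]
  flip <- cand$strand == "-"
  qseq[flip] <- revcomp(qseq[flip])

  if (mm == 0L) {
    keep <- qseq == refsub & !grepl("N", qseq, fixed = TRUE)
    mmv <- rep(0L, sum(keep))
    cand <- cand[keep]
  } else {
    mmv <- mapply(.mismatch_count, qseq, refsub, USE.NAMES = FALSE)
    keep <- mmv <= mm
    mmv <- mmv[keep]
    cand <- cand[keep]
  }
  out <- data.frame(read_id = ids[cand$read_idx], ref = cand$ref,
                    start0 = cand$start0, strand = cand$strand,
                    mismatches = as.integer(mmv), stringsAsFactors = FALSE)
  out[order(out$read_id, out$ref, out$start0, out$strand), , drop = FALSE]
}

#' Map a single read
#'
#' @inheritParams map_reads
#' @param read one read sequence.
#' @return data.frame of placements (see [map_reads()]).
#' @export
map_read <- function(read, index, max_mismatch = 0L) {
  map_reads(setNames(read, "read"), index, max_mismatch)
}

#' Partition read pairs by exact-match membership
#'
#' A pair belongs to `mapped` when at least one mate has a placement with
#' at most `max_mismatch` mismatches — the "at least one end mapped
#' exactly, so the pair is organellar and is removed" rule. The partition
#' is exhaustive and exclusive.
#'
#' @param pairs a [read_pairs()] data.frame.
#' @param index a [build_index()] over (typically) the assembled plastid.
#' @param max_mismatch maximum mismatches (default 0).
#' @return list with `mapped` and `unmapped` `read_pairs` data.frames.
#' @export
partition_pairs <- function(pairs, index, max_mismatch = 0L) {
  if (nrow(pairs) == 0L) return(list(mapped = pairs, unmapped = pairs))
  m1 <- map_reads(setNames(pairs$seq1, pairs$id), index, max_mismatch)
  m2 <- map_reads(setNames(pairs$seq2, pairs$id), index, max_mismatch)
  hit <- pairs$id %in% c(m1$read_id, m2$read_id)
  subset_rp <- function(x) {
    rownames(x) <- NULL
    class(x) <- c("read_pairs", "data.frame")
    x
  }
  list(mapped = subset_rp(pairs[hit, , drop = FALSE]),
       unmapped = subset_rp(pairs[!hit, , drop = FALSE]))
}

#' Mask regions shared between two references
#'
#' Finds maximal intervals of each reference covered by exact substrings
#' of length at least `min_run` shared with the other (computed from
#' shared canonical `min_run`-mers merged into runs). The complement of
#' the mask is the "unique regions" used for unbiased depth estimates.
#'
#' @param refA,refB reference sequences (single strings).
#' @param min_run minimum shared run length in bases (default 100).
#' @return list with `A` and `B`: data.frames of 0-based half-open
#'   intervals (`start0`, `end0`).
#' @export
shared_region_mask <- function(refA, refB, min_run = 100L) {
  k <- as.integer(min_run)
  ka <- kmer_positions(refA, k); kb <- kmer_positions(refB, k)
  ca <- canonical_kmer(ka$kmer); cb <- canonical_kmer(kb$kmer)
  shared <- intersect(ca, cb)
  iv <- function(pos0) {
    if (length(pos0) == 0L) return(data.frame(start0 = integer(0), end0 = integer(0)))
    r <- IRanges::reduce(IRanges::IRanges(start = pos0 + 1L, width = k))
    data.frame(start0 = IRanges::start(r) - 1L, end0 = IRanges::end(r))
  }
  list(A = iv(ka$pos0[ca %in% shared]), B = iv(kb$pos0[cb %in% shared]))
}

#' Mask regions repeated within one reference
#'
#' Intervals covered by `min_run`-mers that occur more than once in the
#' reference (canonically, so an inverted repeat masks both copies).
#' Depth estimates restricted to the complement count each read once,
#' since no read places ambiguously there.
#'
#' @param ref reference sequence (single string).
#' @param min_run kmer/run length (default 100).
#' @return data.frame of 0-based half-open intervals.
#' @export
repeat_region_mask <- function(ref, min_run = 100L) {
  k <- as.integer(min_run)
  kp <- kmer_positions(ref, k)
  canon <- canonical_kmer(kp$kmer)
  dup <- canon %in% canon[duplicated(canon)]
  if (!any(dup)) return(data.frame(start0 = integer(0), end0 = integer(0)))
  r <- IRanges::reduce(IRanges::IRanges(kp$pos0[dup] + 1L, width = k))
  data.frame(start0 = IRanges::start(r) - 1L, end0 = IRanges::end(r))
}

#' Complement of a mask: unique regions
#'
#' @param mask data.frame of 0-based half-open intervals (`start0`, `end0`).
#' @param ref_len total reference length.
#' @return data.frame of the complementary intervals.
#' @export
unique_regions <- function(mask, ref_len) {
  if (nrow(mask) == 0L) return(data.frame(start0 = 0L, end0 = as.integer(ref_len)))
  r <- IRanges::reduce(IRanges::IRanges(mask$start0 + 1L, mask$end0))
  g <- IRanges::gaps(r, start = 1L, end = ref_len)
  data.frame(start0 = IRanges::start(g) - 1L, end0 = IRanges::end(g))
}

#' Depth from mapped bases and region length
#'
#' Sequencing depth in layers, rounded to the nearest integer (the
#' convention of printed depth tables).
#'
#' @param mapped_bases total aligned bases.
#' @param region_length region length in bases (positive).
#' @return integer depth.
#' @examples
#' sequencing_depth(278656000, 142995)  # 1949
#' @export
sequencing_depth <- function(mapped_bases, region_length) {
  if (any(region_length <= 0)) stop("parameter error: zero-length region")
  as.integer(round_half_away(mapped_bases / region_length))
}

#' Per-region depth statistics from placements
#'
#' A placement is attributed to a region when its start position lies in
#' the region; full-length placements contribute `read_length` bases each,
#' so `mapped_bases = mapped_reads * read_length`. Reads with multiple
#' placements (e.g. in an inverted repeat) count once per placement, so
#' repeat depth doubling is visible by design.
#'
#' @param placements data.frame from [map_reads()].
#' @param regions data.frame with columns `region`, `ref`, `start0`, `end0`.
#' @param read_length read length in bases.
#' @return data.frame: `region`, `region_length`, `mapped_reads`,
#'   `mapped_bases`, `depth` (integer layers).
#' @export
depth_stats <- function(placements, regions, read_length) {
  if (any(regions$end0 <= regions$start0)) stop("parameter error: zero-length region")
  rows <- lapply(seq_len(nrow(regions)), function(i) {
    r <- regions[i, ]
    nhit <- sum(placements$ref == r$ref &
                  placements$start0 >= r$start0 & placements$start0 < r$end0)
    len <- r$end0 - r$start0
    data.frame(region = r$region, region_length = len,
               mapped_reads = nhit,
               mapped_bases = nhit * read_length,
               depth = sequencing_depth(nhit * read_length, len),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Export placements as SAM
#'
#' Minimal single-end SAM: QNAME/FLAG/RNAME/POS/CIGAR (full-length match)
#' and the NM tag.
#'
#' @param placements data.frame from [map_reads()].
#' @param reads named character vector of the placed reads (for lengths
#'   and sequence columns).
#' @param index the [build_index()] used, for header lengths.
#' @param path output SAM path.
#' @export
write_sam <- function(placements, reads, index, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:unsorted", con)
  for (nm in names(index$refs)) {
    writeLines(sprintf("@SQ\tSN:%s\tLN:%d", nm, nchar(index$refs[[nm]])), con)
  }
  if (nrow(placements) > 0L) {
    seqs <- reads[placements$read_id]
    flags <- ifelse(placements$strand == "-", 16L, 0L)
    out <- ifelse(placements$strand == "-", revcomp(seqs), seqs)
    writeLines(sprintf("%s\t%d\t%s\t%d\t255\t%dM\t*\t0\t0\t%s\t*\tNM:i:%d",
                       placements$read_id, flags, placements$ref,
                       placements$start0 + 1L, nchar(seqs), out,
                       placements$mismatches), con)
  }
  invisible(path)
}
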