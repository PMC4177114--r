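## Shared fixtures and independent oracles. Everything is generated in
## code at test time; no stored data.

## The three-amplicon qPCR table used throughout the vcqa tests.
qpcr_table3 <- function() {
  list(
    actin = qpcr_measurement("actin", "nuclear", 1.124, 17.79, 23.70),
    ccmB = qpcr_measurement("ccmB", "mitochondrial", 1.060, 17.64, 17.87),
    rpoB = qpcr_measurement("rpoB", "plastid", 1.042, 17.76, 13.40)
  )
}

## Plain paired-end simulator over one genome, independent of simgen
## (used as fixture for assembler/mapping/gap-closure tests).
sim_pairs_one <- function(genome, n, read_len = 100L, insert_mean = 500L,
                          insert_sd = 50L, circular = TRUE, seed = 1L) {
  set.seed(seed)
  L <- nchar(genome)
  ins <- as.integer(pmin(pmax(round(rnorm(n, insert_mean, insert_sd)),
                              2L * read_len), L))
  if (circular) {
    s <- sample.int(L, n, replace = TRUE) - 1L
    gg <- paste0(genome, genome)
  } else {
    s <- vapply(ins, function(i) sample.int(L - i + 1L, 1L) - 1L, 0L)
    gg <- genome
  }
  strand <- sample(c("+", "-"), n, replace = TRUE)
  frag <- substring(gg, s + 1L, s + ins)
  frag[strand == "-"] <- revcomp(frag[strand == "-"])
  read_pairs(sprintf("p%06d", seq_len(n)),
             substring(frag, 1L, read_len),
             revcomp(substring(frag, ins - read_len + 1L, ins)))
}

## Brute-force all-positions Hamming scan: the independent mapping oracle.
brute_map <- function(read, ref, max_mismatch = 0L) {
  L <- nchar(read)
  rows <- list()
  for (strand in c("+", "-")) {
    q <- if (strand == "+") read else revcomp(read)
    qr <- charToRaw(q)
    for (s in 0:(nchar(ref) - L)) {
      rr <- charToRaw(substring(ref, s + 1L, s + L))
      d <- sum(qr != rr | qr == as.raw(78L) | rr == as.raw(78L))
      if (d <= max_mismatch) {
        rows[[length(rows) + 1L]] <-
          data.frame(start0 = s, strand = strand, mismatches = d)
      }
    }
  }
  if (length(rows)) do.call(rbind, rows) else
    data.frame(start0 = integer(0), strand = character(0), mismatches = integer(0))
}

## Brute-force canonical kmer counter (independent of count_kmers).
brute_count_kmers <- function(seqs, k) {
  out <- new.env()
  for (s in seqs) {
    if (nchar(s) < k) next
    for (i in seq_len(nchar(s) - k + 1L)) {
      km <- substring(s, i, i + k - 1L)
      if (grepl("N", km, fixed = TRUE)) next
      rc <- revcomp(km)
      canon <- if (km <= rc) km else rc
      out[[canon]] <- (if (is.null(out[[canon]])) 0L else out[[canon]]) + 1L
    }
  }
  ks <- sort(ls(out))
  data.frame(kmer = ks, count = vapply(ks, function(x) out[[x]], 0L),
             row.names = NULL)
}

## Random DNA under a local seed without touching the session RNG stream.
rdna <- function(n, seed) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
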