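test_that("kmer counting is canonical, skips N and matches brute force", {
  expect_identical(count_kmers("ACGT", 4),
                   data.frame(kmer = "ACGT", count = 1L))
  expect_identical(count_kmers("AAAAA", 3),
                   data.frame(kmer = "AAA", count = 3L))
  expect_identical(nrow(count_kmers("AANAA", 3)), 0L)
  expect_error(count_kmers("ACGT", 10), "read length")
  set.seed(41)
  for (i in 1:5) {
    seqs <- vapply(rep(60, 8), function(n)
      paste(sample(c("A", "C", "G", "T", "N"), n, replace = TRUE,
                   prob = c(.24, .24, .24, .24, .04)), collapse = ""), "")
    k <- sample(c(5L, 7L, 11L), 1)
    got <- count_kmers(seqs, k)
    want <- brute_count_kmers(seqs, k)
    expect_equal(got, want)
  }
})

test_that("modal kmer count tracks the depth implied by the simulated layout", {
  genome <- rdna(10000, seed = 43)
  pairs <- sim_pairs_one(genome, n = 2500, circular = TRUE, seed = 44)
  k <- 41L
  ## oracle: a read of length L at depth D yields kmer depth D*(L-k+1)/L
  read_depth <- 2500 * 200 / 10000                 # 50 layers
  kmer_depth <- read_depth * (100 - k + 1) / 100   # 30 layers
  kc <- count_kmers(pairs, k)
  mode_cnt <- as.integer(names(sort(table(kc$count), decreasing = TRUE))[1])
  expect_gte(mode_cnt, floor(0.8 * kmer_depth))
  expect_lte(mode_cnt, ceiling(1.2 * kmer_depth))
})

test_that("a repeat-free circular genome assembles into itself", {
  genome <- rdna(5000, seed = 47)
  pairs <- sim_pairs_one(genome, n = 2500, circular = TRUE, seed = 48)  # 100x
  cs <- assemble_contigs(pairs, assembly_params(41, 20, 20, 1000))
  expect_identical(nrow(cs), 1L)
  expect_true(cs$circular[1])
  expect_true(same_up_to_rotation(cs$sequence[1], genome))
})

test_that("the kmer-frequency floor separates depth strata", {
  gA <- rdna(5000, seed = 51)
  gB <- rdna(5000, seed = 52)
  pairs <- rbind(sim_pairs_one(gA, 5000, seed = 53),   # 200x
                 sim_pairs_one(gB, 250, seed = 54))    # 10x
  class(pairs) <- c("read_pairs", "data.frame")
  cs <- assemble_contigs(pairs, assembly_params(41, 50, 50, 1000))
  expect_gte(nrow(cs), 1L)
  dblA <- paste0(gA, gA)
  onA <- vapply(cs$sequence, function(s)
    grepl(s, dblA, fixed = TRUE) || grepl(revcomp(s), dblA, fixed = TRUE), TRUE)
  expect_true(all(onA))
  expect_gte(sum(cs$length), 0.99 * nchar(gA))
  dblB <- paste0(gB, gB)
  onB <- vapply(cs$sequence, function(s)
    grepl(s, dblB, fixed = TRUE) || grepl(revcomp(s), dblB, fixed = TRUE), TRUE)
  expect_false(any(onB))
})

test_that("every contig kmer survives the frequency floor (walk audit)", {
  genome <- rdna(4000, seed = 57)
  pairs <- sim_pairs_one(genome, n = 1600, seed = 58)  # 80x
  prm <- assembly_params(41, 20, 20, 1000)
  cs <- assemble_contigs(pairs, prm)
  kc <- count_kmers(pairs, prm$k)
  lookup <- setNames(kc$count, kc$kmer)
  for (s in cs$sequence) {
    km <- canonical_kmer(substring(s, seq_len(nchar(s) - prm$k + 1L),
                                   seq_len(nchar(s) - prm$k + 1L) + prm$k - 1L))
    expect_true(all(lookup[km] >= prm$min_kmer_freq))
  }
})

test_that("raising the kmer-frequency floor never adds assembled sequence", {
  genome <- rdna(4000, seed = 61)
  pairs <- sim_pairs_one(genome, n = 1600, seed = 62)
  ## non-redundant assembled bases: linear unitig ends share k-1 bases, so
  ## count each contig's kmer span (its length for circular contigs)
  nonredundant <- function(cs, k = 41L) {
    if (nrow(cs) == 0L) return(0L)
    sum(ifelse(cs$circular, cs$length, cs$length - (k - 1L)))
  }
  tot <- vapply(c(10L, 20L, 40L, 70L), function(f) {
    nonredundant(assemble_contigs(pairs, assembly_params(41, f, f, 200)))
  }, 0L)
  expect_true(all(diff(tot) <= 0))
})

test_that("the inverted repeat collapses into a double-depth contig", {
  g <- make_genomes(lsc = 8000, ssc = 2000, ir = 2500, mito = 4000,
                    nuclear = 6000, homology_tract = 0, seed = 1)
  pairs <- sim_pairs_one(g$plastid, n = 9000, seed = 63)  # ~120x
  cs <- assemble_contigs(pairs, assembly_params(41, 20, 20, 500))
  expect_gte(nrow(cs), 2L)
  ## the IR contig is the one at roughly double depth
  ratios <- cs$mean_cov / min(cs$mean_cov)
  ir_row <- which.max(cs$mean_cov)
  expect_gt(ratios[ir_row], 1.6)
  expect_lt(ratios[ir_row], 2.4)
  expect_equal(cs$length[ir_row], 2500, tolerance = 0.05)
})

test_that("no reads or no surviving kmers yield an empty contig set", {
  expect_identical(nrow(assemble_contigs(character(0))), 0L)
  lone <- read_pairs("r1", strrep("ACGT", 25), strrep("TTAA", 25))
  expect_identical(nrow(assemble_contigs(lone, assembly_params(41, 20, 20, 100))), 0L)
})

test_that("assembly parameters are validated", {
  expect_error(assembly_params(k = 40), "odd")
  expect_error(assembly_params(k = 13), "odd|15")
  expect_error(assembly_params(min_kmer_freq = 0), "")
})
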