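test_that("the seed index retrieves positions on both strands", {
  idx <- build_index(c(r = "ACGTACGT"), seed_k = 5)
  q <- query_seeds(idx, "ACGTA")
  expect_identical(sort(q$pos0), c(0L, 3L))    # forward hit and its rc twin
  ## duplicating the reference doubles every hit
  idx2 <- build_index(c(a = "ACGTACGT", b = "ACGTACGT"), seed_k = 5)
  expect_identical(nrow(query_seeds(idx2, "ACGTA")), 2L * nrow(q))
})

test_that("every substring of a genome retrieves its own position", {
  ref <- rdna(10000, seed = 71)
  idx <- build_index(c(genome = ref), seed_k = 21)
  starts <- seq(0, 9900, by = 37)
  reads <- substring(ref, starts + 1, starts + 100)
  names(reads) <- as.character(starts)
  pl <- map_reads(reads, idx, 0)
  self <- pl[pl$strand == "+", ]
  expect_true(all(as.integer(self$read_id) == self$start0))
  expect_identical(sort(unique(as.integer(pl$read_id))), as.integer(starts))
})

test_that("placements match strand, mismatch budget and N semantics", {
  ref <- rdna(8000, seed = 73)
  idx <- build_index(c(genome = ref), seed_k = 21)
  rd <- substring(ref, 101, 200)
  expect_identical(map_read(rd, idx)$start0, 100L)
  m <- map_read(revcomp(rd), idx)
  expect_identical(m$start0, 100L)
  expect_identical(m$strand, "-")
  rd2 <- rd
  substr(rd2, 60, 60) <- setdiff(c("A", "C", "G", "T"), substr(rd2, 60, 60))[1]
  expect_identical(nrow(map_read(rd2, idx, 0)), 0L)
  m1 <- map_read(rd2, idx, 1)
  expect_identical(m1$mismatches, 1L)
  expect_identical(m1$start0, 100L)
  ## N never matches, not even N
  rdN <- rd
  substr(rdN, 10, 10) <- "N"
  expect_identical(nrow(map_read(rdN, idx, 0)), 0L)
})

test_that("seed-and-verify agrees with the brute-force Hamming scan", {
  ref <- rdna(6000, seed = 79)
  idx <- build_index(c(genome = ref), seed_k = 21)
  set.seed(80)
  for (i in 1:25) {
    s <- sample(0:5900, 1)
    rd <- substring(ref, s + 1, s + 100)
    mm <- sample(0:2, 1)
    nerr <- sample(0:mm, 1)
    if (nerr > 0) for (j in sample(100, nerr)) {
      substr(rd, j, j) <- sample(c("A", "C", "G", "T"), 1)
    }
    if (sample(c(TRUE, FALSE), 1)) rd <- revcomp(rd)
    want <- brute_map(rd, ref, mm)
    got <- map_read(rd, idx, mm)
    expect_identical(nrow(got), nrow(want))
    expect_identical(sort(got$start0), sort(want$start0))
    expect_identical(got$mismatches[order(got$start0, got$strand)],
                     want$mismatches[order(want$start0, want$strand)])
  }
})

test_that("pair partitioning is exhaustive, exclusive and homology-aware", {
  g <- make_genomes(4000, 1500, 1200, 12000, 8000, 1000, seed = 3)
  idx <- build_index(c(plastid = g$plastid), seed_k = 21)
  lay <- g$truth_layout
  tr <- lay[lay$segment == "tract", ]
  ## mate1 pure plastid, mate2 from the mito homologous tract: removed
  pl_read <- substring(g$plastid, 501, 600)
  tract_read <- substring(g$mito, tr$start0 + 101, tr$start0 + 200)
  ## both mates pure mito outside the tract: kept
  mito_read1 <- substring(g$mito, 101, 200)
  mito_read2 <- revcomp(substring(g$mito, 501, 600))
  pp <- read_pairs(c("homology", "pure_mito"),
                   c(pl_read, mito_read1),
                   c(tract_read, mito_read2))
  part <- partition_pairs(pp, idx, 0)
  expect_identical(part$mapped$id, "homology")
  expect_identical(part$unmapped$id, "pure_mito")
  ## conservation on a simulated library
  p <- read_sim_params(copy_folds = c(100, 10, 1), total_pairs = 2000, seed = 81)
  sim <- sample_read_pairs(g, p)
  part2 <- partition_pairs(sim$pairs, idx, 0)
  expect_identical(nrow(part2$mapped) + nrow(part2$unmapped), nrow(sim$pairs))
  expect_identical(length(intersect(part2$mapped$id, part2$unmapped$id)), 0L)
  ## every plastid-origin pair is removed (its reads match by construction)
  pl_ids <- sim$truth$id[sim$truth$compartment == "plastid"]
  expect_true(all(pl_ids %in% part2$mapped$id))
})

test_that("shared-region masking recovers a planted tract", {
  a <- rdna(5000, seed = 83)
  b <- rdna(5000, seed = 84)
  expect_identical(nrow(shared_region_mask(a, b, 100)$A), 0L)
  m_self <- shared_region_mask(a, a, 100)
  expect_identical(m_self$A, data.frame(start0 = 0L, end0 = 5000L))
  g <- make_genomes(4000, 1500, 1200, 12000, 8000, 1000, seed = 3)
  tr <- g$truth_layout[g$truth_layout$segment == "tract", ]
  msk <- shared_region_mask(g$plastid, g$mito, 100)
  expect_identical(nrow(msk$B), 1L)
  expect_lte(abs(msk$B$start0 - tr$start0), 99L)
  expect_lte(abs(msk$B$end0 - tr$end0), 99L)
  ## unique regions complement the mask
  u <- unique_regions(msk$B, nchar(g$mito))
  expect_identical(sum(u$end0 - u$start0) + sum(msk$B$end0 - msk$B$start0),
                   nchar(g$mito))
})

test_that("within-genome repeats (the IR) are masked for depth", {
  g <- make_genomes(4000, 1500, 1200, 5000, 6000, 0, seed = 3)
  rm <- repeat_region_mask(g$plastid, 100)
  lay <- g$truth_layout
  ira <- lay[lay$segment == "IRa", ]; irb <- lay[lay$segment == "IRb", ]
  covers <- function(mask, s, e) any(mask$start0 <= s + 99 & mask$end0 >= e - 99)
  expect_true(covers(rm, ira$start0, ira$end0))
  expect_true(covers(rm, irb$start0, irb$end0))
  expect_identical(nrow(repeat_region_mask(rdna(4000, seed = 85), 100)), 0L)
})

test_that("depth statistics follow the printed-table arithmetic", {
  expect_identical(sequencing_depth(278656000, 142995), 1949L)
  expect_identical(sequencing_depth(6947500, 3219), 2158L)
  expect_identical(sequencing_depth(19907700, 216086), 92L)
  expect_identical(sequencing_depth(52000, 621), 84L)
  expect_error(sequencing_depth(100, 0), "zero-length")
})

test_that("depth_stats is linear in the placement stream", {
  ref <- rdna(3000, seed = 87)
  idx <- build_index(c(genome = ref), seed_k = 21)
  reads1 <- substring(ref, seq(1, 1000, by = 50), seq(1, 1000, by = 50) + 99)
  reads2 <- substring(ref, seq(1001, 2000, by = 50), seq(1001, 2000, by = 50) + 99)
  p1 <- map_reads(setNames(reads1, paste0("a", seq_along(reads1))), idx)
  p2 <- map_reads(setNames(reads2, paste0("b", seq_along(reads2))), idx)
  regions <- data.frame(region = "all", ref = "genome", start0 = 0L, end0 = 3000L)
  d1 <- depth_stats(p1, regions, 100)
  d2 <- depth_stats(p2, regions, 100)
  d12 <- depth_stats(rbind(p1, p2), regions, 100)
  expect_identical(d12$mapped_reads, d1$mapped_reads + d2$mapped_reads)
  expect_identical(d12$mapped_bases, d1$mapped_bases + d2$mapped_bases)
  d0 <- depth_stats(p1[0, ], regions, 100)
  expect_identical(d0$depth, 0L)
})

test_that("placements export as minimal SAM", {
  ref <- rdna(1000, seed = 89)
  idx <- build_index(c(genome = ref), seed_k = 21)
  reads <- setNames(c(substring(ref, 101, 200), revcomp(substring(ref, 301, 400))),
                    c("r1", "r2"))
  pl <- map_reads(reads, idx)
  tmp <- withr::local_tempfile(fileext = ".sam")
  write_sam(pl, reads, idx, tmp)
  lines <- readLines(tmp)
  expect_true(any(grepl("^@SQ\tSN:genome\tLN:1000$", lines)))
  body <- lines[!startsWith(lines, "@")]
  expect_identical(length(body), 2L)
  expect_true(all(grepl("100M", body)))
  expect_true(any(grepl("\t16\t", body)))     # minus-strand flag
})
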