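test_that("genome triple respects the quadripartite layout and the tract", {
  g <- make_genomes(lsc = 8000, ssc = 2000, ir = 2500, mito = 20000,
                    nuclear = 50000, homology_tract = 1000, seed = 1)
  expect_identical(nchar(g$plastid), 8000L + 2000L + 2L * 2500L)
  lay <- g$truth_layout
  seg <- function(s) lay[lay$segment == s, ]
  ira <- substring(g$plastid, seg("IRa")$start0 + 1, seg("IRa")$end0)
  irb <- substring(g$plastid, seg("IRb")$start0 + 1, seg("IRb")$end0)
  expect_identical(irb, revcomp(ira))
  tr <- seg("tract")
  tract <- substring(g$mito, tr$start0 + 1, tr$end0)
  expect_identical(nchar(tract), 1000L)
  expect_true(grepl(tract, g$plastid, fixed = TRUE))
  expect_true(all(strsplit(paste0(g$plastid, g$mito, g$nuclear), "")[[1]] %in%
                    c("A", "C", "G", "T")))
})

test_that("genome generation is deterministic and validates the tract size", {
  g1 <- make_genomes(2000, 800, 600, 5000, 8000, 300, seed = 7)
  g2 <- make_genomes(2000, 800, 600, 5000, 8000, 300, seed = 7)
  expect_identical(g1$plastid, g2$plastid)
  expect_identical(g1$mito, g2$mito)
  expect_identical(g1$nuclear, g2$nuclear)
  g3 <- make_genomes(2000, 800, 600, 5000, 8000, 300, seed = 8)
  expect_false(identical(g1$plastid, g3$plastid))
  expect_error(make_genomes(2000, 800, 600, 5000, 8000, homology_tract = 2000),
               "single-copy")
})

test_that("IR invariant holds across generated genomes", {
  for (seed in 1:5) {
    g <- make_genomes(3000, 1000, 800, 4000, 6000, 0, seed = seed)
    lay <- g$truth_layout
    ira <- substring(g$plastid, lay$start0[lay$segment == "IRa"] + 1,
                     lay$end0[lay$segment == "IRa"])
    irb <- substring(g$plastid, lay$start0[lay$segment == "IRb"] + 1,
                     lay$end0[lay$segment == "IRb"])
    expect_identical(irb, revcomp(ira))
  }
})

test_that("error-free reads are exact substrings at their truth coordinates", {
  g <- make_genomes(3000, 1000, 800, 6000, 10000, 500, seed = 2)
  p <- read_sim_params(copy_folds = c(20, 5, 1), total_pairs = 500, seed = 3)
  sim <- sample_read_pairs(g, p)
  genomes <- c(plastid = g$plastid, mito = g$mito, nuclear = g$nuclear)
  for (i in seq_len(nrow(sim$truth))) {
    tr <- sim$truth[i, ]
    gg <- paste0(genomes[[tr$compartment]], genomes[[tr$compartment]])
    m1 <- substring(gg, tr$mate1_start0 + 1, tr$mate1_start0 + 100)
    m2 <- substring(gg, tr$mate2_start0 + 1, tr$mate2_start0 + 100)
    expect_identical(sim$pairs$seq1[i],
                     if (tr$mate1_strand == "+") m1 else revcomp(m1))
    expect_identical(sim$pairs$seq2[i],
                     if (tr$mate2_strand == "+") m2 else revcomp(m2))
  }
})

test_that("compartment read counts follow the copy-fold multinomial", {
  g <- make_genomes(3000, 1000, 800, 6000, 10000, 0, seed = 2)
  p <- read_sim_params(copy_folds = c(100, 10, 1), total_pairs = 10000, seed = 11)
  sim <- sample_read_pairs(g, p)
  len <- c(plastid = nchar(g$plastid), mito = nchar(g$mito), nuclear = nchar(g$nuclear))
  w <- p$copy_folds * len
  prob <- w / sum(w)
  cnt <- table(factor(sim$truth$compartment, levels = names(prob)))
  for (comp in names(prob)) {
    mu <- 10000 * prob[[comp]]
    sdv <- sqrt(10000 * prob[[comp]] * (1 - prob[[comp]]))
    expect_lt(abs(cnt[[comp]] - mu), 3 * sdv)
  }
  ## realized depth converges to the copy-fold-proportional expectation
  dep <- vapply(names(len), function(comp) {
    sum(sim$truth$compartment == comp) * 200 / len[[comp]]
  }, 0)
  ed <- expected_depths(g, p)
  for (comp in names(len)) {
    expect_lt(abs(dep[[comp]] - ed[[comp]]) / ed[[comp]], 0.15)
  }
})

test_that("simulation is reproducible and respects parameter validation", {
  g <- make_genomes(3000, 1000, 800, 6000, 10000, 0, seed = 2)
  p <- read_sim_params(copy_folds = c(10, 5, 1), total_pairs = 200, seed = 13)
  s1 <- sample_read_pairs(g, p)
  s2 <- sample_read_pairs(g, p)
  expect_identical(s1$pairs, s2$pairs)
  expect_identical(s1$truth, s2$truth)
  expect_error(read_sim_params(read_length = 300, insert_mean = 200), "insert_mean")
  ## insert longer than the linear nuclear genome
  p2 <- read_sim_params(insert_mean = 20000, total_pairs = 10)
  expect_error(sample_read_pairs(g, p2), "linear")
})

test_that("adaptor planting contaminates the requested fraction", {
  g <- make_genomes(3000, 1000, 800, 6000, 10000, 0, seed = 2)
  ad <- "AGATCGGAAGAGC"
  p <- read_sim_params(copy_folds = c(10, 5, 1), total_pairs = 1000, seed = 17,
                       adaptor = ad, adaptor_frac = 0.1)
  sim <- sample_read_pairs(g, p)
  n_con <- sum(grepl(ad, sim$pairs$seq1, fixed = TRUE))
  expect_identical(n_con, 100L)
})
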