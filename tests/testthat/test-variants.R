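## Plant well-spaced mutations into a copy of a genome, keeping a truth
## ledger of expected events (applied right-to-left so coordinates hold).
plant_mutations <- function(ref, snp_pos, ins_pos, del_pos, seed = 1L) {
  set.seed(seed)
  q <- strsplit(ref, "")[[1]]
  for (p in snp_pos) q[p] <- setdiff(c("A", "C", "G", "T"), q[p])[1]
  q <- paste(q, collapse = "")
  edits <- rbind(
    if (length(ins_pos)) data.frame(pos = ins_pos, kind = "ins"),
    if (length(del_pos)) data.frame(pos = del_pos, kind = "del"))
  edits <- edits[order(-edits$pos), , drop = FALSE]
  for (i in seq_len(nrow(edits))) {
    p <- edits$pos[i]
    if (edits$kind[i] == "ins") {
      q <- paste0(substring(q, 1, p), "CAGTT", substring(q, p + 1))
    } else {
      q <- paste0(substring(q, 1, p), substring(q, p + 4))
    }
  }
  q
}

test_that("identical genomes align with zero differences", {
  ref <- rdna(15000, seed = 121)
  cv <- classify_variants(align_genomes(ref, ref))
  expect_identical(sum(cv$counts), 0L)
  expect_identical(nrow(cv$variants), 0L)
})

test_that("a single substitution is one SNP at the right coordinate", {
  ref <- rdna(15000, seed = 121)
  q <- ref
  substr(q, 5000, 5000) <- setdiff(c("A", "C", "G", "T"), substr(q, 5000, 5000))[1]
  cv <- classify_variants(align_genomes(q, ref))
  expect_identical(unname(cv$counts["SNP"]), 1L)
  expect_identical(sum(cv$counts), 1L)
  expect_identical(cv$variants$ref_pos, 4999L)
})

test_that("adjacent difference columns merge into MNP and CV events", {
  ref <- rdna(15000, seed = 121)
  ## three consecutive substitutions: one MNP, not three SNPs
  q <- ref
  for (p in 7000:7002) {
    substr(q, p, p) <- setdiff(c("A", "C", "G", "T"), substr(q, p, p))[1]
  }
  cv <- classify_variants(align_genomes(q, ref))
  expect_identical(unname(cv$counts["MNP"]), 1L)
  expect_identical(unname(cv$counts["SNP"]), 0L)
  expect_identical(nchar(cv$variants$ref_allele[cv$variants$type == "MNP"]), 3L)
  ## substitution adjacent to a deletion: one complex variation
  q2 <- paste0(substring(ref, 1, 8999),
               setdiff(c("A", "C", "G", "T"), substr(ref, 9000, 9000))[1],
               substring(ref, 9004))   # replace base then delete 3
  cv2 <- classify_variants(align_genomes(q2, ref))
  expect_identical(unname(cv2$counts["CV"]), 1L)
  expect_identical(unname(cv2$counts["SNP"]) + unname(cv2$counts["indel"]), 0L)
})

test_that("planted mutations are recovered with full recall and precision", {
  ref <- rdna(20000, seed = 123)
  snp_at <- seq(500, 10000, by = 500)
  ins_at <- seq(11000, 14000, by = 1000)
  del_at <- seq(15500, 19000, by = 1000)
  q <- plant_mutations(ref, snp_at, ins_at, del_at)
  cv <- classify_variants(align_genomes(q, ref))
  expect_identical(unname(cv$counts["SNP"]), length(snp_at))
  expect_identical(unname(cv$counts["indel"]), length(ins_at) + length(del_at))
  expect_identical(sum(cv$counts), length(snp_at) + length(ins_at) + length(del_at))
  got_snp <- sort(cv$variants$ref_pos[cv$variants$type == "SNP"])
  expect_identical(got_snp, as.integer(snp_at - 1L))
})

test_that("SNP and MNP counts are symmetric under query/reference swap", {
  ref <- rdna(15000, seed = 127)
  q <- plant_mutations(ref, snp_pos = c(2000, 5000, 8000), ins_pos = 11000,
                       del_pos = 13000)
  fwd <- classify_variants(align_genomes(q, ref))
  rev <- classify_variants(align_genomes(ref, q))
  expect_identical(fwd$counts[c("SNP", "MNP")], rev$counts[c("SNP", "MNP")])
  expect_identical(unname(fwd$counts["indel"]), unname(rev$counts["indel"]))
  ## insertion and deletion roles swap
  ins_fwd <- sum(fwd$variants$type == "indel" & nchar(fwd$variants$ref_allele) == 0)
  del_rev <- sum(rev$variants$type == "indel" & nchar(rev$variants$alt_allele) == 0)
  expect_identical(ins_fwd, del_rev)
})

test_that("indels left-align deterministically in homopolymers", {
  ref <- paste0(rdna(500, seed = 131), strrep("A", 8), rdna(500, seed = 132))
  ## delete one A from the middle of the homopolymer run
  q <- paste0(substring(ref, 1, 504), substring(ref, 506))
  cv <- classify_variants(align_genomes(q, ref, anchor_k = 31))
  ind <- cv$variants[cv$variants$type == "indel", ]
  expect_identical(nrow(ind), 1L)
  expect_identical(ind$ref_allele, "A")
  ## the event sits at the leftmost A of the run
  run_start <- regexpr("AAAAAAAA", ref, fixed = TRUE)[1] - 1L
  expect_identical(ind$ref_pos, run_start)
})

test_that("rearranged inputs fail loudly rather than mis-typing", {
  a <- rdna(4000, seed = 135)
  b <- rdna(4000, seed = 136)
  expect_error(align_genomes(a, b), "alignment failure")
})

test_that("coding and synonymy annotation follows the genetic code", {
  ## build a reference with a known + strand CDS: ...ATG GGA TTT...
  lead <- rdna(300, seed = 141)
  cds_seq <- "ATGGGATTTCCCAAATAG"
  ref <- paste0(lead, cds_seq, rdna(300, seed = 142))
  cds <- data.frame(start0 = 300L, end0 = 300L + nchar(cds_seq), strand = "+")
  mkvar <- function(pos0, alt, ref_allele) {
    data.frame(ref_pos = pos0, ref_allele = ref_allele, alt_allele = alt,
               type = "SNP", stringsAsFactors = FALSE)
  }
  ## GGA -> GGG: wobble position, synonymous (both Gly)
  v1 <- annotate_variants(mkvar(305L, "G", "A"), cds, ref)
  expect_true(v1$coding)
  expect_false(v1$nonsynonymous)
  ## ATG -> ATA: Met -> Ile, non-synonymous
  v2 <- annotate_variants(mkvar(302L, "A", "G"), cds, ref)
  expect_true(v2$coding)
  expect_true(v2$nonsynonymous)
  ## outside any CDS
  v3 <- annotate_variants(mkvar(10L, "A", "C"), cds, ref)
  expect_false(v3$coding)
  expect_true(is.na(v3$nonsynonymous))
  ## minus-strand CDS: same codon logic on the reverse complement
  ref_m <- paste0(lead, revcomp(cds_seq), rdna(300, seed = 143))
  cds_m <- data.frame(start0 = 300L, end0 = 300L + nchar(cds_seq), strand = "-")
  ## mutate the base pairing with the ATG->ATA wobble on the minus strand
  p <- 300L + nchar(cds_seq) - 3L   # third codon base of ATG on -
  vm <- annotate_variants(mkvar(p, revcomp("A"), substring(ref_m, p + 1, p + 1)),
                          cds_m, ref_m)
  expect_true(vm$coding)
  expect_true(vm$nonsynonymous)
  ## CDS length must be divisible by 3
  expect_error(annotate_variants(mkvar(305L, "G", "A"),
                                 data.frame(start0 = 0L, end0 = 10L, strand = "+"),
                                 ref),
               "divisible")
})

test_that("variants export as minimal 1-based VCF", {
  ref <- rdna(2000, seed = 145)
  q <- plant_mutations(ref, snp_pos = 500, ins_pos = 1000, del_pos = 1500)
  cv <- classify_variants(align_genomes(q, ref, anchor_k = 31))
  tmp <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(cv$variants, ref, "plastid", tmp)
  lines <- readLines(tmp)
  body <- lines[!startsWith(lines, "#")]
  expect_identical(length(body), nrow(cv$variants))
  snp <- strsplit(body[grepl("TYPE=SNP", body)], "\t")[[1]]
  expect_identical(as.integer(snp[2]),
                   cv$variants$ref_pos[cv$variants$type == "SNP"] + 1L)
})
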