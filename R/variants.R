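## Pairwise genome comparison and variant classification. Two colinear
## genomes are aligned by chaining unique shared anchors and globally
## aligning the short inter-anchor segments with unit costs; maximal runs
## of adjacent difference columns are merged into events and typed:
## SNP (one substituted base), MNP (equal-length multi-base substitution),
## indel (one side empty), CV (length-changing with both sides non-empty).
## Indels are left-aligned in homopolymers for deterministic coordinates.

.unit_submat <- function() {
  b <- c("A", "C", "G", "T", "N")
  m <- matrix(-1, 5, 5, dimnames = list(b, b))
  diag(m) <- 0
  m["N", ] <- -1; m[, "N"] <- -1
  m
}

#' Align two colinear genomes
#'
#' Chains `anchor_k`-mers unique within each genome and shared between
#' them, compresses runs of consistent anchors into exact-match blocks,
#' and aligns the inter-block segments globally with unit mismatch/gap
#' costs. Rearranged inputs (no chainable same-strand anchors) fail
#' loudly rather than being mis-typed.
#'
#' @param query,reference genome sequences (single strings).
#' @param anchor_k anchor kmer size (odd, default 31).
#' @return an object of class `genome_alignment`: list with `query_aln`
#'   and `ref_aln`, equal-length gapped strings (`-` for gaps).
#' @export
align_genomes <- function(query, reference, anchor_k = 31L) {
  anchor_k <- as.integer(anchor_k)
  if (anchor_k %% 2L == 0L) stop("anchor_k must be odd")
  uniq_tab <- function(s) {
    kp <- kmer_positions(s, anchor_k)
    kp <- kp[!grepl("N", kp$kmer, fixed = TRUE)]
    kp[, kmer := canonical_kmer(kmer)]
    cnt <- kp[, .N, by = kmer]
    kp[kmer %in% cnt$kmer[cnt$N == 1L]]
  }
  qt <- uniq_tab(query); rt <- uniq_tab(reference)
  m <- match(qt$kmer, rt$kmer)
  ok <- !is.na(m)
  if (!any(ok)) stop("alignment failure: no shared unique anchors")
  qp <- qt$pos0[ok]; rp <- rt$pos0[m[ok]]
  ord <- order(qp)
  qp <- qp[ord]; rp <- rp[ord]
  idx <- .lis(rp)
  qp <- qp[idx]; rp <- rp[idx]
  if (length(qp) == 0L) stop("alignment failure: no chainable anchors")

  ## compress to exact-match blocks: consecutive anchors with equal offset
  ## and step <= anchor_k guarantee identical intervening sequence
  brk <- c(TRUE, diff(qp) != diff(rp) | diff(qp) > anchor_k)
  block <- cumsum(brk)
  qb_s <- tapply(qp, block, min); qb_e <- tapply(qp, block, max) + anchor_k
  rb_s <- tapply(rp, block, min); rb_e <- tapply(rp, block, max) + anchor_k

  submat <- .unit_submat()
  aln_seg <- function(qs, rs) {
    if (nchar(qs) == 0L && nchar(rs) == 0L) return(c("", ""))
    if (nchar(qs) == 0L) return(c(strrep("-", nchar(rs)), rs))
    if (nchar(rs) == 0L) return(c(qs, strrep("-", nchar(qs))))
    pa <- Biostrings::pairwiseAlignment(qs, rs, type = "global",
                                        substitutionMatrix = submat,
                                        gapOpening = 2, gapExtension = 1)
    c(as.character(Biostrings::alignedPattern(pa)),
      as.character(Biostrings::alignedSubject(pa)))
  }

  q_parts <- character(0); r_parts <- character(0)
  qcur <- 0L; rcur <- 0L
  nb <- length(qb_s)
  for (i in seq_len(nb)) {
    ## adjacent blocks can overlap around an indel; clip both coordinates
    ## by the same amount so the exact-match correspondence is preserved
    shift <- max(0, qcur - qb_s[i], rcur - rb_s[i])
    qs_i <- qb_s[i] + shift; rs_i <- rb_s[i] + shift
    if (qs_i >= qb_e[i] || rs_i >= rb_e[i]) next
    seg <- aln_seg(substring(query, qcur + 1L, qs_i),
                   substring(reference, rcur + 1L, rs_i))
    q_parts <- c(q_parts, seg[1L], substring(query, qs_i + 1L, qb_e[i]))
    r_parts <- c(r_parts, seg[2L], substring(reference, rs_i + 1L, rb_e[i]))
    qcur <- qb_e[i]; rcur <- rb_e[i]
  }
  seg <- aln_seg(substring(query, qcur + 1L, nchar(query)),
                 substring(reference, rcur + 1L, nchar(reference)))
  q_parts <- c(q_parts, seg[1L]); r_parts <- c(r_parts, seg[2L])

  structure(list(query_aln = paste(q_parts, collapse = ""),
                 ref_aln = paste(r_parts, collapse = "")),
            class = "genome_alignment")
}

## Left-align a pure indel in homopolymer context; returns updated
## (ref_pos, allele). `allele` is the inserted or deleted sequence.
.left_align_indel <- function(ref_pos, allele, reference) {
  while (ref_pos > 0L) {
    prev <- substring(reference, ref_pos, ref_pos)
    last <- substring(allele, nchar(allele), nchar(allele))
    if (prev != last) break
    allele <- paste0(prev, substring(allele, 1L, nchar(allele) - 1L))
    ref_pos <- ref_pos - 1L
  }
  list(ref_pos = ref_pos, allele = allele)
}

#' Classify variants from a pairwise alignment
#'
#' Merges maximal runs of adjacent difference columns into single events
#' and types them: SNP, MNP, indel, CV.
#'
#' @param alignment a [align_genomes()] result.
#' @return list with `variants` (data.frame `ref_pos` 0-based,
#'   `ref_allele`, `alt_allele`, `type`) and `counts` (named integer by
#'   type).
#' @export
classify_variants <- function(alignment) {
  qa <- strsplit(alignment$query_aln, "", fixed = TRUE)[[1L]]
  ra <- strsplit(alignment$ref_aln, "", fixed = TRUE)[[1L]]
  stopifnot(length(qa) == length(ra))
  diffcol <- qa != ra
  ref_cum <- cumsum(ra != "-")        # 1-based ref position at each column

  ev <- list()
  if (any(diffcol)) {
    r <- rle(diffcol)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    for (i in which(r$values)) {
      cols <- starts[i]:ends[i]
      refa <- paste(ra[cols][ra[cols] != "-"], collapse = "")
      alta <- paste(qa[cols][qa[cols] != "-"], collapse = "")
      pos0 <- ref_cum[starts[i]] - 1L   # 0-based position of first event column
      if (ra[starts[i]] == "-") pos0 <- pos0 + 1L  # insertion: position after preceding base
      lr <- nchar(refa); la <- nchar(alta)
      type <- if (lr == 1L && la == 1L) "SNP"
      else if (lr == la) "MNP"
      else if (lr == 0L || la == 0L) "indel"
      else "CV"
      ev[[length(ev) + 1L]] <- data.frame(
        ref_pos = pos0, ref_allele = refa, alt_allele = alta, type = type,
        stringsAsFactors = FALSE)
    }
  }
  variants <- if (length(ev)) do.call(rbind, ev) else
    data.frame(ref_pos = integer(0), ref_allele = character(0),
               alt_allele = character(0), type = character(0))

  ## left-align pure indels against the ungapped reference
  refseq <- paste(ra[ra != "-"], collapse = "")
  if (nrow(variants) > 0L) {
    for (i in seq_len(nrow(variants))) {
      if (variants$type[i] != "indel") next
      if (nchar(variants$ref_allele[i]) > 0L) {        # deletion
        la <- .left_align_indel(variants$ref_pos[i], variants$ref_allele[i], refseq)
        variants$ref_pos[i] <- la$ref_pos
        variants$ref_allele[i] <- la$allele
      } else {                                          # insertion
        la <- .left_align_indel(variants$ref_pos[i], variants$alt_allele[i], refseq)
        variants$ref_pos[i] <- la$ref_pos
        variants$alt_allele[i] <- la$allele
      }
    }
    variants <- variants[order(variants$ref_pos), , drop = FALSE]
    rownames(variants) <- NULL
  }
  counts <- vapply(c("SNP", "MNP", "indel", "CV"),
                   function(t) sum(variants$type == t), 0L)
  list(variants = variants, counts = counts)
}

#' Annotate variants with coding and synonymy status
#'
#' An event is coding when it overlaps a CDS interval. For coding SNPs the
#' affected codon is translated on the CDS strand with the standard
#' genetic code; non-SNP coding events get `NA` synonymy.
#'
#' @param variants data.frame from [classify_variants()].
#' @param cds data.frame of CDS intervals: `start0`, `end0` (0-based
#'   half-open), `strand` (`"+"`/`"-"`), optional `name`. Interval lengths
#'   must be divisible by 3.
#' @param reference the reference sequence the variants are called
#'   against.
#' @return the variants data.frame with added `coding` (logical) and
#'   `nonsynonymous` (logical, `NA` where synonymy is undefined), plus a
#'   `counts` attribute (coding, nonsynonymous).
#' @export
annotate_variants <- function(variants, cds, reference) {
  if (any((cds$end0 - cds$start0) %% 3L != 0L)) {
    stop("annotation error: CDS interval length not divisible by 3")
  }
  gc <- Biostrings::GENETIC_CODE
  coding <- logical(nrow(variants))
  nonsyn <- rep(NA, nrow(variants))
  for (i in seq_len(nrow(variants))) {
    p <- variants$ref_pos[i]
    w <- max(1L, nchar(variants$ref_allele[i]))
    hit <- which(cds$start0 < p + w & cds$end0 > p)
    coding[i] <- length(hit) > 0L
    if (!coding[i] || variants$type[i] != "SNP") next
    cd <- cds[hit[1L], ]
    if (cd$strand == "+") {
      off <- p - cd$start0
      cstart <- cd$start0 + 3L * (off %/% 3L)
      codon <- substring(reference, cstart + 1L, cstart + 3L)
      mut <- codon
      substr(mut, off %% 3L + 1L, off %% 3L + 1L) <- variants$alt_allele[i]
    } else {
      off <- cd$end0 - 1L - p
      cstart_f <- cd$end0 - 3L * (off %/% 3L) - 3L
      codon_f <- substring(reference, cstart_f + 1L, cstart_f + 3L)
      mut_f <- codon_f
      substr(mut_f, 3L - off %% 3L, 3L - off %% 3L) <-
        revcomp(variants$alt_allele[i])
      codon <- revcomp(codon_f)
      mut <- revcomp(mut_f)
    }
    nonsyn[i] <- gc[[codon]] != gc[[mut]]
  }
  variants$coding <- coding
  variants$nonsynonymous <- nonsyn
  attr(variants, "counts") <- c(coding = sum(coding),
                                nonsynonymous = sum(nonsyn %in% TRUE))
  variants
}

#' Write variants as minimal VCF
#'
#' 1-based positions per VCF convention; indels are anchored on the
#' preceding reference base.
#'
#' @param variants annotated or raw variants data.frame.
#' @param reference reference sequence (for indel anchor bases).
#' @param chrom chromosome name for the CHROM column.
#' @param path output path.
#' @export
write_vcf <- function(variants, reference, chrom, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               sprintf("##contig=<ID=%s,length=%d>", chrom, nchar(reference)),
               "##INFO=<ID=TYPE,Number=1,Type=String,Description=\"Variant type\">",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"), con)
  for (i in seq_len(nrow(variants))) {
    p <- variants$ref_pos[i]
    refa <- variants$ref_allele[i]; alta <- variants$alt_allele[i]
    if (nchar(refa) == 0L || nchar(alta) == 0L) {
      anchor <- substring(reference, p, p)   # base before the event
      refa <- paste0(anchor, refa); alta <- paste0(anchor, alta)
      pos1 <- p                               # 1-based position of the anchor
    } else {
      pos1 <- p + 1L
    }
    writeLines(sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\tTYPE=%s",
                       chrom, pos1, refa, alta, variants$type[i]), con)
  }
  invisible(path)
}
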