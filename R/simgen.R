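## Synthetic mixed-organelle libraries. Three genome compartments — a
## linear nuclear sequence, a circular quadripartite plastid (LSC + IRa +
## SSC + IRb with IRb the reverse complement of IRa) and a circular
## mitochondrion carrying one tract copied verbatim from the plastid (the
## homology trap) — sampled as paired-end reads at user-set copy folds.
## Every read carries a truth label in a sidecar table so downstream
## stages can be audited against known ground truth.

#' Generate a nuclear/plastid/mitochondrial genome triple
#'
#' The plastid is built as LSC + IRa + SSC + IRb with IRb equal to the
#' reverse complement of IRa; the mitochondrion contains one tract copied
#' verbatim from the plastid's larger single-copy region, emulating the
#' plastid-homologous regions of real plant mitochondria that turn into
#' assembly gaps once plastid-matching read pairs are removed.
#'
#' @param lsc,ssc,ir,mito,nuclear segment sizes in bases (all positive).
#' @param homology_tract length of the plastid tract copied into the
#'   mitochondrion; 0 disables it. Must be shorter than the larger plastid
#'   single-copy region.
#' @param seed integer seed; output is byte-identical for a fixed seed.
#' @return an object of class `genome_triple`: list with `nuclear`,
#'   `plastid`, `mito` (character sequences), and `truth_layout`, a
#'   data.frame of 0-based half-open segment coordinates.
#' @examples
#' g <- make_genomes(lsc = 8000, ssc = 2000, ir = 2500,
#'                   mito = 20000, nuclear = 50000,
#'                   homology_tract = 1000, seed = 1)
#' nchar(g$plastid)  # 15000
#' @export
make_genomes <- function(lsc, ssc, ir, mito, nuclear, homology_tract = 0, seed = 1) {
  stopifnot(lsc > 0, ssc > 0, ir > 0, mito > 0, nuclear > 0, homology_tract >= 0)
  if (homology_tract >= max(lsc, ssc)) {
    stop("parameter error: homology_tract must be shorter than the larger single-copy region")
  }
  with_seed(seed, {
    lsc_seq <- random_dna(lsc)
    ira_seq <- random_dna(ir)
    ssc_seq <- random_dna(ssc)
    plastid <- paste0(lsc_seq, ira_seq, ssc_seq, revcomp(ira_seq))
    mito_seq <- random_dna(mito)
    nuc_seq <- random_dna(nuclear)

    layout <- data.frame(
      compartment = c("plastid", "plastid", "plastid", "plastid", "mito", "nuclear"),
      segment = c("LSC", "IRa", "SSC", "IRb", "mito", "nuclear"),
      start0 = c(0L, lsc, lsc + ir, lsc + ir + ssc, 0L, 0L),
      end0 = c(lsc, lsc + ir, lsc + ir + ssc, lsc + 2L * ir + ssc, mito, nuclear),
      stringsAsFactors = FALSE
    )

    if (homology_tract > 0) {
      ## copy from the interior of the larger single-copy region
      src_off <- if (lsc >= ssc) {
        floor((lsc - homology_tract) / 2)
      } else {
        lsc + ir + floor((ssc - homology_tract) / 2)
      }
      tract <- substring(plastid, src_off + 1L, src_off + homology_tract)
      if (mito < homology_tract + 2L) stop("parameter error: mito too short for tract")
      dst_off <- floor((mito - homology_tract) / 2)
      mito_seq <- paste0(substring(mito_seq, 1L, dst_off),
                         tract,
                         substring(mito_seq, dst_off + homology_tract + 1L, mito))
      layout <- rbind(layout, data.frame(
        compartment = c("plastid", "mito"),
        segment = c("tract_src", "tract"),
        start0 = c(src_off, dst_off),
        end0 = c(src_off + homology_tract, dst_off + homology_tract),
        stringsAsFactors = FALSE
      ))
    }

    structure(
      list(nuclear = nuc_seq, plastid = plastid, mito = mito_seq,
           truth_layout = layout, seed = seed),
      class = "genome_triple"
    )
  })
}

#' @export
print.genome_triple <- function(x, ...) {
  cat(sprintf("<genome_triple> plastid %d nt (circular), mito %d nt (circular), nuclear %d nt; seed %d\n",
              nchar(x$plastid), nchar(x$mito), nchar(x$nuclear), x$seed))
  invisible(x)
}

#' Read-simulation parameters
#'
#' @param read_length read length in bases (default 100).
#' @param insert_mean,insert_sd insert size distribution (normal, rounded
#'   to integer, truncated at `[2 * read_length, genome length]`).
#' @param copy_folds named or ordered numeric of length 3: copies of
#'   (plastid, mito, nuclear) genome per cell-equivalent. Expected read
#'   share of a compartment is proportional to `copy_fold * length`.
#' @param total_pairs number of read pairs to draw.
#' @param error_rate per-base substitution probability.
#' @param seed integer seed.
#' @param adaptor optional adaptor sequence planted into a fraction of
#'   mate-1 reads (tail replacement), for exercising QC.
#' @param adaptor_frac fraction of pairs contaminated with the adaptor.
#' @return list of validated parameters, class `read_sim_params`.
#' @export
read_sim_params <- function(read_length = 100L, insert_mean = 500L, insert_sd = 50L,
                            copy_folds = c(plastid = 1922, mito = 72, nuclear = 1),
                            total_pairs = 10000L, error_rate = 0,
                            seed = 1L, adaptor = NULL, adaptor_frac = 0) {
  stopifnot(read_length > 0, insert_mean >= read_length, all(copy_folds > 0),
            length(copy_folds) == 3L, total_pairs >= 0, error_rate >= 0, error_rate < 1,
            adaptor_frac >= 0, adaptor_frac <= 1)
  names(copy_folds) <- c("plastid", "mito", "nuclear")
  structure(list(read_length = as.integer(read_length),
                 insert_mean = as.integer(insert_mean),
                 insert_sd = as.numeric(insert_sd),
                 copy_folds = copy_folds,
                 total_pairs = as.integer(total_pairs),
                 error_rate = error_rate, seed = as.integer(seed),
                 adaptor = adaptor, adaptor_frac = adaptor_frac),
            class = "read_sim_params")
}

#' Simulate paired-end reads from a genome triple
#'
#' Fragments are assigned to compartments multinomially with weights
#' `copy_fold * genome_length`, placed uniformly (across the origin for
#' the circular plastid and mitochondrion), and sequenced from both ends
#' inward: mate 1 is the first `read_length` bases of the fragment, mate 2
#' the reverse complement of its last `read_length` bases. Base qualities
#' are Q40 except at simulated substitution errors (Q15). Truth labels
#' (compartment, fragment start, strand) live in a sidecar table only.
#'
#' @param g a [make_genomes()] triple.
#' @param p a [read_sim_params()] list.
#' @return list with `pairs` (a [read_pairs()] data.frame) and `truth`
#'   (data.frame: id, compartment, start0, insert, strand, mate1_start0,
#'   mate1_strand, mate2_start0, mate2_strand; positions 0-based on the
#'   forward strand, modulo genome length for circular compartments).
#' @export
sample_read_pairs <- function(g, p) {
  stopifnot(inherits(g, "genome_triple"), inherits(p, "read_sim_params"))
  L <- p$read_length
  genomes <- c(plastid = g$plastid, mito = g$mito, nuclear = g$nuclear)
  circular <- c(plastid = TRUE, mito = TRUE, nuclear = FALSE)
  glen <- nchar(genomes)
  if (p$insert_mean > glen[["nuclear"]]) {
    stop("parameter error: mean insert exceeds the linear nuclear genome length")
  }
  w <- p$copy_folds[c("plastid", "mito", "nuclear")] * glen
  with_seed(p$seed, {
    n_by <- if (p$total_pairs > 0) {
      as.vector(stats::rmultinom(1L, p$total_pairs, w / sum(w)))
    } else c(0L, 0L, 0L)
    names(n_by) <- names(genomes)

    comp_all <- character(0); s_all <- integer(0); ins_all <- integer(0)
    str_all <- character(0); seq1 <- character(0); seq2 <- character(0)

    for (comp in names(genomes)) {
      n <- n_by[[comp]]
      if (n == 0L) next
      len <- glen[[comp]]
      ins <- as.integer(pmin(pmax(round(stats::rnorm(n, p$insert_mean, p$insert_sd)),
                                  2L * L), len))
      if (circular[[comp]]) {
        s <- sample.int(len, n, replace = TRUE) - 1L
      } else {
        s <- vapply(ins, function(i) sample.int(len - i + 1L, 1L) - 1L, 0L)
      }
      strand <- sample(c("+", "-"), n, replace = TRUE)
      gg <- if (circular[[comp]]) paste0(genomes[[comp]], genomes[[comp]]) else genomes[[comp]]
      frag <- substring(gg, s + 1L, s + ins)
      frag[strand == "-"] <- revcomp(frag[strand == "-"])
      seq1 <- c(seq1, substring(frag, 1L, L))
      seq2 <- c(seq2, revcomp(substring(frag, ins - L + 1L, ins)))
      comp_all <- c(comp_all, rep(comp, n)); s_all <- c(s_all, s)
      ins_all <- c(ins_all, ins); str_all <- c(str_all, strand)
    }

    n <- length(seq1)
    ord <- if (n > 0) sample.int(n) else integer(0)
    comp_all <- comp_all[ord]; s_all <- s_all[ord]; ins_all <- ins_all[ord]
    str_all <- str_all[ord]; seq1 <- seq1[ord]; seq2 <- seq2[ord]
    ids <- sprintf("frag%06d", seq_len(n))

    qual1 <- vapply(rep(L, n), function(x) strrep("I", x), "")
    qual2 <- qual1

    ## substitution errors (quality dropped to Q15 at error positions)
    if (p$error_rate > 0 && n > 0) {
      inject <- function(seqs, quals) {
        k <- stats::rbinom(length(seqs), L, p$error_rate)
        for (i in which(k > 0)) {
          pos <- sample.int(L, k[i])
          ch <- strsplit(seqs[i], "", fixed = TRUE)[[1]]
          qc <- strsplit(quals[i], "", fixed = TRUE)[[1]]
          for (j in pos) {
            ch[j] <- sample(setdiff(c("A", "C", "G", "T"), ch[j]), 1L)
            qc[j] <- "0"  # Phred+33 for Q15
          }
          seqs[i] <- paste(ch, collapse = "")
          quals[i] <- paste(qc, collapse = "")
        }
        list(seqs, quals)
      }
      r <- inject(seq1, qual1); seq1 <- r[[1]]; qual1 <- r[[2]]
      r <- inject(seq2, qual2); seq2 <- r[[1]]; qual2 <- r[[2]]
    }

    ## adaptor contamination of mate-1 tails
    if (!is.null(p$adaptor) && p$adaptor_frac > 0 && n > 0) {
      na <- floor(p$adaptor_frac * n)
      if (na > 0) {
        idx <- sample.int(n, na)
        alen <- min(nchar(p$adaptor), L)
        seq1[idx] <- paste0(substring(seq1[idx], 1L, L - alen),
                            substring(p$adaptor, 1L, alen))
      }
    }

    glen_of <- glen[comp_all]
    m1_start <- ifelse(str_all == "+", s_all, (s_all + ins_all - L) %% glen_of)
    m2_start <- ifelse(str_all == "+", (s_all + ins_all - L) %% glen_of, s_all)
    truth <- data.frame(
      id = ids, compartment = comp_all, start0 = s_all, insert = ins_all,
      strand = str_all,
      mate1_start0 = as.integer(m1_start),
      mate1_strand = str_all,
      mate2_start0 = as.integer(m2_start),
      mate2_strand = ifelse(str_all == "+", "-", "+"),
      stringsAsFactors = FALSE
    )
    list(pairs = read_pairs(ids, seq1, seq2, qual1, qual2), truth = truth)
  })
}

#' Expected per-compartment depth for a simulation design
#'
#' @param g a [make_genomes()] triple.
#' @param p a [read_sim_params()] list.
#' @return named numeric: expected sequencing depth (layers) per compartment.
#' @export
expected_depths <- function(g, p) {
  glen <- c(plastid = nchar(g$plastid), mito = nchar(g$mito), nuclear = nchar(g$nuclear))
  w <- p$copy_folds[c("plastid", "mito", "nuclear")] * glen
  bases <- 2 * p$read_length * p$total_pairs * w / sum(w)
  bases / glen
}
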