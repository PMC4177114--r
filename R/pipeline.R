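## End-to-end two-step assembly: (A) quality-filter reads, assemble the
## high-depth plastid stratum with high kmer-frequency thresholds, order
## the contigs on the plastid reference, close gaps; (B) remove every
## pair with at least one end exactly matching the assembled plastid,
## assemble the remainder with standard thresholds, order on the
## mitochondrial reference, and close gaps with the strict iterative
## anchored loop (mapping the TOTAL clean reads each cycle — this is what
## lets gaps created by plastid-homologous tracts close). Finishes with
## shared-region masking, unique-region depth statistics, and optional
## variant calls against the references.

#' Assemble a pipeline configuration
#'
#' Every parameter has a default; anything supplied overrides it. The full
#' effective configuration is echoed into the run report so a run is
#' self-describing.
#'
#' @param pairs a [read_pairs()] data.frame, or `NULL` when `fastq1`/
#'   `fastq2` are given.
#' @param fastq1,fastq2 paired FASTQ paths (alternative to `pairs`).
#' @param plastid_ref,mito_ref reference sequences (strings) or FASTA
#'   paths.
#' @param outdir optional output directory for FASTA/TSV/BED artefacts.
#' @param adaptor,max_n_frac,low_q_thresh,max_lowq_frac QC thresholds
#'   (see [qc_filter_pairs()]).
#' @param step1,step2 [assembly_params()] for the plastid and
#'   mitochondrial assemblies. Step 1 defaults to a high kmer-frequency
#'   floor (the depth stratification that suppresses mitochondrial and
#'   nuclear kmers); step 2 uses the standard 41/20/20.
#' @param anchor_k,min_cov scaffold-alignment parameters
#'   (see [align_scaffold()]).
#' @param min_overlap,gap_floor draft-joining parameters
#'   (see [build_draft()]).
#' @param map_seed_k seed size for exact mapping.
#' @param insert_mean,insert_sd fragment-size model for gap closure.
#' @param min_support,max_iter gap-closure voting floor and iteration cap.
#' @param min_run shared-region mask run length (see
#'   [shared_region_mask()]).
#' @param call_variants compare the assembled genomes against their
#'   references and classify the differences.
#' @param seed recorded in the report (the pipeline itself is
#'   deterministic).
#' @return config list, class `tsa_config`.
#' @export
tsa_config <- function(pairs = NULL, fastq1 = NULL, fastq2 = NULL,
                       plastid_ref, mito_ref, outdir = NULL,
                       adaptor = NULL, max_n_frac = 0.10, low_q_thresh = 5L,
                       max_lowq_frac = 0.50,
                       step1 = assembly_params(k = 41L, min_kmer_freq = 100L,
                                               min_edge_cov = 100L,
                                               min_contig_len = 1000L),
                       step2 = assembly_params(k = 41L, min_kmer_freq = 20L,
                                               min_edge_cov = 20L,
                                               min_contig_len = 1000L),
                       anchor_k = 31L, min_cov = 0.5,
                       min_overlap = 30L, gap_floor = 100L,
                       map_seed_k = 21L, insert_mean = 500L, insert_sd = 50L,
                       min_support = 3L, max_iter = 20L, min_run = 100L,
                       call_variants = TRUE, seed = 1L) {
  cfg <- as.list(environment())
  class(cfg) <- "tsa_config"
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' Scalar fields are passed to [tsa_config()] directly; `step1`/`step2`
#' may be maps with `k`, `min_kmer_freq`, `min_edge_cov`,
#' `min_contig_len`.
#'
#' @param path YAML file path.
#' @return config list, class `tsa_config`.
#' @export
read_tsa_config <- function(path) {
  y <- yaml::read_yaml(path)
  for (s in c("step1", "step2")) {
    if (!is.null(y[[s]])) y[[s]] <- do.call(assembly_params, y[[s]])
  }
  do.call(tsa_config, y)
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s': %s", name, conditionMessage(e)),
         call. = FALSE)
  })
}

.as_seq <- function(x) {
  if (length(x) == 1L && file.exists(x)) unname(read_fasta(x)[1L]) else unname(x)
}

#' Run the two-step assembly pipeline
#'
#' @param config a [tsa_config()] list.
#' @return list with `plastid` and `mito` (assembled sequences), `report`
#'   (nested per-stage counts: QC, contigs total/aligned, gap
#'   iterations, residual gaps, lengths, unique-region depths), and
#'   `variants` when requested.
#' @export
run_tsa <- function(config) {
  stopifnot(inherits(config, "tsa_config"))
  cfg <- config
  report <- list(config = cfg[setdiff(names(cfg), c("pairs"))])

  pairs <- .stage("input", {
    if (!is.null(cfg$pairs)) cfg$pairs
    else read_fastq_pairs(cfg$fastq1, cfg$fastq2)
  })
  pt_ref <- .stage("input", .as_seq(cfg$plastid_ref))
  mt_ref <- .stage("input", .as_seq(cfg$mito_ref))

  qc <- .stage("qc", qc_filter_pairs(pairs, adaptor = cfg$adaptor,
                                     max_n_frac = cfg$max_n_frac,
                                     low_q_thresh = cfg$low_q_thresh,
                                     max_lowq_frac = cfg$max_lowq_frac))
  clean <- qc$kept
  report$qc <- list(input_pairs = nrow(pairs), kept_pairs = nrow(clean),
                    discarded = qc$discarded)

  ## -- step A: plastid ------------------------------------------------
  contigsA <- .stage("assemble", {
    cs <- assemble_contigs(clean, cfg$step1)
    if (nrow(cs) == 0L) stop("no contigs assembled from the input reads")
    cs
  })
  alnsA <- .stage("scaffold-mapping", lapply(seq_len(nrow(contigsA)), function(i) {
    align_scaffold(contigsA$sequence[i], pt_ref, anchor_k = cfg$anchor_k,
                   min_cov = cfg$min_cov, circular_ref = TRUE,
                   scaffold_id = contigsA$contig_id[i])
  }))
  n_alignedA <- sum(!vapply(alnsA, is.null, TRUE))
  draftA <- .stage("draft", build_draft(
    alnsA, setNames(contigsA$sequence, contigsA$contig_id), pt_ref,
    min_overlap = cfg$min_overlap, gap_floor = cfg$gap_floor, circular = TRUE))
  gapsA_total <- nrow(draftA$gaps)
  closeA <- .stage("gapclose", close_gaps_iterative(
    draftA, clean, insert_mean = cfg$insert_mean, insert_sd = cfg$insert_sd,
    min_support = cfg$min_support, max_iter = cfg$max_iter,
    seed_k = cfg$map_seed_k))
  plastid <- closeA$draft$sequence
  residA <- n_runs(plastid)
  report$plastid <- list(
    contigs_total = nrow(contigsA), contigs_aligned = n_alignedA,
    gaps_total = gapsA_total, gaps_filled = gapsA_total - nrow(residA),
    residual_gaps = residA, length = nchar(plastid),
    iterations = length(closeA$reports),
    pairs_mapped_by_cycle = vapply(closeA$reports, attr, 0L, "n_pairs_mapped"))

  ## -- step B: mitochondrion ------------------------------------------
  part <- .stage("plastid-read-removal", partition_pairs(
    clean, build_index(c(plastid = plastid), seed_k = cfg$map_seed_k), 0L))
  report$partition <- list(removed_pairs = nrow(part$mapped),
                           retained_pairs = nrow(part$unmapped),
                           retained_fraction = nrow(part$unmapped) / max(1L, nrow(clean)))

  contigsB <- .stage("assemble", {
    cs <- assemble_contigs(part$unmapped, cfg$step2)
    if (nrow(cs) == 0L) stop("no contigs assembled from plastid-depleted reads")
    cs
  })
  alnsB <- .stage("scaffold-mapping", lapply(seq_len(nrow(contigsB)), function(i) {
    align_scaffold(contigsB$sequence[i], mt_ref, anchor_k = cfg$anchor_k,
                   min_cov = cfg$min_cov, circular_ref = TRUE,
                   scaffold_id = contigsB$contig_id[i])
  }))
  n_alignedB <- sum(!vapply(alnsB, is.null, TRUE))
  draftB <- .stage("draft", build_draft(
    alnsB, setNames(contigsB$sequence, contigsB$contig_id), mt_ref,
    min_overlap = cfg$min_overlap, gap_floor = cfg$gap_floor, circular = TRUE))
  gapsB_total <- nrow(draftB$gaps)
  ## strict cycle maps the total clean reads, not the depleted subset
  closeB <- .stage("gapclose", close_gaps_iterative(
    draftB, clean, insert_mean = cfg$insert_mean, insert_sd = cfg$insert_sd,
    min_support = cfg$min_support, max_iter = cfg$max_iter,
    seed_k = cfg$map_seed_k))
  mito <- closeB$draft$sequence
  residB <- n_runs(mito)
  report$mito <- list(
    contigs_total = nrow(contigsB), contigs_aligned = n_alignedB,
    gaps_total = gapsB_total, gaps_filled = gapsB_total - nrow(residB),
    residual_gaps = residB, length = nchar(mito),
    iterations = length(closeB$reports),
    pairs_mapped_by_cycle = vapply(closeB$reports, attr, 0L, "n_pairs_mapped"))

  ## -- depth over unique regions --------------------------------------
  report$depth <- .stage("depth", {
    mask <- shared_region_mask(plastid, mito, min_run = cfg$min_run)
    ## also exclude within-genome repeats (e.g. the IR), where every read
    ## places twice and per-placement counting would inflate depth
    maskA <- rbind(mask$A, repeat_region_mask(plastid, cfg$min_run))
    maskB <- rbind(mask$B, repeat_region_mask(mito, cfg$min_run))
    uA <- unique_regions(maskA, nchar(plastid))
    uB <- unique_regions(maskB, nchar(mito))
    idx <- build_index(c(plastid = plastid, mito = mito), seed_k = cfg$map_seed_k)
    pl <- rbind(map_reads(setNames(clean$seq1, clean$id), idx, 0L),
                map_reads(setNames(clean$seq2, clean$id), idx, 0L))
    regions <- rbind(
      if (nrow(uA)) data.frame(region = "plastid_unique", ref = "plastid",
                               start0 = uA$start0, end0 = uA$end0),
      if (nrow(uB)) data.frame(region = "mito_unique", ref = "mito",
                               start0 = uB$start0, end0 = uB$end0))
    ds <- depth_stats(pl, regions,
                      read_length = as.integer(stats::median(nchar(clean$seq1))))
    agg <- stats::aggregate(cbind(region_length, mapped_reads, mapped_bases) ~ region,
                            data = ds, FUN = sum)
    agg$depth <- sequencing_depth(agg$mapped_bases, agg$region_length)
    agg
  })

  out <- list(plastid = plastid, mito = mito, report = report)

  if (isTRUE(cfg$call_variants)) {
    out$variants <- .stage("variants", list(
      plastid = classify_variants(align_genomes(
        normalize_rotation(plastid, pt_ref), pt_ref, anchor_k = cfg$anchor_k)),
      mito = classify_variants(align_genomes(
        normalize_rotation(mito, mt_ref), mt_ref, anchor_k = cfg$anchor_k))))
  }

  if (!is.null(cfg$outdir)) {
    .stage("output", {
      dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
      write_fasta(c(plastid = plastid, mito = mito),
                  file.path(cfg$outdir, "assembled_genomes.fasta"))
      if (nrow(residB) > 0L) write_bed(residB, "mito",
                                       file.path(cfg$outdir, "residual_gaps_mito.bed"))
      if (nrow(residA) > 0L) write_bed(residA, "plastid",
                                       file.path(cfg$outdir, "residual_gaps_plastid.bed"))
      utils::write.table(report$depth, file.path(cfg$outdir, "depth_unique_regions.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    })
  }
  out
}
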