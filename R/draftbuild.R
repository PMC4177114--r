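## Reference-guided draft construction: place assembled scaffolds on a
## reference by chains of unique exact anchors, order and orient them,
## and join them into one sequence with unresolved spans as runs of N.
## This automates the manual "order scaffolds by reference position and
## connect with overlap information, gaps filled using N" step. Anchors
## are restricted to kmers unique in the reference, so repeat copies
## (e.g. the plastid IR) never produce ambiguous chains; sample-specific
## insertions survive untouched inside scaffolds because the reference is
## used only for ordering.

## Longest strictly-increasing subsequence (indices), O(n log n).
.lis <- function(v) {
  n <- length(v)
  if (n == 0L) return(integer(0))
  tails <- integer(0)      # indices into v of the smallest tail per length
  prev <- integer(n)
  for (i in seq_len(n)) {
    lo <- 1L; hi <- length(tails) + 1L
    while (lo < hi) {       # first position with v[tails[pos]] >= v[i]
      mid <- (lo + hi) %/% 2L
      if (v[tails[mid]] < v[i]) lo <- mid + 1L else hi <- mid
    }
    prev[i] <- if (lo > 1L) tails[lo - 1L] else 0L
    tails[lo] <- i
  }
  out <- integer(length(tails))
  k <- tails[length(tails)]
  for (j in rev(seq_along(tails))) {
    out[j] <- k
    k <- prev[k]
  }
  out
}

#' Align a scaffold to a reference by unique-anchor chaining
#'
#' Collects exact `anchor_k`-mers that are unique in the reference (across
#' both strands) and shared with the scaffold, chains the largest colinear
#' subset per strand (best strand wins; ties broken toward `+`), and
#' reports the implied reference interval. Returns `NULL` when the chained
#' anchors cover less than `min_cov` of the scaffold — the filter that
#' discards non-organellar contigs.
#'
#' @param scaffold scaffold sequence (single string).
#' @param reference reference sequence (single string).
#' @param anchor_k anchor kmer size, at least 15 and odd (default 31).
#' @param min_cov minimum anchored fraction of the scaffold (default 0.5).
#' @param circular_ref treat the reference as circular: chains may run
#'   across the origin (coordinates then exceed the reference length and
#'   are normalised by [build_draft()]).
#' @param scaffold_id identifier carried into the result.
#' @return `NULL`, or an object of class `scaffold_alignment`: list with
#'   `scaffold_id`, `strand`, `ref_start`, `ref_end` (0-based half-open,
#'   extrapolated to the scaffold ends), `coverage`, and `chain`
#'   (data.frame `scaf_pos`, `ref_pos`, `len`).
#' @export
align_scaffold <- function(scaffold, reference, anchor_k = 31L, min_cov = 0.5,
                           circular_ref = FALSE, scaffold_id = "scaffold") {
  anchor_k <- as.integer(anchor_k)
  if (anchor_k < 15L || anchor_k %% 2L == 0L) stop("anchor_k must be odd and >= 15")
  L <- nchar(reference); Ls <- nchar(scaffold)

  rk <- kmer_positions(reference, anchor_k)
  rk <- rk[!grepl("N", rk$kmer, fixed = TRUE)]
  rk[, kmer := canonical_kmer(kmer)]
  cnt <- rk[, .N, by = kmer]
  uniq <- cnt$kmer[cnt$N == 1L]
  rk <- rk[kmer %in% uniq]

  sk <- kmer_positions(scaffold, anchor_k)
  sk <- sk[!grepl("N", sk$kmer, fixed = TRUE)]
  sk_canon <- canonical_kmer(sk$kmer)
  hit <- match(sk_canon, rk$kmer)
  ok <- !is.na(hit)
  if (!any(ok)) return(NULL)
  scaf_pos <- sk$pos0[ok]
  ref_pos <- rk$pos0[hit[ok]]
  ## orientation of the match: same when scaffold kmer orientation relative
  ## to canonical equals the reference kmer's
  ref_fwd_canon <- substring(reference, ref_pos + 1L, ref_pos + anchor_k) == rk$kmer[hit[ok]]
  scaf_fwd_canon <- sk$kmer[ok] == sk_canon[ok]
  same <- ref_fwd_canon == scaf_fwd_canon

  chain_strand <- function(sel, minus) {
    if (!any(sel)) return(NULL)
    o <- scaf_pos[sel]; p <- ref_pos[sel]
    if (minus) o <- Ls - o - anchor_k
    if (circular_ref) {
      o <- c(o, o); p <- c(p, p + L)
    }
    ord <- order(o, -p)
    o <- o[ord]; p <- p[ord]
    idx <- .lis(p)
    ## enforce strictly increasing scaffold positions too
    keep <- c(TRUE, diff(o[idx]) > 0)
    idx <- idx[keep]
    list(o = o[idx], p = p[idx], n = length(idx))
  }
  cp <- chain_strand(same, minus = FALSE)
  cm <- chain_strand(!same, minus = TRUE)
  use_minus <- (if (is.null(cp)) 0L else cp$n) < (if (is.null(cm)) 0L else cm$n)
  ch <- if (use_minus) cm else cp
  if (is.null(ch) || ch$n == 0L) return(NULL)

  cov_r <- IRanges::reduce(IRanges::IRanges(ch$o + 1L, width = anchor_k))
  coverage <- sum(IRanges::width(cov_r)) / Ls
  if (coverage < min_cov) return(NULL)

  structure(list(
    scaffold_id = scaffold_id,
    strand = if (use_minus) "-" else "+",
    ref_start = ch$p[1L] - ch$o[1L],
    ref_end = ch$p[ch$n] + Ls - ch$o[ch$n],
    coverage = coverage,
    chain = data.frame(scaf_pos = ch$o, ref_pos = ch$p, len = anchor_k)
  ), class = "scaffold_alignment")
}

#' Build an N-gapped draft genome from aligned scaffolds
#'
#' Scaffolds are sorted by reference position and strand-normalised.
#' Adjacent scaffolds are joined seamlessly when their ends share an exact
#' overlap of at least `min_overlap` bases; otherwise they are joined with
#' a run of N sized by the reference-implied distance (but never fewer
#' than `gap_floor` Ns, since the true distance in the sample is only
#' estimated by the reference). With `circular = TRUE`, uncovered
#' reference sequence between the last and first scaffold becomes a
#' trailing gap (or, when the ends overlap exactly, the circle is sealed).
#'
#' @param alignments list of [align_scaffold()] results (NULLs are
#'   dropped).
#' @param scaffolds named character vector of scaffold sequences, keyed by
#'   `scaffold_id`.
#' @param reference the reference sequence used for the alignments.
#' @param min_overlap minimum exact end overlap for a seamless join
#'   (default 30).
#' @param gap_floor minimum N-run length for an unresolved join
#'   (default 100).
#' @param circular treat the reference (and draft) as circular.
#' @return an object of class `draft_genome`: list with `sequence`, `gaps`
#'   (data.frame `start0`, `end0`, `provenance`), `layout` (data.frame
#'   `scaffold_id`, `strand`, `draft_start0`, `draft_end0`), `circular`,
#'   `sealed` (TRUE when a circular draft closed on itself), `ref_length`.
#' @export
build_draft <- function(alignments, scaffolds, reference, min_overlap = 30L,
                        gap_floor = 100L, circular = FALSE) {
  alignments <- Filter(Negate(is.null), alignments)
  if (length(alignments) == 0L) stop("no aligned scaffolds to build from")
  L <- nchar(reference)

  starts <- vapply(alignments, `[[`, 0, "ref_start")
  spans <- vapply(alignments, `[[`, 0, "ref_end") - starts
  ## rotate the reference frame so no scaffold straddles the origin
  shift <- 0
  if (circular) {
    wraps <- which(starts < 0 | (starts %% L) + spans > L)
    if (length(wraps) > 0L) shift <- starts[wraps[1L]] %% L
  }
  nstart <- if (circular) (starts - shift) %% L else starts
  ord <- order(nstart)
  alignments <- alignments[ord]
  nstart <- nstart[ord]; spans <- spans[ord]
  nend <- nstart + spans

  ## conflict surfacing: one interval contained in another is ambiguous
  for (i in seq_along(alignments)[-1L]) {
    if (nend[i] <= nend[i - 1L]) {
      stop(sprintf(
        "ambiguity error: scaffolds %s and %s claim the same reference interval",
        alignments[[i - 1L]]$scaffold_id, alignments[[i]]$scaffold_id))
    }
  }

  seq_of <- function(a) {
    s <- scaffolds[[a$scaffold_id]]
    if (a$strand == "-") revcomp(s) else s
  }

  ## largest verified exact suffix(A)/prefix(B) overlap, 0 if none
  end_overlap <- function(A, B, minimum) {
    if (nchar(A) < minimum || nchar(B) < minimum) return(0L)
    probe <- substring(B, 1L, minimum)
    hits <- gregexpr(probe, A, fixed = TRUE)[[1L]]
    if (hits[1L] == -1L) return(0L)
    for (pos in hits) {                       # ascending pos = descending overlap
      o <- nchar(A) - pos + 1L
      if (o > nchar(B)) next
      if (substring(A, pos, nchar(A)) == substring(B, 1L, o)) return(o)
    }
    0L
  }

  draft <- seq_of(alignments[[1L]])
  layout <- data.frame(scaffold_id = alignments[[1L]]$scaffold_id,
                       strand = alignments[[1L]]$strand,
                       draft_start0 = 0L, draft_end0 = nchar(draft),
                       stringsAsFactors = FALSE)
  gap_prov <- list()
  ref_cursor <- nend[1L]

  for (i in seq_along(alignments)[-1L]) {
    B <- seq_of(alignments[[i]])
    o <- end_overlap(draft, B, min_overlap)
    if (o > 0L) {
      start_b <- nchar(draft) - o
      draft <- paste0(draft, substring(B, o + 1L))
    } else {
      implied <- nstart[i] - ref_cursor
      g <- max(as.integer(implied), gap_floor)
      gap_prov[[length(gap_prov) + 1L]] <-
        data.frame(start0 = nchar(draft), end0 = nchar(draft) + g,
                   provenance = "inter-scaffold", stringsAsFactors = FALSE)
      start_b <- nchar(draft) + g
      draft <- paste0(draft, strrep("N", g), B)
    }
    layout <- rbind(layout, data.frame(
      scaffold_id = alignments[[i]]$scaffold_id, strand = alignments[[i]]$strand,
      draft_start0 = start_b, draft_end0 = start_b + nchar(B),
      stringsAsFactors = FALSE))
    ref_cursor <- max(ref_cursor, nend[i])
  }

  sealed <- FALSE
  if (circular) {
    first_seq <- seq_of(alignments[[1L]])
    o <- end_overlap(draft, first_seq, min_overlap)
    covered <- ref_cursor - nstart[1L]
    if (o > 0L && covered >= L - o) {
      ## ends meet: trim the duplicated overlap and seal the circle
      draft <- substring(draft, 1L, nchar(draft) - o)
      sealed <- TRUE
    } else {
      g <- max(as.integer(L - covered), gap_floor)
      gap_prov[[length(gap_prov) + 1L]] <-
        data.frame(start0 = nchar(draft), end0 = nchar(draft) + g,
                   provenance = "unfilled", stringsAsFactors = FALSE)
      draft <- paste0(draft, strrep("N", g))
    }
  }

  gaps <- n_runs(draft)
  gaps$provenance <- rep("unfilled", nrow(gaps))
  if (length(gap_prov) > 0L) {
    gp <- do.call(rbind, gap_prov)
    m <- match(gaps$start0, gp$start0)
    gaps$provenance[!is.na(m)] <- gp$provenance[m[!is.na(m)]]
  }

  structure(list(sequence = draft, gaps = gaps, layout = layout,
                 circular = circular, sealed = sealed, ref_length = L),
            class = "draft_genome")
}

#' @export
print.draft_genome <- function(x, ...) {
  cat(sprintf("<draft_genome> %d nt, %d gap(s) (%d N), %d scaffold(s), circular=%s sealed=%s\n",
              nchar(x$sequence), nrow(x$gaps), sum(x$gaps$end0 - x$gaps$start0),
              nrow(x$layout), x$circular, x$sealed))
  invisible(x)
}
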