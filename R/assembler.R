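## Depth-stratified de Bruijn assembly. The graph is built on canonical
## kmers (strand-symmetric); kmers below a frequency floor and edges below
## a coverage floor are dropped, which is the mechanism that isolates the
## high-depth plastid stratum from ~20x-lower mitochondrial and ~2000x-
## lower nuclear reads. Output is unitigs only: maximal non-branching
## paths, no bubble popping or tip clipping, so the behaviour of the two
## thresholds stays auditable.

#' Assembly parameters
#'
#' @param k kmer size; must be odd (so no kmer is its own reverse
#'   complement) and at least 15. Default 41.
#' @param min_kmer_freq minimum canonical kmer count to enter the graph
#'   (default 20).
#' @param min_edge_cov minimum (k+1)-mer count supporting an edge
#'   (default 20).
#' @param min_contig_len minimum contig length to report (default 1000).
#' @return validated parameter list, class `assembly_params`.
#' @export
assembly_params <- function(k = 41L, min_kmer_freq = 20L, min_edge_cov = 20L,
                            min_contig_len = 1000L) {
  k <- as.integer(k)
  if (k < 15L || k %% 2L == 0L) stop("k must be odd and >= 15")
  stopifnot(min_kmer_freq >= 1L, min_edge_cov >= 1L, min_contig_len >= 1L)
  structure(list(k = k, min_kmer_freq = as.integer(min_kmer_freq),
                 min_edge_cov = as.integer(min_edge_cov),
                 min_contig_len = as.integer(min_contig_len)),
            class = "assembly_params")
}

#' Count canonical kmers in reads
#'
#' Counts are over canonical kmers (the lexicographic minimum of a kmer
#' and its reverse complement); kmers containing N are skipped.
#'
#' @param reads a [read_pairs()] data.frame, or a character vector of
#'   sequences.
#' @param k kmer size; must not exceed the read length.
#' @return data.frame with columns `kmer` (canonical) and `count`, sorted
#'   by kmer.
#' @examples
#' count_kmers(c("AAAAA"), k = 15)  # empty: reads shorter than k
#' @export
count_kmers <- function(reads, k) {
  seqs <- if (inherits(reads, "read_pairs") || is.data.frame(reads)) {
    c(reads$seq1, reads$seq2)
  } else as.character(reads)
  if (length(seqs) > 0 && k > max(nchar(seqs))) {
    stop("parameter error: k exceeds the read length")
  }
  km <- extract_kmers(seqs, k)
  if (length(km) == 0L) {
    return(data.frame(kmer = character(0), count = integer(0)))
  }
  dt <- data.table::data.table(kmer = km)[, .N, by = kmer]
  dt <- dt[!grepl("N", kmer, fixed = TRUE)]
  if (nrow(dt) == 0L) return(data.frame(kmer = character(0), count = integer(0)))
  dt[, kmer := canonical_kmer(kmer)]
  dt <- dt[, list(count = sum(N)), by = kmer]
  data.table::setkey(dt, kmer)
  out <- as.data.frame(dt)
  names(out) <- c("kmer", "count")
  out
}

## Oriented adjacency of the thresholded graph. Nodes are canonical kmers
## (index into `nodes`); each node has two orientations: 1 = canonical
## string, 2 = its reverse complement. Returns a matrix of successor
## encodings, 0 = none; encoding = node_index * 2 - (orientation == 1).
.debruijn_adjacency <- function(nodes, nodes_rc, edge_set, k) {
  n <- length(nodes)
  oriented <- c(nodes, nodes_rc)                  # index i: +, n+i: -
  suff <- substring(oriented, 2L, k)
  bases <- c("A", "C", "G", "T")
  cand <- paste0(rep(suff, each = 4L), bases)     # 8n candidates
  edge_str <- paste0(rep(oriented, each = 4L), bases)
  cand_canon <- canonical_kmer(cand)
  node_idx <- match(cand_canon, nodes)            # NA if target absent
  edge_ok <- canonical_kmer(edge_str) %in% edge_set
  ok <- !is.na(node_idx) & edge_ok
  orient <- ifelse(cand == nodes[node_idx], 1L, 2L)
  enc <- integer(length(cand))
  enc[ok] <- node_idx[ok] * 2L - (orient[ok] == 1L)
  matrix(enc, nrow = 4L)                          # column j = oriented node j
}

## Decode successor encoding to (node, orientation).
.dec_node <- function(enc) (enc + 1L) %/% 2L
.dec_orient <- function(enc) 2L - (enc %% 2L)     # enc odd -> orientation 1

#' Assemble unitig contigs from reads
#'
#' Builds the canonical de Bruijn graph on kmers with count at least
#' `min_kmer_freq`, removes edges whose (k+1)-mer support is below
#' `min_edge_cov`, and emits maximal non-branching paths (unitigs). A
#' contig whose first and last (k-1)-mers coincide because it closed a
#' cycle is reported circular with the duplicated overlap trimmed.
#' Output order is deterministic: length descending, then sequence.
#'
#' @param reads a [read_pairs()] data.frame or character vector.
#' @param params an [assembly_params()] list.
#' @return an object of class `contig_set`: data.frame with columns
#'   `contig_id`, `sequence`, `length`, `mean_cov` (mean canonical kmer
#'   count along the contig), `circular`.
#' @export
assemble_contigs <- function(reads, params = assembly_params()) {
  stopifnot(inherits(params, "assembly_params"))
  k <- params$k
  empty <- structure(
    data.frame(contig_id = character(0), sequence = character(0),
               length = integer(0), mean_cov = numeric(0), circular = logical(0),
               stringsAsFactors = FALSE),
    class = c("contig_set", "data.frame"))

  seqs <- if (inherits(reads, "read_pairs") || is.data.frame(reads)) {
    c(reads$seq1, reads$seq2)
  } else as.character(reads)
  if (length(seqs) == 0L) return(empty)

  kc <- count_kmers(seqs, k)
  kc <- kc[kc$count >= params$min_kmer_freq, , drop = FALSE]
  if (nrow(kc) == 0L) return(empty)
  ec <- count_kmers(seqs, k + 1L)
  edge_set <- ec$kmer[ec$count >= params$min_edge_cov]

  nodes <- kc$kmer                                # sorted by count_kmers
  counts <- kc$count
  nodes_rc <- revcomp(nodes)
  adj <- .debruijn_adjacency(nodes, nodes_rc, edge_set, k)
  n <- length(nodes)

  outdeg <- colSums(adj != 0L)
  odeg <- function(node, orient) outdeg[node + n * (orient == 2L)]
  indeg <- function(node, orient) outdeg[node + n * (orient == 1L)]  # = outdeg of rc
  succ1 <- function(node, orient) {               # unique successor encoding or 0
    col <- adj[, node + n * (orient == 2L)]
    col <- col[col != 0L]
    if (length(col) == 1L) col else 0L
  }

  visited <- logical(n)
  unitigs <- list()

  in_path <- logical(n)
  walk <- function(node, orient) {
    path_n <- integer(n); path_o <- integer(n)
    len <- 1L; path_n[1L] <- node; path_o[1L] <- orient
    in_path[node] <<- TRUE
    circular <- FALSE
    repeat {
      cur_n <- path_n[len]; cur_o <- path_o[len]
      if (odeg(cur_n, cur_o) != 1L) break
      nx <- succ1(cur_n, cur_o)
      nn <- .dec_node(nx); no <- .dec_orient(nx)
      if (indeg(nn, no) != 1L) break
      if (nn == path_n[1L] && no == path_o[1L]) {  # closed a cycle
        circular <- TRUE
        break
      }
      if (visited[nn] || in_path[nn]) break
      len <- len + 1L; path_n[len] <- nn; path_o[len] <- no
      in_path[nn] <<- TRUE
    }
    in_path[path_n[seq_len(len)]] <<- FALSE
    list(nodes = path_n[seq_len(len)], orients = path_o[seq_len(len)],
         circular = circular)
  }

  emit <- function(w) {
    oriented <- ifelse(w$orients == 1L, nodes[w$nodes], nodes_rc[w$nodes])
    seq <- paste0(oriented[1L],
                  paste(substring(oriented[-1L], k, k), collapse = ""))
    if (w$circular) seq <- substring(seq, 1L, nchar(seq) - (k - 1L))
    visited[w$nodes] <<- TRUE
    unitigs[[length(unitigs) + 1L]] <<-
      list(seq = seq, cov = mean(counts[w$nodes]), circular = w$circular)
  }

  ## linear unitigs: start wherever the walk cannot be extended backwards
  for (i in seq_len(n)) {
    if (visited[i]) next
    for (o in 1:2) {
      ## i/o is a start iff no w with outdeg(w)==1 pointing at it with indeg 1
      if (indeg(i, o) == 1L) {
        pred_enc <- succ1(i, 3L - o)              # unique predecessor, reversed
        if (pred_enc != 0L) {
          pn <- .dec_node(pred_enc); po <- 3L - .dec_orient(pred_enc)
          if (odeg(pn, po) == 1L) next            # extendable backwards: not a start
        }
      }
      if (!visited[i]) emit(walk(i, o))
      break
    }
  }
  ## remaining nodes sit on simple cycles
  for (i in seq_len(n)) {
    if (!visited[i]) emit(walk(i, 1L))
  }

  seqs_out <- vapply(unitigs, `[[`, "", "seq")
  covs <- vapply(unitigs, `[[`, 0, "cov")
  circ <- vapply(unitigs, `[[`, TRUE, "circular")
  ## strand-normalise for determinism
  rc <- revcomp(seqs_out)
  flip <- rc < seqs_out
  seqs_out[flip] <- rc[flip]
  keep <- nchar(seqs_out) >= params$min_contig_len
  seqs_out <- seqs_out[keep]; covs <- covs[keep]; circ <- circ[keep]
  ord <- order(-nchar(seqs_out), seqs_out)
  out <- data.frame(
    contig_id = sprintf("contig%03d", seq_along(ord)),
    sequence = seqs_out[ord], length = nchar(seqs_out[ord]),
    mean_cov = covs[ord], circular = circ[ord], stringsAsFactors = FALSE)
  structure(out, class = c("contig_set", "data.frame"))
}

#' Write contigs as FASTA
#'
#' Headers carry `length=`, `cov=` and `circular=` fields.
#'
#' @param contigs a `contig_set` from [assemble_contigs()].
#' @param path output FASTA path.
#' @export
write_contigs <- function(contigs, path) {
  seqs <- setNames(contigs$sequence,
                   sprintf("%s length=%d cov=%.1f circular=%s",
                           contigs$contig_id, contigs$length,
                           contigs$mean_cov, tolower(contigs$circular)))
  x <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}
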