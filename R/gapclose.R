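## Strict iterative gap closure: map all reads to the draft, keep pairs
## with at least one exactly-mapped end, use the anchored geometry of each
## kept pair to position its unanchored mate over a gap flank, and extend
## the flank base-by-base by strict majority vote. Left and right
## extensions that meet with an exact overlap close the gap; the loop of
## mapping, filtering and extension repeats until no gap extends further.
## Extension never rewrites non-gap draft bases, never writes a base on a
## tied vote, and each productive iteration removes at least one N, so a
## fixpoint is reached in finitely many iterations.

#' Keep read pairs with at least one exactly-mapped end
#'
#' Maps both mates of every pair to the draft with zero mismatches (N in
#' the draft matches nothing) and keeps the pairs with at least one
#' placement. Each kept pair carries its anchor placements.
#'
#' @param pairs a [read_pairs()] data.frame.
#' @param draft a `draft_genome` or a single sequence string.
#' @param seed_k seed size for the underlying [build_index()] (default 21).
#' @return list with `kept` (`read_pairs`), `anchors` (data.frame `id`,
#'   `mate`, `start0`, `strand`), and `n_pairs_mapped`.
#' @export
anchored_pairs <- function(pairs, draft, seed_k = 21L) {
  seqd <- if (inherits(draft, "draft_genome")) draft$sequence else draft
  if (nchar(seqd) == 0L) stop("draft is empty")
  idx <- build_index(c(draft = seqd), seed_k = seed_k)
  m1 <- map_reads(setNames(pairs$seq1, pairs$id), idx, 0L)
  m2 <- map_reads(setNames(pairs$seq2, pairs$id), idx, 0L)
  anchors <- rbind(
    if (nrow(m1)) data.frame(id = m1$read_id, mate = 1L, start0 = m1$start0,
                             strand = m1$strand, stringsAsFactors = FALSE),
    if (nrow(m2)) data.frame(id = m2$read_id, mate = 2L, start0 = m2$start0,
                             strand = m2$strand, stringsAsFactors = FALSE))
  if (is.null(anchors)) anchors <- data.frame(id = character(0), mate = integer(0),
                                              start0 = integer(0), strand = character(0))
  keep <- pairs$id %in% anchors$id
  kept <- pairs[keep, , drop = FALSE]
  rownames(kept) <- NULL
  class(kept) <- c("read_pairs", "data.frame")
  list(kept = kept, anchors = anchors, n_pairs_mapped = sum(keep))
}

## Majority-vote consensus over a set of candidate extension strings.
## Returns the agreed prefix; stops at the first position with a tie,
## with fewer than min_support votes, or without a strict majority.
.vote_consensus <- function(rem, min_support) {
  rem <- rem[nchar(rem) > 0L]
  if (length(rem) < min_support) return("")
  maxlen <- max(nchar(rem))
  mat <- vapply(rem, function(s) {
    c(strsplit(s, "", fixed = TRUE)[[1L]], rep("", maxlen - nchar(s)))
  }, character(maxlen))
  if (is.null(dim(mat))) mat <- matrix(mat, nrow = maxlen)
  out <- character(0)
  for (j in seq_len(maxlen)) {
    votes <- mat[j, ]
    votes <- votes[votes != ""]
    if (length(votes) < min_support) break
    tab <- sort(table(votes), decreasing = TRUE)
    if (tab[1L] * 2L <= length(votes)) break                 # no strict majority
    if (length(tab) > 1L && tab[1L] == tab[2L]) break        # tie: never guess
    out <- c(out, names(tab)[1L])
  }
  paste(out, collapse = "")
}

## Extend one flank. `flank_tail` is the forward-strand sequence ending at
## the gap edge; `voters` are forward-strand candidate sequences. Extends
## rightward; returns the extension string.
.extend_flank <- function(flank_tail, voters, min_support, tip_word, cap) {
  ext <- ""
  if (length(voters) == 0L) return(ext)
  repeat {
    cur <- paste0(flank_tail, ext)
    if (nchar(cur) < tip_word) break
    tip <- substring(cur, nchar(cur) - tip_word + 1L, nchar(cur))
    if (grepl("N", tip, fixed = TRUE)) break
    pos <- regexpr(tip, voters, fixed = TRUE)
    hit <- which(pos > 0L)
    if (length(hit) < min_support) break
    rem <- substring(voters[hit], pos[hit] + tip_word)
    add <- .vote_consensus(rem, min_support)
    if (nchar(add) == 0L) break
    ext <- paste0(ext, add)
    if (nchar(ext) >= cap) { ext <- substring(ext, 1L, cap); break }
  }
  ext
}

## Find an exact merge between the left-extended and right-extended
## strings. SL ends with the left extension; SR starts with the right
## extension (lengths la = retained flank prefix of SL, lr = length of the
## right extension within SR). Returns NULL or list(j, t_end) positions.
.find_merge <- function(SL, SR, la, lr, k_check) {
  if (nchar(SL) < k_check || nchar(SR) < k_check) return(NULL)
  j_lo <- max(k_check, la - 50L)
  for (j in seq(nchar(SL), j_lo, by = -1L)) {
    w <- substring(SL, j - k_check + 1L, j)
    if (grepl("N", w, fixed = TRUE)) next
    p <- regexpr(w, SR, fixed = TRUE)
    if (p < 0L) next
    t_end <- p + k_check - 1L
    o2 <- min(j, t_end)
    if (substring(SL, j - o2 + 1L, j) == substring(SR, t_end - o2 + 1L, t_end)) {
      return(list(j = j, t_end = t_end))
    }
  }
  NULL
}

#' Extend gap flanks by anchored-mate voting
#'
#' For each gap, collects the unanchored mates whose anchored partner
#' places them over a flank (anchor position +/- insert_mean +/- 3 SD,
#' inward orientation), and extends each flank base-by-base by strict
#' majority vote with a support floor. When the two extensions meet with
#' an exact overlap of at least `k_check` bases the gap closes and its Ns
#' disappear; otherwise the N run shrinks by the extended amounts. For a
#' circular draft the trailing gap's right flank is the draft's start.
#'
#' @param draft a `draft_genome` (or sequence string).
#' @param anchored result of [anchored_pairs()].
#' @param insert_mean,insert_sd fragment-size model used to window the
#'   unanchored mate (window: expected position +/- 3 SD).
#' @param min_support minimum votes per extended base (default 3).
#' @param k_check exact overlap needed to declare two extensions merged
#'   (default 25).
#' @param tip_word flank tip length used to register a voter (default 21).
#' @return list with `draft` (updated) and `report`: data.frame per gap
#'   (`gap_start0`, `gap_len`, `ext_left`, `ext_right`, `closed`).
#' @export
extend_gaps <- function(draft, anchored, insert_mean = 500L, insert_sd = 50L,
                        min_support = 3L, k_check = 25L, tip_word = 21L) {
  S <- if (inherits(draft, "draft_genome")) draft$sequence else draft
  circular <- inherits(draft, "draft_genome") && isTRUE(draft$circular)
  gaps <- n_runs(S)
  if (nrow(gaps) == 0L) {
    rep0 <- data.frame(gap_start0 = integer(0), gap_len = integer(0),
                       ext_left = integer(0), ext_right = integer(0),
                       closed = logical(0))
    return(list(draft = draft, report = rep0))
  }
  anchors <- anchored$anchors
  kept <- anchored$kept
  ctx <- max(300L, insert_mean)

  ## per-anchor partner geometry (precomputed once per call)
  voters_all <- NULL
  if (nrow(anchors) > 0L && nrow(kept) > 0L) {
    row <- match(anchors$id, kept$id)
    pseq <- ifelse(anchors$mate == 1L, kept$seq2[row], kept$seq1[row])
    plen <- nchar(pseq)
    e <- ifelse(anchors$strand == "+",
                anchors$start0 + insert_mean - plen,
                anchors$start0 - insert_mean + plen)
    fwd <- ifelse(anchors$strand == "+", revcomp(pseq), pseq)
    partner_key <- paste(anchors$id, 3L - anchors$mate)
    anchored_keys <- unique(paste(anchors$id, anchors$mate))
    un <- !(partner_key %in% anchored_keys)
    voters_all <- data.frame(seq = fwd[un], e = e[un], len = plen[un],
                             stringsAsFactors = FALSE)
    voters_all <- unique(voters_all)
  }
  slack <- 3 * insert_sd

  report <- list()
  segments <- list()   # rebuilt sequence pieces
  cursor <- 0L         # 0-based position up to which S is consumed
  pieces <- character(0)
  trim_front <- 0L
  sealed <- inherits(draft, "draft_genome") && isTRUE(draft$sealed)

  for (gi in seq_len(nrow(gaps))) {
    gs <- gaps$start0[gi]; ge <- gaps$end0[gi]
    g <- ge - gs
    is_trailing <- circular && ge == nchar(S)

    voters <- character(0)
    if (!is.null(voters_all) && nrow(voters_all) > 0L) {
      lo <- voters_all$e - slack
      hi <- voters_all$e + slack + voters_all$len
      ## window may wrap for circular drafts near the ends
      near <- hi >= gs - voters_all$len & lo <= ge + voters_all$len
      if (is_trailing) near <- near | (lo <= voters_all$len + slack)  # wrap to start
      voters <- voters_all$seq[near]
    }

    flank_tail <- substring(S, max(1L, gs - ctx + 1L), gs)
    nrun <- gregexpr("N", flank_tail, fixed = TRUE)[[1L]]
    if (nrun[1L] != -1L) flank_tail <- substring(flank_tail, max(nrun) + 1L)
    head_src <- if (is_trailing) substring(S, 1L, ctx) else
      substring(S, ge + 1L, min(nchar(S), ge + ctx))
    hrun <- gregexpr("N", head_src, fixed = TRUE)[[1L]]
    if (hrun[1L] != -1L) head_src <- substring(head_src, 1L, min(hrun) - 1L)

    cap <- g + insert_mean
    lx <- .extend_flank(flank_tail, voters, min_support, tip_word, cap)
    rx_rc <- .extend_flank(revcomp(head_src), revcomp(voters), min_support, tip_word, cap)
    rx <- revcomp(rx_rc)
    if (nchar(rx) == 0L) rx <- ""

    SL <- paste0(flank_tail, lx)
    SR <- paste0(rx, head_src)
    mg <- .find_merge(SL, SR, nchar(flank_tail), nchar(rx), k_check)

    closed <- FALSE
    if (!is.null(mg)) {
      closed <- TRUE
      fill_left <- if (mg$j > nchar(flank_tail))
        substring(SL, nchar(flank_tail) + 1L, mg$j) else ""
      trimA <- max(0L, nchar(flank_tail) - mg$j)
      fill_right <- if (mg$t_end < nchar(rx))
        substring(SR, mg$t_end + 1L, nchar(rx)) else ""
      trimB <- max(0L, mg$t_end - nchar(rx))
      repl <- paste0(fill_left, fill_right)
      if (is_trailing) {
        ## circle sealed: duplicated head bases are trimmed off the front
        pieces <- c(pieces, substring(S, cursor + 1L,
                                      gs - trimA), repl)
        trim_front <- trimB
        sealed <- TRUE
        cursor <- nchar(S)
      } else {
        pieces <- c(pieces, substring(S, cursor + 1L, gs - trimA), repl)
        cursor <- ge + trimB
      }
    } else {
      resid <- if (nchar(lx) + nchar(rx) > 0L)
        max(g - nchar(lx) - nchar(rx), 100L) else g
      repl <- paste0(lx, strrep("N", resid), rx)
      pieces <- c(pieces, substring(S, cursor + 1L, gs), repl)
      cursor <- ge
    }
    report[[gi]] <- data.frame(gap_start0 = gs, gap_len = g,
                               ext_left = nchar(lx), ext_right = nchar(rx),
                               closed = closed)
  }
  pieces <- c(pieces, substring(S, cursor + 1L, nchar(S)))
  newS <- paste(pieces, collapse = "")
  if (trim_front > 0L) newS <- substring(newS, trim_front + 1L)

  newdraft <- if (inherits(draft, "draft_genome")) {
    draft$sequence <- newS
    g2 <- n_runs(newS)
    g2$provenance <- rep("unfilled", nrow(g2))
    draft$gaps <- g2
    draft$sealed <- sealed
    draft
  } else newS
  list(draft = newdraft, report = do.call(rbind, report))
}

#' Iterate mapping, filtering and gap filling to a fixpoint
#'
#' Alternates [anchored_pairs()] and [extend_gaps()] until an iteration
#' extends nothing anywhere (the global fixpoint) or `max_iter` is hit.
#'
#' @param draft a `draft_genome` (or sequence string).
#' @param pairs the read pairs to map each cycle (the total clean reads:
#'   mapping to the draft is what selects the usable ones).
#' @param insert_mean,insert_sd fragment-size model.
#' @param min_support minimum votes per extended base.
#' @param max_iter iteration cap (default 20); reaching it with nonzero
#'   extension warns but does not fail.
#' @param seed_k seed size for mapping.
#' @param k_check,tip_word see [extend_gaps()].
#' @return list with `draft` (final), `reports` (list of per-iteration
#'   data.frames, each with attributes `n_pairs_mapped`).
#' @export
close_gaps_iterative <- function(draft, pairs, insert_mean = 500L, insert_sd = 50L,
                                 min_support = 3L, max_iter = 20L, seed_k = 21L,
                                 k_check = 25L, tip_word = 21L) {
  reports <- list()
  it <- 0L
  repeat {
    S <- if (inherits(draft, "draft_genome")) draft$sequence else draft
    if (nrow(n_runs(S)) == 0L) break
    it <- it + 1L
    if (it > max_iter) {
      warning("iteration cap reached with gaps remaining")
      break
    }
    anc <- anchored_pairs(pairs, draft, seed_k = seed_k)
    res <- extend_gaps(draft, anc, insert_mean = insert_mean,
                       insert_sd = insert_sd, min_support = min_support,
                       k_check = k_check, tip_word = tip_word)
    draft <- res$draft
    rep_i <- res$report
    attr(rep_i, "n_pairs_mapped") <- anc$n_pairs_mapped
    reports[[it]] <- rep_i
    if (sum(rep_i$ext_left + rep_i$ext_right) == 0L && !any(rep_i$closed)) break
  }
  list(draft = draft, reports = reports)
}
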