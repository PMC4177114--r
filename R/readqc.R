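## Read-pair cleaning. A pair is discarded whole if EITHER mate contains
## the adaptor, has more than 10% unknown bases (N), or has more than 50%
## low-quality (< Q5) bases. Thresholds are strict inequalities ("more
## than"); kept pairs are unmodified (no trimming).

#' Quality-filter read pairs
#'
#' Applies the three discard rules in fixed order — adaptor, N fraction,
#' low-quality fraction — attributing each discarded pair to the first
#' rule that fails on either mate. Adaptor detection is an exact substring
#' match of the full adaptor (and its reverse complement); a shorter
#' minimum prefix match may be enabled via `min_adaptor_match`.
#'
#' @param pairs a [read_pairs()] data.frame.
#' @param adaptor adaptor sequence, or `NULL` to skip the adaptor rule.
#' @param max_n_frac discard when N fraction exceeds this (strict; default 0.10).
#' @param low_q_thresh Phred score counted as low quality when below this
#'   (strict; default 5).
#' @param max_lowq_frac discard when the low-quality base fraction exceeds
#'   this (strict; default 0.50).
#' @param min_adaptor_match minimum adaptor prefix length to count as a
#'   hit; `NULL` (default) requires the full adaptor.
#' @return list with `kept` (a `read_pairs` data.frame) and `discarded`
#'   (named counts: adaptor, n_bases, low_quality).
#' @examples
#' p <- read_pairs("r1", strrep("A", 100), strrep("C", 100))
#' qc_filter_pairs(p)$discarded
#' @export
qc_filter_pairs <- function(pairs, adaptor = NULL, max_n_frac = 0.10,
                            low_q_thresh = 5L, max_lowq_frac = 0.50,
                            min_adaptor_match = NULL) {
  stopifnot(max_n_frac >= 0, max_n_frac <= 1, max_lowq_frac >= 0, max_lowq_frac <= 1)
  n <- nrow(pairs)
  counts <- c(adaptor = 0L, n_bases = 0L, low_quality = 0L)
  if (n == 0L) return(list(kept = pairs, discarded = counts))

  has_adaptor <- rep(FALSE, n)
  if (!is.null(adaptor) && nzchar(adaptor)) {
    probe <- if (is.null(min_adaptor_match)) adaptor else
      substring(adaptor, 1L, min(min_adaptor_match, nchar(adaptor)))
    hit <- function(s) grepl(probe, s, fixed = TRUE) | grepl(revcomp(probe), s, fixed = TRUE)
    has_adaptor <- hit(pairs$seq1) | hit(pairs$seq2)
  }

  nfrac <- function(s) {
    vapply(gregexpr("N", s, fixed = TRUE),
           function(m) if (m[1] == -1L) 0L else length(m), 0L) / nchar(s)
  }
  too_n <- nfrac(pairs$seq1) > max_n_frac | nfrac(pairs$seq2) > max_n_frac

  lowq <- function(q) {
    vapply(phred_decode(q), function(v) mean(v < low_q_thresh), 0)
  }
  too_lowq <- lowq(pairs$qual1) > max_lowq_frac | lowq(pairs$qual2) > max_lowq_frac

  reason <- rep(NA_character_, n)
  reason[too_lowq] <- "low_quality"
  reason[too_n] <- "n_bases"
  reason[has_adaptor] <- "adaptor"

  tab <- table(factor(reason, levels = c("adaptor", "n_bases", "low_quality")))
  counts[] <- as.integer(tab)
  kept <- pairs[is.na(reason), , drop = FALSE]
  rownames(kept) <- NULL
  class(kept) <- c("read_pairs", "data.frame")
  list(kept = kept, discarded = counts)
}
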