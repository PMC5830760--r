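#' Sliding-window quality filter for read pairs
#'
#' A pair is dropped when, in either mate, any contiguous window of mean
#' Phred quality falls below `score_limit`.  The window length is
#' `max(1, round(window_frac * read_length))`, computed per mate.  Reads
#' are never truncated: the whole pair is kept or dropped.
#'
#' @param pairs a `rad_pairs` data frame.
#' @param window_frac window size as a fraction of the read length.
#' @param score_limit Phred score limit for the window mean.
#' @return logical vector, `TRUE` for pairs to keep.
#' @export
filter_quality <- function(pairs, window_frac = 0.1, score_limit = 13) {
  stopifnot(window_frac > 0, window_frac <= 1)
  ok_one <- function(qstr) {
    q <- utf8ToInt(qstr) - 33L
    n <- length(q)
    w <- max(1L, as.integer(round(window_frac * n)))
    cs <- cumsum(c(0L, q))
    means <- (cs[(w + 1L):(n + 1L)] - cs[1:(n - w + 1L)]) / w
    all(means >= score_limit)
  }
  vapply(seq_len(nrow(pairs)), function(i) {
    ok_one(pairs$fwd_qual[i]) && ok_one(pairs$rev_qual[i])
  }, logical(1))
}

#' Restriction-site retention filter
#'
#' Keeps a pair iff its forward read starts with the enzyme remnant,
#' allowing up to `allowed_mismatch` mismatches.  The default remnant
#' `TGCAGG` is what SbfI (CCTGCA^GG) leaves at the 5' end of forward reads.
#'
#' @param pairs a `rad_pairs` data frame.
#' @param remnant the cut-site remnant expected at forward-read starts.
#' @param allowed_mismatch maximum mismatches tolerated in the remnant.
#' @return logical keep vector.
#' @export
check_cut_site <- function(pairs, remnant = "TGCAGG", allowed_mismatch = 0L) {
  stopifnot(nzchar(remnant))
  pre <- substr(pairs$fwd_seq, 1L, nchar(remnant))
  if (allowed_mismatch == 0L) return(pre == remnant)
  vapply(pre, function(p) {
    nchar(p) == nchar(remnant) && .hamming_cpp(p, remnant) <= allowed_mismatch
  }, logical(1), USE.NAMES = FALSE)
}

#' Remove PCR duplicates from one individual's read pairs
#'
#' Among pairs sharing an identical (forward, reverse) sequence pair, only
#' the first encountered is retained (clone_filter semantics: qualities are
#' ignored, the random-sheared reverse end distinguishes true clones from
#' independent fragments).
#'
#' @param pairs a `rad_pairs` data frame from a single individual.
#' @return the surviving pairs, in input order.
#' @export
remove_pcr_duplicates <- function(pairs) {
  keep <- !duplicated(paste(pairs$fwd_seq, pairs$rev_seq, sep = "\r"))
  pairs[keep, , drop = FALSE]
}

#' Full preprocessing of one individual's read pairs
#'
#' Applies, in order: the sliding-window quality filter, the cut-site
#' retention filter, and PCR-duplicate removal.  The two predicate filters
#' are pure per-pair functions, so their order does not affect the result.
#'
#' @param pairs a `rad_pairs` data frame.
#' @inheritParams filter_quality
#' @inheritParams check_cut_site
#' @return list with `pairs` (survivors) and `report` (one-row data frame:
#'   `n_in`, `drop_quality`, `drop_site`, `clones_removed`, `retained`).
#' @export
preprocess_pairs <- function(pairs, window_frac = 0.1, score_limit = 13,
                             remnant = "TGCAGG", allowed_mismatch = 0L) {
  n_in <- nrow(pairs)
  kq <- filter_quality(pairs, window_frac, score_limit)
  p1 <- pairs[kq, , drop = FALSE]
  ks <- check_cut_site(p1, remnant, allowed_mismatch)
  p2 <- p1[ks, , drop = FALSE]
  p3 <- remove_pcr_duplicates(p2)
  list(pairs = p3,
       report = data.frame(n_in = n_in,
                           drop_quality = sum(!kq),
                           drop_site = sum(!ks),
                           clones_removed = nrow(p2) - nrow(p3),
                           retained = nrow(p3)))
}
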