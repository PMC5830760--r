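#' Assembly length statistics
#'
#' N50 is the length of the shortest contig in the smallest set of longest
#' contigs whose summed length reaches half the total.  `N`s count toward
#' length; the mean is rounded to the nearest integer bp.
#'
#' @param contigs character vector of contig sequences, or integer vector
#'   of contig lengths.
#' @return list `n_contigs`, `n50`, `mean_len`, `total_cov`.
#' @export
contig_stats <- function(contigs) {
  if (length(contigs) == 0) stop("no contigs")
  len <- if (is.character(contigs)) nchar(contigs) else as.integer(contigs)
  len <- sort(len, decreasing = TRUE)
  total <- sum(len)
  n50 <- len[which(cumsum(len) >= total / 2)[1]]
  list(n_contigs = length(len), n50 = n50,
       mean_len = as.integer(round(total / length(len))), total_cov = total)
}

#' Re-map read pairs to contigs and score proper pairing
#'
#' Each read is aligned to its best contig position by exact k-mer seeding
#' and full-length ungapped extension; it is mapped when its identity over
#' the full read length reaches `min_identity` (ties break to the lowest
#' contig index).  A pair is properly mapped when both mates map to the
#' same contig in forward/reverse orientation with the plus-strand mate's
#' 5' end not past the minus-strand mate's 3' end and an inferred insert
#' within `insert_range` (ten-N spacer columns count toward the insert,
#' as for a padded reference).
#'
#' @param contigs character vector of contig sequences.
#' @param pairs a `rad_pairs` data frame (typically the pairs used for
#'   assembly).
#' @param k seed k-mer length.
#' @param min_identity minimum full-length identity to call a read mapped.
#' @param insert_range accepted insert-size range (bp), `c(lo, hi)`.
#' @return list `total_mapped_pct` (percent of reads mapped),
#'   `proper_paired_pct` (percent of pairs properly mapped), `n_pairs`,
#'   and the per-mate hit tables `fwd_hits`, `rev_hits`.
#' @export
map_read_pairs <- function(contigs, pairs, k = 21L, min_identity = 0.9,
                           insert_range = c(100L, 1000L)) {
  if (length(contigs) == 0) stop("no contigs")
  n <- nrow(pairs)
  h1 <- .map_reads_cpp(pairs$fwd_seq, contigs, as.integer(k), min_identity)
  h2 <- .map_reads_cpp(pairs$rev_seq, contigs, as.integer(k), min_identity)
  mapped1 <- h1[, "contig"] > 0
  mapped2 <- h2[, "contig"] > 0
  l1 <- nchar(pairs$fwd_seq); l2 <- nchar(pairs$rev_seq)
  same <- mapped1 & mapped2 & h1[, "contig"] == h2[, "contig"]
  fr <- h1[, "strand"] * h2[, "strand"] == -1
  # leftmost coordinate of the plus-strand mate; rightmost of the minus mate
  plus_start <- ifelse(h1[, "strand"] == 1, h1[, "start"], h2[, "start"])
  minus_end <- ifelse(h1[, "strand"] == -1, h1[, "start"] + l1 - 1L,
                      h2[, "start"] + l2 - 1L)
  insert <- minus_end - plus_start + 1L
  proper <- same & fr & !is.na(insert) & plus_start <= minus_end &
    insert >= insert_range[1] & insert <= insert_range[2]
  list(total_mapped_pct = 100 * (sum(mapped1) + sum(mapped2)) / (2 * n),
       proper_paired_pct = 100 * sum(proper, na.rm = TRUE) / n,
       n_pairs = n, fwd_hits = h1, rev_hits = h2)
}

#' Identity of assembled contigs against simulated truth
#'
#' Each contig is matched to its truth locus (by majority vote of its
#' member reads' ground-truth labels, supplied as `truth_locus`) and
#' globally aligned to the truth sequence; for padded contigs the segments
#' on either side of the ten-N spacer are aligned separately so spacer
#' columns are never scored.  A contig is "matched" when at least 80% of
#' its non-N bases match the truth.  Identity is percent of non-N contig
#' bases matching.
#'
#' @param contigs data frame with columns `seq` and `truth_locus` (the
#'   truth `locus_id` each contig derives from, e.g. from
#'   [majority_truth_locus()]).
#' @param truth truth-locus table from [truth_loci()].
#' @return list `pct_contigs_matched`, `mean_identity` (over matched
#'   contigs), and per-contig data frame `per_contig`.
#' @export
truth_identity <- function(contigs, truth) {
  if (is.null(truth)) stop("truth table absent")
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1)
  score_seg <- function(seg, ref) {
    if (nchar(seg) == 0) return(0L)
    al <- Biostrings::pairwiseAlignment(seg, ref, type = "global-local",
                                        substitutionMatrix = mat,
                                        gapOpening = 5, gapExtension = 2)
    Biostrings::nmatch(al)
  }
  res <- lapply(seq_len(nrow(contigs)), function(i) {
    ti <- match(contigs$truth_locus[i], truth$locus_id)
    if (is.na(ti))
      return(data.frame(matched = FALSE, identity = NA_real_))
    ref <- truth$ref_seq[ti]
    segs <- strsplit(contigs$seq[i], "N{10,}")[[1]]
    segs <- segs[nzchar(segs)]
    nonN <- sum(nchar(segs))
    matches <- sum(vapply(segs, score_seg, integer(1), ref = ref))
    data.frame(matched = matches >= 0.8 * nonN,
               identity = 100 * matches / nonN)
  })
  per <- do.call(rbind, res)
  per$cat_id <- contigs$cat_id
  matched <- which(per$matched)
  list(pct_contigs_matched = 100 * length(matched) / nrow(per),
       mean_identity = mean(per$identity[matched]),
       per_contig = per)
}

#' Majority ground-truth locus of each assembled contig
#'
#' @param read_sets locus read sets from [sort_read_pairs()] (read ids must
#'   carry simulator truth labels).
#' @return data frame `cat_id`, `truth_locus`.
#' @export
majority_truth_locus <- function(read_sets) {
  rows <- lapply(read_sets, function(rs) {
    if (nrow(rs$reads) == 0)
      return(data.frame(cat_id = rs$cat_id, truth_locus = NA_integer_))
    lab <- parse_truth_labels(rs$reads$id)
    tab <- table(lab$locus_id)
    data.frame(cat_id = rs$cat_id,
               truth_locus = as.integer(names(tab)[which.max(tab)]))
  })
  do.call(rbind, rows)
}

#' Mean read pairs per individual
#'
#' @param counts integer vector of retained pair counts per individual.
#' @param truncate report the mean truncated to an integer, as in summary
#'   tables.
#' @return the mean (numeric, or truncated integer).
#' @export
mean_pairs_per_individual <- function(counts, truncate = FALSE) {
  stopifnot(length(counts) > 0)
  m <- mean(counts)
  if (truncate) trunc(m) else m
}
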