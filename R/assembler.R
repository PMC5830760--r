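#' Discover suffix-prefix overlaps and containments
#'
#' Ungapped overlap discovery between all pairs of sequences.  For each
#' ordered pair the best suffix(a)-to-prefix(b) overlap of length at least
#' `min_overlap` with mismatch fraction at most `max_mismatch_rate` is
#' reported; full containments of one sequence inside another (at the same
#' mismatch rate over the contained length) are reported with the
#' `contained` flag.  Overlaps are scored `matches - mismatch_penalty *
#' mismatches`.
#'
#' @param seqs character vector of DNA sequences.
#' @param min_overlap minimum dovetail overlap length (bp).
#' @param max_mismatch_rate maximum mismatch fraction within an overlap.
#' @param mismatch_penalty score penalty per mismatch.
#' @return data frame `a`, `b` (1-based indices; `a` is the left or
#'   containing sequence), `length`, `mismatches`, `offset` (of `b` in
#'   `a`), `contained`, `score`.
#' @export
find_overlaps <- function(seqs, min_overlap = 20L, max_mismatch_rate = 0.06,
                          mismatch_penalty = 2L) {
  stopifnot(length(seqs) > 0)
  .find_overlaps_cpp(seqs, as.integer(min_overlap), max_mismatch_rate,
                     as.integer(mismatch_penalty))
}

#' Greedy overlap-layout-consensus assembly
#'
#' Repeatedly merges the highest-scoring remaining overlap (ties: longer
#' overlap, then fewer mismatches, then the smaller index pair), absorbing
#' contained reads, and recomputes each merged consensus by per-column
#' depth-weighted majority (ties to the alphabetically smallest base).
#' Iterates until no eligible overlap remains; singleton reads come back
#' as contigs.  Deterministic for a fixed input order.
#'
#' @inheritParams find_overlaps
#' @return list with `contigs` (character, sorted by length descending),
#'   `assignment` (per input sequence, 1-based contig index) and
#'   `n_reads` (reads per contig).
#' @export
greedy_assemble <- function(seqs, min_overlap = 20L, max_mismatch_rate = 0.06,
                            mismatch_penalty = 2L) {
  stopifnot(length(seqs) > 0)
  .greedy_assemble_cpp(seqs, as.integer(min_overlap), max_mismatch_rate,
                       as.integer(mismatch_penalty))
}

#' Two-step per-locus assembly with ten-N padding
#'
#' Step 1 assembles the locus's reverse-complemented second reads on their
#' own; step 2 re-assembles the step-1 contigs together with the
#' forward-read consensus.  If the final contig containing the consensus
#' absorbed at least one step-1 contig the locus assembled through; if
#' not, the consensus and the longest step-1 contig are concatenated with
#' exactly ten `N`s marking the unsequenced gap.  Step-2 contigs not
#' incorporated into the final contig are dropped (counted in the report).
#'
#' @param second_reads character vector of second reads as sequenced
#'   (reverse-strand); they are reverse-complemented internally so all
#'   assembly happens in genome-forward orientation.
#' @param fwd_consensus forward-read consensus of the locus.
#' @inheritParams find_overlaps
#' @return list `seq`, `padded`, `pad_start` (1-based start of the N run,
#'   `NA` if unpadded), `n_reads`, `n_step1_contigs`, `n_dropped`.
#' @export
two_step_assemble <- function(second_reads, fwd_consensus, min_overlap = 20L,
                              max_mismatch_rate = 0.06, mismatch_penalty = 2L) {
  if (length(second_reads) == 0) stop("empty read set; route consensus-only loci around assembly")
  step1 <- greedy_assemble(revcomp(second_reads), min_overlap,
                           max_mismatch_rate, mismatch_penalty)
  step2_in <- c(fwd_consensus, step1$contigs)
  step2 <- greedy_assemble(step2_in, min_overlap, max_mismatch_rate,
                           mismatch_penalty)
  ci <- step2$assignment[1]              # final contig holding the consensus
  absorbed <- sum(step2$assignment == ci) - 1L
  if (absorbed >= 1L) {
    list(seq = step2$contigs[ci], padded = FALSE, pad_start = NA_integer_,
         n_reads = length(second_reads),
         n_step1_contigs = length(step1$contigs),
         n_dropped = length(step2$contigs) - 1L)
  } else {
    list(seq = paste0(fwd_consensus, strrep("N", 10L), step1$contigs[1]),
         padded = TRUE, pad_start = nchar(fwd_consensus) + 1L,
         n_reads = length(second_reads),
         n_step1_contigs = length(step1$contigs),
         n_dropped = length(step1$contigs) - 1L)
  }
}

#' Assemble every catalog locus
#'
#' Runs the two-step assembly over the locus read sets from
#' [sort_read_pairs()].  Loci marked `consensus_only` bypass assembly and
#' emit their forward consensus, so no catalog locus silently disappears.
#' Per-locus tasks are independent; with `threads > 1` they run on a
#' worker pool and results are re-ordered by `cat_id`, so the thread count
#' never changes the output.  Contigs shorter than `min_contig_len`
#' (applied after padding) are dropped.
#'
#' @param read_sets list of locus read sets from [sort_read_pairs()].
#' @inheritParams find_overlaps
#' @param min_contig_len minimum final contig length (bp).
#' @param threads worker processes for per-locus assembly.
#' @return list with `contigs` (data frame `cat_id`, `seq`, `length`,
#'   `n_reads`, `padded`, `pad_start`, `source`) and `report` (per-locus
#'   data frame incl. `n_step1_contigs`, `n_dropped`, `filtered`).
#' @export
assemble_loci <- function(read_sets, min_overlap = 20L,
                          max_mismatch_rate = 0.06, mismatch_penalty = 2L,
                          min_contig_len = 125L, threads = 1L) {
  one <- function(rs) {
    if (isTRUE(rs$consensus_only) || nrow(rs$reads) == 0) {
      list(cat_id = rs$cat_id, seq = rs$consensus, n_reads = 0L,
           padded = FALSE, pad_start = NA_integer_, source = "consensus_only",
           n_step1_contigs = 0L, n_dropped = 0L)
    } else {
      a <- two_step_assemble(rs$reads$seq, rs$consensus, min_overlap,
                             max_mismatch_rate, mismatch_penalty)
      list(cat_id = rs$cat_id, seq = a$seq, n_reads = a$n_reads,
           padded = a$padded, pad_start = a$pad_start, source = "two_step",
           n_step1_contigs = a$n_step1_contigs, n_dropped = a$n_dropped)
    }
  }
  res <- if (threads > 1L) {
    parallel::mclapply(read_sets, one, mc.cores = threads)
  } else lapply(read_sets, one)
  res <- res[order(vapply(res, `[[`, integer(1), "cat_id"))]
  contigs <- data.frame(
    cat_id = vapply(res, `[[`, integer(1), "cat_id"),
    seq = vapply(res, `[[`, character(1), "seq"),
    n_reads = vapply(res, `[[`, integer(1), "n_reads"),
    padded = vapply(res, `[[`, logical(1), "padded"),
    pad_start = vapply(res, `[[`, integer(1), "pad_start"),
    source = vapply(res, `[[`, character(1), "source"))
  contigs$length <- nchar(contigs$seq)
  report <- data.frame(
    cat_id = contigs$cat_id, n_reads_in = contigs$n_reads,
    n_step1_contigs = vapply(res, `[[`, integer(1), "n_step1_contigs"),
    n_dropped = vapply(res, `[[`, integer(1), "n_dropped"),
    padded = contigs$padded, final_length = contigs$length,
    filtered = contigs$length < min_contig_len)
  list(contigs = contigs[contigs$length >= min_contig_len, , drop = FALSE],
       report = report)
}
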