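#' Choose the optimal within-individual mismatch threshold
#'
#' Clusters one individual's forward reads at every `m` in `m_range` and
#' picks the threshold maximizing the number of loci with two haplotypes
#' (alleles), breaking ties by the smaller number of one-haplotype loci
#' and then by the smaller `m`.  The rationale: in a diploid, a correctly
#' merged polymorphic locus carries exactly two alleles, while
#' over-splitting inflates the one-allele count.
#'
#' @param reads data frame `id`, `seq` of one individual's forward reads.
#' @param m_range integer range of thresholds to scan.
#' @param min_depth minimum stack depth.
#' @param max_stacks repeat-flagging component size.
#' @param removal lumberjack-stack removal (off by default during
#'   scanning, matching plain clustering runs).
#' @return list `m_opt` and `curve` (data frame `m`, `n_loci_1hap`,
#'   `n_loci_2hap`, `n_loci`).
#' @export
select_within <- function(reads, m_range = 1:10, min_depth = 5L,
                          max_stacks = 3L, removal = FALSE) {
  stopifnot(length(m_range) > 0)
  if (nrow(reads) == 0) stop("no reads")
  st <- build_stacks(reads, min_depth)
  curve <- lapply(m_range, function(m) {
    mg <- merge_stacks(st$primary, m, max_stacks, removal)
    data.frame(m = m,
               n_loci_1hap = sum(mg$loci$haplotypes == 1L),
               n_loci_2hap = sum(mg$loci$haplotypes == 2L),
               n_loci = nrow(mg$loci))
  })
  curve <- do.call(rbind, curve)
  best <- order(-curve$n_loci_2hap, curve$n_loci_1hap, curve$m)[1]
  list(m_opt = curve$m[best], curve = curve)
}

#' Choose the optimal across-individual mismatch threshold
#'
#' For each candidate `n`, individuals' locus sets are merged sequentially
#' into a catalog and the number of new catalog loci contributed by each
#' successive individual (the increment) is recorded.  Let `delta(n)` be
#' the mean increment over individuals 2..k.  The optimum is the smallest
#' `n` from which the curve has settled at its inflection: every
#' consecutive relative drop `(delta(n') - delta(n'+1)) / delta(n')` for
#' `n' >= n` within the range stays below `tau` (a `delta` of zero always
#' qualifies outright).  If no `n` qualifies, the maximum of the range is
#' returned with a warning.
#'
#' @param per_individual_loci list (one per individual, merge order =
#'   list order) of locus consensus character vectors.
#' @param n_range integer range of thresholds to scan.
#' @param tau relative-drop tolerance defining "changed little".
#' @return list `n_opt` and `curve` (data frame `n`, `delta`, plus a
#'   list-column `increments`).
#' @export
select_across <- function(per_individual_loci, n_range = 1:8, tau = 0.05) {
  stopifnot(length(n_range) > 0)
  k <- length(per_individual_loci)
  if (k < 2) stop("need at least two individuals")
  n_range <- sort(n_range)
  cats <- lapply(n_range, function(n) build_catalog(per_individual_loci, n))
  curve <- data.frame(n = n_range,
                      delta = vapply(cats, function(x) mean(x$increments[-1]),
                                     numeric(1)))
  curve$increments <- lapply(cats, `[[`, "increments")
  K <- nrow(curve)
  rel_drop <- ifelse(curve$delta[-K] == 0, 0,
                     (curve$delta[-K] - curve$delta[-1]) / curve$delta[-K])
  n_opt <- NA_integer_
  for (i in seq_len(K)) {
    settled <- if (curve$delta[i] == 0) TRUE
               else if (i == K) FALSE
               else all(rel_drop[i:(K - 1)] < tau)
    if (settled) { n_opt <- curve$n[i]; break }
  }
  if (is.na(n_opt)) {
    warning("no inflection point found in n_range; returning its maximum")
    n_opt <- max(n_range)
  }
  list(n_opt = n_opt, curve = curve)
}

#' Seeded subsample of individuals for across-threshold scanning
#'
#' @param individuals character vector (or list) of individuals.
#' @param k number to keep.
#' @param seed RNG seed.
#' @return the subsample, in original order.
#' @export
subsample_individuals <- function(individuals, k, seed = 1L) {
  if (k >= length(individuals)) return(individuals)
  idx <- with_seed(seed, sort(sample(seq_along(individuals), k)))
  individuals[idx]
}
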