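#' Pile identical forward reads into stacks
#'
#' Reads are grouped by exact sequence identity (all reads must share one
#' length); groups reaching `min_depth` become primary stacks, the rest
#' secondary.  Stacks are ordered by first occurrence of their sequence.
#'
#' @param reads data frame with columns `id`, `seq`.
#' @param min_depth minimum depth to create a (primary) stack.
#' @return list of two data frames `primary` and `secondary`, each with
#'   `seq`, `depth` and a list-column `ids`.
#' @export
build_stacks <- function(reads, min_depth = 5L) {
  if (nrow(reads) == 0)
    stop("no reads to stack")
  len <- nchar(reads$seq)
  if (length(unique(len)) != 1L) stop("reads must share one length")
  useq <- unique(reads$seq)
  grp <- match(reads$seq, useq)
  ids <- split(reads$id, factor(grp, levels = seq_along(useq)))
  depth <- lengths(ids)
  st <- data.frame(seq = useq, depth = as.integer(depth))
  st$ids <- unname(ids)
  prim <- st$depth >= min_depth
  list(primary = st[prim, , drop = FALSE],
       secondary = st[!prim, , drop = FALSE])
}

#' Merge primary stacks into individual loci
#'
#' Builds a graph with an edge between stacks at Hamming distance `<= m`;
#' loci are its connected components.  With `removal = TRUE`, lumberjack
#' stacks (depth greater than mean + 2 sd of primary-stack depths) are
#' deleted before graphing, mirroring the repeat-removal rule of stack-based
#' RAD clustering.  Components with more than `max_stacks` primary stacks
#' are flagged as repetitive (likely paralogous) and excluded from the
#' catalog downstream.  The locus consensus is the per-column
#' depth-weighted majority over its primary stacks (ties break to the
#' alphabetically smallest base).
#'
#' @param primary primary-stack data frame from [build_stacks()].
#' @param m mismatches allowed between stacks.
#' @param max_stacks components with more primary stacks are flagged.
#' @param removal delete over-deep stacks before graphing.
#' @return list with `loci` (data frame `locus_id`, `consensus`,
#'   `haplotypes`, `depth`, `flagged`, list-columns `stack_seqs`,
#'   `stack_depths`, `ids`) and `removed_ids` (reads lost to removal).
#' @export
merge_stacks <- function(primary, m, max_stacks = 3L, removal = FALSE) {
  stopifnot(m >= 0)
  removed_ids <- character(0)
  if (removal && nrow(primary) > 1) {
    thr <- mean(primary$depth) + 2 * sd(primary$depth)
    lumber <- primary$depth > thr
    removed_ids <- unlist(primary$ids[lumber])
    primary <- primary[!lumber, , drop = FALSE]
  }
  n <- nrow(primary)
  if (n == 0)
    return(list(loci = data.frame(locus_id = integer(), consensus = character(),
                                  haplotypes = integer(), depth = integer(),
                                  flagged = logical()),
                removed_ids = removed_ids))
  edges <- .hamming_edges_cpp(primary$seq, as.integer(m))
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) { parent[x] <<- parent[parent[x]]; x <- parent[x] }; x }
  if (nrow(edges)) for (k in seq_len(nrow(edges))) {
    a <- find(edges[k, 1]); b <- find(edges[k, 2])
    if (a != b) parent[max(a, b)] <- min(a, b)
  }
  root <- vapply(seq_len(n), find, integer(1))
  comp <- match(root, sort(unique(root)))  # components numbered by smallest member
  K <- max(comp)
  loci <- lapply(seq_len(K), function(k) {
    idx <- which(comp == k)
    cons <- .consensus_cpp(primary$seq[idx], as.numeric(primary$depth[idx]))
    data.frame(locus_id = k, consensus = cons, haplotypes = length(idx),
               depth = sum(primary$depth[idx]),
               flagged = length(idx) > max_stacks)
  })
  loci <- do.call(rbind, loci)
  loci$stack_seqs <- lapply(seq_len(K), function(k) primary$seq[comp == k])
  loci$stack_depths <- lapply(seq_len(K), function(k) primary$depth[comp == k])
  loci$ids <- lapply(seq_len(K), function(k) unlist(primary$ids[comp == k]))
  list(loci = loci, removed_ids = removed_ids)
}

#' Assign secondary stacks to loci
#'
#' Each secondary stack is added to the unique locus whose consensus lies
#' within `m` mismatches; ties (more than one such locus) or no match leave
#' it unassigned.  Secondary reads contribute to locus depth and read
#' lists but never add haplotypes, and the consensus is not recomputed.
#'
#' @param loci locus table from [merge_stacks()].
#' @param secondary secondary-stack data frame from [build_stacks()].
#' @param m mismatches allowed against the locus consensus.
#' @return list with updated `loci` and `unassigned_ids`.
#' @export
assign_secondary <- function(loci, secondary, m) {
  if (nrow(secondary) == 0 || nrow(loci) == 0)
    return(list(loci = loci,
                unassigned_ids = if (nrow(secondary)) unlist(secondary$ids) else character(0)))
  hits <- .hamming_hits_cpp(secondary$seq, loci$consensus, as.integer(m))
  take <- hits[, 1] == 1L
  for (j in which(take)) {
    li <- hits[j, 2]
    loci$depth[li] <- loci$depth[li] + secondary$depth[j]
    loci$ids[[li]] <- c(loci$ids[[li]], secondary$ids[[j]])
  }
  list(loci = loci, unassigned_ids = unlist(secondary$ids[!take]))
}

#' Cluster one individual's forward reads into loci
#'
#' Runs [build_stacks()], [merge_stacks()] and [assign_secondary()] with a
#' single mismatch threshold, the usual within-individual clustering of
#' stack-based RAD analysis.
#'
#' @param reads data frame `id`, `seq` of forward reads (uniform length).
#' @param m mismatches allowed within the individual.
#' @param min_depth minimum stack depth.
#' @param max_stacks repeat flagging threshold (component size).
#' @param removal lumberjack-stack removal before graphing.
#' @return list `loci` (locus table), `unassigned_ids`, and `n_reads`.
#' @export
cluster_individual <- function(reads, m, min_depth = 5L, max_stacks = 3L,
                               removal = TRUE) {
  st <- build_stacks(reads, min_depth)
  mg <- merge_stacks(st$primary, m, max_stacks, removal)
  as2 <- assign_secondary(mg$loci, st$secondary, m)
  list(loci = as2$loci,
       unassigned_ids = c(mg$removed_ids, as2$unassigned_ids),
       n_reads = nrow(reads))
}
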