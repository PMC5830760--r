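#' Merge individuals' loci into a catalog
#'
#' Individuals are merged sequentially in list order.  Each incoming locus
#' joins the first existing catalog locus (lowest `cat_id`) whose consensus
#' lies within `n` mismatches, otherwise it founds a new catalog locus.
#' The catalog consensus stays the founder's consensus (never updated), so
#' the result is deterministic and order-stable.  Loci from one individual
#' never merge with each other (a catalog entry only absorbs loci from
#' later individuals), so a single individual's catalog is its locus set.
#'
#' @param per_individual_loci list, one element per individual (merge
#'   order), each either a character vector of locus consensi or a data
#'   frame with columns `locus_id` and `consensus` (flagged loci should be
#'   excluded by the caller).
#' @param n mismatches allowed between loci across individuals.
#' @return list with `catalog` (data frame `cat_id`, `consensus`,
#'   `founder`), `membership` (data frame `individual`, `locus_id`,
#'   `cat_id`) and `increments` (new loci founded per individual).
#' @export
build_catalog <- function(per_individual_loci, n) {
  k <- length(per_individual_loci)
  nms <- names(per_individual_loci)
  if (is.null(nms)) nms <- sprintf("ind%02d", seq_len(k))
  cons <- list(); lid <- list(); grp <- list()
  for (i in seq_len(k)) {
    el <- per_individual_loci[[i]]
    if (is.data.frame(el)) {
      cons[[i]] <- el$consensus
      lid[[i]] <- el$locus_id
    } else {
      cons[[i]] <- as.character(el)
      lid[[i]] <- seq_along(el)
    }
    grp[[i]] <- rep(i, length(cons[[i]]))
  }
  cons <- unlist(cons); lid <- unlist(lid); grp <- unlist(grp)
  if (length(cons) == 0)
    return(list(catalog = data.frame(cat_id = integer(), consensus = character(),
                                     founder = character()),
                membership = data.frame(individual = character(),
                                        locus_id = integer(), cat_id = integer()),
                increments = rep(0L, k)))
  assign <- .catalog_merge_cpp(cons, as.integer(grp), as.integer(n))
  founder_row <- match(seq_len(max(assign)), assign)
  catalog <- data.frame(cat_id = seq_len(max(assign)),
                        consensus = cons[founder_row],
                        founder = nms[grp[founder_row]])
  membership <- data.frame(individual = nms[grp], locus_id = lid,
                           cat_id = assign)
  increments <- vapply(seq_len(k), function(i)
    sum(founder_row %in% which(grp == i)), integer(1))
  list(catalog = catalog, membership = membership, increments = increments)
}

#' Pool second reads per catalog locus, with data reduction
#'
#' Second (reverse) reads are pooled per catalog locus through the
#' individual-locus membership map, in deterministic order (individuals in
#' catalog order, then locus read lists).  Pools larger than `max_reads`
#' are uniformly subsampled without replacement (seeded); pools smaller
#' than `min_reads` are marked `consensus_only` and skip assembly, with
#' the forward consensus emitted as their contig downstream.
#'
#' @param catalog_result result of [build_catalog()].
#' @param cluster_results named list (by individual) of
#'   [cluster_individual()] results, providing per-locus read-id lists.
#' @param pairs named list (by individual) of `rad_pairs` data frames.
#' @param min_reads minimum pool size to attempt assembly.
#' @param max_reads maximum reads used per locus.
#' @param seed RNG seed for the subsampling.
#' @return list of locus read sets: each has `cat_id`, `consensus`,
#'   `reads` (data frame `individual`, `id`, `seq` of reverse reads, after
#'   reduction), `n_before`, `consensus_only`.
#' @export
sort_read_pairs <- function(catalog_result, cluster_results, pairs,
                            min_reads = 10L, max_reads = 400L, seed = 1L) {
  mem <- catalog_result$membership
  cat <- catalog_result$catalog
  # one row per pooled read: (cat_id, individual, id, rev seq), assembled
  # per individual with vectorized id matching
  per_ind <- lapply(names(cluster_results), function(nm) {
    cl <- cluster_results[[nm]]
    mi <- mem[mem$individual == nm, , drop = FALSE]
    if (nrow(mi) == 0 || nrow(cl$loci) == 0) return(NULL)
    li <- match(mi$locus_id, cl$loci$locus_id)
    ids <- cl$loci$ids[li]
    df <- data.frame(cat_id = rep(mi$cat_id, lengths(ids)),
                     individual = nm, id = unlist(ids))
    df$seq <- pairs[[nm]]$rev_seq[match(df$id, pairs[[nm]]$id)]
    df[!is.na(df$seq), , drop = FALSE]
  })
  pool <- do.call(rbind, per_ind)
  sets <- vector("list", nrow(cat))
  if (!is.null(pool) && nrow(pool)) {
    for (sub in split(pool, pool$cat_id)) {
      cid <- sub$cat_id[1]
      n_before <- nrow(sub)
      if (n_before > max_reads) {
        sel <- with_seed(derive_seed(seed, paste0("sort:", cid)),
                         sort(sample(n_before, max_reads)))
        sub <- sub[sel, , drop = FALSE]
      }
      sets[[cid]] <- list(cat_id = cid,
                          consensus = cat$consensus[match(cid, cat$cat_id)],
                          reads = sub[, c("individual", "id", "seq")],
                          n_before = n_before,
                          consensus_only = n_before < min_reads)
    }
  }
  # catalog loci without any pooled reads still get a (consensus-only) set
  for (cid in cat$cat_id) if (is.null(sets[[cid]]))
    sets[[cid]] <- list(cat_id = cid,
                        consensus = cat$consensus[match(cid, cat$cat_id)],
                        reads = data.frame(individual = character(),
                                           id = character(), seq = character()),
                        n_before = 0L, consensus_only = TRUE)
  sets
}
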