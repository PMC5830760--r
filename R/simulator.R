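#' In-silico restriction digest
#'
#' Scans one strand of each chromosome for exact occurrences of the
#' recognition site (SbfI's `CCTGCAGG` is palindromic, so one strand
#' suffices).  Overlapping occurrences are counted.
#'
#' @param chroms named character vector of chromosome sequences.
#' @param site recognition sequence (IUPAC-free).
#' @return data frame with columns `chrom`, `pos` (0-based site start).
#' @export
digest <- function(chroms, site = "CCTGCAGG") {
  stopifnot(nzchar(site))
  res <- lapply(names(chroms), function(cn) {
    s <- chroms[[cn]]
    hits <- integer(0)
    from <- 1L
    repeat {
      i <- regexpr(site, substr(s, from, nchar(s)), fixed = TRUE)
      if (i < 0) break
      hits <- c(hits, from + i - 2L)  # 0-based
      from <- from + i                # step by 1 past the hit start: overlapping hits kept
    }
    if (length(hits)) data.frame(chrom = cn, pos = hits) else NULL
  })
  out <- do.call(rbind, res)
  if (is.null(out)) out <- data.frame(chrom = character(), pos = integer())
  out
}

#' Generate a synthetic genome with planted restriction sites
#'
#' Uniform-random background sequence on one chromosome with exactly
#' `n_loci` planted recognition sites, evenly spaced so that neighbouring
#' RAD loci can never overlap (spacing at least `2 * max_span`).
#' Background windows that happen to spell an extra recognition site are
#' re-rolled, so [digest()] finds exactly the planted sites.
#'
#' @param n_loci number of sites to plant.
#' @param chrom_len chromosome length in bp; must accommodate the spacing.
#' @param seed RNG seed (deterministic output).
#' @param site recognition sequence.
#' @param max_span maximal RAD locus span (bp) used for spacing.
#' @return list with `chroms` (named character vector), `sites`
#'   (data frame `chrom`, `pos`), and `site`.
#' @export
generate_genome <- function(n_loci, chrom_len, seed, site = "CCTGCAGG",
                            max_span = 700L) {
  margin <- max_span + 100L
  need <- 2L * margin + n_loci * (2L * max_span + nchar(site))
  if (chrom_len < need)
    stop(sprintf("chrom_len %d too small for %d sites (need >= %d)",
                 chrom_len, n_loci, need))
  spacing <- (chrom_len - 2L * margin) %/% n_loci
  pos <- margin + (seq_len(n_loci) - 1L) * spacing  # 0-based
  with_seed(seed, {
    s <- paste(sample(c("A", "C", "G", "T"), chrom_len, replace = TRUE),
               collapse = "")
    for (p in pos) substr(s, p + 1L, p + nchar(site)) <- site
    # re-roll accidental background occurrences until only planted remain
    for (iter in 1:100) {
      found <- digest(c(chr1 = s), site)$pos
      extra <- setdiff(found, pos)
      if (!length(extra)) break
      for (p in extra) {
        repl <- paste(sample(c("A", "C", "G", "T"), nchar(site), replace = TRUE),
                      collapse = "")
        substr(s, p + 1L, p + nchar(site)) <- repl
      }
      # planted sites are spaced far apart; re-rolls cannot touch them
      for (p in pos) substr(s, p + 1L, p + nchar(site)) <- site
    }
    list(chroms = c(chr1 = s),
         sites = data.frame(chrom = "chr1", pos = as.integer(pos)),
         site = site)
  })
}

#' Ground-truth RAD loci downstream of cut sites
#'
#' One locus per cut site on the + strand (the default, consistent with
#' treating each site as a single sequencing direction); with
#' `bidirectional = TRUE` a second, reverse-complemented locus is emitted
#' upstream of each site.  Each locus starts at the cut-site remnant and
#' spans `max_span` bp.
#'
#' @param genome a genome list from [generate_genome()] (or with the same
#'   shape: `chroms`, `sites`, `site`).
#' @param max_span locus span in bp.
#' @param bidirectional emit loci from both sides of each site.
#' @return data frame `locus_id`, `chrom`, `start` (0-based), `end`
#'   (exclusive), `strand`, `ref_seq`.
#' @export
truth_loci <- function(genome, max_span = 700L, bidirectional = FALSE) {
  # SbfI cuts CCTGCA^GG: the forward read begins at the remnant TGCAGG,
  # i.e. 2 bp into the recognition site.
  cut_off <- 2L
  rows <- list()
  k <- 0L
  for (i in seq_len(nrow(genome$sites))) {
    cn <- genome$sites$chrom[i]
    p <- genome$sites$pos[i]
    start <- p + cut_off
    if (start + max_span <= nchar(genome$chroms[[cn]])) {
      k <- k + 1L
      rows[[length(rows) + 1L]] <- data.frame(
        locus_id = k, chrom = cn, start = start, end = start + max_span,
        strand = "+",
        ref_seq = substr(genome$chroms[[cn]], start + 1L, start + max_span))
    }
    if (bidirectional) {
      end2 <- p + nchar(genome$site) - cut_off
      if (end2 - max_span >= 0) {
        k <- k + 1L
        rows[[length(rows) + 1L]] <- data.frame(
          locus_id = k, chrom = cn, start = end2 - max_span, end = end2,
          strand = "-",
          ref_seq = revcomp(substr(genome$chroms[[cn]], end2 - max_span + 1L, end2)))
      }
    }
  }
  do.call(rbind, rows)
}

#' Draw a diploid individual's variants over the truth loci
#'
#' `het` is the per-base mutation (polymorphism) rate, the meaning of the
#' heterozygosity dial in the wgsim simulator family: every base beyond
#' the cut-site remnant is independently a mutation with probability
#' `het`; a mutation is homozygous (both haplotypes carry the same random
#' non-reference base) with probability `hom_frac` (wgsim hard-codes 1/3),
#' otherwise heterozygous (one random haplotype carries the non-reference
#' base).  Realized per-base heterozygosity is therefore
#' `het * (1 - hom_frac)`.  The remnant itself is never mutated, since a
#' disrupted recognition site would not have been cut and sequenced.
#'
#' @param truth truth-locus table from [truth_loci()].
#' @param name individual label.
#' @param het per-base mutation rate (0..0.1).
#' @param seed RNG seed.
#' @param hom_frac fraction of mutations that are homozygous.
#' @param remnant_len number of 5' bases protected from variants.
#' @return list with `name` and `variants` (data frame `locus_id`,
#'   `offset` 0-based within locus, `ref`, `hap1`, `hap2`).
#' @export
make_individual <- function(truth, name, het, seed, hom_frac = 1/3,
                            remnant_len = 6L) {
  stopifnot(het >= 0, het <= 0.1, hom_frac >= 0, hom_frac < 1)
  mu <- het
  bases <- c("A", "C", "G", "T")
  with_seed(seed, {
    vars <- lapply(seq_len(nrow(truth)), function(i) {
      span <- nchar(truth$ref_seq[i])
      n_free <- span - remnant_len
      hit <- which(runif(n_free) < mu)
      if (!length(hit)) return(NULL)
      off <- hit + remnant_len - 1L  # 0-based offsets within the locus
      ref <- substring(truth$ref_seq[i], off + 1L, off + 1L)
      alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L),
                    character(1), USE.NAMES = FALSE)
      is_het <- runif(length(off)) >= hom_frac
      hap1 <- ifelse(is_het, NA, alt)
      hap2 <- ifelse(is_het, NA, alt)
      carrier <- sample(1:2, length(off), replace = TRUE)
      hap1[is_het & carrier == 1] <- alt[is_het & carrier == 1]
      hap1[is_het & carrier == 2] <- ref[is_het & carrier == 2]
      hap2[is_het & carrier == 2] <- alt[is_het & carrier == 2]
      hap2[is_het & carrier == 1] <- ref[is_het & carrier == 1]
      data.frame(locus_id = truth$locus_id[i], offset = off,
                 ref = ref, hap1 = hap1, hap2 = hap2)
    })
    vars <- do.call(rbind, vars)
    if (is.null(vars))
      vars <- data.frame(locus_id = integer(), offset = integer(),
                         ref = character(), hap1 = character(),
                         hap2 = character())
    list(name = name, variants = vars)
  })
}

apply_variants <- function(ref_seq, vars, hap) {
  if (is.null(vars) || nrow(vars) == 0) return(ref_seq)
  alle <- if (hap == 1) vars$hap1 else vars$hap2
  for (i in seq_len(nrow(vars)))
    substr(ref_seq, vars$offset[i] + 1L, vars$offset[i] + 1L) <- alle[i]
  ref_seq
}

#' Simulate overlapping paired-end RAD reads for one individual
#'
#' For every truth locus and every insert size in the ladder
#' `insert_min + i * step, i = 0..n_steps`, a Poisson(`depth_per_step`)
#' number of read pairs is drawn.  Each pair picks a haplotype uniformly;
#' the forward read copies the first `read_len` bases of the haplotype
#' (beginning at the cut-site remnant) and the reverse read is the reverse
#' complement of the last `read_len` bases of the insert.  Substitution
#' errors are then applied per base with probability `err`; qualities are
#' uniform Q40.  Read ids encode the ground truth as
#' `L<locus>_<individual>_s<insert>_h<hap>_<serial>`.
#'
#' @param truth truth-locus table.
#' @param individual an individual from [make_individual()].
#' @param insert_min smallest insert size (bp).
#' @param n_steps number of 'elongation' steps beyond `insert_min`.
#' @param step insert-size increment per step (bp).
#' @param depth_per_step mean pair depth per insert-size step.
#' @param read_len read length (bp); must be `<= insert_min`.
#' @param err per-base substitution error rate.
#' @param seed RNG seed.
#' @return a `rad_pairs` data frame with Q40 qualities.
#' @export
simulate_pairs <- function(truth, individual, insert_min = 200L,
                           n_steps = 10L, step = 50L, depth_per_step = 10,
                           read_len = 125L, err = 0.01, seed = 1L) {
  stopifnot(read_len <= insert_min)
  inserts <- insert_min + (0:n_steps) * step
  with_seed(seed, {
    fwd <- list(); rev <- list(); ids <- list()
    for (i in seq_len(nrow(truth))) {
      lid <- truth$locus_id[i]
      span <- nchar(truth$ref_seq[i])
      if (max(inserts) > span) {
        warning(sprintf("locus %d: insert ladder exceeds locus span; skipped", lid))
        next
      }
      vs <- individual$variants[individual$variants$locus_id == lid, , drop = FALSE]
      haps <- c(apply_variants(truth$ref_seq[i], vs, 1L),
                apply_variants(truth$ref_seq[i], vs, 2L))
      serial <- 0L
      for (s in inserts) {
        cnt <- rpois(1L, depth_per_step)
        if (cnt == 0) next
        h <- sample(1:2, cnt, replace = TRUE)
        f <- substr(haps[h], 1L, read_len)
        r <- revcomp(substr(haps[h], s - read_len + 1L, s))
        fwd[[length(fwd) + 1L]] <- f
        rev[[length(rev) + 1L]] <- r
        ids[[length(ids) + 1L]] <- sprintf("L%05d_%s_s%03d_h%d_%04d", lid,
                                           individual$name, s, h,
                                           serial + seq_len(cnt))
        serial <- serial + cnt
      }
    }
    fwd <- unlist(fwd); rev <- unlist(rev); ids <- unlist(ids)
    if (is.null(fwd))
      return(rad_pairs(character(), character(), character(), character(),
                       character(), character()))
    if (err > 0) {
      fwd <- as.character(.inject_errors_cpp(fwd, err))
      rev <- as.character(.inject_errors_cpp(rev, err))
    }
    rad_pairs(id = ids, individual = individual$name, fwd_seq = fwd,
              rev_seq = rev)
  })
}

#' Parse ground-truth labels out of simulated read ids
#'
#' @param id character vector of simulated read ids.
#' @return data frame `locus_id`, `individual`, `insert_size`, `haplotype`.
#' @export
parse_truth_labels <- function(id) {
  m <- regmatches(id, regexec("^L(\\d+)_(.+)_s(\\d+)_h([12])_\\d+$", id))
  bad <- vapply(m, length, integer(1)) == 0
  if (any(bad)) stop("unparseable simulated read id: ", id[which(bad)[1]])
  data.frame(locus_id = as.integer(vapply(m, `[`, "", 2)),
             individual = vapply(m, `[`, "", 3),
             insert_size = as.integer(vapply(m, `[`, "", 4)),
             haplotype = as.integer(vapply(m, `[`, "", 5)))
}

#' Expected RAD library coverage
#'
#' The per-individual library footprint implied by single-direction RAD
#' loci: `n_sites * max_span` bp.
#'
#' @param n_sites number of cut sites.
#' @param max_span expected per-locus span (bp).
#' @return expected coverage in bp.
#' @export
expected_library_coverage <- function(n_sites, max_span = 700L) {
  stopifnot(n_sites >= 0)
  n_sites * max_span
}

#' Simulate a full multi-individual RAD-seq experiment
#'
#' Convenience driver: generates a genome, truth loci, `n_individuals`
#' diploid individuals and their read pairs.  Per-individual seeds are
#' derived stably from `seed`.
#'
#' @param n_loci number of RAD loci (planted cut sites).
#' @param n_individuals number of diploid individuals.
#' @param het per-base variant probability.
#' @param seed master seed.
#' @param chrom_len genome length (default sized to fit the loci).
#' @inheritParams simulate_pairs
#' @return list `genome`, `truth`, `individuals`, `pairs` (one `rad_pairs`
#'   data frame per individual, named by individual).
#' @export
simulate_radseq <- function(n_loci = 200L, n_individuals = 12L, het = 0.02,
                            seed = 1L, chrom_len = NULL, insert_min = 200L,
                            n_steps = 10L, step = 50L, depth_per_step = 10,
                            read_len = 125L, err = 0.01) {
  max_span <- insert_min + n_steps * step
  if (is.null(chrom_len)) chrom_len <- (n_loci + 2L) * (2L * max_span + 200L)
  genome <- generate_genome(n_loci, chrom_len, derive_seed(seed, "genome"),
                            max_span = max_span)
  truth <- truth_loci(genome, max_span = max_span)
  names <- sprintf("ind%02d", seq_len(n_individuals))
  individuals <- lapply(names, function(nm)
    make_individual(truth, nm, het, derive_seed(seed, paste0("ind:", nm))))
  pairs <- lapply(individuals, function(ind)
    simulate_pairs(truth, ind, insert_min, n_steps, step, depth_per_step,
                   read_len, err, derive_seed(seed, paste0("reads:", ind$name))))
  names(pairs) <- names
  list(genome = genome, truth = truth, individuals = individuals,
       pairs = pairs)
}
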