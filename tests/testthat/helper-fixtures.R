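# Shared fixtures.  Heavy runs are memoized per session so the acceptance
# tests and property suites reuse one scaled pipeline execution.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_env)) assign(key, expr, envir = .fixture_env)
  get(key, envir = .fixture_env)
}

random_dna <- function(n, seed = NULL) {
  draw <- function() paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                           collapse = "")
  if (is.null(seed)) draw() else radasm:::with_seed(seed, draw())
}

# Error-free reads tiling a template at fixed offsets (genome-forward).
tiled_reads <- function(template, offsets, read_len = 125L) {
  substring(template, offsets + 1L, offsets + read_len)
}

# Scaled-down replication of the simulation experiment: ~200 loci,
# 12 individuals, het 0.02, 125 bp reads, inserts 200-700 by 50, depth 10
# per step, error 0.01 -- the package defaults.  Fixed seed 1.
scaled_run <- function() memo("scaled",
  suppressWarnings(run_pipeline(rad_config(seed = 1L))))

# Error-free, variant-free run used by the perfect-reconstruction
# criterion; smaller locus count keeps it fast, all rate/length/depth
# defaults unchanged.
perfect_run <- function() memo("perfect", {
  run_pipeline(rad_config(n_loci = 25L, n_individuals = 4L, het = 0,
                          err = 0, seed = 11L))
})

# Independent exhaustive assembly oracle for tiny instances: explores every
# order of eligible merges (overlaps enumerated by its own naive scan,
# merges spliced by plain string operations) and returns the set of
# terminal contig multisets.
oracle_overlaps <- function(seqs, min_overlap, max_rate) {
  out <- list()
  n <- length(seqs)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    a <- seqs[i]; b <- seqs[j]
    la <- nchar(a); lb <- nchar(b)
    if (min(la, lb) - 1L >= min_overlap) for (L in min_overlap:(min(la, lb) - 1L)) {
      sa <- substring(a, la - L + 1L, la)
      sb <- substring(b, 1L, L)
      mm <- sum(strsplit(sa, "")[[1]] != strsplit(sb, "")[[1]])
      if (mm <= max_rate * L)
        out[[length(out) + 1L]] <- list(i = i, j = j, type = "dovetail", L = L)
    }
    if (lb <= la && i < j || lb < la) {
      for (o in 0:(la - lb)) {
        sa <- substring(a, o + 1L, o + lb)
        mm <- sum(strsplit(sa, "")[[1]] != strsplit(b, "")[[1]])
        if (mm <= max_rate * lb)
          out[[length(out) + 1L]] <- list(i = i, j = j, type = "contain", L = lb, o = o)
      }
    }
  }
  out
}

oracle_assemble_all <- function(seqs, min_overlap = 20L, max_rate = 0) {
  seen <- new.env(parent = emptyenv())
  results <- new.env(parent = emptyenv())
  recurse <- function(ss) {
    key <- paste(sort(ss), collapse = "|")
    if (exists(key, envir = seen)) return(invisible())
    assign(key, TRUE, envir = seen)
    ovs <- if (length(ss) > 1) oracle_overlaps(ss, min_overlap, max_rate) else list()
    if (!length(ovs)) {
      assign(key, sort(ss), envir = results)
      return(invisible())
    }
    for (ov in ovs) {
      merged <- if (ov$type == "dovetail") {
        paste0(ss[ov$i], substring(ss[ov$j], ov$L + 1L))
      } else ss[ov$i]
      recurse(c(ss[-c(ov$i, ov$j)], merged))
    }
  }
  recurse(seqs)
  unique(lapply(ls(results), function(k) get(k, envir = results)))
}
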