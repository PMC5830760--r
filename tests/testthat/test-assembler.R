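test_that("find_overlaps enumerates dovetails and containments as specified", {
  ov <- find_overlaps(c("AAACCC", "CCCGGG"), min_overlap = 3, max_mismatch_rate = 0)
  expect_equal(nrow(ov), 1L)
  expect_equal(ov$a, 1L)
  expect_equal(ov$b, 2L)
  expect_equal(ov$length, 3L)
  expect_equal(ov$mismatches, 0L)
  expect_false(ov$contained)

  # no perfect overlap; at rate 0.34 the length-3 suffix-prefix with one
  # mismatch qualifies (all suffix-prefix lengths enumerated by hand)
  expect_equal(nrow(find_overlaps(c("AAACCC", "CCGGGG"), 3, 0)), 0L)
  ov2 <- find_overlaps(c("AAACCC", "CCGGGG"), 3, 0.34)
  expect_equal(ov2$length, 3L)
  expect_equal(ov2$mismatches, 1L)

  ov3 <- find_overlaps(c("ACGTACGT", "GTAC"), 3, 0)
  ct <- ov3[ov3$contained, ]
  expect_equal(nrow(ct), 1L)
  expect_equal(ct$a, 1L)
  expect_equal(ct$b, 2L)
  expect_equal(ct$offset, 2L)
})

test_that("greedy assembly reconstructs a tiled template exactly", {
  set.seed(31)
  tpl <- random_dna(700)
  reads <- tiled_reads(tpl, seq(0, 575, by = 25))
  a <- greedy_assemble(reads)
  expect_length(a$contigs, 1L)
  expect_identical(a$contigs[1], tpl)
  expect_true(all(a$assignment == 1L))

  # two disjoint templates give exactly two contigs
  tpl2 <- random_dna(700)
  b <- greedy_assemble(c(reads, tiled_reads(tpl2, seq(0, 575, by = 25))))
  expect_length(b$contigs, 2L)
  expect_setequal(b$contigs, c(tpl, tpl2))
})

test_that("per-column consensus over depth >= 3 error-free reads is exact", {
  set.seed(32)
  tpl <- random_dna(400)
  offs <- rep(seq(0, 275, by = 25), each = 3)
  reads <- tiled_reads(tpl, offs)
  # corrupt one read per offset at one position; majority must restore
  idx <- seq(1, length(reads), by = 3)
  for (i in idx) {
    p <- 60
    substr(reads[i], p, p) <- setdiff(c("A", "C", "G", "T"),
                                      substr(reads[i], p, p))[1]
  }
  a <- greedy_assemble(reads)
  expect_identical(a$contigs[1], tpl)
})

test_that("tiny instances match the exhaustive merge-order oracle", {
  set.seed(33)
  for (case in 1:5) {
    tpl <- random_dna(120)
    offs <- sort(sample(0:70, 4))
    reads <- unique(tiled_reads(tpl, c(0, offs, 70), read_len = 50))
    oracle <- oracle_assemble_all(reads, min_overlap = 20L, max_rate = 0)
    g <- greedy_assemble(reads, min_overlap = 20L, max_mismatch_rate = 0)
    expect_true(any(vapply(oracle, identical, logical(1), sort(g$contigs))),
                info = paste("case", case))
    # error-free tilings converge: every merge order ends in the same set
    if (length(oracle) == 1L)
      expect_identical(sort(g$contigs), oracle[[1]])
  }
})

test_that("assembly is deterministic and bounded on error-free input", {
  set.seed(34)
  tpl <- random_dna(700)
  offs <- rep(seq(0, 575, 50), each = 5)
  reads <- tiled_reads(tpl, offs)
  a1 <- greedy_assemble(reads)
  a2 <- greedy_assemble(reads)
  expect_identical(a1, a2)
  expect_true(all(nchar(a1$contigs) <= 1.25 * 700))
})

test_that("two-step assembly merges through or pads with exactly ten Ns", {
  set.seed(35)
  tpl <- random_dna(700)
  cons <- substr(tpl, 1, 125)
  # full second-read coverage from 75..700: merges into the full template
  offs <- rep(seq(75, 575, by = 50), each = 4)
  second <- revcomp(tiled_reads(tpl, offs))
  ts <- two_step_assemble(second, cons)
  expect_false(ts$padded)
  expect_identical(ts$seq, tpl)

  # second reads covering only 400..700: no overlap with the consensus
  offs2 <- rep(seq(400, 575, by = 25), each = 3)
  second2 <- revcomp(tiled_reads(tpl, offs2))
  ts2 <- two_step_assemble(second2, cons)
  expect_true(ts2$padded)
  expect_equal(ts2$pad_start, 126L)
  expect_identical(ts2$seq, paste0(cons, strrep("N", 10),
                                   substr(tpl, 401, 700)))
  expect_equal(nchar(ts2$seq), 125L + 10L + 300L)
  # padded contig contains exactly one run of exactly ten Ns
  expect_equal(gregexpr("N+", ts2$seq)[[1]] |> attr("match.length"), 10L)

  expect_error(two_step_assemble(character(0), cons), "empty read set")
})

test_that("consensus-only routing emits the forward consensus unchanged", {
  rs <- list(list(cat_id = 1L, consensus = strrep("ACGT", 10),
                  reads = data.frame(individual = character(),
                                     id = character(), seq = character()),
                  n_before = 3L, consensus_only = TRUE))
  out <- assemble_loci(rs, min_contig_len = 10L)
  expect_equal(out$contigs$seq, strrep("ACGT", 10))
  expect_equal(out$contigs$source, "consensus_only")
})

test_that("thread count never changes assembly results", {
  run <- scaled_run()
  sets <- run$read_sets[1:12]
  a1 <- assemble_loci(sets, threads = 1L)
  a2 <- assemble_loci(sets, threads = 2L)
  expect_identical(a1$contigs, a2$contigs)
})
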