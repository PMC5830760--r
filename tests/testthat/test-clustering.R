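reads_of <- function(seqs) data.frame(id = sprintf("r%04d", seq_along(seqs)),
                                      seq = seqs)

test_that("build_stacks groups identical reads and splits by min_depth", {
  r <- reads_of(c(rep("ACGT", 5), "ACGA"))
  st <- build_stacks(r, 5L)
  expect_equal(st$primary$seq, "ACGT")
  expect_equal(st$primary$depth, 5L)
  expect_equal(st$secondary$seq, "ACGA")

  st2 <- build_stacks(reads_of(c("AAAA", "CCCC", "GGGG")), 2L)
  expect_equal(nrow(st2$primary), 0L)
  expect_equal(nrow(st2$secondary), 3L)

  # conservation: stack depths sum to the read count
  set.seed(2)
  seqs <- sample(c("AAAA", "AAAT", "GGGG", "TTTT"), 100, TRUE)
  st3 <- build_stacks(reads_of(seqs), 3L)
  expect_equal(sum(st3$primary$depth) + sum(st3$secondary$depth), 100L)
  expect_error(build_stacks(reads_of(c("AA", "AAA"))), "one length")
})

test_that("merge_stacks joins components at Hamming <= m with the tie-safe consensus", {
  st <- build_stacks(reads_of(c(rep("AAAA", 5), rep("AAAT", 5))), 5L)
  mg <- merge_stacks(st$primary, m = 1L)
  expect_equal(nrow(mg$loci), 1L)
  expect_equal(mg$loci$haplotypes, 2L)
  expect_equal(mg$loci$consensus, "AAAA")  # depth tie at column 4 -> smallest base

  mg2 <- merge_stacks(build_stacks(reads_of(c(rep("AAAA", 5), rep("TTTT", 5))), 5L)$primary, 1L)
  expect_equal(mg2$loci$haplotypes, c(1L, 1L))

  # chain AAAA-AAAT-AATT connects transitively at m=1; flagged at max_stacks=2
  chain <- build_stacks(reads_of(rep(c("AAAA", "AAAT", "AATT"), each = 5)), 5L)
  mg3 <- merge_stacks(chain$primary, 1L)
  expect_equal(mg3$loci$haplotypes, 3L)
  expect_false(mg3$loci$flagged)
  mg4 <- merge_stacks(chain$primary, 1L, max_stacks = 2L)
  expect_true(mg4$loci$flagged)

  # m = 0 gives one locus per primary stack
  mg5 <- merge_stacks(chain$primary, 0L)
  expect_equal(nrow(mg5$loci), 3L)
})

test_that("lumberjack removal deletes over-deep stacks before graphing", {
  set.seed(8)
  shallow <- vapply(1:8, function(i) random_dna(12), "")
  deep <- random_dna(12)
  seqs <- c(rep(shallow, each = 5), rep(deep, 200))
  st <- build_stacks(reads_of(seqs), 5L)
  # depth 200 > mean + 2 sd of (5 x8, 200) = 26.7 + 2*64.9
  mg <- merge_stacks(st$primary, 1L, removal = TRUE)
  expect_false(deep %in% mg$loci$consensus)
  expect_equal(length(mg$removed_ids), 200L)
  expect_equal(nrow(mg$loci), 8L)
  # removal off keeps it
  mg2 <- merge_stacks(st$primary, 1L, removal = FALSE)
  expect_true(deep %in% unlist(mg2$loci$stack_seqs))
})

test_that("secondary assignment requires a unique locus within m", {
  st <- build_stacks(reads_of(c(rep("AAAA", 5), rep("TTTT", 5),
                                "AAAT", "AATT", "GGGG")), 5L)
  mg <- merge_stacks(st$primary, 0L)
  res <- assign_secondary(mg$loci, st$secondary, 1L)
  # AAAT -> AAAA locus; AATT equidistant would need m=2; GGGG no match
  li <- match("AAAA", res$loci$consensus)
  expect_equal(res$loci$depth[li], 6L)
  expect_setequal(res$unassigned_ids,
                  reads_of(c(rep("AAAA", 5), rep("TTTT", 5), "AAAT", "AATT",
                             "GGGG"))$id[12:13])
  # equidistant tie at m=2: AATT is 2 from both AAAA and TTTT -> unassigned
  res2 <- assign_secondary(mg$loci, st$secondary, 2L)
  expect_true(any(grepl("r0012", res2$unassigned_ids)))
  # m=0 and no exact match -> unassigned
  res3 <- assign_secondary(mg$loci, st$secondary, 0L)
  expect_equal(length(res3$unassigned_ids), 3L)
})

test_that("read counts are conserved through clustering", {
  set.seed(4)
  base <- random_dna(60)
  alt <- base
  substr(alt, 10, 10) <- if (substr(alt, 10, 10) == "A") "C" else "A"
  seqs <- c(rep(base, 20), rep(alt, 15),
            vapply(1:12, function(i) {
              s <- base; p <- sample(60, 1)
              substr(s, p, p) <- sample(setdiff(c("A", "C", "G", "T"),
                                                substr(s, p, p)), 1)
              s
            }, ""))
  r <- reads_of(seqs)
  cl <- cluster_individual(r, m = 2L, removal = FALSE)
  expect_equal(sum(cl$loci$depth) + length(cl$unassigned_ids), nrow(r))
  expect_setequal(c(unlist(cl$loci$ids), cl$unassigned_ids), r$id)
})

test_that("locus count is non-increasing in m (removal off)", {
  set.seed(6)
  seqs <- unlist(lapply(1:8, function(i) {
    b <- random_dna(40)
    c(rep(b, 6), rep({ s <- b; substr(s, 5, 5) <- "A"; s }, 6))
  }))
  st <- build_stacks(reads_of(seqs), 5L)
  counts <- vapply(0:6, function(m) nrow(merge_stacks(st$primary, m)$loci),
                   integer(1))
  expect_true(all(diff(counts) <= 0))
})
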