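test_that("contig_stats matches a brute-force N50 on random length sets", {
  s <- contig_stats(c(300L, 200L, 100L))
  expect_equal(s$total_cov, 600L)
  expect_equal(s$n50, 300L)  # sorted desc, cumulative 300 >= 300 at first
  expect_equal(s$mean_len, 200L)
  expect_equal(contig_stats(rep(1L, 4))[c("n50", "mean_len", "total_cov")],
               list(n50 = 1L, mean_len = 1L, total_cov = 4L))
  expect_equal(contig_stats(c(500L, 500L))$n50, 500L)
  expect_error(contig_stats(integer(0)), "no contigs")

  brute_n50 <- function(len) {
    len <- sort(len, decreasing = TRUE)
    for (k in seq_along(len)) if (sum(len[1:k]) >= sum(len) / 2) return(len[k])
  }
  set.seed(41)
  for (i in 1:25) {
    len <- sample(1:1000, sample(1:40, 1), replace = TRUE)
    expect_equal(contig_stats(len)$n50, brute_n50(len), info = paste("case", i))
  }
  # N50 belongs to the length multiset; sequences count Ns toward length
  expect_equal(contig_stats(c("ACGTNNNNNNNNNNAC"))$total_cov, 16L)
})

test_that("read-pair mapping applies orientation and insert rules", {
  set.seed(42)
  ctg <- random_dna(700)
  mk <- function(fwd, rev, id = "p1")
    rad_pairs(id = id, individual = "i", fwd_seq = fwd, rev_seq = rev)
  # a pair drawn exactly from the contig with insert 300 is proper
  p <- mk(substr(ctg, 1, 125), revcomp(substr(ctg, 176, 300)))
  mp <- map_read_pairs(ctg, p)
  expect_equal(mp$proper_paired_pct, 100)
  expect_equal(mp$total_mapped_pct, 100)
  # same orientation (both forward) is mapped but not proper
  p2 <- mk(substr(ctg, 1, 125), substr(ctg, 176, 300))
  mp2 <- map_read_pairs(ctg, p2)
  expect_equal(mp2$total_mapped_pct, 100)
  expect_equal(mp2$proper_paired_pct, 0)
  # mates on different contigs: mapped, not proper
  ctg2 <- random_dna(700)
  p3 <- mk(substr(ctg, 1, 125), revcomp(substr(ctg2, 176, 300)))
  mp3 <- map_read_pairs(c(ctg, ctg2), p3)
  expect_equal(mp3$total_mapped_pct, 100)
  expect_equal(mp3$proper_paired_pct, 0)
  # insert outside the accepted range is not proper
  p4 <- mk(substr(ctg, 1, 125), revcomp(substr(ctg, 576, 700)))
  expect_equal(map_read_pairs(ctg, p4, insert_range = c(100, 500))$proper_paired_pct, 0)
  expect_equal(map_read_pairs(ctg, p4, insert_range = c(100, 1000))$proper_paired_pct, 100)
  # low-identity reads stay unmapped
  p5 <- mk(random_dna(125), revcomp(substr(ctg, 176, 300)))
  expect_equal(map_read_pairs(ctg, p5)$total_mapped_pct, 50)
})

test_that("mapping ties break to the lowest contig index, deterministically", {
  set.seed(43)
  ctg <- random_dna(400)
  p <- rad_pairs(id = "p", individual = "i",
                 fwd_seq = substr(ctg, 1, 125),
                 rev_seq = revcomp(substr(ctg, 176, 300)))
  mp <- map_read_pairs(c(ctg, ctg), p)   # duplicate contigs
  expect_equal(unname(mp$fwd_hits[1, "contig"]), 1)
  expect_equal(unname(mp$rev_hits[1, "contig"]), 1)
  expect_equal(mp$proper_paired_pct, 100)
  mp2 <- map_read_pairs(c(ctg, ctg), p)
  expect_identical(mp, mp2)
})

test_that("truth identity scores non-N columns and the 80% match rule", {
  set.seed(44)
  ref <- random_dna(700)
  truth <- data.frame(locus_id = 7L, chrom = "chr1", start = 0L, end = 700L,
                      strand = "+", ref_seq = ref)
  ctg <- data.frame(cat_id = 1L, seq = ref, truth_locus = 7L)
  ti <- truth_identity(ctg, truth)
  expect_equal(ti$mean_identity, 100)
  expect_equal(ti$pct_contigs_matched, 100)

  # 7 mismatches over 700 aligned bp -> 99.0%
  mut <- ref
  for (p in seq(50, 650, by = 100)) substr(mut, p, p) <-
    setdiff(c("A", "C", "G", "T"), substr(mut, p, p))[1]
  ti2 <- truth_identity(data.frame(cat_id = 1L, seq = mut, truth_locus = 7L),
                        truth)
  expect_equal(ti2$mean_identity, 99.0)

  # padded contig: only non-N columns scored
  pad <- paste0(substr(ref, 1, 125), strrep("N", 10), substr(ref, 401, 700))
  ti3 <- truth_identity(data.frame(cat_id = 1L, seq = pad, truth_locus = 7L),
                        truth)
  expect_equal(ti3$mean_identity, 100)

  # an unrelated contig fails the 80% rule
  ti4 <- truth_identity(data.frame(cat_id = 1L, seq = random_dna(700),
                                   truth_locus = 7L), truth)
  expect_equal(ti4$pct_contigs_matched, 0)
  expect_error(truth_identity(ctg, NULL), "truth table absent")
})

test_that("mean pairs per individual matches the summary-table convention", {
  expect_equal(mean_pairs_per_individual(rep(62960475 / 24, 24), truncate = TRUE),
               2623353)
  expect_equal(mean_pairs_per_individual(5L), 5)
  expect_equal(mean_pairs_per_individual(c(1, 2, 3)), 2)
})
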