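test_that("catalog merging is sequential, founder-anchored and first-match", {
  set.seed(21)
  L <- vapply(1:5, function(i) random_dna(30), "")
  # two identical individuals at n=0: everything merges
  cat0 <- build_catalog(list(i1 = L, i2 = L), 0L)
  expect_equal(cat0$increments, c(5L, 0L))
  expect_equal(nrow(cat0$catalog), 5L)

  # pairwise 3 apart at n=2: nothing merges
  shift3 <- vapply(L, function(s) {
    for (p in c(2, 11, 23)) substr(s, p, p) <-
        setdiff(c("A", "C", "G", "T"), substr(s, p, p))[1]
    s
  }, "", USE.NAMES = FALSE)
  cat1 <- build_catalog(list(i1 = L, i2 = shift3), 2L)
  expect_equal(cat1$increments, c(5L, 5L))

  # founder-consensus rule: d(A,B)=2, d(B,C)=2, d(A,C)=4; at n=2 B merges
  # into A's locus but C is 4 from the catalog consensus (still A) -> new
  A <- random_dna(30)
  B <- A; for (p in c(4, 9)) substr(B, p, p) <-
    setdiff(c("A", "C", "G", "T"), substr(B, p, p))[1]
  C <- B; for (p in c(15, 21)) substr(C, p, p) <-
    setdiff(c("A", "C", "G", "T"), substr(C, p, p))[1]
  expect_equal(hamming(A, B), 2L)
  expect_equal(hamming(B, C), 2L)
  expect_equal(hamming(A, C), 4L)
  cat2 <- build_catalog(list(i1 = A, i2 = B, i3 = C), 2L)
  expect_equal(cat2$increments, c(1L, 0L, 1L))
  expect_equal(cat2$catalog$consensus, c(A, C))  # consensus never updated
  expect_equal(cat2$membership$cat_id, c(1L, 1L, 2L))
})

test_that("catalog invariants: increments sum to size; single individual unchanged", {
  set.seed(22)
  inds <- lapply(1:4, function(i) vapply(1:12, function(j) random_dna(25), ""))
  cat1 <- build_catalog(inds, 3L)
  expect_equal(sum(cat1$increments), nrow(cat1$catalog))
  one <- build_catalog(inds[1], 3L)
  expect_equal(one$catalog$consensus, inds[[1]])
  expect_equal(one$increments, 12L)
  # loci of one individual never merge with each other
  twin <- c(inds[[1]][1], inds[[1]][1])
  self <- build_catalog(list(twin), 5L)
  expect_equal(nrow(self$catalog), 2L)
})

test_that("sort_read_pairs pools per catalog locus with seeded reduction", {
  # two individuals, one shared locus; forward reads assigned by clustering
  set.seed(23)
  cons <- random_dna(40)
  mk_pairs <- function(nm, n) {
    rad_pairs(id = sprintf("%s_r%03d", nm, 1:n), individual = nm,
              fwd_seq = rep(cons, n),
              rev_seq = vapply(1:n, function(i) random_dna(40), ""))
  }
  pairs <- list(i1 = mk_pairs("i1", 30), i2 = mk_pairs("i2", 25))
  clusters <- lapply(names(pairs), function(nm)
    cluster_individual(data.frame(id = pairs[[nm]]$id,
                                  seq = pairs[[nm]]$fwd_seq), m = 2L))
  names(clusters) <- names(pairs)
  cat_res <- build_catalog(lapply(clusters, function(cl)
    cl$loci[, c("locus_id", "consensus")]), 2L)
  expect_equal(nrow(cat_res$catalog), 1L)

  rs <- sort_read_pairs(cat_res, clusters, pairs, min_reads = 10L,
                        max_reads = 40L, seed = 7L)
  expect_length(rs, 1L)
  expect_equal(rs[[1]]$n_before, 55L)
  expect_equal(nrow(rs[[1]]$reads), 40L)          # reduced to max_reads
  expect_true(all(rs[[1]]$reads$id %in% c(pairs$i1$id, pairs$i2$id)))
  expect_false(rs[[1]]$consensus_only)
  # deterministic per seed
  rs2 <- sort_read_pairs(cat_res, clusters, pairs, min_reads = 10L,
                         max_reads = 40L, seed = 7L)
  expect_identical(rs[[1]]$reads$id, rs2[[1]]$reads$id)
  # reverse reads belong to the right mates
  expect_equal(rs[[1]]$reads$seq,
               unname(c(setNames(pairs$i1$rev_seq, pairs$i1$id),
                        setNames(pairs$i2$rev_seq, pairs$i2$id))[rs[[1]]$reads$id]))

  # small pools are marked consensus-only; mid-size pass through unchanged
  rs3 <- sort_read_pairs(cat_res, clusters, pairs, min_reads = 100L,
                         max_reads = 400L, seed = 7L)
  expect_true(rs3[[1]]$consensus_only)
  expect_equal(nrow(rs3[[1]]$reads), 55L)
  rs4 <- sort_read_pairs(cat_res, clusters, pairs, min_reads = 10L,
                         max_reads = 400L, seed = 7L)
  expect_equal(nrow(rs4[[1]]$reads), 55L)
})

test_that("sorting never mixes reads across catalog loci", {
  set.seed(24)
  consA <- random_dna(40); consB <- random_dna(40)
  pairs <- list(i1 = rad_pairs(id = sprintf("r%03d", 1:40), individual = "i1",
                               fwd_seq = rep(c(consA, consB), each = 20),
                               rev_seq = vapply(1:40, function(i) random_dna(40), "")))
  clusters <- list(i1 = cluster_individual(
    data.frame(id = pairs$i1$id, seq = pairs$i1$fwd_seq), m = 2L))
  cat_res <- build_catalog(lapply(clusters, function(cl)
    cl$loci[, c("locus_id", "consensus")]), 2L)
  rs <- sort_read_pairs(cat_res, clusters, pairs, min_reads = 5L,
                        max_reads = 400L, seed = 1L)
  ids_by_locus <- lapply(rs, function(x) x$reads$id)
  expect_equal(sort(unlist(ids_by_locus)), sort(pairs$i1$id))
  fwd_of <- setNames(pairs$i1$fwd_seq, pairs$i1$id)
  for (x in rs)
    expect_length(unique(fwd_of[x$reads$id]), 1L)
})
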