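#' @useDynLib radasm, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rpois runif sd setNames
#' @importFrom utils read.delim write.table head
NULL

#' Reverse complement of DNA strings
#'
#' @param x character vector of DNA sequences over \{A,C,G,T,N\}.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  chartr("ACGTN", "TGCAN", vapply(x, function(s) {
    paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE))
}

#' Hamming distance between two equal-length sequences
#'
#' @param a,b single DNA strings of equal length.
#' @return integer number of mismatching positions.
#' @export
hamming <- function(a, b) .hamming_cpp(a, b)

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG state afterwards.  All stochastic operations in the
# package funnel through this so a user-facing `seed` argument never
# clobbers the session RNG.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Stable positive sub-seed < 2^31 derived from a base seed and a label,
# so per-stage / per-individual randomness is reproducible regardless of
# evaluation order.
derive_seed <- function(seed, label) {
  h <- 0
  for (c in utf8ToInt(paste0(label))) h <- (h * 31 + c) %% 2147483647
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483647) + 1L
}

check_dna <- function(x, what = "sequence") {
  bad <- grepl("[^ACGTN]", x)
  if (any(bad))
    stop(sprintf("%s contains characters outside {A,C,G,T,N} (first offender: %s)",
                 what, x[which(bad)[1]]), call. = FALSE)
  invisible(x)
}

# Phred+33 helpers: qualities travel as compact ASCII strings internally.
qual_to_int <- function(q) lapply(q, function(s) utf8ToInt(s) - 33L)
int_to_qual <- function(q) vapply(q, function(v) intToUtf8(v + 33L), character(1))
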