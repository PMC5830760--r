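#' Read a FASTA file
#'
#' Reads plain or gzip-compressed FASTA (detected by a `.gz` suffix) into a
#' data frame of records.  Multi-line sequences are joined, sequences are
#' uppercase-normalized, and any description after the first whitespace is
#' split off the id but retained.
#'
#' @param path path to a FASTA file (optionally `.gz`).
#' @return data frame with columns `id`, `desc`, `seq`.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  x <- Biostrings::readBStringSet(path, format = "fasta")
  if (length(x) == 0)
    return(data.frame(id = character(), desc = character(), seq = character(),
                      stringsAsFactors = FALSE))
  nm <- names(x)
  id <- sub("\\s.*$", "", nm)
  desc <- ifelse(grepl("\\s", nm), sub("^\\S+\\s+", "", nm), "")
  seq <- toupper(as.character(x))
  names(seq) <- NULL
  check_dna(seq, "FASTA sequence")
  if (any(nchar(seq) == 0)) stop("empty sequence in ", path)
  if (anyDuplicated(id)) stop("duplicate ids in ", path)
  data.frame(id = id, desc = desc, seq = seq, stringsAsFactors = FALSE)
}

#' Write a FASTA file
#'
#' Round-trips losslessly with [read_fasta()].  Gzip compression is chosen
#' by a `.gz` suffix on `path`.
#'
#' @param records data frame with columns `id` and `seq` (optional `desc`).
#' @param path output path.
#' @param wrap line width for sequence wrapping.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, wrap = 70L) {
  x <- Biostrings::BStringSet(records$seq)
  nm <- records$id
  if (!is.null(records$desc)) {
    has <- !is.na(records$desc) & nzchar(records$desc)
    nm[has] <- paste(nm[has], records$desc[has])
  }
  names(x) <- nm
  Biostrings::writeXStringSet(x, path, format = "fasta", width = max(1L, wrap),
                              compress = grepl("\\.gz$", path))
  invisible(path)
}

read_fastq_one <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE)
  id <- names(x)
  qual <- as.character(S4Vectors::mcols(x)$qualities)
  seq <- toupper(as.character(x))
  names(seq) <- NULL
  data.frame(id = id, seq = seq, qual = qual, stringsAsFactors = FALSE)
}

strip_mate_suffix <- function(id) sub("[/_][12]$", "", sub("\\s.*$", "", id))

#' Read paired FASTQ files into a read-pair table
#'
#' Files must have the same record count; mates are paired by position and
#' ids must agree after stripping a trailing `/1`, `/2` (or `_1`, `_2`)
#' mate suffix.  Phred+33 is the only supported quality encoding; gzip
#' input is handled transparently.
#'
#' @param path1,path2 forward / reverse FASTQ paths.
#' @param individual label recorded in the `individual` column.
#' @return a `rad_pairs` data frame: columns `id`, `individual`, `fwd_seq`,
#'   `rev_seq`, `fwd_qual`, `rev_qual` (qualities as Phred+33 strings).
#' @export
read_fastq_pairs <- function(path1, path2, individual = "ind1") {
  r1 <- read_fastq_one(path1)
  r2 <- read_fastq_one(path2)
  if (nrow(r1) != nrow(r2))
    stop(sprintf("record count mismatch: %d vs %d", nrow(r1), nrow(r2)))
  id1 <- strip_mate_suffix(r1$id)
  id2 <- strip_mate_suffix(r2$id)
  bad <- which(id1 != id2)
  if (length(bad))
    stop(sprintf("mate id mismatch at record %d: '%s' vs '%s'",
                 bad[1], r1$id[bad[1]], r2$id[bad[1]]))
  check_dna(r1$seq, "forward read")
  check_dna(r2$seq, "reverse read")
  rad_pairs(id = id1, individual = individual,
            fwd_seq = r1$seq, rev_seq = r2$seq,
            fwd_qual = r1$qual, rev_qual = r2$qual)
}

#' Construct a read-pair table
#'
#' @param id read-pair identifiers.
#' @param individual individual label(s).
#' @param fwd_seq,rev_seq mate sequences.
#' @param fwd_qual,rev_qual Phred+33 quality strings (default Q40).
#' @return data frame of class `rad_pairs`.
#' @export
rad_pairs <- function(id, individual, fwd_seq, rev_seq,
                      fwd_qual = strrep("I", nchar(fwd_seq)),
                      rev_qual = strrep("I", nchar(rev_seq))) {
  stopifnot(nchar(fwd_seq) == nchar(fwd_qual), nchar(rev_seq) == nchar(rev_qual))
  out <- data.frame(id = id, individual = individual, fwd_seq = fwd_seq,
                    rev_seq = rev_seq, fwd_qual = fwd_qual, rev_qual = rev_qual,
                    stringsAsFactors = FALSE)
  class(out) <- c("rad_pairs", "data.frame")
  out
}

#' Write a read-pair table as two FASTQ files
#'
#' @param pairs a `rad_pairs` data frame.
#' @param path1,path2 output FASTQ paths (gzip by `.gz` suffix).
#' @param mate_suffix add `/1`, `/2` to record ids.
#' @return invisibly, `c(path1, path2)`.
#' @export
write_fastq_pairs <- function(pairs, path1, path2, mate_suffix = TRUE) {
  write_one <- function(seq, qual, id, path) {
    x <- Biostrings::DNAStringSet(seq)
    names(x) <- id
    Biostrings::writeXStringSet(x, path, format = "fastq",
                                qualities = Biostrings::BStringSet(qual),
                                compress = grepl("\\.gz$", path))
  }
  s1 <- if (mate_suffix) paste0(pairs$id, "/1") else pairs$id
  s2 <- if (mate_suffix) paste0(pairs$id, "/2") else pairs$id
  write_one(pairs$fwd_seq, pairs$fwd_qual, s1, path1)
  write_one(pairs$rev_seq, pairs$rev_qual, s2, path2)
  invisible(c(path1, path2))
}
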