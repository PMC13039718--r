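#' @import stats
#' @import utils
#' @importFrom IRanges IRanges findOverlaps reduce width start end
#' @importFrom Biostrings DNAStringSet readDNAStringSet writeXStringSet
NULL

DNA_BASES <- c("A", "C", "G", "T")

#' Reverse-complement a DNA string
#'
#' Vector-safe reverse complement over the {A,C,G,T,N} alphabet.
#'
#' @param x character vector of DNA sequences.
#' @return character vector of the same length.
#' @export
revcomp <- function(x) {
  if (length(x) == 0) return(character(0))
  vapply(x, function(s) {
    chartr("ACGTN", "TGCAN", paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = ""))
  }, character(1), USE.NAMES = FALSE)
}

#' Generate a random DNA sequence
#'
#' @param n length in bp.
#' @param gc GC content in [0,1].
#' @return a single DNA string.
#' @export
random_dna <- function(n, gc = 0.38) {
  stopifnot(n >= 0, gc >= 0, gc <= 1)
  if (n == 0) return("")
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(DNA_BASES, n, replace = TRUE, prob = p), collapse = "")
}

# total overlap (bp) of interval [s, e] (1-based closed) with a set of intervals
interval_coverage_bp <- function(s, e, starts, ends) {
  if (length(starts) == 0 || e < s) return(0L)
  ir <- IRanges::reduce(IRanges::IRanges(pmax(starts, s), pmin(ends, e)))
  ir <- ir[IRanges::width(ir) > 0]
  keep <- IRanges::start(ir) <= IRanges::end(ir)
  sum(IRanges::width(ir[keep]))
}

# fraction of [s,e] covered
interval_coverage_frac <- function(s, e, starts, ends) {
  len <- e - s + 1
  if (len <= 0) return(0)
  ok <- ends >= s & starts <= e
  interval_coverage_bp(s, e, starts[ok], ends[ok]) / len
}

# hamming identity of two equal-length strings
seq_identity <- function(a, b) {
  if (nchar(a) != nchar(b) || nchar(a) == 0) return(0)
  va <- strsplit(a, "", fixed = TRUE)[[1]]
  vb <- strsplit(b, "", fixed = TRUE)[[1]]
  mean(va == vb)
}

#' Read a multi-FASTA file into a named character vector
#'
#' @param path FASTA file path.
#' @return named character vector of uppercase sequences.
#' @export
read_fasta_genome <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  out <- toupper(as.character(ss))
  names(out) <- sub("\\s.*$", "", names(ss))
  out
}

#' Write a named character vector of sequences as FASTA
#'
#' @param genome named character vector of sequences.
#' @param path output file.
#' @export
write_fasta_genome <- function(genome, path) {
  ss <- Biostrings::DNAStringSet(unlist(genome))
  names(ss) <- names(genome)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
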