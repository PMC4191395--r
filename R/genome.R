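#' Generate a reproducible random toy genome
#'
#' Draws one or more uniform-random nucleotide sequences.  The same seed
#' always yields the same genome, so downstream results are reproducible
#' without shipping sequence files.  Uniform sampling gives a GC content of
#' 0.5 with binomial fluctuation (about +/- 0.01 at 10 kb), and makes long
#' exact repeats vanishingly unlikely, which is what the exact-match read
#' placement in [map_read_start()] relies on.
#'
#' @param seed Integer RNG seed.
#' @param n_refs Number of reference sequences to generate.
#' @param length Length of each reference in nucleotides; at least 1000.
#' @return A named [Biostrings::DNAStringSet] (`ref1`, `ref2`, ...).
#' @examples
#' g <- make_genome(1, 1, 1000)
#' names(g)
#' @export
make_genome <- function(seed, n_refs = 1L, length = 50000L) {
  if (!is.numeric(length) || length(length) != 1L || is.na(length) || length <= 0)
    stop("`length` must be a positive integer")
  if (length < 1000)
    stop("`length` must be at least 1000")
  n_refs <- as.integer(n_refs)
  if (is.na(n_refs) || n_refs < 1L)
    stop("`n_refs` must be a positive integer")
  length <- as.integer(length)
  seqs <- with_seed(seed, vapply(seq_len(n_refs), function(i) {
    paste(sample(c("A", "C", "G", "T"), length, replace = TRUE), collapse = "")
  }, character(1)))
  names(seqs) <- paste0("ref", seq_len(n_refs))
  Biostrings::DNAStringSet(seqs)
}

#' GC fraction of a genome
#'
#' @param genome A [Biostrings::DNAStringSet].
#' @return Numeric vector of per-reference G+C fractions.
#' @export
gc_fraction <- function(genome) {
  freq <- Biostrings::letterFrequency(genome, letters = c("G", "C"))
  as.numeric(rowSums(freq) / Biostrings::width(genome))
}

#' Read and write genomes as FASTA
#'
#' Thin wrappers around the Biostrings FASTA readers/writers so the
#' simulation and counting stages interoperate with standard tooling.
#'
#' @param genome A [Biostrings::DNAStringSet].
#' @param path File path.
#' @return `read_genome_fasta()` returns a [Biostrings::DNAStringSet];
#'   `write_genome_fasta()` returns `path` invisibly.
#' @export
write_genome_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(genome, filepath = path, format = "fasta")
  invisible(path)
}

#' @rdname write_genome_fasta
#' @export
read_genome_fasta <- function(path) {
  Biostrings::readDNAStringSet(path, format = "fasta")
}
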