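#' Simulate a 5'-monophosphorylated-end sequencing library as counts
#'
#' Computes a weight for every detectable 5' end and draws `library_size`
#' reads from a single multinomial over those weights.  Fixed-total sampling
#' is deliberate: when cleavage creates new ends, the pre-existing ends lose
#' a corresponding share of the library (competitive amplification), which is
#' what shifts the background population to a negative M value rather than
#' leaving it at zero.
#'
#' Weights per transcript with abundance `a`:
#' * native 5' end: `a * native_end_fraction * (1 - total cleavage fraction)`
#'   where the total cleavage fraction is `1 - prod(1 - efficiency)` over the
#'   transcript's sites at this timepoint - molecules that have been cleaved
#'   contribute their new downstream end instead of the native one;
#' * each cleaved site: `a * efficiency` at one position downstream of the
#'   site coordinate (strand-aware).
#'
#' When the library's `deplete_dependence` is set, site ends with a matching
#' dependence are multiplied by `depletion_factor` and native ends of
#' transcripts with a matching `accumulation_group` by `accumulation_factor`.
#'
#' @param transcripts List of [transcript_model()] objects.
#' @param spec A [library_spec()].
#' @param timepoint Timepoint label present in every site's efficiency map,
#'   or `"before"` for the untreated sample (all efficiencies zero).
#' @return An [end_counts] table whose counts sum to `spec$library_size`.
#' @examples
#' tx <- transcript_model("ref1", "+", 1000, 3000,
#'                        sites = list(cleavage_site(1500, c(t10 = 0.5))))
#' simulate_end_counts(list(tx), library_spec("after", 1000), "t10")
#' @export
simulate_end_counts <- function(transcripts, spec, timepoint = "before") {
  if (!inherits(spec, "library_spec")) stop("`spec` must be a library_spec")
  if (length(transcripts) == 0L) stop("`transcripts` must be a non-empty list")
  if (!all(vapply(transcripts, inherits, logical(1), "transcript_model")))
    stop("`transcripts` must be a list of transcript_model objects")

  rows <- lapply(transcripts, function(tx) {
    effs <- vapply(tx$sites, function(s) {
      if (identical(timepoint, "before")) return(0)
      if (!timepoint %in% names(s$efficiency_by_time))
        stop("timepoint \"", timepoint, "\" missing from a site's efficiency map")
      unname(s$efficiency_by_time[[timepoint]])
    }, numeric(1))
    cleaved <- if (length(effs)) 1 - prod(1 - effs) else 0
    native_w <- tx$abundance * tx$native_end_fraction * (1 - cleaved)
    acc <- !is.na(spec$deplete_dependence) &&
      identical(tx$accumulation_group, spec$deplete_dependence)
    if (acc) native_w <- native_w * spec$accumulation_factor
    out <- data.frame(reference = tx$reference, strand = tx$strand,
                      position = five_prime_end(tx), weight = native_w,
                      stringsAsFactors = FALSE)
    if (length(tx$sites)) {
      dep <- vapply(tx$sites, function(s) s$dependence, character(1))
      w <- tx$abundance * effs
      hit <- !is.na(spec$deplete_dependence) & dep == spec$deplete_dependence
      w[hit] <- w[hit] * spec$depletion_factor
      out <- rbind(out, data.frame(
        reference = tx$reference, strand = tx$strand,
        position = vapply(tx$sites, function(s) site_end_position(tx, s),
                          integer(1)),
        weight = w, stringsAsFactors = FALSE))
    }
    out
  })
  ends <- do.call(rbind, rows)
  ends <- ends[ends$weight > 0, , drop = FALSE]
  if (nrow(ends) == 0L || sum(ends$weight) <= 0)
    stop("all end weights are zero; nothing to sample")

  # collapse coincident ends before sampling
  key <- end_key(ends$reference, ends$strand, ends$position)
  agg <- rowsum(ends$weight, group = key)
  first <- !duplicated(key)
  idx <- match(rownames(agg), key[first])
  tab <- data.frame(reference = ends$reference[first][idx],
                    strand = ends$strand[first][idx],
                    position = ends$position[first][idx],
                    weight = agg[, 1L], stringsAsFactors = FALSE)

  counts <- with_seed(spec$seed,
                      as.integer(stats::rmultinom(1L, spec$library_size,
                                                  prob = tab$weight)))
  keep <- counts > 0L
  end_counts(data.frame(reference = tab$reference[keep],
                        strand = tab$strand[keep],
                        position = tab$position[keep],
                        count = counts[keep], stringsAsFactors = FALSE),
             condition = spec$condition,
             total_mapped = spec$library_size)
}

#' Default 5' sequencing adapter used by the simulator
#' @return A character scalar.
#' @export
default_adapter <- function() "GTTCAGAGTTCTACAGTCCGACGATC"

#' Emit synthetic reads from an end-count table
#'
#' Each count unit yields one read: `adapter + genome fragment (+ poly(A))`.
#' The genome-derived segment starts exactly at the counted position on the
#' counted strand (reverse-complemented for minus-strand ends, whose
#' fragments extend toward decreasing coordinates).  When `transcripts` are
#' supplied and the fragment would run past the 3' boundary of the transcript
#' containing the position, it is truncated there and a poly(A) run of
#' `polyA_len` is appended, mimicking poly(A)-polymerase tailing before
#' reverse transcription.  Qualities are constant `"I"` (Phred+33 score 40).
#'
#' @param counts An [end_counts] table.
#' @param genome A [Biostrings::DNAStringSet].
#' @param adapter 5' adapter sequence prefixed to every read.
#' @param read_length Target length of the genome-derived fragment (>= 20).
#' @param polyA_len Length of the appended poly(A) run on truncated
#'   fragments.
#' @param seed Seed used to shuffle read order.
#' @param transcripts Optional list of [transcript_model()] objects supplying
#'   3' boundaries for truncation.
#' @return A data frame with columns `id`, `sequence`, `quality`.
#' @export
emit_reads <- function(counts, genome, adapter = default_adapter(),
                       read_length = 40L, polyA_len = 8L, seed = 1L,
                       transcripts = NULL) {
  if (read_length < 20L) stop("`read_length` must be >= 20")
  ref_len <- stats::setNames(Biostrings::width(genome), names(genome))
  if (any(!counts$reference %in% names(genome)))
    stop("count table references missing from genome")
  if (any(counts$position < 1L | counts$position > ref_len[counts$reference]))
    stop("counted position outside genome bounds")

  limit3 <- function(ref, strand, pos) {
    # 3' boundary (strand-aware) of the first transcript containing pos
    if (!is.null(transcripts)) {
      for (tx in transcripts) {
        if (tx$reference == ref && tx$strand == strand &&
            pos >= tx$start && pos <= tx$end)
          return(if (strand == "+") tx$end else tx$start)
      }
    }
    if (strand == "+") unname(ref_len[ref]) else 1L
  }

  n <- nrow(counts)
  frag <- character(n)
  truncated <- logical(n)
  genome_chr <- stats::setNames(as.character(genome), names(genome))
  for (i in seq_len(n)) {
    ref <- counts$reference[i]; s <- counts$strand[i]; p <- counts$position[i]
    lim <- limit3(ref, s, p)
    if (s == "+") {
      e <- min(p + read_length - 1L, lim)
      frag[i] <- substr(genome_chr[[ref]], p, e)
      truncated[i] <- e < p + read_length - 1L
    } else {
      b <- max(p - read_length + 1L, lim)
      fwd <- substr(genome_chr[[ref]], b, p)
      frag[i] <- as.character(
        Biostrings::reverseComplement(Biostrings::DNAString(fwd)))
      truncated[i] <- b > p - read_length + 1L
    }
  }
  seqs <- paste0(adapter, frag,
                 ifelse(truncated, strrep("A", polyA_len), ""))
  seqs <- rep(seqs, times = counts$count)
  ord <- with_seed(seed, sample.int(length(seqs)))
  seqs <- seqs[ord]
  data.frame(id = sprintf("read%07d", seq_along(seqs)),
             sequence = seqs,
             quality = strrep("I", nchar(seqs)),
             stringsAsFactors = FALSE)
}

#' Read and write reads as FASTQ
#'
#' @param reads Data frame with columns `id`, `sequence`, `quality`, as
#'   produced by [emit_reads()].
#' @param path File path (gzip-transparent on read).
#' @return `write_fastq()` returns `path` invisibly; `read_fastq()` returns a
#'   data frame with columns `id`, `sequence`, `quality`.
#' @export
write_fastq <- function(reads, path) {
  x <- Biostrings::DNAStringSet(stats::setNames(reads$sequence, reads$id))
  Biostrings::writeXStringSet(x, filepath = path, format = "fastq",
                              qualities = Biostrings::BStringSet(reads$quality))
  invisible(path)
}

#' @rdname write_fastq
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq",
                                    with.qualities = TRUE)
  data.frame(id = names(x), sequence = as.character(x),
             quality = as.character(S4Vectors::mcols(x)$qualities),
             stringsAsFactors = FALSE, row.names = NULL)
}
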