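#' Count read starts from aligned reads (SAM text or BED6)
#'
#' The real-data entry point: per alignment record the 5'-end position is
#'
#' * forward strand - the first aligned reference base (`POS`; 5' soft clips
#'   are *not* added back, since adapters are removed before alignment in
#'   this protocol and residual clips denote low-quality tails);
#' * reverse strand (`FLAG` 0x10) - the last aligned reference base,
#'   `POS + reference-consumed CIGAR length - 1`;
#' * BED6 - `start + 1` for `+`, `end` for `-` (BED is 0-based half-open).
#'
#' Unmapped (0x4), secondary (0x100) and supplementary (0x800) records are
#' skipped.  Malformed CIGAR strings or truncated records raise a parse
#' error naming the offending line.
#'
#' @param path Path to a SAM text file or a BED file with >= 6 columns.
#' @param format `"auto"` (by file extension), `"sam"` or `"bed"`.
#' @param condition Condition label for the resulting table.
#' @return An [end_counts] table.
#' @export
count_starts_from_alignments <- function(path,
                                         format = c("auto", "sam", "bed"),
                                         condition = NA_character_) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.bed(\\.gz)?$", path, ignore.case = TRUE))
      "bed" else "sam"
  }
  if (format == "sam") count_starts_from_sam(path, condition)
  else count_starts_from_bed(path, condition)
}

# Reference-consumed length of a CIGAR string (ops M, D, N, =, X).
cigar_ref_length <- function(cigar, line = NA_integer_) {
  if (is.na(cigar) || cigar == "*" || cigar == "")
    stop("malformed CIGAR at line ", line)
  m <- gregexpr("([0-9]+)([MIDNSHP=X])", cigar)[[1L]]
  if (m[1L] == -1L ||
      sum(attr(m, "match.length")) != nchar(cigar))
    stop("malformed CIGAR \"", cigar, "\" at line ", line)
  tok <- regmatches(cigar, gregexpr("([0-9]+)([MIDNSHP=X])", cigar))[[1L]]
  len <- as.integer(sub("[MIDNSHP=X]$", "", tok))
  op <- sub("^[0-9]+", "", tok)
  sum(len[op %in% c("M", "D", "N", "=", "X")])
}

count_starts_from_sam <- function(path, condition = NA_character_) {
  lines <- readLines(path)
  body <- which(!startsWith(lines, "@"))
  refs <- character(0); strands <- character(0); pos <- integer(0)
  for (i in body) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 11L)
      stop("truncated SAM record at line ", i)
    flag <- suppressWarnings(as.integer(f[2L]))
    if (is.na(flag)) stop("invalid FLAG at line ", i)
    if (bitwAnd(flag, 0x4L) != 0L) next            # unmapped
    if (bitwAnd(flag, 0x100L) != 0L) next          # secondary
    if (bitwAnd(flag, 0x800L) != 0L) next          # supplementary
    p <- suppressWarnings(as.integer(f[4L]))
    if (is.na(p) || p < 1L) stop("invalid POS at line ", i)
    rlen <- cigar_ref_length(f[6L], line = i)
    if (bitwAnd(flag, 0x10L) != 0L) {
      strands <- c(strands, "-"); pos <- c(pos, p + rlen - 1L)
    } else {
      strands <- c(strands, "+"); pos <- c(pos, p)
    }
    refs <- c(refs, f[3L])
  }
  if (length(refs) == 0L) stop("no usable alignment records in ", path)
  tab <- tally_ends(refs, strands, pos)
  end_counts(tab, condition = condition, total_mapped = length(refs))
}

count_starts_from_bed <- function(path, condition = NA_character_) {
  gr <- rtracklayer::import(path, format = "BED")
  strand <- as.character(GenomicRanges::strand(gr))
  if (any(!strand %in% c("+", "-")))
    stop("BED records must carry a +/- strand in column 6")
  pos <- ifelse(strand == "+", GenomicRanges::start(gr),
                GenomicRanges::end(gr))
  tab <- tally_ends(as.character(GenomicRanges::seqnames(gr)), strand, pos)
  end_counts(tab, condition = condition, total_mapped = length(gr))
}
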