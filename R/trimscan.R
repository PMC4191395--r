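#' Configuration for the 5'-trimming pair scan
#'
#' Thresholds are read off a single WT-numerator M-A table: a *processed*
#' end is depleted in the mutant when `M >= depletion_m`; a *precursor* end
#' is accumulated when `M <= -accumulation_m`.  The scan window extends
#' strictly less than `max_extension` nucleotides upstream in transcript
#' orientation.
#'
#' @param max_extension Window size in nucleotides (strict `<`).
#' @param depletion_m Minimum M for a depleted processed end.
#' @param accumulation_m Minimum magnitude of the (negative) M of an
#'   accumulated precursor end.
#' @param min_reads Minimum supporting reads at each member (numerator reads
#'   for the depleted end, denominator reads for the accumulated end).
#' @return An object of class `trim_scan_config`.
#' @export
trim_scan_config <- function(max_extension = 200L, depletion_m = 2,
                             accumulation_m = 2, min_reads = 5L) {
  max_extension <- as.integer(max_extension)
  if (is.na(max_extension) || max_extension < 1L)
    stop("`max_extension` must be >= 1")
  if (depletion_m <= 0 || accumulation_m <= 0)
    stop("thresholds must be > 0")
  structure(list(max_extension = max_extension, depletion_m = depletion_m,
                 accumulation_m = accumulation_m,
                 min_reads = as.integer(min_reads)),
            class = "trim_scan_config")
}

#' Detect paired 5'-trimming events
#'
#' The signature of a 5'-trimming nuclease in a WT-versus-knockout
#' comparison: the processed 5' end it generates is depleted in the
#' knockout (positive M with WT in the numerator) while a 5'-extended
#' precursor end accumulates a short distance *upstream* (negative M).
#' Upstream is taken in transcript orientation - smaller coordinates on the
#' plus strand, larger on the minus strand - because 5' extension is a
#' transcript-coordinate concept.
#'
#' For each depleted position the upstream window of `max_extension - 1`
#' nucleotides is scanned; if one or more accumulated positions exist, one
#' event is emitted using the partner with the most negative M (ties broken
#' by the shortest distance).  Depleted positions with no partner emit
#' nothing.  Set `all_pairs = TRUE` to emit every qualifying partner
#' instead of the single best one.
#'
#' @param ma An `ma_table` from a WT-numerator comparison.
#' @param config A [trim_scan_config()].
#' @param all_pairs Emit all qualifying partners per depleted end.
#' @return A data frame of class `trim_pair_events` with columns
#'   `reference`, `strand`, `processed_position`, `precursor_position`,
#'   `distance`, `M_processed`, `M_precursor`, `tss_match` (`NA` until
#'   [match_to_tss()] is applied).
#' @export
detect_trim_pairs <- function(ma, config = trim_scan_config(),
                              all_pairs = FALSE) {
  dep <- which(ma$M >= config$depletion_m & ma$reads_a >= config$min_reads)
  acc <- which(ma$M <= -config$accumulation_m & ma$reads_b >= config$min_reads)
  rows <- list()
  for (i in dep) {
    j <- acc[ma$reference[acc] == ma$reference[i] &
               ma$strand[acc] == ma$strand[i]]
    if (length(j) == 0L) next
    d <- if (ma$strand[i] == "+") ma$position[i] - ma$position[j]
         else ma$position[j] - ma$position[i]
    ok <- d >= 1L & d < config$max_extension
    j <- j[ok]; d <- d[ok]
    if (length(j) == 0L) next
    pick <- if (all_pairs) order(ma$M[j], d) else
      order(ma$M[j], d)[1L]   # most negative M, then shortest distance
    rows[[length(rows) + 1L]] <- data.frame(
      reference = ma$reference[i], strand = ma$strand[i],
      processed_position = ma$position[i],
      precursor_position = ma$position[j][pick],
      distance = as.integer(d[pick]),
      M_processed = ma$M[i], M_precursor = ma$M[j][pick],
      tss_match = NA, stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(reference = character(0), strand = character(0),
               processed_position = integer(0),
               precursor_position = integer(0), distance = integer(0),
               M_processed = numeric(0), M_precursor = numeric(0),
               tss_match = logical(0), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out, config = config,
            class = c("trim_pair_events", "data.frame"))
}

#' Flag trim-pair precursors that coincide with transcription start sites
#'
#' A precursor whose 5' end lies within `tolerance` nucleotides of an
#' annotated TSS on the same reference and strand is a candidate primary
#' transcript, implying the trimming cleavage acts downstream of
#' pyrophosphate removal.
#'
#' @param events A `trim_pair_events` data frame.
#' @param tss TSS annotation: a BED6 file path, or a data frame with columns
#'   `reference`, `strand`, `position` (1-based TSS coordinates).
#' @param tolerance Maximum distance in nucleotides.
#' @return `events` with the `tss_match` column filled in.
#' @export
match_to_tss <- function(events, tss, tolerance = 1L) {
  tolerance <- as.integer(tolerance)
  if (is.character(tss)) {
    gr <- rtracklayer::import(tss, format = "BED")
    strand <- as.character(GenomicRanges::strand(gr))
    if (any(!strand %in% c("+", "-")))
      stop("TSS BED records must carry a +/- strand")
    tss <- data.frame(reference = as.character(GenomicRanges::seqnames(gr)),
                      strand = strand,
                      position = ifelse(strand == "+",
                                        GenomicRanges::start(gr),
                                        GenomicRanges::end(gr)),
                      stringsAsFactors = FALSE)
  }
  events$tss_match <- vapply(seq_len(nrow(events)), function(i) {
    any(tss$reference == events$reference[i] &
          tss$strand == events$strand[i] &
          abs(tss$position - events$precursor_position[i]) <= tolerance)
  }, logical(1))
  events
}

#' Write trim-pair events as TSV
#'
#' @param events A `trim_pair_events` data frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trim_pairs_tsv <- function(events, path) {
  utils::write.table(as.data.frame(events), file = path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
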