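#' Strand-specific 5'-end count table
#'
#' The central container of the pipeline: a data frame with one row per
#' (reference, strand, 1-based position) holding the number of read 5' ends
#' counted there.  Zero counts are never stored.  The condition label and the
#' total number of mapped reads travel as attributes.
#'
#' @param df Data frame with columns `reference`, `strand`, `position`,
#'   `count`.
#' @param condition Condition label.
#' @param total_mapped Total mapped reads (defaults to `sum(count)`).
#' @return A data frame of class `end_counts`, sorted by reference, strand
#'   and position.
#' @export
end_counts <- function(df, condition = NA_character_,
                       total_mapped = sum(df$count)) {
  need <- c("reference", "strand", "position", "count")
  if (!all(need %in% names(df)))
    stop("`df` must have columns ", paste(need, collapse = ", "))
  df <- df[, need, drop = FALSE]
  df$reference <- as.character(df$reference)
  df$strand <- as.character(df$strand)
  df$position <- as.integer(df$position)
  df$count <- as.integer(df$count)
  if (any(!df$strand %in% c("+", "-"))) stop("strand must be \"+\" or \"-\"")
  if (any(df$count < 1L)) stop("zero or negative counts must not be stored")
  if (any(df$position < 1L)) stop("positions must be 1-based and positive")
  df <- df[order(df$reference, df$strand, df$position), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, condition = as.character(condition),
            total_mapped = as.integer(total_mapped),
            class = c("end_counts", "data.frame"))
}

#' @export
print.end_counts <- function(x, ...) {
  cat(sprintf("<end_counts> condition=%s positions=%d total_mapped=%d\n",
              attr(x, "condition"), nrow(x), attr(x, "total_mapped")))
  print(utils::head(as.data.frame(x), 6L))
  if (nrow(x) > 6L) cat("...\n")
  invisible(x)
}

# Aggregate duplicate (reference, strand, position) keys by summing counts.
tally_ends <- function(reference, strand, position, count = 1L) {
  key <- end_key(reference, strand, position)
  count <- rep_len(as.numeric(count), length(key))
  agg <- rowsum(count, group = key)
  first <- !duplicated(key)
  idx <- match(rownames(agg), key[first])
  data.frame(reference = reference[first][idx], strand = strand[first][idx],
             position = position[first][idx], count = as.integer(agg[, 1L]),
             stringsAsFactors = FALSE)
}

#' Read and write end-count tables as TSV
#'
#' The TSV layout is `reference`, `strand`, `position` (1-based) and
#' `count`, with a header line.
#'
#' @param x An [end_counts] table.
#' @param path File path.
#' @param condition Condition label to attach on read (defaults to the file
#'   name).
#' @return `write_end_counts_tsv()` returns `path` invisibly;
#'   `read_end_counts_tsv()` returns an [end_counts] table.
#' @export
write_end_counts_tsv <- function(x, path) {
  utils::write.table(as.data.frame(x), file = path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_end_counts_tsv
#' @export
read_end_counts_tsv <- function(path, condition = basename(path)) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = c("character", "character",
                                         "integer", "integer"))
  end_counts(df, condition = condition)
}

#' Write an end-count table as a strand-split bedGraph pair
#'
#' Produces `<prefix>_plus.bedgraph` and `<prefix>_minus.bedgraph`.  Internal
#' coordinates are 1-based closed; the bedGraph files are 0-based half-open
#' intervals of width 1, with the conversion handled by the rtracklayer
#' writer.
#'
#' @param x An [end_counts] table.
#' @param prefix Output path prefix.
#' @return Character vector of the two file paths, invisibly.
#' @export
write_bedgraph_pair <- function(x, prefix) {
  paths <- c(paste0(prefix, "_plus.bedgraph"), paste0(prefix, "_minus.bedgraph"))
  for (i in 1:2) {
    s <- c("+", "-")[i]
    sub <- x[x$strand == s, , drop = FALSE]
    gr <- GenomicRanges::GRanges(
      seqnames = sub$reference,
      ranges = IRanges::IRanges(start = sub$position, width = 1L),
      score = sub$count)
    rtracklayer::export(gr, paths[i], format = "bedGraph")
  }
  invisible(paths)
}

#' Write positions as BED6
#'
#' Used for planted-truth sites (score = efficiency x 1000) and for site
#' calls (score = `min(1000, round(100 * M))`).  Input coordinates are
#' 1-based single nucleotides; the writer emits standard 0-based half-open
#' BED.
#'
#' @param reference,strand,position Parallel vectors describing positions.
#' @param score Numeric BED score.
#' @param name Feature names.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_bed6 <- function(reference, strand, position, score, name, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = reference,
    ranges = IRanges::IRanges(start = position, width = 1L),
    strand = strand)
  gr$score <- score
  gr$name <- name
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}
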