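#' Trimming policy for 5'-end sequencing reads
#'
#' The adapter is matched only as an anchored prefix; a terminal 3' A-run of
#' at least `min_polyA` nucleotides is removed (internal A-runs are genomic
#' signal and are kept).  Reads lacking the adapter, or shorter than
#' `min_length` after trimming, are rejected with a counted reason rather
#' than an error.
#'
#' @param adapter Adapter sequence expected at the 5' end of every read.
#' @param max_mismatches Maximum mismatches tolerated in the adapter prefix.
#' @param min_polyA Minimum length of a terminal A-run for it to be trimmed.
#' @param min_length Minimum post-trim read length; must be >= 12, below
#'   which exact placement on even a toy genome is not unique.
#' @return An object of class `trim_policy`.
#' @export
trim_policy <- function(adapter = default_adapter(), max_mismatches = 0L,
                        min_polyA = 5L, min_length = 15L) {
  if (!nzchar(adapter)) stop("`adapter` must be a non-empty sequence")
  if (min_length < 12L) stop("`min_length` must be >= 12")
  if (min_polyA < 1L) stop("`min_polyA` must be >= 1")
  structure(list(adapter = toupper(adapter),
                 max_mismatches = as.integer(max_mismatches),
                 min_polyA = as.integer(min_polyA),
                 min_length = as.integer(min_length)),
            class = "trim_policy")
}

#' Trim adapter and poly(A) from reads
#'
#' @param sequences Character vector of read sequences.
#' @param policy A [trim_policy()].
#' @return A list with `sequence` (trimmed sequence, `NA` where rejected) and
#'   `reason` (`"kept"`, `"no_adapter"` or `"too_short"`), both parallel to
#'   the input.
#' @examples
#' p <- trim_policy(adapter = "ADAPT" , min_polyA = 5)
#' trim_reads(paste0("ADAPT", "ACGTACGTACGTACGT", "AAAAAA"), p)
#' @export
trim_reads <- function(sequences, policy = trim_policy()) {
  x <- toupper(as.character(sequences))
  alen <- nchar(policy$adapter)
  pref <- substr(x, 1L, alen)
  if (policy$max_mismatches == 0L) {
    ok <- pref == policy$adapter & nchar(x) >= alen
  } else {
    ad <- charToRaw(policy$adapter)
    mm <- vapply(pref, function(p) {
      if (nchar(p) < alen) return(alen)
      sum(charToRaw(p) != ad)
    }, integer(1), USE.NAMES = FALSE)
    ok <- mm <= policy$max_mismatches
  }
  body <- substr(x, alen + 1L, nchar(x))
  body <- sub(sprintf("A{%d,}$", policy$min_polyA), "", body)
  reason <- rep("kept", length(x))
  reason[!ok] <- "no_adapter"
  reason[ok & nchar(body) < policy$min_length] <- "too_short"
  body[reason != "kept"] <- NA_character_
  list(sequence = body, reason = reason)
}

#' @rdname trim_reads
#' @param sequence A single read sequence.
#' @export
trim_read <- function(sequence, policy = trim_policy()) {
  r <- trim_reads(sequence, policy)
  list(sequence = r$sequence[[1L]], reason = r$reason[[1L]])
}

#' Place trimmed reads on a genome by exact match
#'
#' Attempts a full-length exact match of each read on both strands of every
#' reference.  A unique match yields the genomic coordinate of the read's
#' 5'-most base: the match start on the plus strand, the match *end* (larger
#' coordinate) on the minus strand.  Zero matches reject the read as
#' `"unmapped"`, more than one as `"multimapped"` (positional precision is
#' the product here, so multi-mappers are discarded rather than assigned
#' fractionally).
#'
#' @param sequences Character vector of trimmed read sequences.
#' @param genome A [Biostrings::DNAStringSet].
#' @return A data frame parallel to the input with columns `reference`,
#'   `strand`, `position` (`NA` where rejected) and `reason` (`"mapped"`,
#'   `"unmapped"` or `"multimapped"`).
#' @export
map_read_start <- function(sequences, genome) {
  x <- as.character(sequences)
  uq <- unique(x[!is.na(x)])
  place <- function(s) {
    hits <- list()
    pat <- Biostrings::DNAString(s)
    rcp <- Biostrings::reverseComplement(pat)
    for (rn in names(genome)) {
      f <- Biostrings::matchPattern(pat, genome[[rn]])
      if (length(f))
        hits[[length(hits) + 1L]] <- data.frame(
          reference = rn, strand = "+",
          position = Biostrings::start(f), stringsAsFactors = FALSE)
      r <- Biostrings::matchPattern(rcp, genome[[rn]])
      if (length(r))
        hits[[length(hits) + 1L]] <- data.frame(
          reference = rn, strand = "-",
          position = Biostrings::end(r), stringsAsFactors = FALSE)
    }
    if (length(hits) == 0L)
      return(data.frame(reference = NA_character_, strand = NA_character_,
                        position = NA_integer_, reason = "unmapped",
                        stringsAsFactors = FALSE))
    h <- do.call(rbind, hits)
    if (nrow(h) > 1L)
      return(data.frame(reference = NA_character_, strand = NA_character_,
                        position = NA_integer_, reason = "multimapped",
                        stringsAsFactors = FALSE))
    h$reason <- "mapped"
    h
  }
  lookup <- do.call(rbind, lapply(uq, place))
  idx <- match(x, uq)
  out <- lookup[idx, , drop = FALSE]
  out[is.na(idx), ] <- data.frame(reference = NA_character_,
                                  strand = NA_character_,
                                  position = NA_integer_,
                                  reason = NA_character_)
  rownames(out) <- NULL
  out
}

#' Count read starts from raw reads
#'
#' Full raw-read path: trim (adapter + poly(A)), place by exact match, and
#' tally 5'-end positions.  Every input read is accounted for:
#' `input = mapped + no_adapter + too_short + unmapped + multimapped`.
#'
#' @param reads Data frame with a `sequence` column (e.g. from
#'   [emit_reads()] or [read_fastq()]), or a character vector of sequences.
#' @param genome A [Biostrings::DNAStringSet].
#' @param policy A [trim_policy()].
#' @param condition Condition label for the resulting table.
#' @return A list with `counts` (an [end_counts] table) and `report` (named
#'   integer vector of read fates).
#' @export
count_from_reads <- function(reads, genome, policy = trim_policy(),
                             condition = NA_character_) {
  seqs <- if (is.data.frame(reads)) reads$sequence else as.character(reads)
  tr <- trim_reads(seqs, policy)
  kept <- tr$reason == "kept"
  mp <- map_read_start(tr$sequence[kept], genome)
  reason <- tr$reason
  reason[kept] <- mp$reason
  ok <- which(kept)[mp$reason == "mapped"]
  mpd <- mp[mp$reason == "mapped", , drop = FALSE]
  report <- c(input = length(seqs),
              mapped = nrow(mpd),
              no_adapter = sum(reason == "no_adapter"),
              too_short = sum(reason == "too_short"),
              unmapped = sum(reason == "unmapped"),
              multimapped = sum(reason == "multimapped"))
  if (nrow(mpd) == 0L) stop("no reads mapped; check adapter and genome")
  tab <- tally_ends(mpd$reference, mpd$strand, mpd$position)
  list(counts = end_counts(tab, condition = condition,
                           total_mapped = nrow(mpd)),
       report = report)
}

#' Write a trimming/mapping report as key:value text
#'
#' @param report Named integer vector from [count_from_reads()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trim_report <- function(report, path) {
  writeLines(paste0(names(report), ":", as.integer(report)), path)
  invisible(path)
}
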