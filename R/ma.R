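#' Per-position M and A values between two count tables
#'
#' For every position with a read-start count in at least one table,
#' `M = log2(reads_a / reads_b)` and `A = (log2 reads_a + log2 reads_b) / 2`,
#' with `reads_a` the numerator condition (e.g. after incubation with the
#' enzyme, or the wild type in a WT/mutant comparison).  A side with no
#' reads is replaced by the nominal count (default 1, the lowest limit of
#' detection) and flagged; positions absent from both tables never appear.
#' No library-size normalisation is applied: M is computed on raw read
#' counts and composition effects are handled downstream via the baseline.
#'
#' @param table_a Numerator [end_counts] table.
#' @param table_b Denominator [end_counts] table.
#' @param nominal Positive count substituted for an absent side.
#' @return A data frame of class `ma_table` with columns `reference`,
#'   `strand`, `position`, `reads_a`, `reads_b`, `nominal_a`, `nominal_b`,
#'   `M`, `A`; condition labels are carried in attributes `condition_a` and
#'   `condition_b`.
#' @examples
#' a <- end_counts(data.frame(reference = "ref1", strand = "+",
#'                            position = 100, count = 64), "after")
#' b <- end_counts(data.frame(reference = "ref1", strand = "+",
#'                            position = 100, count = 4), "before")
#' compute_ma(a, b)   # M = 4, A = 4
#' @export
compute_ma <- function(table_a, table_b, nominal = 1) {
  if (!is.numeric(nominal) || nominal <= 0)
    stop("`nominal` must be a positive count")
  ka <- end_key(table_a$reference, table_a$strand, table_a$position)
  kb <- end_key(table_b$reference, table_b$strand, table_b$position)
  keys <- union(ka, kb)
  ia <- match(keys, ka); ib <- match(keys, kb)
  src <- ifelse(is.na(ia), ib + nrow(table_a), ia)
  both <- rbind(as.data.frame(table_a)[, c("reference", "strand", "position")],
                as.data.frame(table_b)[, c("reference", "strand", "position")])
  out <- both[src, , drop = FALSE]
  out$reads_a <- ifelse(is.na(ia), nominal, table_a$count[ia])
  out$reads_b <- ifelse(is.na(ib), nominal, table_b$count[ib])
  out$nominal_a <- is.na(ia)
  out$nominal_b <- is.na(ib)
  la <- log2(out$reads_a); lb <- log2(out$reads_b)
  out$M <- la - lb
  out$A <- (la + lb) / 2
  out <- out[order(out$reference, out$strand, out$position), , drop = FALSE]
  rownames(out) <- NULL
  structure(out,
            condition_a = attr(table_a, "condition"),
            condition_b = attr(table_b, "condition"),
            nominal = nominal,
            class = c("ma_table", "data.frame"))
}

#' @export
print.ma_table <- function(x, ...) {
  cat(sprintf("<ma_table> %s vs %s, %d positions\n",
              attr(x, "condition_a"), attr(x, "condition_b"), nrow(x)))
  print(utils::head(as.data.frame(x), 6L))
  if (nrow(x) > 6L) cat("...\n")
  invisible(x)
}

#' Estimate the baseline M of the unenriched population
#'
#' The background of pre-existing 5' ends forms a dense cone on the M-A
#' plot whose centre sits below zero (newly generated ends dilute the
#' starting material under fixed-depth sampling).  Because the enriched
#' cloud can outnumber the cone, the estimate is the *mode* of the M
#' histogram - the centre of the densest bin - over non-nominal records,
#' not a mean or median, which the enriched points would bias.  Bins are
#' anchored at multiples of `bin_width`; ties go to the smaller M.
#'
#' @param records An `ma_table` (or data frame with `M`, `nominal_a`,
#'   `nominal_b`).
#' @param bin_width Histogram bin width in M units.
#' @param exclude_nominal Drop records where either side used the nominal
#'   count (they have no defined ratio).
#' @return An object of class `baseline_estimate` with fields `baseline`,
#'   `method`, `bin_width`, `n_used`.
#' @export
estimate_baseline <- function(records, bin_width = 0.1,
                              exclude_nominal = TRUE) {
  if (bin_width <= 0) stop("`bin_width` must be > 0")
  m <- records$M
  if (exclude_nominal) m <- m[!records$nominal_a & !records$nominal_b]
  m <- m[is.finite(m)]
  if (length(m) < 100L)
    stop("fewer than 100 usable records; supply the baseline manually or ",
         "set exclude_nominal = FALSE")
  bin <- round(m / bin_width)   # bins centred on multiples of bin_width
  tab <- table(bin)
  best <- as.integer(names(tab)[tab == max(tab)])
  centre <- min(best) * bin_width           # ties broken toward smaller M
  structure(list(baseline = centre, method = "histogram_mode",
                 bin_width = bin_width, n_used = length(m)),
            class = "baseline_estimate")
}

#' @export
print.baseline_estimate <- function(x, ...) {
  cat(sprintf("<baseline_estimate> M = %.3f (%s, bin %.2g, n = %d)\n",
              x$baseline, x$method, x$bin_width, x$n_used))
  invisible(x)
}

#' Baseline-normalised fold change
#'
#' `2^(M - baseline)`: the fold enrichment of a position relative to the
#' centre of the unenriched population.  With the in vitro baseline of -1.6,
#' a raw M of 2 is already a >10-fold increase.
#'
#' @param M Raw M value(s).
#' @param baseline Baseline M of the unenriched population.
#' @return Positive numeric fold change.
#' @examples
#' normalized_fold(2, -1.6)    # 12.13
#' normalized_fold(3.4, -1.6)  # 32
#' @export
normalized_fold <- function(M, baseline) 2^(M - baseline)

#' Raw M threshold for a desired baseline-normalised enrichment
#'
#' `baseline + enrichment`: e.g. requiring a log2 enrichment of 5 over a
#' baseline of -1.6 means calling raw M values of at least 3.4.
#'
#' @param enrichment Desired normalised log2 enrichment.
#' @param baseline Baseline M.
#' @return Raw M threshold.
#' @export
threshold_for_enrichment <- function(enrichment, baseline)
  baseline + enrichment

#' Configuration for site calling
#'
#' Defaults follow the in vitro comparison: raw M threshold 3.4 over a
#' baseline of -1.6 (a 32-fold normalised enrichment).  For WT-versus-mutant
#' in vivo comparisons use `threshold = 5, baseline = 0`.  The minimum-reads
#' filter suppresses nominal-count artifacts at singleton positions; set it
#' to 0 to disable.
#'
#' @param threshold Raw M threshold (inclusive).
#' @param baseline Baseline M used for normalised fold reporting.
#' @param min_reads Minimum numerator reads for a call.
#' @return An object of class `site_call_config`.
#' @export
site_call_config <- function(threshold = 3.4, baseline = -1.6,
                             min_reads = 5L) {
  if (threshold <= baseline) stop("`threshold` must exceed `baseline`")
  if (min_reads < 0L) stop("`min_reads` must be >= 0")
  structure(list(threshold = threshold, baseline = baseline,
                 min_reads = as.integer(min_reads)),
            class = "site_call_config")
}

#' Call sites above an M threshold
#'
#' Emits exactly the records with `M >= threshold` and
#' `reads_a >= min_reads`, sorted by decreasing M (ties by coordinate),
#' annotated with the baseline-normalised log2 enrichment and fold change.
#'
#' @param records An `ma_table`.
#' @param config A [site_call_config()].
#' @return A data frame of class `site_calls` with columns `reference`,
#'   `strand`, `position`, `reads_a`, `reads_b`, `M`, `A`, `enrichment`,
#'   `fold`, `comparison`.
#' @export
call_sites <- function(records, config = site_call_config()) {
  if (!inherits(config, "site_call_config"))
    stop("`config` must be a site_call_config")
  sel <- records$M >= config$threshold & records$reads_a >= config$min_reads
  out <- as.data.frame(records)[sel, c("reference", "strand", "position",
                                       "reads_a", "reads_b", "M", "A"),
                                drop = FALSE]
  out$enrichment <- out$M - config$baseline
  out$fold <- 2^out$enrichment
  out$comparison <- rep_len(paste(attr(records, "condition_a"), "vs",
                                  attr(records, "condition_b")), nrow(out))
  out <- out[order(-out$M, out$reference, out$strand, out$position),
             , drop = FALSE]
  rownames(out) <- NULL
  structure(out, config = config, class = c("site_calls", "data.frame"))
}

#' Write site calls as BED6
#'
#' Score is `min(1000, round(100 * M))`.
#'
#' @param calls A `site_calls` data frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_site_calls_bed <- function(calls, path) {
  write_bed6(calls$reference, calls$strand, calls$position,
             score = pmin(1000, round(100 * calls$M)),
             name = sprintf("site%04d", seq_len(nrow(calls))),
             path = path)
}

#' Count records exceeding each of several M thresholds
#'
#' Strictly-greater-than counts (`M > t`), matching how genome-wide tallies
#' above a cutoff are usually quoted; the calling threshold in
#' [call_sites()] is by contrast inclusive.
#'
#' @param records An `ma_table` (or anything with an `M` column).
#' @param thresholds Numeric vector of thresholds.
#' @return Named integer vector, one count per threshold; non-increasing in
#'   the threshold.
#' @examples
#' df <- data.frame(M = c(1, 3, 6, 11))
#' count_by_threshold(df, c(2, 5, 10))  # 3, 2, 1
#' @export
count_by_threshold <- function(records, thresholds) {
  if (any(!is.finite(thresholds))) stop("`thresholds` must be finite")
  stats::setNames(vapply(thresholds, function(t) sum(records$M > t),
                         integer(1)),
                  as.character(thresholds))
}

#' Read and write M-A tables as TSV
#'
#' @param x An `ma_table`.
#' @param path File path.
#' @return `write_ma_tsv()` returns `path` invisibly; `read_ma_tsv()`
#'   returns an `ma_table`.
#' @export
write_ma_tsv <- function(x, path) {
  utils::write.table(as.data.frame(x), file = path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ma_tsv
#' @export
read_ma_tsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  structure(df, class = c("ma_table", "data.frame"))
}
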