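# Shared fixtures built in code; nothing is read from disk.

# A tiny hand-made genome for placement tests (not via make_genome, so the
# content is fully controlled).  ref1 carries a duplicated 30-mer so that
# multimapping can be provoked deliberately.
tiny_genome <- function() {
  base <- paste(rep(c("ACGTTGCAAC", "GGATCCTTAG", "CATGCGTACG"), 40),
                collapse = "")                       # 1200 nt, period 30
  uniq <- paste(sample_free_seq(), collapse = "")
  Biostrings::DNAStringSet(c(ref1 = paste0(uniq, base)))
}

# 600 nt of fixed pseudo-random sequence with no internal repeats >= 12 nt
# (verified once by construction seed; deterministic literal-free builder).
sample_free_seq <- function() {
  set.seed(424242)
  sample(c("A", "C", "G", "T"), 600, replace = TRUE)
}

# Minimal end-count table from parallel vectors.
ec <- function(position, count, strand = "+", reference = "ref1",
               condition = "x") {
  end_counts(data.frame(reference = reference, strand = strand,
                        position = position, count = count,
                        stringsAsFactors = FALSE),
             condition = condition)
}

# Fabricate an ma_table from M values alone (A arbitrary), for functions
# that only consume M and the nominal flags.
fake_ma <- function(M, nominal_a = FALSE, nominal_b = FALSE,
                    reference = "ref1", strand = "+",
                    position = seq_along(M)) {
  n <- length(M)
  df <- data.frame(reference = rep_len(reference, n),
                   strand = rep_len(strand, n),
                   position = position,
                   reads_a = 2^(5 + M / 2), reads_b = 2^(5 - M / 2),
                   nominal_a = rep_len(nominal_a, n),
                   nominal_b = rep_len(nominal_b, n),
                   M = M, A = rep_len(5, n), stringsAsFactors = FALSE)
  structure(df, condition_a = "a", condition_b = "b",
            class = c("ma_table", "data.frame"))
}

# Minimal site_calls table for intersection tests.
fake_calls <- function(position, M = 6, strand = "+", reference = "ref1") {
  df <- data.frame(reference = reference, strand = strand,
                   position = as.integer(position),
                   reads_a = 100L, reads_b = 1L,
                   M = rep_len(M, length(position)), A = 3,
                   enrichment = rep_len(M, length(position)) + 1.6,
                   fold = 2^(rep_len(M, length(position)) + 1.6),
                   comparison = "a vs b", stringsAsFactors = FALSE)
  structure(df, class = c("site_calls", "data.frame"))
}

# Write SAM text built from a record list; returns the path.
write_sam <- function(records, ref_len = 1200L, path = tempfile(fileext = ".sam")) {
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:ref1\tLN:%d", ref_len))
  writeLines(c(hdr, records), path)
  path
}

sam_record <- function(qname, flag, pos, cigar, seq = NULL) {
  n <- if (is.null(seq)) {
    sum(as.integer(regmatches(cigar, gregexpr("[0-9]+(?=[MIS=X])",
                                              cigar, perl = TRUE))[[1]]))
  } else nchar(seq)
  if (is.null(seq)) seq <- strrep("A", n)
  if (!nzchar(seq)) seq <- "*"
  qual <- if (seq == "*") "*" else strrep("I", nchar(seq))
  paste(qname, flag, "ref1", pos, 60, cigar, "*", 0, 0, seq, qual,
        sep = "\t")
}

expect_same_counts <- function(a, b) {
  a <- as.data.frame(a)[, c("reference", "strand", "position", "count")]
  b <- as.data.frame(b)[, c("reference", "strand", "position", "count")]
  a <- a[do.call(order, a), ]; rownames(a) <- NULL
  b <- b[do.call(order, b), ]; rownames(b) <- NULL
  expect_equal(a, b)
}

key_of <- function(df, pos_col = "position") {
  paste(df$reference, df$strand, df[[pos_col]])
}
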