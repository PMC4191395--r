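test_that("adapter and poly(A) trimming follows the anchored-prefix policy", {
  p <- trim_policy(adapter = "ADAPT", min_polyA = 5, min_length = 12)
  r <- trim_read(paste0("ADAPT", "ACGTACGTACGTACGT", "AAAAAA"), p)
  expect_identical(r$sequence, "ACGTACGTACGTACGT")
  expect_identical(r$reason, "kept")

  # missing adapter is a counted rejection, not an error
  r2 <- trim_read("ACGTACGTACGTACGTACGT", p)
  expect_identical(r2$reason, "no_adapter")
  expect_true(is.na(r2$sequence))

  # internal A-runs are genomic signal
  r3 <- trim_read(paste0("ADAPT", "ACGTAAAAAGTACGTACGT"), p)
  expect_identical(r3$sequence, "ACGTAAAAAGTACGTACGT")

  # a 3' A-run below the minimum length is kept
  r4 <- trim_read(paste0("ADAPT", "ACGTACGTACGTACGT", "AAAA"), p)
  expect_identical(r4$sequence, "ACGTACGTACGTACGTAAAA")

  # too short after trimming
  r5 <- trim_read(paste0("ADAPT", "ACGTACG", "AAAAAA"), p)
  expect_identical(r5$reason, "too_short")

  # mismatch tolerance in the adapter prefix
  pm <- trim_policy(adapter = "ADAPT", max_mismatches = 1, min_polyA = 5,
                    min_length = 12)
  expect_identical(trim_read(paste0("ADCPT", "ACGTACGTACGTACGT"), pm)$reason,
                   "kept")
  expect_identical(trim_read(paste0("TTCPT", "ACGTACGTACGTACGT"), pm)$reason,
                   "no_adapter")

  expect_error(trim_policy(min_length = 10), ">= 12")
})

test_that("exact placement reports the 5'-most base, strand-aware", {
  g <- tiny_genome()
  gs <- as.character(g[[1]])
  fwd <- substr(gs, 101, 140)       # inside the repeat-free region
  hit <- map_read_start(fwd, g)
  expect_identical(hit$strand, "+")
  expect_identical(hit$position, 101L)

  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(substr(gs, 201, 240))))
  hit2 <- map_read_start(rc, g)
  expect_identical(hit2$strand, "-")
  expect_identical(hit2$position, 240L)   # larger coordinate of the match

  # read from the periodic region occurs many times -> rejected
  rep_read <- substr(gs, 651, 690)
  expect_identical(map_read_start(rep_read, g)$reason, "multimapped")

  # absent sequence
  expect_identical(map_read_start(strrep("ACGT", 10), g)$reason, "unmapped")
})

test_that("read accounting is exact across all rejection classes", {
  g <- tiny_genome()
  gs <- as.character(g[[1]])
  ad <- default_adapter()
  p <- trim_policy()
  reads <- c(paste0(ad, substr(gs, 101, 140)),          # mapped
             paste0(ad, substr(gs, 151, 190)),          # mapped
             substr(gs, 101, 140),                      # no adapter
             paste0(ad, "ACGTACGTAC"),                  # too short
             paste0(ad, strrep("ACGT", 10)),            # unmapped
             paste0(ad, substr(gs, 651, 690)))          # multimapped
  res <- count_from_reads(reads, g, p)
  expect_identical(unname(res$report["input"]), 6L)
  expect_identical(unname(res$report["mapped"]), 2L)
  expect_identical(unname(res$report["no_adapter"]), 1L)
  expect_identical(unname(res$report["too_short"]), 1L)
  expect_identical(unname(res$report["unmapped"]), 1L)
  expect_identical(unname(res$report["multimapped"]), 1L)
  expect_identical(unname(res$report["input"]),
                   unname(sum(res$report[-1])))
  expect_identical(attr(res$counts, "total_mapped"), 2L)
})

test_that("simulate -> emit -> trim -> map -> count reproduces the table", {
  sc <- scenario_direct_entry(17, library_size = 2e4)
  reads <- emit_reads(sc$counts$after, sc$genome,
                      transcripts = sc$transcripts_in_vitro, seed = 3)
  res <- count_from_reads(reads, sc$genome, trim_policy())
  expect_identical(unname(res$report["mapped"]), 20000L)
  expect_same_counts(sc$counts$after, res$counts)
})

test_that("SAM 5'-end extraction follows FLAG and CIGAR conventions", {
  sam <- write_sam(c(
    sam_record("r1", 0, 100, "50M"),
    sam_record("r2", 16, 100, "50M"),
    sam_record("r3", 0, 100, "50M"),          # duplicate of r1's key
    sam_record("r4", 4, 0, "*"),              # unmapped: skipped
    sam_record("r5", 256, 300, "50M"),        # secondary: skipped
    sam_record("r6", 2048, 300, "50M"),       # supplementary: skipped
    sam_record("r7", 16, 400, "10M5I10M5D10M", strrep("C", 35)),
    sam_record("r8", 0, 500, "5S30M", strrep("G", 35))))
  ct <- count_starts_from_alignments(sam, format = "sam")
  df <- as.data.frame(ct)
  expect_identical(df$count[df$position == 100 & df$strand == "+"], 2L)
  expect_identical(df$count[df$position == 149 & df$strand == "-"], 1L)
  # reference-consumed length of 10M5I10M5D10M is 35: end = 400 + 35 - 1
  expect_identical(df$count[df$position == 434 & df$strand == "-"], 1L)
  # soft clips are not added back: forward 5' end stays at POS
  expect_identical(df$count[df$position == 500 & df$strand == "+"], 1L)
  expect_identical(attr(ct, "total_mapped"), 5L)
})

test_that("malformed SAM records raise errors naming the line", {
  bad_cigar <- write_sam(sam_record("r1", 0, 100, "50Q"))
  expect_error(count_starts_from_alignments(bad_cigar, format = "sam"),
               "line 3")
  truncated <- tempfile(fileext = ".sam")
  writeLines(c("@HD\tVN:1.6", "r1\t0\tref1\t100"), truncated)
  expect_error(count_starts_from_alignments(truncated, format = "sam"),
               "truncated SAM record at line 2")
})

test_that("SAM text parsing agrees with the Rsamtools BAM route", {
  g <- make_genome(23, 1, 5000)
  gs <- as.character(g[[1]])
  recs <- c(sam_record("a", 0, 101, "40M", substr(gs, 101, 140)),
            sam_record("b", 16, 201, "40M", substr(gs, 201, 240)),
            sam_record("c", 0, 101, "40M", substr(gs, 101, 140)),
            sam_record("d", 16, 301, "20M5D15M", strrep("A", 35)))
  sam <- write_sam(recs, ref_len = 5000L)
  ours <- count_starts_from_alignments(sam, format = "sam")

  bam <- Rsamtools::asBam(sam, tempfile(), overwrite = TRUE,
                          indexDestination = FALSE)
  aln <- Rsamtools::scanBam(bam, param = Rsamtools::ScanBamParam(
    what = c("rname", "strand", "pos", "cigar")))[[1]]
  ref_consumed <- vapply(aln$cigar, function(cg) {
    tok <- regmatches(cg, gregexpr("[0-9]+[MIDNSHP=X]", cg))[[1]]
    sum(as.integer(sub(".$", "", tok))[sub("^[0-9]+", "", tok) %in%
                                         c("M", "D", "N", "=", "X")])
  }, integer(1), USE.NAMES = FALSE)
  pos5 <- ifelse(aln$strand == "-", aln$pos + ref_consumed - 1L, aln$pos)
  oracle <- end_counts(
    data.frame(reference = as.character(aln$rname),
               strand = ifelse(aln$strand == "-", "-", "+"),
               position = pos5, count = 1L)[
      , c("reference", "strand", "position", "count")] |>
      (\(d) aggregate(count ~ reference + strand + position, d, sum))(),
    condition = "oracle")
  expect_same_counts(ours, oracle)
})

test_that("counting from SAM and from equivalent BED6 is identical", {
  recs <- c(sam_record("a", 0, 101, "40M"),
            sam_record("b", 16, 201, "40M"),
            sam_record("c", 0, 101, "40M"))
  sam <- write_sam(recs, ref_len = 5000L)
  bed <- tempfile(fileext = ".bed")
  # same alignments in BED6: 0-based half-open, name/score/strand
  writeLines(c("ref1\t100\t140\ta\t0\t+",
               "ref1\t200\t240\tb\t0\t-",
               "ref1\t100\t140\tc\t0\t+"), bed)
  expect_same_counts(count_starts_from_alignments(sam, format = "sam"),
                     count_starts_from_alignments(bed, format = "bed"))
})
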