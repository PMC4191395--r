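test_that("make_genome is reproducible, seed-sensitive and balanced", {
  g1 <- make_genome(1, 1, 50000)
  g2 <- make_genome(1, 1, 50000)
  g3 <- make_genome(2, 1, 50000)
  expect_identical(as.character(g1), as.character(g2))
  expect_false(identical(as.character(g1), as.character(g3)))
  # binomial bound: P(|GC - 0.5| > 0.05) < 1e-6 at 50 kb
  expect_gt(gc_fraction(g1), 0.45)
  expect_lt(gc_fraction(g1), 0.55)
  expect_error(make_genome(1, 1, 0), "positive")
  expect_error(make_genome(1, 1, 500), "1000")
  expect_identical(names(make_genome(1, 3, 1000)), c("ref1", "ref2", "ref3"))
})

test_that("transcript and site constructors enforce their invariants", {
  expect_error(cleavage_site(0, c(t1 = 0.5)), "positive")
  expect_error(cleavage_site(10, c(t1 = 1.2)), "\\[0, 1\\]")
  expect_error(cleavage_site(10, c(t1 = 0.6, t2 = 0.4)), "non-decreasing")
  expect_error(cleavage_site(10, c(0.5)), "named")
  s <- cleavage_site(10, c(t1 = 0.2, t2 = 0.2), "rng_dependent")
  expect_s3_class(s, "cleavage_site")
  expect_error(transcript_model("r", "+", 100, 50), "start")
  expect_error(transcript_model("r", "*", 1, 50), "strand")
  expect_error(transcript_model("r", "+", 1, 50, abundance = 0), "> 0")
  expect_error(
    transcript_model("r", "+", 5, 15, sites = list(cleavage_site(15, c(t = 1)))),
    "strictly inside")
  expect_error(library_spec("c", 0), ">= 1")
  expect_error(library_spec("c", 10, depletion_factor = 0), "\\(0, 1\\]")
  expect_error(library_spec("c", 10, accumulation_factor = 0.5), ">= 1")
})

test_that("simulated counts land on the modelled ends and sum to N", {
  tx <- transcript_model("ref1", "+", 1000, 3000, abundance = 2,
                         native_end_fraction = 0.5,
                         sites = list(cleavage_site(1500, c(t10 = 0.8))))
  # untreated sample: only the native 5' end is detectable
  ct <- simulate_end_counts(list(tx), library_spec("b", 5000, seed = 3),
                            "before")
  expect_identical(nrow(ct), 1L)
  expect_identical(ct$position, 1000L)
  expect_identical(sum(ct$count), 5000L)

  # complete cleavage of an undetectable-native transcript: all reads at
  # the downstream end, one position past the site coordinate
  tx2 <- transcript_model("ref1", "+", 1000, 3000, native_end_fraction = 0,
                          sites = list(cleavage_site(1500, c(t10 = 1))))
  ct2 <- simulate_end_counts(list(tx2), library_spec("a", 777, seed = 4),
                             "t10")
  expect_identical(ct2$position, 1501L)
  expect_identical(sum(ct2$count), 777L)

  # minus strand: downstream means decreasing coordinate
  tx3 <- transcript_model("ref1", "-", 1000, 3000, native_end_fraction = 0,
                          sites = list(cleavage_site(1500, c(t10 = 1))))
  ct3 <- simulate_end_counts(list(tx3), library_spec("a", 100, seed = 4),
                             "t10")
  expect_identical(ct3$position, 1499L)

  expect_error(simulate_end_counts(list(), library_spec("x", 10)), "non-empty")
  expect_error(simulate_end_counts(list(tx2), library_spec("x", 10), "before"),
               "zero")
  expect_error(simulate_end_counts(list(tx), library_spec("x", 10), "t99"),
               "missing")
})

test_that("half-efficient cleavage splits the library evenly", {
  # native weight 1 * (1 - 0.5), site weight 0.5: multinomial expectation 1:1
  tx <- transcript_model("ref1", "+", 1000, 3000, abundance = 1,
                         native_end_fraction = 1,
                         sites = list(cleavage_site(2000, c(t = 0.5))))
  ct <- simulate_end_counts(list(tx), library_spec("a", 1e6, seed = 11), "t")
  ratio <- ct$count[ct$position == 2001L] / ct$count[ct$position == 1000L]
  expect_lt(abs(ratio - 1), 0.01)
})

test_that("identical seeds give identical tables; different seeds differ", {
  tx <- transcript_model("ref1", "+", 1000, 3000,
                         sites = list(cleavage_site(1500, c(t = 0.5))))
  c1 <- simulate_end_counts(list(tx), library_spec("a", 1e4, seed = 5), "t")
  c2 <- simulate_end_counts(list(tx), library_spec("a", 1e4, seed = 5), "t")
  c3 <- simulate_end_counts(list(tx), library_spec("a", 1e4, seed = 6), "t")
  expect_identical(as.data.frame(c1), as.data.frame(c2))
  expect_false(identical(as.data.frame(c1), as.data.frame(c3)))
})

test_that("fixed-depth sampling shifts the unenriched population to log2(1-f)", {
  # planted cleavage converts fraction f of molecule weight into new ends;
  # native ends must settle at M = log2(1 - f)
  for (f in c(0.5, 0.67)) {
    sc <- scenario_dilution(31, dilution = 1 - f, library_size = 2e5,
                            n_transcripts = 120)
    ma <- compute_ma(sc$after, sc$before)
    native <- !ma$nominal_a & !ma$nominal_b
    expect_lt(abs(median(ma$M[native]) - log2(1 - f)), 0.1)
  }
})

test_that("depletion of a dependent end is read out as M near -log2(d)", {
  d <- 0.1
  # keep the depleted end a small share of the library so the composition
  # shift stays well inside the tolerance
  txs <- c(
    lapply(1:20, function(i)
      transcript_model("ref1", "+", 1 + (i - 1) * 2000, 1500 + (i - 1) * 2000,
                       abundance = 1, native_end_fraction = 1)),
    list(transcript_model("ref1", "+", 40001, 41500, abundance = 1,
                          native_end_fraction = 0.5,
                          sites = list(cleavage_site(40500, c(v = 0.5),
                                                     "rne_dependent")))))
  wt <- simulate_end_counts(txs, library_spec("wt", 1e6, seed = 21), "v")
  mut <- simulate_end_counts(txs, library_spec(
    "mut", 1e6, depletion_factor = d, deplete_dependence = "rne_dependent",
    seed = 22), "v")
  ma <- compute_ma(wt, mut)
  m_dep <- ma$M[ma$position == 40501L]
  expect_lt(abs(m_dep - (-log2(d))), 0.2)
})

test_that("emitted reads start exactly at the counted positions", {
  g <- make_genome(7, 1, 2000)
  gs <- as.character(g[[1]])
  ad <- default_adapter()
  counts <- ec(c(100L, 500L), c(3L, 1L))
  reads <- emit_reads(counts, g, read_length = 40, seed = 1)
  expect_identical(nrow(reads), 4L)
  frag100 <- substr(gs, 100, 139)
  expect_identical(sum(reads$sequence == paste0(ad, frag100)), 3L)

  # minus strand: fragment is the reverse complement ending at the position
  cm <- ec(200L, 1L, strand = "-")
  rm_ <- emit_reads(cm, g, read_length = 40, seed = 1)
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(substr(gs, 161, 200))))
  expect_identical(rm_$sequence, paste0(ad, rc))

  # truncation at a transcript 3' boundary appends the poly(A) run
  tx <- list(transcript_model("ref1", "+", 90, 120))
  rt <- emit_reads(ec(100L, 1L), g, read_length = 40, polyA_len = 8,
                   transcripts = tx, seed = 1)
  expect_identical(rt$sequence,
                   paste0(ad, substr(gs, 100, 120), strrep("A", 8)))

  expect_error(emit_reads(ec(5000L, 1L), g), "outside")
  expect_error(emit_reads(counts, g, read_length = 10), ">= 20")
})

test_that("FASTQ writer and reader round-trip reads", {
  g <- make_genome(7, 1, 2000)
  reads <- emit_reads(ec(c(100L, 500L), c(2L, 1L)), g, seed = 1)
  fp <- tempfile(fileext = ".fastq")
  write_fastq(reads, fp)
  back <- read_fastq(fp)
  expect_identical(back$sequence, reads$sequence)
  expect_identical(back$id, reads$id)
  expect_identical(back$quality, reads$quality)
})

test_that("count-table writers produce the documented formats", {
  x <- ec(c(10L, 20L, 30L), c(1L, 2L, 3L), strand = c("+", "-", "+"))
  fp <- tempfile(fileext = ".tsv")
  write_end_counts_tsv(x, fp)
  back <- read_end_counts_tsv(fp, condition = "x")
  expect_same_counts(x, back)

  pre <- tempfile()
  paths <- write_bedgraph_pair(x, pre)
  plus <- read.table(paste0(pre, "_plus.bedgraph"))
  # bedGraph is 0-based half-open width-1: position p becomes [p-1, p)
  expect_identical(plus$V2, c(9L, 29L))
  expect_identical(plus$V3, c(10L, 30L))
  expect_identical(plus$V4, c(1L, 3L))
  minus <- read.table(paste0(pre, "_minus.bedgraph"))
  expect_identical(minus$V2, 19L)
})
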