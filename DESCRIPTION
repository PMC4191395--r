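Package: endmap
Title: Mapping Endonuclease Cleavage Sites from 5'-Monophosphorylated-End
    Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for transcriptome-wide mapping of endoribonuclease
    cleavage sites from sequencing libraries that capture
    5'-monophosphorylated RNA ends.  Simulates toy genomes, transcript
    models with planted cleavage sites and 5'-end sequencing libraries;
    trims and exactly maps reads and counts strand-specific read starts;
    computes per-position M (log-ratio) and A (intensity) values between
    conditions, estimates the baseline of the unenriched population and
    calls sites above baseline-normalised thresholds; intersects in
    vivo-dependent with in vitro-generated site sets; detects paired
    5'-trimming events (a depleted processed end with an accumulated
    upstream end); and performs exact coordinate arithmetic for defined
    in vitro substrates with codon-relative, zero-skipping coordinates.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    stats,
    utils
Suggests:
    Rsamtools,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
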