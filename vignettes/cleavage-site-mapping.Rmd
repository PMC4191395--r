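---
title: "Mapping endonuclease cleavage sites from 5'-end sequencing: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping endonuclease cleavage sites from 5'-end sequencing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(endmap)
```

## The measurement model

Endoribonucleases such as *E. coli* RNase E leave a 5'-monophosphorylated
end on the downstream product of every cleavage. A sequencing protocol that
ligates its 5' adapter only onto monophosphorylated ends therefore converts
cleavage events into countable read starts: the number of reads whose
5'-most base maps to a genomic position estimates the abundance of RNA
fragments with a 5' end there. Triphosphorylated (primary) and hydroxylated
ends are invisible to the assay.

Two conditions are compared position by position on the M-A scale familiar
from expression microarrays:

$$M = \log_2\frac{n_\text{a}}{n_\text{b}}, \qquad
  A = \frac{\log_2 n_\text{a} + \log_2 n_\text{b}}{2},$$

where $n_\text{a}$ is the read-start count in the numerator condition
(after enzyme incubation in vitro, or the wild type in a WT/mutant
comparison) and $n_\text{b}$ the denominator. A position observed in only
one condition takes a *nominal* count of 1 on the silent side - the lowest
limit of detection - and is flagged; positions observed in neither never
enter the table. M is computed on raw counts, not depth-normalised ones:
both libraries are sequenced to a fixed depth, and the composition effect
this induces is handled explicitly through the baseline (below). A
counts-per-million rescaling would *remove* the very dilution signal the
baseline estimates.

### Why the background sits below zero

Sequencing a fixed number of reads is competitive: if incubation with the
enzyme converts a fraction $f$ of the molecule population into new
5'-monophosphorylated ends, the pre-existing ends can only claim a
$(1 - f)$ share of the "after" library. Their M values therefore
concentrate not at 0 but at $\log_2(1 - f)$ - a cone of unenriched points
below the axis, with enzyme-generated ends forming a cloud far above it.
The simulator reproduces this mechanically by drawing each library from a
single multinomial over end weights (see below), and
`estimate_baseline()` recovers $\log_2(1-f)$ from the M histogram.

Because the enriched cloud can outnumber the cone, the baseline estimator
uses the *mode* of the M histogram over non-nominal records - the centre of
the densest bin (default width 0.1 M units, bins centred on multiples of
the width, ties resolved toward the smaller M) - rather than a mean or
median, which the cloud would drag upward. The number of records used and
the method label are reported in the returned object so the choice is
visible in output metadata.

### Thresholds and normalised fold change

Site calling is a plain threshold, not a hypothesis test: the assay's
designers quote end counts, not dispersions, and no replicate structure is
assumed. `call_sites()` emits positions with $M \ge$ threshold (inclusive)
and at least `min_reads` numerator reads. The default in vitro
configuration is threshold 3.4 against a baseline of $-1.6$, i.e. a
normalised log2 enrichment of 5 ($2^5 = 32$-fold); for WT/mutant in vivo
comparisons threshold 5 against baseline 0 is conventional.
`normalized_fold(M, baseline)` $= 2^{M - \text{baseline}}$ and
`threshold_for_enrichment(e, baseline)` $= \text{baseline} + e$ convert
between the two scales. `count_by_threshold()` deliberately uses strict
inequality ($M > t$), matching how genome-wide tallies are usually quoted;
the calling threshold is inclusive. The `min_reads` filter (default 5) is
an addition beyond the plain threshold rule: a single read at an otherwise
silent position yields $M = \log_2(n/1)$ limited only by depth, and the
filter bounds such nominal-count artifacts. Set it to 0 for strict
threshold-only behaviour.

## The generative model

`simulate_end_counts()` computes one weight per detectable end and draws
the whole library from one multinomial:

* native 5' end of a transcript with abundance $a$:
  $w = a \cdot \text{native\_end\_fraction} \cdot \prod_s (1 - e_s)$,
  where $e_s$ are the cleavage efficiencies of the transcript's sites at
  the requested timepoint - a cleaved molecule contributes its new
  downstream end instead of its native end;
* each site: $w = a \cdot e_s$, located one position downstream of the
  site coordinate (strand-aware; the site coordinate is the last
  nucleotide of the upstream product, applied uniformly across the whole
  package).

Condition effects are multiplicative on weights: in a mutant library,
site ends whose dependence matches the library's `deplete_dependence` are
scaled by `depletion_factor`, and native ends of transcripts whose
`accumulation_group` matches are scaled by `accumulation_factor` (the
5'-extended precursors that pile up when a trimming nuclease is missing).
Efficiencies are constrained non-decreasing across ordered timepoints
because cleavage in a timecourse is cumulative.

What the generator does *not* model, by design: sequencing errors, PCR
duplicates, fragment-length distributions (beyond truncation at transcript
3' ends, which triggers the poly(A) tail), rRNA depletion chemistry, or
positional sequence preferences of the enzyme. Passing recovery tests on
these simulations therefore demonstrates that the analysis correctly
inverts its own generative assumptions - counting, dilution, depletion and
pairing logic - not that it is robust to artifacts real libraries contain.

### Read-level emulation and the round trip

`emit_reads()` turns a count table into FASTQ-ready reads
(`adapter + fragment [+ poly(A)]`, constant quality "I"), and
`count_from_reads()` inverts it: anchored-prefix adapter trimming, removal
of a terminal A-run of at least `min_polyA` nucleotides, exact full-length
placement on both strands, and strand-aware start counting. On a
repeat-free random genome the composition `simulate -> emit -> trim ->
map -> count` reproduces the simulated table *exactly*, and every input
read is accounted for as mapped or rejected with one of four reasons.
Multi-mapping reads are discarded, not fractionally assigned; reads
shorter than `min_length` (floor 12 nt) after trimming are rejected
because exact placement of very short fragments is not unique even on a
50-kb genome.

For aligned input, SAM text and BED6 are supported. The 5' end of a
reverse-strand SAM record is `POS + reference-consumed CIGAR length - 1`;
5' soft clips are *not* added back, since adapters are removed before
alignment in this protocol and residual clips denote low-quality tails.
All internal coordinates are 1-based closed; BED/bedGraph conversion
happens only in the readers and writers.

## Study conditions and defaults

The packaged scenarios fix the desk-scale study conditions used throughout
the tests:

* `scenario_direct_entry()`: one 50-kb reference, 30 transcripts
  (log-normal abundances, sdlog 0.7), 20 planted sites of which 14 are
  enzyme-dependent in vivo, libraries of $2 \times 10^5$ reads - about 50
  reads per planted end at the low-abundance tail. In vitro efficiencies
  are drawn from 0.3-0.9 at the first timepoint; in vivo efficiencies from
  0.4-0.7. The dephosphorylated in vitro starting material retains a
  residual detectable native-end fraction of 0.02 (a free simulation
  parameter - the assay literature does not quantify residual
  monophosphates after dephosphorylation); in vivo the fraction is 0.2,
  reflecting decapped and processed molecules. The temperature-inactivated
  mutant retains 1% of activity at dependent sites
  (`depletion_factor = 0.01`, a strong 45-min inactivation), giving those
  positions an expected M near $-\log_2(0.01) \approx 6.6$ before the
  composition shift.
* `scenario_dilution()`: 150 short transcripts, fully detectable native
  ends, one site per transcript cleaved with efficiency $1 - d$, so the
  unenriched population sits exactly at $\log_2 d$; used to validate the
  baseline estimator at $d \in \{0.25, 0.33, 0.5\}$ with $10^6$ reads.
* `scenario_trimming()`: 12 planted depletion/accumulation pairs at
  extensions 10-150 nt, 12 decoy depleted-only sites, and one boundary
  control at exactly 200 nt that the strict $<$ 200 window must reject.
  Knockout modifiers are depletion 0.1 and accumulation 6, placing the
  paired ends comfortably past the default $|M| \ge 2$ scan thresholds
  (which are declared defaults, not literature values). Five of the twelve
  precursors coincide with annotated TSSs to exercise `match_to_tss()`.

These sizes keep the full test suite under half a minute on one CPU while
leaving every planted signal several standard errors clear of its
threshold.

## 5'-trimming pairs

`detect_trim_pairs()` reads a single WT-numerator M-A table twice: a
*processed* end is depleted in the mutant when $M \ge$ `depletion_m`; a
*precursor* end is accumulated when $M \le -$`accumulation_m`. For each
depleted end the window of `max_extension` $- 1$ nucleotides *upstream in
transcript orientation* (smaller coordinates on `+`, larger on `-`) is
scanned, and one event is emitted per depleted end using the partner with
the most negative M, ties broken by the shortest extension - the
one-best-partner rule reflects the expectation of a single extended
precursor species per processed end, with `all_pairs = TRUE` available for
exploration. Depleted ends with no partner emit nothing, which is what
makes decoys cheap to reject.

## Site-set comparison

`intersect_sites()` matches in vivo-dependent calls against
in vitro-generated calls at a position tolerance (default 0, with a
documented $\pm 1$ option because end-coordinate conventions differ by one
nucleotide between reasonable definitions). Matching is greedy in
coordinate order, each side used at most once, nearest partner first and
ties to the smaller coordinate. Matched sites are direct-entry candidates;
the remainder are classified `in_vivo_only` / `in_vitro_only`, and the
three class counts always sum to
$|\text{vivo}| + |\text{vitro}| - |\text{matched}|$.

`spearman_reproducibility()` quantifies between-timepoint agreement on the
positions passing the selection threshold in the first table; a position
absent from the second table altogether scores M = 0 there (both sides at
the nominal count). The p-value uses the t approximation on $n - 2$
degrees of freedom for $n > 10$ and a seeded $10^4$-shuffle permutation
test otherwise, where the approximation is unreliable.

## Substrate arithmetic

Defined in vitro substrates are specified in codon-relative coordinates
with no position zero ($-1$ abuts $+1$) and carry a 3-nt GGG prefix from
T7 transcription initiation. `axis_offset()` maps the punctured axis onto
consecutive integers, after which lengths and product sizes are ordinary
differences:

```{r substrate}
rnc <- substrate_spec("rnc_3p", 354, 708)
substrate_length(rnc)
product_sizes(rnc, 559)
product_sizes(rnc, 415)
substrate_length(substrate_spec("uspF", -22, 465))
```

The cleavage coordinate is the last nucleotide of the upstream product, so
the two product sizes sum exactly to the substrate length for every valid
cut - the convention under which the 358-nt worked example's product
pairs ($209 + 149 = 65 + 293 = 358$) are internally consistent. One
reference substrate's reported product sizes contain an unresolved
off-by-one ($257 + 234 = 491$ against a 490-nt fragment), so that pair is
not used as an exact check anywhere in the package.

## Numerical and degenerate-input behaviour

* Every M-A record is exactly invertible: $n_a = 2^{A + M/2}$,
  $n_b = 2^{A - M/2}$ to within $10^{-9}$.
* `estimate_baseline()` refuses to run on fewer than 100 usable records
  and directs the user to supply the baseline manually.
* `simulate_end_counts()` raises an error when all end weights are zero
  (e.g. an untreated sample of fully dephosphorylated transcripts); the
  empty transcript list is likewise an error, not an empty table.
* Zero counts are never stored in count tables, so the nominal-count rule
  in `compute_ma()` is the only place absent observations are imputed.
* All RNG use is confined to `with_seed()` blocks keyed by caller-supplied
  seeds; identical seeds give identical genomes, libraries and reads, and
  the caller's RNG state is never disturbed.

## Known limitations

The exact-match mapper is intended for repeat-free toy genomes; real
genomes need an external aligner, whose SAM output enters through
`count_starts_from_alignments()`. The simulator's fixed-depth multinomial
ignores overdispersion between library preparations, so observed M
variances on real replicates will exceed the simulated ones. Site calling
is threshold-based by construction; if replicate libraries are available,
count-model packages with dispersion estimation are the right tool for
significance statements, with this package supplying the end counting and
conventions.
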