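#' Codon-relative coordinate axis without a position zero
#'
#' Defined in vitro substrates are numbered relative to the start codon with
#' no position zero: ..., -2, -1, +1, +2, ...  `axis_offset()` maps these
#' coordinates onto consecutive integers (a monotone, unit-step bijection
#' with `axis_offset(-1) + 1 == axis_offset(+1)`), which makes span lengths
#' and product sizes ordinary differences.
#'
#' @param coordinate Nonzero integer codon-relative coordinate(s).
#' @return Integer offset(s) on a gap-free axis.
#' @examples
#' axis_offset(c(-2, -1, 1, 2))  # -1, 0, 1, 2
#' @export
axis_offset <- function(coordinate) {
  coordinate <- as.integer(coordinate)
  if (any(is.na(coordinate)) || any(coordinate == 0L))
    stop("codon-relative coordinates have no position zero")
  ifelse(coordinate > 0L, coordinate, coordinate + 1L)
}

# Number of codon-relative positions in the closed span [start, end].
n_axis_positions <- function(start, end) {
  axis_offset(end) - axis_offset(start) + 1L
}

#' Describe a defined in vitro substrate
#'
#' A T7-transcribed fragment spanning codon-relative coordinates
#' `[start, end]` (no position zero) with `prefix_length` extra 5'
#' nucleotides - the GGG appended by T7 transcription initiation.
#'
#' @param name Substrate name.
#' @param start,end Nonzero codon-relative boundaries, `start` 5' of `end`.
#' @param prefix_length Number of extra 5' nucleotides (default 3, the GGG).
#' @return An object of class `substrate_spec`.
#' @examples
#' substrate_spec("rnc_3p", 354, 708)
#' @export
substrate_spec <- function(name, start, end, prefix_length = 3L) {
  start <- as.integer(start); end <- as.integer(end)
  if (start == 0L || end == 0L)
    stop("codon-relative coordinates have no position zero")
  if (axis_offset(start) > axis_offset(end))
    stop("`start` must not lie 3' of `end`")
  prefix_length <- as.integer(prefix_length)
  if (is.na(prefix_length) || prefix_length < 0L)
    stop("`prefix_length` must be >= 0")
  structure(list(name = as.character(name), start = start, end = end,
                 prefix_length = prefix_length),
            class = "substrate_spec")
}

#' Total substrate length in nucleotides
#'
#' The 5' prefix plus the number of codon-relative positions in the span
#' (remembering that the axis skips zero, so -22 to +465 holds 487
#' positions, not 488).
#'
#' @param spec A [substrate_spec()].
#' @return Integer length in nucleotides.
#' @examples
#' substrate_length(substrate_spec("rnc_3p", 354, 708))   # 358
#' substrate_length(substrate_spec("uspF", -22, 465))     # 490
#' @export
substrate_length <- function(spec) {
  spec$prefix_length + n_axis_positions(spec$start, spec$end)
}

#' Sizes of the two products of a single cleavage
#'
#' The cleavage coordinate is the last nucleotide of the upstream product,
#' so `upstream = prefix + positions in [start, cut]` and
#' `downstream = positions in (cut, end]`; the two always sum to the
#' substrate length.
#'
#' @param spec A [substrate_spec()].
#' @param cut Nonzero codon-relative cleavage coordinate with
#'   `start <= cut < end` on the mapped axis.
#' @return Named integer vector `c(upstream = , downstream = )`.
#' @examples
#' rnc <- substrate_spec("rnc_3p", 354, 708)
#' product_sizes(rnc, 559)  # 209, 149
#' product_sizes(rnc, 415)  # 65, 293
#' @export
product_sizes <- function(spec, cut) {
  cut <- as.integer(cut)
  if (cut == 0L) stop("codon-relative coordinates have no position zero")
  oc <- axis_offset(cut)
  if (oc < axis_offset(spec$start))
    stop("cut lies 5' of the substrate")
  if (oc >= axis_offset(spec$end))
    stop("cut at or beyond the substrate 3' end leaves no downstream product")
  upstream <- spec$prefix_length + (oc - axis_offset(spec$start) + 1L)
  downstream <- axis_offset(spec$end) - oc
  c(upstream = upstream, downstream = downstream)
}

#' Upstream-product size of a shifted cleavage
#'
#' If cleavage at offset `d1` (relative to some reference point, e.g. a tRNA
#' 3' end) gives a known upstream product, cleavage at offset `d2` on the
#' same axis gives `known + (d2 - d1)`.
#'
#' @param known_upstream Upstream-product size at offset `d1`, in nt.
#' @param d1,d2 Offsets of the two cleavages from the same reference point.
#' @return Integer upstream-product size at `d2`.
#' @examples
#' relative_product_shift(172, 2, 39)  # 209
#' @export
relative_product_shift <- function(known_upstream, d1, d2) {
  as.integer(known_upstream + (d2 - d1))
}

#' Does a blocking oligonucleotide cover a cleavage point?
#'
#' Pure geometry: `TRUE` when the cut position, or the first nucleotide of
#' the downstream product, lies within the blocked interval.  Whether a
#' distal oligonucleotide also affects cleavage is biology, not geometry,
#' and is out of scope here.
#'
#' @param spec A [substrate_spec()].
#' @param block_start,block_end Nonzero codon-relative boundaries of the
#'   annealed oligonucleotide, within the substrate.
#' @param cut Nonzero codon-relative cleavage coordinate.
#' @return Logical.
#' @examples
#' rnc <- substrate_spec("rnc_3p", 354, 708)
#' block_overlap(rnc, 545, 570, 559)  # TRUE
#' block_overlap(rnc, 545, 570, 415)  # FALSE
#' @export
block_overlap <- function(spec, block_start, block_end, cut) {
  ob <- axis_offset(block_start); oe <- axis_offset(block_end)
  if (ob > oe) stop("blocked interval is reversed")
  if (ob < axis_offset(spec$start) || oe > axis_offset(spec$end))
    stop("blocked interval extends outside the substrate")
  oc <- axis_offset(cut)
  (oc >= ob && oc <= oe) || (oc + 1L >= ob && oc + 1L <= oe)
}
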