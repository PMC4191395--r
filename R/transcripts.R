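#' Describe a planted cleavage site
#'
#' A cleavage site is identified by the genomic coordinate of the *last*
#' nucleotide of the upstream product; the 5'-monophosphorylated end it
#' generates lies one position downstream in transcript orientation
#' (position + 1 on the plus strand, position - 1 on the minus strand).
#' Cleavage efficiencies are given per timepoint label and must be
#' non-decreasing along the supplied order, as cleavage in a timecourse is
#' cumulative.
#'
#' @param position 1-based genomic coordinate of the last nucleotide of the
#'   upstream product.
#' @param efficiency_by_time Named numeric vector in `[0, 1]`: fraction of
#'   molecules cleaved at each timepoint, non-decreasing in the given order.
#' @param dependence One of `"independent"`, `"rne_dependent"`,
#'   `"rng_dependent"`: which enzyme the site depends on in vivo.
#' @return An object of class `cleavage_site`.
#' @examples
#' cleavage_site(1500, c(t10 = 0.4, t30 = 0.6), "rne_dependent")
#' @export
cleavage_site <- function(position,
                          efficiency_by_time,
                          dependence = c("independent", "rne_dependent",
                                         "rng_dependent")) {
  dependence <- match.arg(dependence)
  position <- as.integer(position)
  if (is.na(position) || position < 1L)
    stop("`position` must be a positive 1-based coordinate")
  eff <- as.numeric(efficiency_by_time)
  if (is.null(names(efficiency_by_time)) || any(!nzchar(names(efficiency_by_time))))
    stop("`efficiency_by_time` must be a named vector of timepoint labels")
  names(eff) <- names(efficiency_by_time)
  if (any(is.na(eff)) || any(eff < 0) || any(eff > 1))
    stop("cleavage efficiencies must lie in [0, 1]")
  if (is.unsorted(eff))
    stop("cleavage efficiencies must be non-decreasing over ordered timepoints")
  structure(list(position = position, efficiency_by_time = eff,
                 dependence = dependence),
            class = "cleavage_site")
}

#' Describe a transcript with optional planted cleavage sites
#'
#' The model carries everything the library simulator needs: where the
#' molecule lies on the genome, how abundant it is, what fraction of its
#' native 5' ends is detectable (i.e. monophosphorylated - triphosphorylated
#' and hydroxylated ends are invisible to the assay), and which internal
#' positions are cleaved.  On the minus strand "downstream" means decreasing
#' genomic coordinate and the native 5' end sits at `end`.
#'
#' @param reference Reference sequence name.
#' @param strand `"+"` or `"-"`.
#' @param start,end 1-based closed genomic span of the transcript.
#' @param abundance Positive relative molecule count.
#' @param native_end_fraction Fraction in `[0, 1]` of molecules whose native
#'   5' end is monophosphorylated and hence detectable.
#' @param sites List of [cleavage_site()] objects lying strictly inside the
#'   span.
#' @param accumulation_group Optional dependence label; when a library is
#'   simulated with a matching `deplete_dependence`, the *native* end of this
#'   transcript is multiplied by the library's `accumulation_factor`
#'   (the precursor that piles up when its trimming nuclease is disabled).
#' @return An object of class `transcript_model`.
#' @examples
#' transcript_model("ref1", "+", 1000, 2200, abundance = 2,
#'                  native_end_fraction = 0.2,
#'                  sites = list(cleavage_site(1500, c(t10 = 0.5))))
#' @export
transcript_model <- function(reference, strand, start, end, abundance = 1,
                             native_end_fraction = 1, sites = list(),
                             accumulation_group = NA_character_) {
  if (!strand %in% c("+", "-")) stop("`strand` must be \"+\" or \"-\"")
  start <- as.integer(start); end <- as.integer(end)
  if (is.na(start) || is.na(end) || start < 1L || end < start)
    stop("`start`/`end` must satisfy 1 <= start <= end")
  if (!is.numeric(abundance) || abundance <= 0)
    stop("`abundance` must be > 0")
  if (native_end_fraction < 0 || native_end_fraction > 1)
    stop("`native_end_fraction` must lie in [0, 1]")
  if (!all(vapply(sites, inherits, logical(1), "cleavage_site")))
    stop("`sites` must be a list of cleavage_site objects")
  for (s in sites) {
    if (s$position <= start || s$position >= end)
      stop("planted site at ", s$position,
           " does not lie strictly inside the span [", start, ", ", end, "]")
  }
  structure(list(reference = as.character(reference), strand = strand,
                 start = start, end = end, abundance = abundance,
                 native_end_fraction = native_end_fraction,
                 sites = sites,
                 accumulation_group = accumulation_group),
            class = "transcript_model")
}

#' Library specification for a simulated 5'-end sequencing run
#'
#' `depletion_factor` scales the site-derived ends whose dependence matches
#' `deplete_dependence` (a temperature-inactivated or knocked-out nuclease
#' generates fewer of its products); `accumulation_factor` scales the native
#' ends of transcripts whose `accumulation_group` matches (the 5'-extended
#' precursors that pile up).  With `deplete_dependence = NA` both factors are
#' inert and the library models an unperturbed condition.
#'
#' @param condition Condition label stored on the resulting count table.
#' @param library_size Total number of reads `N` to sample.
#' @param depletion_factor Real in `(0, 1]`.
#' @param accumulation_factor Real `>= 1`.
#' @param deplete_dependence Dependence label the factors act on, or `NA`.
#' @param seed Integer seed for the multinomial draw.
#' @return An object of class `library_spec`.
#' @export
library_spec <- function(condition, library_size, depletion_factor = 1,
                         accumulation_factor = 1,
                         deplete_dependence = NA_character_, seed = 1L) {
  library_size <- as.integer(library_size)
  if (is.na(library_size) || library_size < 1L)
    stop("`library_size` must be >= 1")
  if (depletion_factor <= 0 || depletion_factor > 1)
    stop("`depletion_factor` must lie in (0, 1]")
  if (accumulation_factor < 1)
    stop("`accumulation_factor` must be >= 1")
  structure(list(condition = as.character(condition),
                 library_size = library_size,
                 depletion_factor = depletion_factor,
                 accumulation_factor = accumulation_factor,
                 deplete_dependence = deplete_dependence,
                 seed = as.integer(seed)),
            class = "library_spec")
}

# Genomic coordinate of a transcript's native (most 5') end.
five_prime_end <- function(tx) {
  if (tx$strand == "+") tx$start else tx$end
}

# 5' end of the downstream cleavage product of a site, strand-aware.
site_end_position <- function(tx, site) {
  if (tx$strand == "+") site$position + 1L else site$position - 1L
}

#' @export
print.transcript_model <- function(x, ...) {
  cat(sprintf("<transcript_model> %s:%d-%d(%s) abundance=%.3g nef=%.3g sites=%d\n",
              x$reference, x$start, x$end, x$strand, x$abundance,
              x$native_end_fraction, length(x$sites)))
  invisible(x)
}
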