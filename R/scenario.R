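#' Simulated direct-entry study: in vitro and in vivo library pairs
#'
#' Builds the package's standard desk-scale study on a 50-kb toy genome with
#' 30 transcripts: 20 carry one planted cleavage site each (14 enzyme
#' dependent in vivo, 6 independent), with in vitro cleavage efficiencies
#' drawn from `efficiency_range` and in vivo efficiencies from 0.4-0.7.
#' Four libraries are sampled:
#'
#' * `before` / `after` - the in vitro pair: dephosphorylated starting
#'   material (native ends detectable at a residual
#'   `native_end_fraction_in_vitro`) against the same sample after enzyme
#'   incubation (timepoints `t10`, `t30`).
#' * `wt` / `ts` - the in vivo pair: the heat-inactivated mutant retains
#'   only `depletion_factor` of the ends at dependent sites.
#'
#' @param seed Integer seed controlling layout, abundances and sampling.
#' @param n_transcripts,n_sites,n_rne_dependent Toy-study composition.
#' @param library_size Reads per library.
#' @param genome_length Toy genome length.
#' @param efficiency_range In vitro cleavage-efficiency range at `t10`.
#' @param depletion_factor Residual activity of the inactivated enzyme.
#' @param native_end_fraction_in_vitro Residual monophosphorylated native
#'   ends after dephosphorylation of the in vitro starting material.
#' @param native_end_fraction_in_vivo Monophosphorylated fraction of native
#'   ends in vivo (decapped or processed molecules).
#' @param abundance_sdlog Log-normal spread of transcript abundances.
#' @return A list with `genome`, `transcripts_in_vitro`,
#'   `transcripts_in_vivo`, `truth` (data frame of planted site ends) and
#'   `counts` (list of the four [end_counts] tables).
#' @export
scenario_direct_entry <- function(seed, n_transcripts = 30L, n_sites = 20L,
                                  n_rne_dependent = 14L,
                                  library_size = 2e5,
                                  genome_length = 50000L,
                                  efficiency_range = c(0.3, 0.9),
                                  depletion_factor = 0.01,
                                  native_end_fraction_in_vitro = 0.02,
                                  native_end_fraction_in_vivo = 0.2,
                                  abundance_sdlog = 0.7) {
  stopifnot(n_sites <= n_transcripts, n_rne_dependent <= n_sites)
  genome <- make_genome(seed, 1L, genome_length)
  slot <- genome_length %/% n_transcripts
  lay <- with_seed(seed + 1L, {
    tx_len <- pmin(slot - 120L, 1400L)
    data.frame(
      start = (seq_len(n_transcripts) - 1L) * slot + 30L,
      len = tx_len,
      strand = rep(c("+", "-"), length.out = n_transcripts),
      abundance = stats::rlnorm(n_transcripts, meanlog = 0,
                                sdlog = abundance_sdlog),
      eff10 = stats::runif(n_transcripts, efficiency_range[1L],
                           efficiency_range[2L]),
      eff_vivo = stats::runif(n_transcripts, 0.4, 0.7),
      # site offset from the transcript 5' end, away from both boundaries
      site_off = sample(100:900, n_transcripts, replace = TRUE),
      stringsAsFactors = FALSE)
  })
  lay$end <- lay$start + lay$len - 1L
  dependence <- rep("independent", n_transcripts)
  dependence[seq_len(n_rne_dependent)] <- "rne_dependent"
  has_site <- seq_len(n_transcripts) <= n_sites

  build <- function(vivo) {
    lapply(seq_len(n_transcripts), function(i) {
      sites <- list()
      if (has_site[i]) {
        pos5 <- if (lay$strand[i] == "+") lay$start[i] else lay$end[i]
        # site coordinate = last nt of the upstream product
        site_pos <- if (lay$strand[i] == "+") pos5 + lay$site_off[i] - 1L
                    else pos5 - lay$site_off[i] + 1L
        eff <- if (vivo) c(vivo = lay$eff_vivo[i])
               else c(t10 = lay$eff10[i], t30 = min(1, lay$eff10[i] + 0.05))
        sites <- list(cleavage_site(site_pos, eff, dependence[i]))
      }
      transcript_model("ref1", lay$strand[i], lay$start[i], lay$end[i],
                       abundance = lay$abundance[i],
                       native_end_fraction =
                         if (vivo) native_end_fraction_in_vivo
                         else native_end_fraction_in_vitro,
                       sites = sites)
    })
  }
  tx_vitro <- build(vivo = FALSE)
  tx_vivo <- build(vivo = TRUE)

  truth <- do.call(rbind, lapply(which(has_site), function(i) {
    tx <- tx_vitro[[i]]
    data.frame(reference = "ref1", strand = lay$strand[i],
               position = site_end_position(tx, tx$sites[[1L]]),
               site_coordinate = tx$sites[[1L]]$position,
               dependence = dependence[i],
               efficiency_t10 = lay$eff10[i],
               efficiency_vivo = lay$eff_vivo[i],
               stringsAsFactors = FALSE)
  }))

  counts <- list(
    before = simulate_end_counts(tx_vitro,
                                 library_spec("before", library_size,
                                              seed = seed + 101L), "before"),
    after = simulate_end_counts(tx_vitro,
                                library_spec("after_t10", library_size,
                                             seed = seed + 102L), "t10"),
    after_t30 = simulate_end_counts(tx_vitro,
                                    library_spec("after_t30", library_size,
                                                 seed = seed + 105L), "t30"),
    wt = simulate_end_counts(tx_vivo,
                             library_spec("wt", library_size,
                                          seed = seed + 103L), "vivo"),
    ts = simulate_end_counts(tx_vivo,
                             library_spec("rne_ts", library_size,
                                          depletion_factor = depletion_factor,
                                          deplete_dependence = "rne_dependent",
                                          seed = seed + 104L), "vivo"))
  list(genome = genome, transcripts_in_vitro = tx_vitro,
       transcripts_in_vivo = tx_vivo, truth = truth, counts = counts)
}

#' Simulated amplification-dilution study with a known dilution factor
#'
#' Every transcript carries one site cleaved with efficiency `1 - dilution`,
#' so after incubation the native ends retain exactly a `dilution` share of
#' the library and their M values concentrate at `log2(dilution)` - the
#' negative baseline that fixed-depth sampling imposes on the unenriched
#' population.  Native ends are fully detectable (`native_end_fraction = 1`)
#' so the baseline is measured on non-nominal records.
#'
#' @param seed Integer seed.
#' @param dilution Native-end share of the post-incubation library, in
#'   (0, 1).
#' @param library_size Reads per library.
#' @param n_transcripts Number of transcripts (also the number of
#'   non-nominal background records; keep >= 100 so
#'   [estimate_baseline()] has enough support).
#' @param genome_length Toy genome length.
#' @return A list with `before`, `after` ([end_counts]) and the transcript
#'   list.
#' @export
scenario_dilution <- function(seed, dilution, library_size = 1e6,
                              n_transcripts = 150L, genome_length = 50000L) {
  if (dilution <= 0 || dilution >= 1) stop("`dilution` must lie in (0, 1)")
  slot <- genome_length %/% n_transcripts
  if (slot < 60L) stop("too many transcripts for the genome length")
  abund <- with_seed(seed + 1L,
                     stats::rlnorm(n_transcripts, meanlog = 0, sdlog = 0.7))
  tx <- lapply(seq_len(n_transcripts), function(i) {
    start <- (i - 1L) * slot + 5L
    end <- start + slot - 10L
    transcript_model("ref1", "+", start, end, abundance = abund[i],
                     native_end_fraction = 1,
                     sites = list(cleavage_site(start + (end - start) %/% 2L,
                                                c(after = 1 - dilution))))
  })
  list(before = simulate_end_counts(tx, library_spec("before", library_size,
                                                     seed = seed + 2L),
                                    "before"),
       after = simulate_end_counts(tx, library_spec("after", library_size,
                                                    seed = seed + 3L),
                                   "after"),
       transcripts = tx)
}

#' Simulated 5'-trimming study with planted pairs, decoys and a boundary
#' control
#'
#' Lays out three kinds of transcripts, each with one trimming-dependent
#' site cleaved in vivo:
#'
#' * *pairs* - the native (precursor) end accumulates in the knockout
#'   (`accumulation_group` set), at planted extension distances spanning
#'   `distances`;
#' * *decoys* - the site is depleted in the knockout but the precursor does
#'   not accumulate, so no event should be emitted;
#' * an optional *negative control* pair at an extension of exactly
#'   `max_extension` nucleotides, which the strict `<` window must reject.
#'
#' @param seed Integer seed.
#' @param n_pairs,n_decoys Numbers of planted pairs and decoys.
#' @param distances Planted extension distances for the pairs (nt).
#' @param negative_control_distance Extension distance of the boundary
#'   control pair, or `NULL` to omit it.
#' @param n_tss How many pair precursors coincide with annotated TSSs.
#' @param library_size Reads per library.
#' @param depletion_factor,accumulation_factor Knockout modifiers.
#' @param genome_length Toy genome length.
#' @return A list with `wt`, `ko` ([end_counts]), `ma` (their `ma_table`,
#'   WT numerator), `tss` (data frame of annotated TSSs), and `truth`
#'   (planted pairs, decoys and control positions).
#' @export
scenario_trimming <- function(seed, n_pairs = 12L, n_decoys = 12L,
                              distances = round(seq(10, 150,
                                                    length.out = n_pairs)),
                              negative_control_distance = 200L,
                              n_tss = 5L,
                              library_size = 2e5,
                              depletion_factor = 0.1,
                              accumulation_factor = 6,
                              genome_length = 50000L) {
  stopifnot(length(distances) == n_pairs, n_tss <= n_pairs)
  n_ctrl <- if (is.null(negative_control_distance)) 0L else 1L
  n_tx <- n_pairs + n_decoys + n_ctrl
  slot <- genome_length %/% n_tx
  if (slot < 500L) stop("too many transcripts for the genome length")
  kind <- c(rep("pair", n_pairs), rep("decoy", n_decoys),
            rep("control", n_ctrl))
  dist <- c(distances,
            with_seed(seed + 9L, sample(10:150, n_decoys, replace = TRUE)),
            if (n_ctrl) negative_control_distance)
  abund <- with_seed(seed + 1L, stats::rlnorm(n_tx, 0, 0.7))
  strand <- rep(c("+", "-"), length.out = n_tx)
  tx <- vector("list", n_tx)
  truth <- vector("list", n_tx)
  for (i in seq_len(n_tx)) {
    start <- (i - 1L) * slot + 30L
    end <- start + min(slot - 80L, 420L)
    pos5 <- if (strand[i] == "+") start else end
    # processed end lies `dist` nt downstream of the native (precursor) end
    proc <- if (strand[i] == "+") pos5 + dist[i] else pos5 - dist[i]
    site_pos <- if (strand[i] == "+") proc - 1L else proc + 1L
    tx[[i]] <- transcript_model(
      "ref1", strand[i], start, end, abundance = abund[i],
      native_end_fraction = 0.2,
      sites = list(cleavage_site(site_pos, c(vivo = 0.5), "rng_dependent")),
      accumulation_group = if (kind[i] %in% c("pair", "control"))
        "rng_dependent" else NA_character_)
    truth[[i]] <- data.frame(reference = "ref1", strand = strand[i],
                             processed_position = proc,
                             precursor_position = pos5,
                             distance = dist[i], kind = kind[i],
                             is_tss = kind[i] == "pair" & i <= n_tss,
                             stringsAsFactors = FALSE)
  }
  truth <- do.call(rbind, truth)
  wt <- simulate_end_counts(tx, library_spec("wt", library_size,
                                             seed = seed + 2L), "vivo")
  ko <- simulate_end_counts(tx, library_spec(
    "rng_ko", library_size, depletion_factor = depletion_factor,
    accumulation_factor = accumulation_factor,
    deplete_dependence = "rng_dependent", seed = seed + 3L), "vivo")
  tss <- truth[truth$is_tss, c("reference", "strand", "precursor_position")]
  names(tss)[3L] <- "position"
  rownames(tss) <- NULL
  list(wt = wt, ko = ko, ma = compute_ma(wt, ko), tss = tss, truth = truth,
       transcripts = tx)
}
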