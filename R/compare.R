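#' Spearman reproducibility between two M-A tables
#'
#' Selects the positions with `M >= min_m` in the first table, matches them
#' by (reference, strand, position) in the second, and computes Spearman's
#' rank correlation with average ranks for ties.  Positions absent from the
#' second table altogether get M = 0 there (both sides at the nominal
#' count).  The p-value uses the t-distribution approximation on `n - 2`
#' degrees of freedom for `n > 10`, and a seeded permutation test (10^4
#' shuffles) for small `n`, where the t approximation is unreliable.
#'
#' @param ma_1,ma_2 `ma_table` objects from the same condition pair (e.g.
#'   two timepoints of the same reaction).
#' @param min_m Selection threshold applied to `ma_1`.
#' @param seed Seed for the permutation p-value (only used when `n <= 10`).
#' @return An object of class `reproducibility_result` with fields `rho`,
#'   `p_value`, `n`, `min_m`.
#' @export
spearman_reproducibility <- function(ma_1, ma_2, min_m, seed = 1L) {
  sel <- which(ma_1$M >= min_m)
  if (length(sel) < 3L)
    stop("need at least 3 positions with M >= min_m")
  k1 <- end_key(ma_1$reference[sel], ma_1$strand[sel], ma_1$position[sel])
  k2 <- end_key(ma_2$reference, ma_2$strand, ma_2$position)
  idx <- match(k1, k2)
  x <- ma_1$M[sel]
  y <- ifelse(is.na(idx), 0, ma_2$M[idx])   # absent: nominal on both sides
  n <- length(x)
  rho <- stats::cor(rank(x), rank(y))
  if (n > 10L) {
    tt <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
    p <- 2 * stats::pt(-abs(tt), df = n - 2)
  } else {
    B <- 10000L
    obs <- abs(rho)
    rx <- rank(x)
    hits <- with_seed(seed, sum(vapply(seq_len(B), function(b) {
      abs(stats::cor(rx, rank(sample(y)))) >= obs - 1e-12
    }, logical(1))))
    p <- (1 + hits) / (1 + B)
  }
  structure(list(rho = rho, p_value = p, n = n, min_m = min_m),
            class = "reproducibility_result")
}

#' @export
print.reproducibility_result <- function(x, ...) {
  cat(sprintf("<reproducibility> Spearman rho = %.3f (n = %d, M >= %g), p = %.3g\n",
              x$rho, x$n, x$min_m, x$p_value))
  invisible(x)
}

#' Write a reproducibility result as key:value text
#'
#' @param x A `reproducibility_result`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_reproducibility <- function(x, path) {
  writeLines(c(paste0("rho:", format(x$rho, digits = 10)),
               paste0("p_value:", format(x$p_value, digits = 10)),
               paste0("n:", x$n),
               paste0("min_m:", x$min_m)), path)
  invisible(path)
}

#' Intersect in vivo-dependent and in vitro-generated site calls
#'
#' A pair matches when reference and strand agree and the positions differ
#' by at most `tolerance` nucleotides.  Each in vivo site is matched at most
#' once: the nearest unmatched in vitro site wins, ties toward the smaller
#' coordinate.  Matched sites are direct-entry candidates (cleaved by the
#' enzyme in a purified system *and* dependent on it in the cell); the rest
#' are classified `in_vivo_only` / `in_vitro_only`.  The default tolerance
#' is 0; a documented +/-1 option absorbs the one-nucleotide ambiguity
#' between end-coordinate conventions.
#'
#' @param in_vivo,in_vitro `site_calls` data frames.
#' @param tolerance Maximum position difference in nucleotides.
#' @return A data frame of class `classified_sites` with columns
#'   `reference`, `strand`, `position_in_vivo`, `position_in_vitro`,
#'   `M_in_vivo`, `M_in_vitro`, `class`; class counts are in attribute
#'   `class_counts`.
#' @export
intersect_sites <- function(in_vivo, in_vitro, tolerance = 0L) {
  tolerance <- as.integer(tolerance)
  if (tolerance < 0L) stop("`tolerance` must be >= 0")
  vivo <- as.data.frame(in_vivo)
  vitro <- as.data.frame(in_vitro)
  vitro$matched <- FALSE
  rows <- vector("list", nrow(vivo) + nrow(vitro))
  r <- 0L
  ord <- order(vivo$reference, vivo$strand, vivo$position)
  for (i in ord) {
    cand <- which(!vitro$matched &
                    vitro$reference == vivo$reference[i] &
                    vitro$strand == vivo$strand[i] &
                    abs(vitro$position - vivo$position[i]) <= tolerance)
    r <- r + 1L
    if (length(cand) == 0L) {
      rows[[r]] <- data.frame(reference = vivo$reference[i],
                              strand = vivo$strand[i],
                              position_in_vivo = vivo$position[i],
                              position_in_vitro = NA_integer_,
                              M_in_vivo = vivo$M[i],
                              M_in_vitro = NA_real_,
                              class = "in_vivo_only",
                              stringsAsFactors = FALSE)
    } else {
      d <- abs(vitro$position[cand] - vivo$position[i])
      best <- cand[order(d, vitro$position[cand])][1L]
      vitro$matched[best] <- TRUE
      rows[[r]] <- data.frame(reference = vivo$reference[i],
                              strand = vivo$strand[i],
                              position_in_vivo = vivo$position[i],
                              position_in_vitro = vitro$position[best],
                              M_in_vivo = vivo$M[i],
                              M_in_vitro = vitro$M[best],
                              class = "direct_entry_candidate",
                              stringsAsFactors = FALSE)
    }
  }
  for (j in which(!vitro$matched)) {
    r <- r + 1L
    rows[[r]] <- data.frame(reference = vitro$reference[j],
                            strand = vitro$strand[j],
                            position_in_vivo = NA_integer_,
                            position_in_vitro = vitro$position[j],
                            M_in_vivo = NA_real_,
                            M_in_vitro = vitro$M[j],
                            class = "in_vitro_only",
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows[seq_len(r)])
  rownames(out) <- NULL
  counts <- table(factor(out$class, levels = c("direct_entry_candidate",
                                               "in_vivo_only",
                                               "in_vitro_only")))
  structure(out, class_counts = counts, tolerance = tolerance,
            class = c("classified_sites", "data.frame"))
}

#' @export
print.classified_sites <- function(x, ...) {
  cc <- attr(x, "class_counts")
  cat(sprintf("<classified_sites> candidates=%d in_vivo_only=%d in_vitro_only=%d (tol=%d)\n",
              cc[["direct_entry_candidate"]], cc[["in_vivo_only"]],
              cc[["in_vitro_only"]], attr(x, "tolerance")))
  invisible(x)
}

#' Top-k direct-entry candidates by M value
#'
#' @param classified A `classified_sites` data frame.
#' @param by Which M value to rank by.
#' @param k Number of sites to return.
#' @return The top `k` candidate rows, ordered by the chosen M descending,
#'   ties broken by coordinate.
#' @export
rank_top_sites <- function(classified, by = c("M_in_vitro", "M_in_vivo"),
                           k = 100L) {
  by <- match.arg(by)
  k <- as.integer(k)
  if (is.na(k) || k < 1L) stop("`k` must be >= 1")
  cand <- classified[classified$class == "direct_entry_candidate", ,
                     drop = FALSE]
  pos <- ifelse(is.na(cand$position_in_vivo), cand$position_in_vitro,
                cand$position_in_vivo)
  ord <- order(-cand[[by]], cand$reference, cand$strand, pos)
  out <- cand[utils::head(ord, k), , drop = FALSE]
  rownames(out) <- NULL
  out
}
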