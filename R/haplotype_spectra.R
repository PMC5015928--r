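# Window haplotype spectra: enumerate 50-marker haplotypes per window,
# track their frequencies between cohorts with stable identities, compare
# haplotype-level to allele-level change in sneak vs neutral windows, and
# scan the average pairwise shared-haplotype length (H).

#' Window haplotype spectra for one cohort
#'
#' Per sliding window, the distinct complete haplotype strings (the
#' window's call sequence) and their frequencies among usable lines.
#' Lines with a missing or heterozygous call inside a window are excluded
#' from that window's denominator.
#'
#' @param g `genotype_matrix` cohort subset.
#' @param window,step Window width and increment in markers.
#' @return A `haplotype_spectrum_set`: list with `windows` (the
#'   [window_grid()] plus `n_lines` used; windows where every line was
#'   excluded are flagged via `n_lines = 0`) and `spectra` (per window, a
#'   `data.frame(haplotype, freq)` sorted by descending frequency).
#' @export
window_haplotype_spectrum <- function(g, window = 50, step = 10) {
  if (nrow(g$calls) < 1) stop("window_haplotype_spectrum: empty cohort")
  wins <- window_grid(g$map, window, step)
  usable <- !is.na(g$calls) & g$calls != CALL_HET
  spectra <- vector("list", nrow(wins))
  n_used <- integer(nrow(wins))
  for (k in seq_len(nrow(wins))) {
    cols <- wins$col_start[k]:wins$col_stop[k]
    ok <- rowSums(usable[, cols, drop = FALSE]) == length(cols)
    n_used[k] <- sum(ok)
    if (!any(ok)) {
      spectra[[k]] <- data.frame(haplotype = character(), freq = numeric(),
                                 stringsAsFactors = FALSE)
      next
    }
    strings <- apply(g$calls[ok, cols, drop = FALSE], 1, paste, collapse = "")
    tab <- sort(table(strings), decreasing = TRUE)
    spectra[[k]] <- data.frame(haplotype = names(tab),
                               freq = as.numeric(tab) / sum(tab),
                               stringsAsFactors = FALSE)
  }
  if (any(n_used == 0))
    warning("window_haplotype_spectrum: ", sum(n_used == 0),
            " window(s) with no usable line")
  wins$n_lines <- n_used
  names(spectra) <- wins$window_id
  structure(list(windows = wins, spectra = spectra),
            class = "haplotype_spectrum_set")
}

#' Track haplotype spectra between an early and a late cohort
#'
#' Haplotype identities are matched by exact string equality: haplotypes
#' seen in the early cohort keep their early identity rank (descending
#' early frequency); new late-cohort haplotypes receive the next ranks.
#' Ranks above 7 are lumped as `OTHER` for display, but frequency changes
#' are computed on the raw strings (an absent haplotype has frequency 0).
#'
#' @param early,late `haplotype_spectrum_set`s on the same windows (e.g.
#'   pre-1970s and 2000s cohorts).
#' @param max_ranks Distinct identities before lumping (default 7).
#' @return A `tracked_spectra`: list with `windows` (the grid plus
#'   `max_haplotype_change` = max over haplotypes of |freq_late -
#'   freq_early|) and `tracked` (per window,
#'   `data.frame(haplotype, rank, freq_early, freq_late)`, rank `"OTHER"`
#'   beyond `max_ranks`).
#' @export
track_spectra_over_cohorts <- function(early, late, max_ranks = 7) {
  if (!identical(early$windows$window_id, late$windows$window_id))
    stop("track_spectra_over_cohorts: window grids differ")
  wins <- early$windows
  tracked <- vector("list", nrow(wins))
  maxchg <- numeric(nrow(wins))
  for (k in seq_len(nrow(wins))) {
    e <- early$spectra[[k]]; l <- late$spectra[[k]]
    haps <- c(e$haplotype, setdiff(l$haplotype, e$haplotype))
    fe <- e$freq[match(haps, e$haplotype)]; fe[is.na(fe)] <- 0
    fl <- l$freq[match(haps, l$haplotype)]; fl[is.na(fl)] <- 0
    maxchg[k] <- if (length(haps)) max(abs(fl - fe)) else 0
    rank <- seq_along(haps)
    tracked[[k]] <- data.frame(
      haplotype = haps,
      rank = ifelse(rank <= max_ranks, as.character(rank), "OTHER"),
      freq_early = fe, freq_late = fl, stringsAsFactors = FALSE)
  }
  wins$max_haplotype_change <- maxchg
  names(tracked) <- wins$window_id
  structure(list(windows = wins, tracked = tracked),
            class = "tracked_spectra")
}

#' Haplotype-change vs allele-change ratio in sneak vs neutral windows
#'
#' Per window the ratio of the largest haplotype frequency change
#' (early vs late cohort) to the largest single-marker total frequency
#' change (early vs late). Windows called `sneak` should fix as
#' haplotypes while their constituent alleles move slowly, elevating this
#' ratio relative to `neutral` windows. The group difference in medians
#' is tested by label permutation.
#'
#' @param calls `data.frame` with `window_id` and `category` (e.g.
#'   `classify_windows()$calls`).
#' @param max_haplotype_change Numeric vector aligned with `calls`
#'   (e.g. `track_spectra_over_cohorts()$windows$max_haplotype_change`).
#' @param max_allele_change Largest single-marker |frequency change|
#'   between the early and late cohorts, aligned with `calls`.
#' @param n_perm Number of label permutations (default 1e5).
#' @param seed Optional integer seed.
#' @return List: `median_sneak`, `median_neutral`, `ratio_excess`
#'   (sneak/neutral - 1), `p_value` (one-sided, sneak > neutral),
#'   `n_sneak`, `n_neutral`, `n_zero_denominator`, `n_perm`, `method`.
#' @export
sneak_ratio_test <- function(calls, max_haplotype_change, max_allele_change,
                             n_perm = 1e5, seed = NULL) {
  stopifnot(nrow(calls) == length(max_haplotype_change),
            nrow(calls) == length(max_allele_change))
  ratio <- max_haplotype_change / max_allele_change
  usable <- !is.na(calls$category) & calls$category %in% c("sneak", "neutral") &
    is.finite(ratio)
  n_zero <- sum(calls$category %in% c("sneak", "neutral") &
                  (is.na(max_allele_change) | max_allele_change == 0),
                na.rm = TRUE)
  r <- ratio[usable]
  lab <- calls$category[usable]
  n_s <- sum(lab == "sneak"); n_n <- sum(lab == "neutral")
  if (n_s < 10 || n_n < 10)
    stop("sneak_ratio_test: need >= 10 windows in each of sneak and neutral")
  med_s <- stats::median(r[lab == "sneak"])
  med_n <- stats::median(r[lab == "neutral"])
  obs <- med_s - med_n
  perm <- .with_seed(seed, vapply(seq_len(n_perm), function(i) {
    sh <- sample(lab)
    stats::median(r[sh == "sneak"]) - stats::median(r[sh == "neutral"])
  }, numeric(1)))
  p <- (1 + sum(perm >= obs)) / (n_perm + 1)
  list(median_sneak = med_s, median_neutral = med_n,
       ratio_excess = med_s / med_n - 1, p_value = p,
       n_sneak = n_s, n_neutral = n_n, n_zero_denominator = n_zero,
       n_perm = n_perm, method = "label permutation of the median difference")
}

#' Average pairwise shared-haplotype length scan (H)
#'
#' For each marker, H is the average over line pairs of the length in
#' markers of the maximal identical tract containing that marker (calls
#' must be exactly equal; a pair disagreeing at the focal marker, or
#' either call missing there, contributes 0; tracts truncate at
#' chromosome boundaries). Long H marks recent haplotype sharing.
#'
#' @param g `genotype_matrix` cohort subset with >= 2 lines.
#' @param bp Report tract lengths in bp spanned instead of marker counts.
#' @return `data.frame`: `marker`, `chrom`, `index`, `H`.
#' @export
h_scan <- function(g, bp = FALSE) {
  n <- nrow(g$calls)
  if (n < 2) stop("h_scan: need at least 2 lines")
  M <- ncol(g$calls)
  chrom <- g$map$chrom
  new_chrom <- c(TRUE, chrom[-1] != chrom[-M])
  total <- numeric(M)
  n_pairs <- 0L
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      agree <- g$calls[i, ] == g$calls[j, ]
      agree[is.na(agree)] <- FALSE
      brk <- c(TRUE, agree[-1] != agree[-M] | new_chrom[-1])
      runid <- cumsum(brk)
      if (bp) {
        span <- vapply(split(g$map$pos, runid),
                       function(p) p[length(p)] - p[1] + 1L, numeric(1))
        total <- total + span[runid] * agree
      } else {
        runlen <- tabulate(runid)
        total <- total + runlen[runid] * agree
      }
      n_pairs <- n_pairs + 1L
    }
  }
  data.frame(marker = g$map$marker, chrom = chrom, index = g$map$index,
             H = total / n_pairs, stringsAsFactors = FALSE)
}
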