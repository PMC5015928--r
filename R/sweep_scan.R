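# Sweep-mode classification: combine per-window allele-frequency change
# with cohort diversity ratios into hard sweep / soft sweep / haplotype
# sneak / neutral calls, and tabulate cross-population candidate alleles.

#' Per-window average of the three largest marker |delta-f| values
#'
#' Averaging the top three per-marker rates of change balances the noise
#' of a single extreme marker against the insensitivity of a whole-window
#' mean.
#'
#' @param delta_f_by_marker Named numeric vector of per-marker delta-f
#'   values (names = marker ids; markers without a value may be absent or
#'   `NA`).
#' @param windows A [window_grid()] for the map the markers belong to.
#' @param map The marker map (provides window membership).
#' @return `windows` with a `top3_delta_f` column; windows with fewer
#'   than 3 scored markers are `NA` with a warning.
#' @export
window_selection_stats <- function(delta_f_by_marker, windows, map) {
  vals <- delta_f_by_marker[match(map$marker, names(delta_f_by_marker))]
  top3 <- vapply(seq_len(nrow(windows)), function(k) {
    v <- abs(vals[windows$col_start[k]:windows$col_stop[k]])
    v <- v[!is.na(v)]
    if (length(v) < 3) return(NA_real_)
    mean(sort(v, decreasing = TRUE)[1:3])
  }, numeric(1))
  if (anyNA(top3))
    warning("window_selection_stats: ", sum(is.na(top3)),
            " window(s) with <3 scored markers skipped")
  windows$top3_delta_f <- top3
  windows
}

#' Four-quadrant sweep-mode classification
#'
#' A window is a `hard` sweep when allele change is fast and local
#' diversity collapsed (`top3 >= delta_f_threshold` and
#' `log2_ratio <= -diversity_threshold`); `soft` when change is fast
#' without the diversity collapse; `sneak` when diversity collapsed
#' without fast change of any constituent allele; `neutral` otherwise.
#' `diversity_threshold` is a positive magnitude of log2 reduction.
#'
#' @param stats `data.frame` with `window_id`, `top3_delta_f` and
#'   `log2_ratio` columns (see [window_selection_stats()] and
#'   [log2_diversity_ratio()]).
#' @param delta_f_threshold Population delta-f threshold (e.g. from
#'   [neutral_thresholds()]).
#' @param diversity_threshold Positive log2-units diversity threshold.
#' @return A `sweep_calls` list: `calls` (`stats` plus `category`),
#'   `counts` (per category: count and percent of putatively selected
#'   windows), and the thresholds.
#' @export
classify_windows <- function(stats, delta_f_threshold, diversity_threshold) {
  stopifnot(delta_f_threshold > 0, diversity_threshold > 0)
  fast <- stats$top3_delta_f >= delta_f_threshold
  lowdiv <- stats$log2_ratio <= -diversity_threshold
  category <- rep("neutral", nrow(stats))
  category[fast & lowdiv] <- "hard"
  category[fast & !lowdiv] <- "soft"
  category[!fast & lowdiv] <- "sneak"
  category[is.na(fast) | is.na(lowdiv)] <- NA_character_
  stats$category <- category
  sel <- category[!is.na(category) & category != "neutral"]
  counts <- data.frame(
    category = c("sneak", "hard", "soft"),
    count = c(sum(sel == "sneak"), sum(sel == "hard"), sum(sel == "soft")),
    stringsAsFactors = FALSE)
  counts$percent_of_selected <-
    if (length(sel)) round(100 * counts$count / length(sel)) else NA_real_
  structure(list(calls = stats, counts = counts,
                 total_windows = nrow(stats),
                 delta_f_threshold = delta_f_threshold,
                 diversity_threshold = diversity_threshold),
            class = "sweep_calls")
}

#' @export
print.sweep_calls <- function(x, ...) {
  cat(sprintf("sweep_calls: %d windows (thresholds: delta-f %.4g, diversity %.3g)\n",
              x$total_windows, x$delta_f_threshold, x$diversity_threshold))
  print(x$counts)
  invisible(x)
}

#' Cross-population candidate alleles
#'
#' Markers whose frequency change in a source population exceeds that
#' population's threshold while the same allele is fixed in the opposite
#' direction of the change in at least one other population
#' (final frequency <= 0.05 when the source allele rose, >= 0.95 when it
#' fell). Polarity must be shared across populations (one reference
#' allele per marker). Delta-f values are reported multiplied by 1000
#' (presentation convention); internal units stay per generation.
#'
#' @param stats_by_pop Named list (one entry per population) of
#'   `data.frame(marker, delta_f, final_freq)` on the identical marker
#'   set and polarity.
#' @param thresholds Named per-population delta-f thresholds.
#' @param fixed_bounds Fixation bounds for "fixed" (default 0.05/0.95).
#' @return `data.frame`: `marker`, `source`, `sinks` (comma-separated),
#'   then per population `delta_f_x1000_<pop>`, `final_freq_<pop>`, and
#'   `exceeds_<pop>` (beyond that population's threshold).
#' @export
cross_population_candidates <- function(stats_by_pop, thresholds,
                                        fixed_bounds = c(0.05, 0.95)) {
  pops <- names(stats_by_pop)
  stopifnot(length(pops) >= 2, all(pops %in% names(thresholds)))
  markers <- stats_by_pop[[1]]$marker
  for (p in pops[-1])
    if (!identical(stats_by_pop[[p]]$marker, markers))
      stop("cross_population_candidates: marker sets/polarity differ between populations")
  df <- vapply(pops, function(p) stats_by_pop[[p]]$delta_f, numeric(length(markers)))
  ff <- vapply(pops, function(p) stats_by_pop[[p]]$final_freq, numeric(length(markers)))
  exceeds <- sweep(abs(df), 2, unlist(thresholds[pops]), `>`)
  rows <- list()
  for (m in seq_along(markers)) {
    for (src in which(exceeds[m, ])) {
      dir <- sign(df[m, src])
      if (dir == 0) next
      sinks <- setdiff(seq_along(pops), src)
      sinks <- sinks[if (dir > 0) ff[m, sinks] <= fixed_bounds[1]
                     else ff[m, sinks] >= fixed_bounds[2]]
      if (!length(sinks)) next
      rows[[length(rows) + 1L]] <- data.frame(
        marker = markers[m], source = pops[src],
        sinks = paste(pops[sinks], collapse = ","),
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows)
         else data.frame(marker = character(), source = character(),
                         sinks = character(), stringsAsFactors = FALSE)
  idx <- match(out$marker, markers)
  for (p in seq_along(pops)) {
    out[[paste0("delta_f_x1000_", pops[p])]] <- round(1000 * df[idx, p], 2)
    out[[paste0("final_freq_", pops[p])]] <- ff[idx, p]
    out[[paste0("exceeds_", pops[p])]] <- exceeds[idx, p]
  }
  out
}
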