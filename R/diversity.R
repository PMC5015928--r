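# Sliding-window nucleotide diversity (pi), log2 diversity ratios between
# a focal cohort and a reference panel, and low-diversity region reports
# with founder-haplotype attribution.

#' Sliding marker-window grid
#'
#' Windows are defined on the per-chromosome marker index (not bp): width
#' `window` markers advancing by `step`; a final partial window is
#' dropped.
#'
#' @param map Marker map of the genotype matrix the windows will index.
#' @param window,step Window width and increment in markers (default 50/10).
#' @return `data.frame` with `window_id`, `chrom`, `start_index`,
#'   `stop_index` (1-based inclusive per-chromosome indices),
#'   `midsite_index`, `start_bp`, `stop_bp`, and `col_start`/`col_stop`
#'   (column positions in the calls matrix).
#' @export
window_grid <- function(map, window = 50, step = 10) {
  out <- lapply(unique(map$chrom), function(ch) {
    cols <- which(map$chrom == ch)
    M <- length(cols)
    if (M < window) return(NULL)
    n_win <- (M - window) %/% step + 1L
    start <- (seq_len(n_win) - 1L) * step + 1L
    stop <- start + window - 1L
    data.frame(window_id = paste0(ch, ":", start, "-", stop),
               chrom = ch, start_index = start, stop_index = stop,
               midsite_index = (start + stop) %/% 2L,
               start_bp = map$pos[cols[start]], stop_bp = map$pos[cols[stop]],
               col_start = cols[start], col_stop = cols[stop],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(window_id = character(), chrom = character(),
                      start_index = integer(), stop_index = integer(),
                      midsite_index = integer(), start_bp = integer(),
                      stop_bp = integer(), col_start = integer(),
                      col_stop = integer(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Sliding-window nucleotide diversity
#'
#' Per window, pi is the mean over line pairs of the proportion of
#' comparable markers at which the pair differs (heterozygote vs
#' homozygote counts a half-difference; missing calls are excluded
#' pairwise; pairs with no comparable marker in a window are dropped from
#' the mean). Units: pairwise differences per marker.
#'
#' @param g `genotype_matrix` subset (e.g. one cohort) with >= 2 lines.
#' @param window,step Window width and increment in markers.
#' @return `data.frame` (the [window_grid()] columns plus `pi`).
#' @export
sliding_pi <- function(g, window = 50, step = 10) {
  if (nrow(g$calls) < 2) stop("sliding_pi: need at least 2 lines")
  wins <- window_grid(g$map, window, step)
  D <- .dosage(g$calls)
  ut <- upper.tri(diag(nrow(D)))
  wins$pi <- vapply(seq_len(nrow(wins)), function(k) {
    st <- .cross_diff_stats(D[, wins$col_start[k]:wins$col_stop[k], drop = FALSE],
                            D[, wins$col_start[k]:wins$col_stop[k], drop = FALSE])
    prop <- st$diff[ut] / st$count[ut]
    mean(prop[st$count[ut] > 0])
  }, numeric(1))
  wins
}

#' Log2 diversity ratio between aligned window series
#'
#' `log2(pi_x / pi_a)` per window, capped to \[-cap, cap\]; windows with
#' `pi_x = 0` report the lower cap (the "<-8" reporting convention) and
#' windows with `pi_a = 0` are masked (`NA`, ratio undefined).
#'
#' @param pi_x Focal-population window series from [sliding_pi()].
#' @param pi_a Reference-panel series on identical windows.
#' @param cap Cap magnitude in log2 units (default 8).
#' @return `pi_x` with columns `pi_a` and `log2_ratio` added.
#' @export
log2_diversity_ratio <- function(pi_x, pi_a, cap = 8) {
  if (!identical(pi_x$window_id, pi_a$window_id))
    stop("log2_diversity_ratio: window series are not aligned")
  out <- pi_x
  names(out)[names(out) == "pi"] <- "pi_x"
  out$pi_a <- pi_a$pi
  r <- log2(out$pi_x / out$pi_a)
  r[out$pi_x == 0] <- -Inf
  r <- pmin(pmax(r, -cap), cap)
  r[out$pi_a == 0] <- NA_real_
  out$log2_ratio <- r
  out
}

# Most frequent complete homozygous window haplotype among rows of calls
# restricted to cols; NULL if no usable line.
.major_haplotype <- function(calls, cols) {
  sub <- calls[, cols, drop = FALSE]
  ok <- rowSums(is.na(sub)) == 0 & rowSums(sub == CALL_HET, na.rm = TRUE) == 0
  if (!any(ok)) return(NULL)
  strings <- apply(sub[ok, , drop = FALSE], 1, paste, collapse = "")
  names(which.max(table(strings)))
}

#' Report merged low-diversity regions with founder attribution
#'
#' Windows whose log2 diversity ratio falls below `threshold` are merged
#' when overlapping or adjacent into regions; each region reports the
#' minimum-ratio window's midsite marker index, bp span, ratio and
#' reference diversity, and the percent of founding ancestors carrying
#' the focal population's major window haplotype at that window.
#'
#' @param ratios Output of [log2_diversity_ratio()].
#' @param g_focal `genotype_matrix` of the focal population (the lines
#'   whose diversity `pi_x` describes).
#' @param founders Ancestor `genotype_matrix` restricted to the founding
#'   ancestors, sharing the marker map (or `NULL`: percent reported
#'   missing).
#' @param threshold Log2-units report threshold (default -2.3); windows
#'   with ratio strictly below it enter the report.
#' @return `data.frame` of regions sorted by ascending log2 ratio:
#'   `chrom`, `midsite_index`, `start_bp`, `stop_bp`, `log2_ratio`,
#'   `pi_a`, `percent_founders`, `n_windows`.
#' @export
low_diversity_report <- function(ratios, g_focal, founders = NULL,
                                 threshold = -2.3) {
  hit <- which(!is.na(ratios$log2_ratio) & ratios$log2_ratio < threshold)
  if (!length(hit))
    return(data.frame(chrom = character(), midsite_index = integer(),
                      start_bp = integer(), stop_bp = integer(),
                      log2_ratio = numeric(), pi_a = numeric(),
                      percent_founders = numeric(), n_windows = integer(),
                      stringsAsFactors = FALSE))
  if (!is.null(founders) && !identical(g_focal$map$marker, founders$map$marker))
    stop("low_diversity_report: founder marker map differs")
  sub <- ratios[hit, , drop = FALSE]
  new_region <- c(TRUE, sub$chrom[-1] != sub$chrom[-nrow(sub)] |
                    sub$start_index[-1] > sub$stop_index[-nrow(sub)] + 1L)
  region <- cumsum(new_region)
  out <- do.call(rbind, lapply(split(sub, region), function(rs) {
    k <- which.min(rs$log2_ratio)
    pct <- NA_real_
    if (!is.null(founders) && nrow(founders$calls) > 0) {
      cols <- rs$col_start[k]:rs$col_stop[k]
      major <- .major_haplotype(g_focal$calls, cols)
      if (!is.null(major)) {
        fsub <- founders$calls[, cols, drop = FALSE]
        fok <- rowSums(is.na(fsub)) == 0 &
          rowSums(fsub == CALL_HET, na.rm = TRUE) == 0
        if (any(fok)) {
          fstr <- apply(fsub[fok, , drop = FALSE], 1, paste, collapse = "")
          pct <- round(100 * mean(fstr == major))
        }
      }
    }
    data.frame(chrom = rs$chrom[1], midsite_index = rs$midsite_index[k],
               start_bp = min(rs$start_bp), stop_bp = max(rs$stop_bp),
               log2_ratio = rs$log2_ratio[k], pi_a = rs$pi_a[k],
               percent_founders = pct, n_windows = nrow(rs),
               stringsAsFactors = FALSE)
  }))
  out <- out[order(out$log2_ratio), , drop = FALSE]
  rownames(out) <- NULL
  out
}
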