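# Shared fixture builders and independent brute-force oracles.
# Calls are coded 0 = A0 homozygote, 1 = A1 homozygote, 2 = HET, NA missing.

make_map <- function(n_markers, n_chrom = 1, spacing = 1000L) {
  per <- diff(round(seq(0, n_markers, length.out = n_chrom + 1)))
  marker_map(chrom = rep(paste0("chr", seq_len(n_chrom)), times = per),
             pos = unlist(lapply(per, function(m) seq_len(m) * spacing)),
             allele0 = rep("A", n_markers), allele1 = rep("B", n_markers))
}

make_geno <- function(calls, n_chrom = 1, panel = NULL) {
  calls <- as.matrix(calls)
  if (is.null(rownames(calls)) && nrow(calls) > 0)
    rownames(calls) <- paste0("L", seq_len(nrow(calls)))
  suppressWarnings(genotype_matrix(calls, make_map(ncol(calls), n_chrom),
                                   panel = panel))
}

make_panel <- function(line_id, mg, year) {
  assign_cohorts_and_populations(data.frame(
    line_id = line_id, maturity_group = mg, year_of_release = year,
    stringsAsFactors = FALSE))
}

# pairwise match score between two call codes: 1 identical (or HET/HET),
# 0.5 HET vs homozygote, 0 opposite homozygotes, NA if either missing
match_score <- function(a, b) {
  if (is.na(a) || is.na(b)) return(NA_real_)
  if (a == b) return(1)
  if (a == 2 || b == 2) return(0.5)
  0
}

# brute-force IBS between two call vectors
bf_ibs <- function(x, y) {
  sc <- mapply(match_score, x, y)
  mean(sc, na.rm = TRUE)
}

# brute-force window pi: mean over pairs of (mismatch / comparable)
bf_pi <- function(calls) {
  n <- nrow(calls)
  vals <- c()
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    sc <- mapply(match_score, calls[i, ], calls[j, ])
    if (all(is.na(sc))) next
    vals <- c(vals, mean(1 - sc, na.rm = TRUE))
  }
  mean(vals)
}

# brute-force match extent of line vs one ancestor at marker m:
# expand left/right over agreeing markers (line HET or ancestor HET are
# wildcards, missing breaks), 0 if the focal marker disagrees
bf_extent <- function(line, anc, m, chrom) {
  ag <- function(k) {
    if (is.na(line[k]) || is.na(anc[k])) return(FALSE)
    line[k] == anc[k] || line[k] == 2 || anc[k] == 2
  }
  if (!ag(m)) return(0)
  len <- 1
  k <- m - 1
  while (k >= 1 && chrom[k] == chrom[m] && ag(k)) { len <- len + 1; k <- k - 1 }
  k <- m + 1
  while (k <= length(line) && chrom[k] == chrom[m] && ag(k)) {
    len <- len + 1; k <- k + 1
  }
  len
}

# brute-force margin-rule donor assignment for one line
bf_assign <- function(line, anc_calls, chrom, margin_threshold = 5) {
  M <- length(line)
  donor <- character(M)
  for (m in seq_len(M)) {
    ext <- vapply(seq_len(nrow(anc_calls)), function(a)
      bf_extent(line, anc_calls[a, ], m, chrom), numeric(1))
    o <- order(ext, decreasing = TRUE)
    donor[m] <- if (ext[o[1]] > ext[o[2]] + margin_threshold)
      rownames(anc_calls)[o[1]] else "AMBIGUOUS"
  }
  donor
}

# brute-force H: average over pairs of the identical tract length
# containing each marker (0 when the pair differs at the marker)
bf_h_scan <- function(calls, chrom) {
  n <- nrow(calls); M <- ncol(calls)
  tot <- numeric(M)
  np <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    np <- np + 1
    eq <- function(k) !is.na(calls[i, k]) && !is.na(calls[j, k]) &&
      calls[i, k] == calls[j, k]
    for (m in seq_len(M)) {
      if (!eq(m)) next
      len <- 1
      k <- m - 1
      while (k >= 1 && chrom[k] == chrom[m] && eq(k)) { len <- len + 1; k <- k - 1 }
      k <- m + 1
      while (k <= M && chrom[k] == chrom[m] && eq(k)) { len <- len + 1; k <- k + 1 }
      tot[m] <- tot[m] + len
    }
  }
  tot / np
}
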