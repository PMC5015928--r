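# Call codes used throughout: 0 = homozygous first allele (A0),
# 1 = homozygous second allele (A1), 2 = heterozygous, NA = missing.
CALL_A0 <- 0L
CALL_A1 <- 1L
CALL_HET <- 2L

#' Construct a marker map
#'
#' A marker map records, for each biallelic SNP, its chromosome, physical
#' position and the two allele codes. Markers are sorted by position within
#' chromosome and given a 1-based per-chromosome index (the "marker index"
#' convention used in window and region reports).
#'
#' @param chrom Chromosome identifier per marker.
#' @param pos Integer physical position (bp, 1-based).
#' @param allele0,allele1 Single-character allele codes; must differ per marker.
#' @param marker Optional marker names; defaults to `chrom_pos`.
#' @return A `data.frame` with columns `marker`, `chrom`, `pos`, `index`,
#'   `allele0`, `allele1`, sorted by (chrom, pos), with `index` running
#'   1..M within each chromosome.
#' @export
marker_map <- function(chrom, pos, allele0, allele1, marker = NULL) {
  n <- length(chrom)
  stopifnot(length(pos) == n, length(allele0) == n, length(allele1) == n)
  if (any(allele0 == allele1))
    stop("marker_map: alleles must be distinct at every marker")
  if (is.null(marker)) marker <- paste(chrom, pos, sep = "_")
  map <- data.frame(marker = as.character(marker), chrom = as.character(chrom),
                    pos = as.integer(pos), stringsAsFactors = FALSE)
  map$allele0 <- as.character(allele0)
  map$allele1 <- as.character(allele1)
  ord <- order(map$chrom, map$pos)
  map <- map[ord, , drop = FALSE]
  map$index <- as.integer(stats::ave(map$pos, map$chrom, FUN = seq_along))
  if (any(duplicated(map[c("chrom", "pos")])))
    warning("marker_map: duplicated chrom/pos entries")
  rownames(map) <- NULL
  map[c("marker", "chrom", "pos", "index", "allele0", "allele1")]
}

#' Construct a genotype matrix object
#'
#' The central container: a lines x markers matrix of integer call codes
#' (0/1 homozygotes, 2 heterozygote, NA missing), a marker map, and an
#' optional sample panel with cohort/population assignments.
#'
#' @param calls Integer matrix, lines x markers; rownames are line ids,
#'   colnames marker names matching `map$marker`.
#' @param map Marker map from [marker_map()].
#' @param panel Optional sample panel `data.frame` with a `line_id` column
#'   covering every row of `calls` (see [assign_cohorts_and_populations()]).
#' @param het_warn Per-line heterozygous-call fraction above which a warning
#'   is emitted (inbred panels should be nearly homozygous).
#' @return An object of class `genotype_matrix` (list with elements `calls`,
#'   `map`, `panel`).
#' @export
genotype_matrix <- function(calls, map, panel = NULL, het_warn = 0.01) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  if (ncol(calls) != nrow(map))
    stop("genotype_matrix: ncol(calls) must equal nrow(map)")
  bad <- calls[!is.na(calls)]
  if (length(bad) && !all(bad %in% c(0L, 1L, 2L)))
    stop("genotype_matrix: calls must be coded 0/1/2/NA")
  if (is.null(colnames(calls))) colnames(calls) <- map$marker
  if (is.null(rownames(calls)) && nrow(calls) > 0)
    rownames(calls) <- paste0("line", seq_len(nrow(calls)))
  if (!is.null(panel)) {
    missing_lines <- setdiff(rownames(calls), panel$line_id)
    if (length(missing_lines))
      stop("genotype_matrix: lines absent from panel: ",
           paste(utils::head(missing_lines, 5), collapse = ", "))
    panel <- panel[match(rownames(calls), panel$line_id), , drop = FALSE]
    rownames(panel) <- NULL
  }
  het_frac <- rowMeans(calls == CALL_HET, na.rm = TRUE)
  if (any(het_frac > het_warn, na.rm = TRUE))
    warning(sprintf("genotype_matrix: %d line(s) exceed %.2f%% heterozygous calls",
                    sum(het_frac > het_warn, na.rm = TRUE), 100 * het_warn))
  structure(list(calls = calls, map = map, panel = panel),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d lines x %d markers on %d chromosome(s)\n",
              nrow(x$calls), ncol(x$calls), length(unique(x$map$chrom))))
  if (!is.null(x$panel) && "population" %in% names(x$panel)) {
    cat("populations:\n")
    print(table(x$panel$population))
  }
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$calls)

#' Subset a genotype matrix by lines and/or markers
#'
#' @param g A `genotype_matrix`.
#' @param lines Line ids or row indices (default all).
#' @param markers Marker names or column indices (default all).
#' @return A `genotype_matrix` restricted to the selection; marker indices
#'   in the map are kept as in the parent (positions along the chromosome),
#'   so window/report coordinates remain comparable.
#' @export
subset_genotypes <- function(g, lines = NULL, markers = NULL) {
  calls <- g$calls
  map <- g$map
  panel <- g$panel
  if (!is.null(lines)) {
    idx <- if (is.character(lines)) match(lines, rownames(calls)) else lines
    if (anyNA(idx)) stop("subset_genotypes: unknown line id")
    calls <- calls[idx, , drop = FALSE]
    if (!is.null(panel)) panel <- panel[idx, , drop = FALSE]
  }
  if (!is.null(markers)) {
    midx <- if (is.character(markers)) match(markers, colnames(calls)) else markers
    if (anyNA(midx)) stop("subset_genotypes: unknown marker")
    calls <- calls[, midx, drop = FALSE]
    map <- map[midx, , drop = FALSE]
  }
  structure(list(calls = calls, map = map, panel = panel),
            class = "genotype_matrix")
}

decade_cohorts <- c("pre1970s", "1970s", "1980s", "1990s", "2000s")

#' Assign decade cohorts and maturity-group populations
#'
#' Pure function of (maturity group, year of release): years before 1970
#' fold into the `pre1970s` cohort, later decades map to `1970s` ...
#' `2000s`. Maturity groups 00/0/I form population `MG0-I`, III/IV form
#' `MGIII-IV`, V and later `MGV+`; MG II lines are `EXCLUDED` (they migrate
#' between the flanking populations over time and confound the cohorts).
#'
#' @param panel `data.frame` with columns `line_id`, `maturity_group`
#'   (one of 00, 0, I, ..., VIII) and `year_of_release` (integer year).
#' @return The panel with `cohort` and `population` columns added.
#' @export
assign_cohorts_and_populations <- function(panel) {
  stopifnot(all(c("line_id", "maturity_group", "year_of_release") %in% names(panel)))
  mg <- toupper(trimws(as.character(panel$maturity_group)))
  known <- c("00", "0", "I", "II", "III", "IV", "V", "VI", "VII", "VIII")
  bad <- !(mg %in% known)
  if (any(bad))
    stop("unknown maturity group for line(s): ",
         paste(panel$line_id[bad], collapse = ", "))
  pop <- rep(NA_character_, length(mg))
  pop[mg %in% c("00", "0", "I")] <- "MG0-I"
  pop[mg == "II"] <- "EXCLUDED"
  pop[mg %in% c("III", "IV")] <- "MGIII-IV"
  pop[mg %in% c("V", "VI", "VII", "VIII")] <- "MGV+"
  yr <- as.integer(panel$year_of_release)
  cohort <- rep("pre1970s", length(yr))
  cohort[yr >= 1970 & yr < 1980] <- "1970s"
  cohort[yr >= 1980 & yr < 1990] <- "1980s"
  cohort[yr >= 1990 & yr < 2000] <- "1990s"
  cohort[yr >= 2000] <- "2000s"
  panel$cohort <- factor(cohort, levels = decade_cohorts)
  panel$population <- pop
  panel
}

# Dosage recoding: A0 -> 0, A1 -> 1, HET -> 0.5, used by IBS and pi.
.dosage <- function(calls) {
  d <- matrix(NA_real_, nrow(calls), ncol(calls), dimnames = dimnames(calls))
  d[calls == CALL_A0] <- 0
  d[calls == CALL_A1] <- 1
  d[calls == CALL_HET] <- 0.5
  d
}

# Pairwise per-marker mismatch scores between rows of two dosage matrices.
# Scoring: identical homozygotes 0, opposite homozygotes 1, het vs homozygote
# 0.5, het vs het 0; missing excluded pairwise. Returns total mismatch and
# comparable-marker counts (rows of D1 x rows of D2).
.cross_diff_stats <- function(D1, D2) {
  M1 <- !is.na(D1); M2 <- !is.na(D2)
  Z1 <- D1; Z1[!M1] <- 0
  Z2 <- D2; Z2[!M2] <- 0
  storage.mode(M1) <- "double"; storage.mode(M2) <- "double"
  sq <- tcrossprod(Z1 * Z1, M2) + tcrossprod(M1, Z2 * Z2) -
    2 * tcrossprod(Z1, Z2)
  H1 <- (D1 == 0.5); H1[is.na(H1)] <- FALSE
  H2 <- (D2 == 0.5); H2[is.na(H2)] <- FALSE
  O1 <- M1 == 1 & !H1; O2 <- M2 == 1 & !H2
  storage.mode(H1) <- "double"; storage.mode(H2) <- "double"
  storage.mode(O1) <- "double"; storage.mode(O2) <- "double"
  hh <- tcrossprod(H1, O2) + tcrossprod(O1, H2)
  list(diff = sq + 0.25 * hh, count = tcrossprod(M1, M2))
}

#' Identity-by-state matrix
#'
#' Pairwise IBS between all lines: the proportion of comparable (pairwise
#' non-missing) markers at which the calls match. Heterozygote vs
#' homozygote scores a half-match; heterozygote vs heterozygote a full
#' match; missing calls are excluded from numerator and denominator.
#'
#' @param g A `genotype_matrix` with at least two lines.
#' @return An `ibs_matrix`: list with `values` (symmetric matrix in
#'   \[0,1\], diagonal 1, NA where a pair shares no comparable marker) and
#'   `counts` (comparable-marker counts).
#' @export
ibs_matrix <- function(g) {
  if (nrow(g$calls) < 2) stop("ibs_matrix: need at least 2 lines")
  D <- .dosage(g$calls)
  st <- .cross_diff_stats(D, D)
  vals <- 1 - st$diff / st$count
  vals[st$count == 0] <- NA_real_
  diag(vals) <- 1
  vals <- (vals + t(vals)) / 2  # enforce exact symmetry against fp noise
  dimnames(vals) <- list(rownames(g$calls), rownames(g$calls))
  structure(list(values = vals, counts = st$count), class = "ibs_matrix")
}

#' @export
print.ibs_matrix <- function(x, ...) {
  cat(sprintf("ibs_matrix: %d lines, mean off-diagonal IBS %.3f\n",
              nrow(x$values),
              mean(x$values[upper.tri(x$values)], na.rm = TRUE)))
  invisible(x)
}

#' Per-population IBS distributions against each ancestor
#'
#' For every (population, ancestor) pair, the IBS of each population member
#' to that ancestor, with summary quartiles — the numeric content of an
#' ancestor-relatedness boxplot panel.
#'
#' @param g A `genotype_matrix` whose panel carries `population`.
#' @param ancestors A `genotype_matrix` of ancestor haplotypes sharing the
#'   same marker map (same markers, same order).
#' @return List with `values` (long `data.frame`: population, ancestor,
#'   line_id, ibs) and `summary` (per population x ancestor: n, median,
#'   q1, q3).
#' @export
population_ancestor_ibs_summary <- function(g, ancestors) {
  if (!identical(g$map$marker, ancestors$map$marker))
    stop("population_ancestor_ibs_summary: marker maps differ")
  if (is.null(g$panel) || !"population" %in% names(g$panel))
    stop("population_ancestor_ibs_summary: panel with populations required")
  st <- .cross_diff_stats(.dosage(g$calls), .dosage(ancestors$calls))
  ibs <- 1 - st$diff / st$count
  ibs[st$count == 0] <- NA_real_
  pops <- unique(g$panel$population)
  anc_names <- rownames(ancestors$calls)
  long <- data.frame(
    population = rep(g$panel$population, times = length(anc_names)),
    ancestor = rep(anc_names, each = nrow(g$calls)),
    line_id = rep(rownames(g$calls), times = length(anc_names)),
    ibs = as.vector(ibs), stringsAsFactors = FALSE)
  sm <- do.call(rbind, lapply(pops, function(p) {
    sub <- long[long$population == p, , drop = FALSE]
    do.call(rbind, lapply(anc_names, function(a) {
      v <- sub$ibs[sub$ancestor == a]
      v <- v[!is.na(v)]
      data.frame(population = p, ancestor = a, n = length(v),
                 median = if (length(v)) stats::median(v) else NA_real_,
                 q1 = if (length(v)) unname(stats::quantile(v, 0.25)) else NA_real_,
                 q3 = if (length(v)) unname(stats::quantile(v, 0.75)) else NA_real_,
                 stringsAsFactors = FALSE)
    }))
  }))
  rownames(sm) <- NULL
  list(values = long, summary = sm)
}
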