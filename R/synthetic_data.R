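# Synthetic inputs: ancestor haplotype panels, recombinant-inbred mosaic
# cohorts with known per-marker ancestry, and haploid Wright-Fisher
# allele-frequency trajectories with selection and temporal sampling.

# Run expr with a locally-seeded RNG, restoring the caller's RNG state.
.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else if (exists(".Random.seed", globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Temporal sampling schedule
#'
#' @param generations Strictly increasing integer generations, starting
#'   at 0. Default `c(0, 15, 25, 35, 45)`: decade cohorts of a breeding
#'   program with a pooled pre-1970s base population.
#' @param sample_sizes Integer lines genotyped per timepoint, or `NULL`
#'   for census observation (observed frequency = population frequency).
#' @return A `sampling_schedule` list.
#' @export
sampling_schedule <- function(generations = c(0, 15, 25, 35, 45),
                              sample_sizes = NULL) {
  generations <- as.integer(generations)
  if (generations[1] != 0L || is.unsorted(generations, strictly = TRUE))
    stop("sampling_schedule: generations must start at 0 and strictly increase")
  if (!is.null(sample_sizes)) {
    sample_sizes <- as.integer(sample_sizes)
    if (length(sample_sizes) != length(generations))
      stop("sampling_schedule: one sample size per generation required")
    if (any(sample_sizes < 1)) stop("sampling_schedule: sample sizes must be >= 1")
  }
  structure(list(generations = generations, sample_sizes = sample_sizes),
            class = "sampling_schedule")
}

.synthetic_map <- function(n_markers, n_chrom = 1, spacing_bp = 10000L) {
  per <- diff(round(seq(0, n_markers, length.out = n_chrom + 1)))
  chrom <- rep(paste0("chr", seq_len(n_chrom)), times = per)
  pos <- unlist(lapply(per, function(m) seq_len(m) * spacing_bp), use.names = FALSE)
  marker_map(chrom, pos, allele0 = rep("A", n_markers),
             allele1 = rep("B", n_markers))
}

#' Generate a panel of fully homozygous ancestor haplotypes
#'
#' Site allele frequencies are drawn from `maf_spectrum`; each ancestor is
#' an independent draw per site. Designated near-duplicate pairs (ancestor
#' 2k paired with 2k-1) are created by copying and flipping 10% of markers,
#' giving pairwise IBS 0.90 — the "almost identical ancestors" situation
#' that makes haplotype attribution ambiguous.
#'
#' @param n_ancestors Number of ancestors (>= 2).
#' @param n_markers Total markers.
#' @param maf_spectrum Either a single frequency applied to all sites or a
#'   function `f(n)` returning `n` site frequencies in (0,1). Default
#'   `function(n) runif(n, 0.1, 0.5)`.
#' @param near_duplicate_pairs Number of leading ancestor pairs to make
#'   near-identical (at most `n_ancestors/2`).
#' @param n_chrom Number of chromosomes the markers are split across.
#' @param seed Optional integer seed (local to this call).
#' @return A `genotype_matrix` of ancestors (calls all 0/1, no panel).
#' @export
generate_ancestor_panel <- function(n_ancestors, n_markers,
                                    maf_spectrum = function(n) stats::runif(n, 0.1, 0.5),
                                    near_duplicate_pairs = 0, n_chrom = 1,
                                    seed = NULL) {
  if (n_ancestors < 2) stop("generate_ancestor_panel: need >= 2 ancestors")
  if (near_duplicate_pairs > n_ancestors / 2)
    stop("generate_ancestor_panel: near_duplicate_pairs exceeds n_ancestors/2")
  .with_seed(seed, {
    p <- if (is.function(maf_spectrum)) maf_spectrum(n_markers)
         else rep(maf_spectrum, n_markers)
    stopifnot(all(p > 0 & p < 1))
    calls <- matrix(stats::rbinom(n_ancestors * n_markers, 1L,
                                  rep(p, each = n_ancestors)),
                    nrow = n_ancestors)
    if (near_duplicate_pairs > 0) {
      n_flip <- max(1L, floor(0.1 * n_markers))
      for (k in seq_len(near_duplicate_pairs)) {
        a <- 2L * k - 1L; b <- 2L * k
        calls[b, ] <- calls[a, ]
        flip <- sample.int(n_markers, n_flip)
        calls[b, flip] <- 1L - calls[b, flip]
      }
    }
    rownames(calls) <- paste0("ANC", seq_len(n_ancestors))
    genotype_matrix(calls, .synthetic_map(n_markers, n_chrom))
  })
}

#' Simulate recombinant-inbred mosaic cohorts with known ancestry
#'
#' Each simulated line draws two parents from the ancestor panel by
#' weighted sampling with replacement and inherits a single crossover
#' mosaic of their haplotypes: the donor switches between the two parents
#' with probability `recomb_per_interval` at each marker interval
#' (independently; chromosome starts re-draw the starting parent). After
#' `selfing_generations >= 6` rounds of selfing, residual heterozygosity is
#' negligible and lines are emitted fully homozygous; fewer rounds leave
#' heterozygous calls at rate `0.5^selfing_generations` where the parents
#' differ. No phenotypic selection acts (selection is exercised through
#' the Wright-Fisher path).
#'
#' @param ancestors Ancestor panel from [generate_ancestor_panel()].
#' @param contributions Named nonnegative weights (names = ancestor ids);
#'   expected genome fraction per ancestor is proportional to weight.
#' @param n_lines_per_cohort Named integer vector of lines per cohort
#'   (names among `pre1970s, 1970s, 1980s, 1990s, 2000s`), or a single
#'   unnamed count for one pre-1970s cohort.
#' @param recomb_per_interval Crossover probability per marker interval
#'   (default 0.001, i.e. ~0.1 cM between adjacent chip markers).
#' @param selfing_generations Rounds of selfing (default 6).
#' @param maturity_group Maturity-group label stamped on all lines.
#' @param het_rate,missing_rate Rates of randomly injected heterozygous
#'   (default 3e-4, the residual rate of real chip data) and missing calls.
#' @param seed Optional integer seed.
#' @return List: `genotypes` (a `genotype_matrix` with cohort-stamped
#'   panel) and `truth` (character matrix lines x markers of donor ids).
#' @export
simulate_breeding_cohorts <- function(ancestors, contributions,
                                      n_lines_per_cohort,
                                      recomb_per_interval = 0.001,
                                      selfing_generations = 6,
                                      maturity_group = "III",
                                      het_rate = 3e-4, missing_rate = 0,
                                      seed = NULL) {
  anc_calls <- ancestors$calls
  if (nrow(anc_calls) == 0) stop("simulate_breeding_cohorts: empty ancestor panel")
  w <- contributions[rownames(anc_calls)]
  w[is.na(w)] <- 0
  if (any(w < 0) || sum(w) <= 0)
    stop("simulate_breeding_cohorts: weights must be nonnegative, sum > 0")
  if (is.null(names(n_lines_per_cohort))) {
    stopifnot(length(n_lines_per_cohort) == 1)
    n_lines_per_cohort <- c(pre1970s = unname(n_lines_per_cohort))
  }
  stopifnot(all(names(n_lines_per_cohort) %in% decade_cohorts))
  cohort_year <- c(pre1970s = 1960L, `1970s` = 1975L, `1980s` = 1985L,
                   `1990s` = 1995L, `2000s` = 2005L)
  n_total <- sum(n_lines_per_cohort)
  M <- ncol(anc_calls)
  chrom <- ancestors$map$chrom
  new_chrom <- c(TRUE, chrom[-1] != chrom[-M])
  .with_seed(seed, {
    calls <- matrix(NA_integer_, n_total, M)
    truth <- matrix(NA_character_, n_total, M)
    het_resid <- 0.5^selfing_generations
    for (i in seq_len(n_total)) {
      par <- sample(rownames(anc_calls), 2L, replace = TRUE, prob = w)
      # donor indicator: 1 = first parent, 2 = second; switches at crossovers
      switch_pts <- stats::runif(M) < recomb_per_interval
      switch_pts[new_chrom] <- stats::runif(sum(new_chrom)) < 0.5
      donor <- 1L + (cumsum(switch_pts) %% 2L)
      hap <- ifelse(donor == 1L, anc_calls[par[1], ], anc_calls[par[2], ])
      truth[i, ] <- par[donor]
      if (het_resid > 1e-9 && par[1] != par[2]) {
        differ <- anc_calls[par[1], ] != anc_calls[par[2], ]
        het_hit <- differ & stats::runif(M) < het_resid
        hap[het_hit] <- CALL_HET
      }
      calls[i, ] <- hap
    }
    if (het_rate > 0) {
      hit <- stats::runif(length(calls)) < het_rate
      calls[hit] <- CALL_HET
    }
    if (missing_rate > 0) {
      hit <- stats::runif(length(calls)) < missing_rate
      calls[hit] <- NA_integer_
    }
    ids <- paste0("L", seq_len(n_total))
    rownames(calls) <- ids
    rownames(truth) <- ids
    colnames(truth) <- ancestors$map$marker
    panel <- assign_cohorts_and_populations(data.frame(
      line_id = ids,
      maturity_group = maturity_group,
      year_of_release = rep(cohort_year[names(n_lines_per_cohort)],
                            times = n_lines_per_cohort),
      stringsAsFactors = FALSE))
    g <- suppressWarnings(genotype_matrix(calls, ancestors$map, panel = panel))
    list(genotypes = g, truth = truth)
  })
}

# Vectorized haploid WF propagation of many loci at once.
# p: vector of current frequencies; returns matrix loci x length(record_at)
# of population frequencies at the requested generations (0-based).
# Selection: favored allele fitness 1, alternative 1-s, so
# p* = p / (1 - s + ps); to first order in s this equals the
# 1+s-vs-1 parameterization.
.wf_sim <- function(p0, N, s, generations, record_at = NULL) {
  if (s <= -1) stop("wright_fisher_trajectory: s must be > -1")
  if (s > 1) stop("wright_fisher_trajectory: s must be <= 1")
  if (N < 2) stop("wright_fisher_trajectory: N must be >= 2")
  stopifnot(all(p0 >= 0 & p0 <= 1))
  if (is.null(record_at)) record_at <- 0:generations
  p <- p0
  out <- matrix(NA_real_, length(p0), length(record_at))
  col <- match(0L, record_at)
  if (!is.na(col)) out[, col] <- p
  for (g in seq_len(generations)) {
    pstar <- p / (1 - s + p * s)
    p <- stats::rbinom(length(p), N, pstar) / N
    col <- match(g, record_at)
    if (!is.na(col)) out[, col] <- p
  }
  out
}

#' Simulate a haploid Wright-Fisher allele-frequency trajectory
#'
#' Per generation the favored-allele frequency is updated
#' deterministically by selection, `p* = p / (1 - s + ps)` (relative
#' fitness 1 for the favored allele vs `1 - s` for the alternative; to
#' first order in `s` this is the familiar 1+s-vs-1 scheme), followed by
#' binomial reproduction `p' ~ Binomial(N, p*)/N`. Frequencies absorb at
#' 0 and 1. Haploid (ploidy 1) because inbred lines carry a single
#' effective haplotype.
#'
#' @param N Haploid population size (>= 2).
#' @param s Selection coefficient (> -1; 0 = neutral drift).
#' @param p0 Initial frequency in \[0,1\].
#' @param generations Number of generations to simulate.
#' @param seed Optional integer seed.
#' @return A `wf_trajectory`: list with `p` (length `generations+1`),
#'   `N`, `s`, `p0`.
#' @export
wright_fisher_trajectory <- function(N, s, p0, generations, seed = NULL) {
  p <- .with_seed(seed, .wf_sim(p0, N, s, generations))
  structure(list(p = as.vector(p), N = N, s = s, p0 = p0),
            class = "wf_trajectory")
}

#' Observe a trajectory through a temporal sampling schedule
#'
#' At each scheduled timepoint the observed favored-allele count is
#' binomial in the per-timepoint sample size; with census sampling
#' (`sample_sizes = NULL`) the observed frequency equals the population
#' frequency.
#'
#' @param traj A `wf_trajectory`.
#' @param schedule A [sampling_schedule()] whose generations fall within
#'   the trajectory.
#' @param seed Optional integer seed.
#' @param locus Locus id stamped on the output.
#' @return A [temporal_frequency_series()].
#' @export
sample_observed_counts <- function(traj, schedule, seed = NULL,
                                   locus = "locus1") {
  gens <- schedule$generations
  if (max(gens) + 1L > length(traj$p))
    stop("sample_observed_counts: schedule extends beyond the trajectory")
  p_true <- traj$p[gens + 1L]
  if (is.null(schedule$sample_sizes)) {
    temporal_frequency_series(locus, gens, p_true, sample_sizes = NULL)
  } else {
    n <- schedule$sample_sizes
    k <- .with_seed(seed, stats::rbinom(length(gens), n, p_true))
    temporal_frequency_series(locus, gens, k / n, sample_sizes = n)
  }
}

#' Simulate many independent Wright-Fisher loci observed on a schedule
#'
#' Vectorized companion to [wright_fisher_trajectory()] /
#' [sample_observed_counts()]: simulates `n_loci` independent haploid
#' Wright-Fisher loci and observes them at the scheduled generations,
#' through binomial sampling when the schedule carries sample sizes.
#'
#' @param n_loci Number of loci.
#' @param N Haploid population size.
#' @param s Selection coefficient (0 = neutral).
#' @param p0 Initial frequency: a scalar, a vector of length `n_loci`,
#'   or a function `f(n)` drawing `n` initial frequencies (the locus
#'   spectrum).
#' @param schedule A [sampling_schedule()].
#' @param polarize_major Fold each locus to its major allele at the
#'   first observed timepoint (the polarity used for cohort scans).
#' @param seed Optional integer seed.
#' @return A `frequency_series_set`.
#' @export
simulate_wf_loci <- function(n_loci, N, s, p0, schedule = sampling_schedule(),
                             polarize_major = FALSE, seed = NULL) {
  .with_seed(seed, {
    p0v <- if (is.function(p0)) p0(n_loci) else rep_len(p0, n_loci)
    P <- .wf_sim(p0v, N, s, max(schedule$generations),
                 record_at = schedule$generations)
    n <- schedule$sample_sizes
    if (!is.null(n))
      for (t in seq_along(n))
        P[, t] <- stats::rbinom(n_loci, n[t], P[, t]) / n[t]
    if (polarize_major) {
      flip <- P[, 1] < 0.5
      P[flip, ] <- 1 - P[flip, , drop = FALSE]
    }
    structure(list(loci = paste0("locus", seq_len(n_loci)),
                   generations = schedule$generations,
                   freqs = P,
                   sample_sizes = if (is.null(n)) NULL else
                     matrix(n, n_loci, length(n), byrow = TRUE),
                   initial_freq = P[, 1]),
              class = "frequency_series_set")
  })
}

#' Filter a frequency series set on its initial frequency
#'
#' @param set A `frequency_series_set`.
#' @param freq_range Closed lower / (optionally open) upper bounds on the
#'   first-timepoint frequency.
#' @param upper_strict If `TRUE` the upper bound is exclusive.
#' @return The set restricted to passing loci.
#' @export
filter_series_set <- function(set, freq_range, upper_strict = FALSE) {
  init <- set$freqs[, 1]
  ok <- init >= freq_range[1] &
    (if (upper_strict) init < freq_range[2] else init <= freq_range[2])
  structure(list(loci = set$loci[ok], generations = set$generations,
                 freqs = set$freqs[ok, , drop = FALSE],
                 sample_sizes = if (is.null(set$sample_sizes)) NULL else
                   set$sample_sizes[ok, , drop = FALSE],
                 initial_freq = init[ok],
                 population = set$population),
            class = "frequency_series_set")
}
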