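# Time-serial selection statistics on per-locus allele-frequency series:
# delta-f (OLS slope with fixation truncation), logistic regression beta,
# temporal Fst, exact-likelihood effective population size, and simulated
# neutral thresholds.

#' Default cohort-to-generation mapping
#'
#' Pooled pre-1970s base cohort at generation 0, then 15 effective
#' generations to the 1970s cohort and 10 per later decade:
#' `c(0, 15, 25, 35, 45)`.
#' @export
default_generation_map <- c(pre1970s = 0, `1970s` = 15, `1980s` = 25,
                            `1990s` = 35, `2000s` = 45)

#' Single-locus temporal frequency series
#'
#' @param locus Locus identifier.
#' @param generations Integer generations of the timepoints.
#' @param freqs Observed frequencies of the tracked allele (polarity:
#'   major allele in the first timepoint) in \[0,1\].
#' @param sample_sizes Lines genotyped per timepoint, or `NULL` for
#'   census observation.
#' @return A `temporal_frequency_series` list.
#' @export
temporal_frequency_series <- function(locus, generations, freqs,
                                      sample_sizes = NULL) {
  stopifnot(length(generations) == length(freqs),
            all(freqs >= 0 & freqs <= 1))
  if (!is.null(sample_sizes))
    stopifnot(length(sample_sizes) == length(freqs))
  structure(list(locus = locus, generations = as.numeric(generations),
                 freqs = as.numeric(freqs), sample_sizes = sample_sizes),
            class = "temporal_frequency_series")
}

#' Build per-locus temporal frequency series for one population
#'
#' For each marker, allele frequencies are computed per cohort (each
#' inbred line contributes one allele; a heterozygous call contributes
#' half; missing calls are excluded from the denominator), the major
#' allele of the first cohort sets the polarity, and loci are filtered on
#' that initial major-allele frequency.
#'
#' @param g A `genotype_matrix` with cohort/population assignments.
#' @param population Population label to analyse.
#' @param freq_range Initial major-allele frequency filter, e.g.
#'   `c(0.5, 0.6)` for effective-population-size estimation or
#'   `c(0.5, 0.95)` for selection scans.
#' @param upper_strict If `TRUE` the upper filter bound is exclusive
#'   (the scan convention "initial frequency < 0.95").
#' @param generation_map Named cohort-to-generation mapping.
#' @return A `frequency_series_set`: list with `loci`, `generations`,
#'   `freqs` (loci x timepoints), `sample_sizes` (per-locus non-missing
#'   allele counts), and `initial_freq`.
#' @export
build_frequency_series <- function(g, population,
                                   freq_range = c(0.5, 0.6),
                                   upper_strict = FALSE,
                                   generation_map = default_generation_map) {
  if (is.null(g$panel) || !all(c("cohort", "population") %in% names(g$panel)))
    stop("build_frequency_series: panel with cohort/population required")
  keep <- g$panel$population == population
  if (!any(keep)) stop("build_frequency_series: empty population ", population)
  calls <- g$calls[keep, , drop = FALSE]
  cohorts <- as.character(g$panel$cohort[keep])
  cohort_levels <- names(generation_map)
  counts1 <- matrix(0, length(cohort_levels), ncol(calls))
  totals <- matrix(0, length(cohort_levels), ncol(calls))
  for (ci in seq_along(cohort_levels)) {
    rows <- cohorts == cohort_levels[ci]
    if (!any(rows))
      stop("build_frequency_series: empty cohort ", cohort_levels[ci],
           " in population ", population)
    sub <- calls[rows, , drop = FALSE]
    counts1[ci, ] <- colSums(sub == CALL_A1, na.rm = TRUE) +
      0.5 * colSums(sub == CALL_HET, na.rm = TRUE)
    totals[ci, ] <- colSums(!is.na(sub))
  }
  f1 <- counts1 / totals  # frequency of allele1 per cohort x marker
  major_is_1 <- f1[1, ] >= 0.5
  f1[, !major_is_1] <- 1 - f1[, !major_is_1, drop = FALSE]
  fmaj <- t(f1)
  init <- fmaj[, 1]
  ok <- init >= freq_range[1] &
    (if (upper_strict) init < freq_range[2] else init <= freq_range[2])
  ok <- ok & !is.na(init)
  structure(list(loci = colnames(calls)[ok],
                 generations = unname(generation_map),
                 freqs = fmaj[ok, , drop = FALSE],
                 sample_sizes = t(totals)[ok, , drop = FALSE],
                 initial_freq = init[ok],
                 population = population),
            class = "frequency_series_set")
}

#' @export
print.frequency_series_set <- function(x, ...) {
  cat(sprintf("frequency_series_set: %d loci x %d timepoints (generations %s)\n",
              nrow(x$freqs), length(x$generations),
              paste(x$generations, collapse = ",")))
  invisible(x)
}

# Truncation at fixation: per row of Y, the index of the first timepoint
# with frequency < lo or > hi (that timepoint is kept, later ones dropped);
# ncol(Y) when never fixed.
.trunc_len <- function(Y, lo = 0.05, hi = 0.95) {
  fixed <- Y < lo | Y > hi
  len <- rep(ncol(Y), nrow(Y))
  for (t in rev(seq_len(ncol(Y)))) len[fixed[, t]] <- t
  len
}

# Vectorized delta-f: OLS slope of frequency on generation over the
# truncated series. Rows with < 2 usable timepoints get slope 0.
.delta_f_mat <- function(Y, gens, lo = 0.05, hi = 0.95) {
  len <- .trunc_len(Y, lo, hi)
  out <- numeric(nrow(Y))
  for (k in unique(len)) {
    rows <- len == k
    if (k < 2) { out[rows] <- 0; next }
    t_k <- gens[1:k]
    ct <- t_k - mean(t_k)
    out[rows] <- (Y[rows, 1:k, drop = FALSE] %*% ct) / sum(ct^2)
  }
  attr(out, "n_used") <- len
  out
}

#' Per-generation allele-frequency change (delta-f)
#'
#' The least-squares slope of frequency on generation, using timepoints up
#' to and including the first at which the allele reaches fixation
#' (frequency < 0.05 or > 0.95). Series with fewer than two usable
#' timepoints return 0, flagged via the `n_used` attribute.
#'
#' @param series A [temporal_frequency_series()] or a
#'   `frequency_series_set`.
#' @param fixation_bounds Lower/upper fixation boundaries.
#' @return Slope(s) with attribute `n_used` (timepoints retained).
#' @export
delta_f <- function(series, fixation_bounds = c(0.05, 0.95)) {
  Y <- if (inherits(series, "frequency_series_set")) series$freqs
       else matrix(series$freqs, nrow = 1)
  gens <- series$generations
  out <- .delta_f_mat(Y, gens, fixation_bounds[1], fixation_bounds[2])
  if (!inherits(series, "frequency_series_set")) {
    n_used <- attr(out, "n_used")
    out <- out[1]; attr(out, "n_used") <- n_used[1]
  } else names(out) <- series$loci
  out
}

# Vectorized logistic (binomial-family) regression of frequency on
# generation: logit(mu) = a + b*t, IRLS with optional binomial weights
# n (vector per timepoint or matrix loci x timepoints). Returns b per row;
# rows whose frequencies are all exactly 0 or all exactly 1 are complete
# separations and get -Inf/+Inf.
.logistic_beta_mat <- function(Y, gens, n = NULL, max_iter = 60, tol = 1e-10) {
  nl <- nrow(Y); nt <- ncol(Y)
  sep_hi <- rowSums(Y == 1) == nt
  sep_lo <- rowSums(Y == 0) == nt
  W0 <- if (is.null(n)) matrix(1, nl, nt)
        else if (is.matrix(n)) n else matrix(n, nl, nt, byrow = TRUE)
  eps <- 1e-9
  mu0 <- pmin(pmax(rowMeans(Y), eps), 1 - eps)
  a <- log(mu0 / (1 - mu0))
  b <- numeric(nl)
  tv <- matrix(gens, nl, nt, byrow = TRUE)
  for (it in seq_len(max_iter)) {
    eta <- a + b * tv
    mu <- stats::plogis(eta)
    mu <- pmin(pmax(mu, eps), 1 - eps)
    v <- mu * (1 - mu)
    w <- W0 * v
    z <- eta + (Y - mu) / v
    Sw <- rowSums(w); Swt <- rowSums(w * tv); Swtt <- rowSums(w * tv * tv)
    Swz <- rowSums(w * z); Swtz <- rowSums(w * tv * z)
    det <- Sw * Swtt - Swt^2
    b_new <- (Sw * Swtz - Swt * Swz) / det
    a_new <- (Swz - b_new * Swt) / Sw
    delta <- max(abs(b_new - b), na.rm = TRUE)
    a <- a_new; b <- b_new
    if (delta < tol) break
  }
  b[sep_hi] <- Inf
  b[sep_lo] <- -Inf
  attr(b, "separation") <- sep_hi | sep_lo
  b
}

#' Logistic-regression slope of a temporal frequency series
#'
#' Slope of a binomial-family generalized linear fit of frequency on
#' generation. With `weights = "binomial"` (the default when sample sizes
#' are available) timepoint frequencies are weighted by their allele
#' counts; `weights = "none"` fits unweighted proportions (the
#' convention used for the power analysis). All timepoints are used — no
#' fixation truncation. Complete separation (all observed frequencies
#' exactly 0 or exactly 1) yields a signed infinite sentinel, flagged via
#' the `separation` attribute.
#'
#' @param series A [temporal_frequency_series()] or `frequency_series_set`.
#' @param weights `"auto"` (binomial when sample sizes exist), `"binomial"`
#'   or `"none"`.
#' @return Slope(s), attributes `separation` (logical) and `mode`.
#' @export
logistic_beta <- function(series, weights = c("auto", "binomial", "none")) {
  weights <- match.arg(weights)
  set <- inherits(series, "frequency_series_set")
  Y <- if (set) series$freqs else matrix(series$freqs, nrow = 1)
  n <- series$sample_sizes
  use_n <- switch(weights, auto = !is.null(n), binomial = TRUE, none = FALSE)
  if (use_n && is.null(n))
    stop("logistic_beta: weights='binomial' requires sample sizes")
  b <- .logistic_beta_mat(Y, series$generations, n = if (use_n) n else NULL)
  sepa <- attr(b, "separation")
  if (!set) { sepa <- sepa[1]; b <- b[1] } else names(b) <- series$loci
  attr(b, "separation") <- sepa
  attr(b, "mode") <- if (use_n) "binomial" else "unweighted"
  b
}

# Vectorized temporal Fst between the first and last post-truncation
# timepoints: with J_t = p^2 + (1-p)^2 the within-timepoint identity,
# J_w = mean of first/last, and J_b the identity at the pooled mean
# frequency, fst = (J_w - J_b) / (1 - J_b); 0 (flagged) when both ends
# are fixed for the same allele (J_b = 1).
.temporal_fst_mat <- function(Y, gens, lo = 0.05, hi = 0.95) {
  len <- .trunc_len(Y, lo, hi)
  p1 <- Y[, 1]
  p2 <- Y[cbind(seq_len(nrow(Y)), len)]
  J1 <- p1^2 + (1 - p1)^2
  J2 <- p2^2 + (1 - p2)^2
  Jw <- (J1 + J2) / 2
  pb <- (p1 + p2) / 2
  Jb <- pb^2 + (1 - pb)^2
  fst <- (Jw - Jb) / (1 - Jb)
  degenerate <- abs(1 - Jb) < 1e-12
  fst[degenerate] <- 0
  attr(fst, "degenerate") <- degenerate
  fst
}

#' Temporal fixation index between first and last timepoints
#'
#' Probability that two alleles sampled within a single timepoint are
#' identical, relative to that probability for alleles sampled from the
#' combined first and last timepoints. Fixation truncation is applied as
#' for [delta_f()]: the "last" timepoint is the first that reached
#' fixation, when one did.
#'
#' @inheritParams delta_f
#' @return Fst value(s); attribute `degenerate` flags series with both
#'   ends fixed for the same allele (Fst 0 by convention).
#' @export
temporal_fst <- function(series, fixation_bounds = c(0.05, 0.95)) {
  set <- inherits(series, "frequency_series_set")
  Y <- if (set) series$freqs else matrix(series$freqs, nrow = 1)
  out <- .temporal_fst_mat(Y, series$generations,
                           fixation_bounds[1], fixation_bounds[2])
  deg <- attr(out, "degenerate")
  if (!set) { out <- out[1]; attr(out, "degenerate") <- deg[1] }
  else { names(out) <- series$loci; attr(out, "degenerate") <- deg }
  out
}

# ---- effective population size ----------------------------------------

# One-generation haploid WF transition matrix on states 0..N (neutral).
.wf_transition <- function(N) {
  states <- 0:N
  outer(states, states, function(i, j) stats::dbinom(j, N, i / N))
}

# Matrix powers of the one-generation transition for the gap lengths.
.wf_gap_matrices <- function(N, gaps) {
  T1 <- .wf_transition(N)
  cache <- list(`1` = T1)
  pow <- function(k) {
    key <- as.character(k)
    if (!is.null(cache[[key]])) return(cache[[key]])
    m <- if (k %% 2 == 0) { h <- pow(k %/% 2); h %*% h }
         else pow(k - 1) %*% T1
    cache[[key]] <<- m
    m
  }
  lapply(gaps, pow)
}

# Log-likelihood of observed data at haploid size N.
# K: loci x T observed allele counts; n: T sample sizes (NULL = census,
# in which case K holds observed frequencies, interpolated onto the
# candidate chain's state grid). prior0: optional density over
# frequencies (a function of p in [0,1]) for the initial state.
.ne_loglik <- function(N, K, n, gaps, prior_fun = NULL) {
  prior0 <- if (is.null(prior_fun)) NULL else {
    v <- prior_fun((0:N) / N)
    v / sum(v)
  }
  mats <- .wf_gap_matrices(N, gaps)
  states <- 0:N
  tiny <- 1e-300
  if (is.null(n)) {
    # census: an observed frequency pins the chain state to the grid's
    # resolution. Off-grid frequencies are split linearly over the two
    # flanking states (avoids rounding aliasing across candidate N), and
    # the 1/N bin width makes state probabilities comparable across N as
    # densities (hence the + log(N) per observation).
    x <- K * N
    lo <- pmin(pmax(floor(x), 0), N)
    fr <- x - lo
    lo <- lo + 1L; hi <- pmin(lo + 1L, N + 1L)
    w_hi <- fr; w_lo <- 1 - fr
    ll <- 0
    nr <- seq_len(nrow(K))
    for (t in seq_along(gaps)) {
      M <- mats[[t]]
      i_lo <- lo[, t]; i_hi <- hi[, t]; j_lo <- lo[, t + 1L]; j_hi <- hi[, t + 1L]
      pr <- w_lo[, t] * (w_lo[, t + 1L] * M[cbind(i_lo, j_lo)] +
                           w_hi[, t + 1L] * M[cbind(i_lo, j_hi)]) +
            w_hi[, t] * (w_lo[, t + 1L] * M[cbind(i_hi, j_lo)] +
                           w_hi[, t + 1L] * M[cbind(i_hi, j_hi)])
      ll <- ll + sum(log(pmax(pr, tiny)))
    }
    return(ll + nrow(K) * length(gaps) * log(N))
  }
  emission <- function(t) {
    ks <- 0:n[t]
    tab <- vapply(states / N, function(p) stats::dbinom(ks, n[t], p),
                  numeric(length(ks)))      # (n+1) x (N+1)
    tab[K[, t] + 1L, , drop = FALSE]        # loci x (N+1)
  }
  # Initial state: posterior given the first sample under the prior
  # (default diffuse/uniform over states, appropriate for the broad
  # folded frequency spectra of common-variant chip markers; callers
  # with an informative unfiltered spectrum can supply it).
  L0 <- emission(1)
  alpha <- if (is.null(prior0)) L0 else L0 * rep(prior0, each = nrow(L0))
  sc <- rowSums(alpha)
  ll <- 0  # conditioning on the first sample: its marginal is normalized out
  alpha <- alpha / pmax(sc, tiny)
  for (t in seq_along(gaps)) {
    alpha <- (alpha %*% mats[[t]]) * emission(t + 1L)
    sc <- rowSums(alpha)
    ll <- ll + sum(log(pmax(sc, tiny)))
    alpha <- alpha / pmax(sc, tiny)
  }
  ll
}

# Integer grid the likelihood is evaluated on: step 1 up to 400, then 5.
.ne_grid_round <- function(N) {
  N <- round(N)
  if (N > 400) N <- round(N / 5) * 5
  as.integer(N)
}

#' Maximum-likelihood effective population size from temporal samples
#'
#' Likelihood per locus is the probability of the observed allele-count
#' path under an exact neutral haploid Wright-Fisher Markov chain on
#' states 0..N, with binomial sampling at each timepoint (or exact state
#' observation under census sampling); loci are independent; the initial
#' state distribution is the posterior given the first sample under a
#' uniform state prior, so the likelihood is conditional on the first
#' sample. The maximum is located on an integer grid (step 1 up to
#' N = 400, step 5 above) and the 95% CI from the likelihood-ratio
#' statistic (chi-square, 1 df).
#'
#' @param series_set A `frequency_series_set` from
#'   [build_frequency_series()], or a list of
#'   [temporal_frequency_series()] sharing one schedule. Sampling sizes
#'   must be constant across loci within a timepoint (the cohort design);
#'   `NULL` sizes mean census observation.
#' @param bounds Search interval for N (default `c(20, 1000)`).
#' @param initial_prior Optional prior density over the initial allele
#'   frequency, as a function of p in \[0,1\] (evaluated on the state
#'   grid and normalized). Default `NULL`: uniform over states, the
#'   appropriate diffuse choice for the broad folded spectra of
#'   common-variant chip markers. Supplying the population's unfiltered
#'   spectrum matters when the loci entering the estimate were drawn
#'   from a strongly informative initial-frequency distribution.
#' @return An `ne_estimate`: list with `ne`, `ci95`, `n_loci`, `bounds`,
#'   `loglik`, and `at_bound` flag.
#' @export
estimate_ne <- function(series_set, bounds = c(20, 1000),
                        initial_prior = NULL) {
  if (is.list(series_set) && !inherits(series_set, "frequency_series_set") &&
      all(vapply(series_set, inherits, TRUE, "temporal_frequency_series"))) {
    gens <- series_set[[1]]$generations
    Y <- do.call(rbind, lapply(series_set, `[[`, "freqs"))
    ns <- series_set[[1]]$sample_sizes
    series_set <- list(freqs = Y, generations = gens, sample_sizes = ns,
                       loci = vapply(series_set, `[[`, "", "locus"))
  }
  Y <- series_set$freqs
  if (is.null(Y) || nrow(Y) == 0) stop("estimate_ne: no loci pass the filter")
  if (nrow(Y) < 50)
    warning("estimate_ne: fewer than 50 loci; the estimate will be unstable")
  gens <- series_set$generations
  gaps <- diff(gens)
  ns <- series_set$sample_sizes
  if (is.matrix(ns)) {
    n <- round(apply(ns, 2, stats::median))
    K <- round(Y * matrix(n, nrow(Y), length(n), byrow = TRUE))
  } else if (!is.null(ns)) {
    n <- as.integer(ns)
    K <- round(Y * matrix(n, nrow(Y), length(n), byrow = TRUE))
  } else {
    n <- NULL
    K <- Y
  }
  cache <- new.env(parent = emptyenv())
  ll <- function(N) {
    N <- .ne_grid_round(max(bounds[1], min(bounds[2], N)))
    key <- as.character(N)
    if (is.null(cache[[key]]))
      cache[[key]] <- .ne_loglik(N, K, n, gaps, prior_fun = initial_prior)
    cache[[key]]
  }
  # moment-based start: standardized variance of first-vs-last change
  p1 <- Y[, 1]; p2 <- Y[, ncol(Y)]
  pb <- (p1 + p2) / 2
  usable <- pb > 0 & pb < 1
  Fc <- mean((p1 - p2)[usable]^2 / (pb * (1 - pb))[usable])
  samp_corr <- if (is.null(n)) 0 else 1 / n[1] + 1 / length(n)^0 / n[length(n)]
  drift <- max(Fc - samp_corr, 1e-4)
  N0 <- min(max((gens[length(gens)] - gens[1]) / drift, bounds[1]), bounds[2])
  # golden-section search on the integer grid around the moment start,
  # expanding the bracket if the optimum lands on an edge
  lo <- max(bounds[1], N0 / 3); hi <- min(bounds[2], N0 * 3)
  repeat {
    opt <- .golden_int(ll, lo, hi, round_fun = .ne_grid_round)
    # expand (never shrink) the bracket while the optimum sits on an edge
    if (opt$x <= .ne_grid_round(lo) + 1 && lo > bounds[1]) {
      lo <- max(bounds[1], lo / 3)
    } else if (opt$x >= .ne_grid_round(hi) - 5 && hi < bounds[2]) {
      hi <- min(bounds[2], hi * 3)
    } else break
  }
  mle <- opt$x; llmax <- opt$fx
  crit <- stats::qchisq(0.95, df = 1) / 2
  bound_search <- function(side) {
    f <- function(N) llmax - ll(N) - crit
    lo_b <- if (side < 0) bounds[1] else mle
    hi_b <- if (side < 0) mle else bounds[2]
    if (f(if (side < 0) lo_b else hi_b) < 0)
      return(if (side < 0) bounds[1] else bounds[2])
    a <- lo_b; b <- hi_b
    while (b - a > 1.5) {
      m <- .ne_grid_round((a + b) / 2)
      if (m <= a) m <- a + 1
      if (m >= b) m <- b - 1
      inside <- f(m) < 0  # within the confidence region
      if (side < 0) { if (inside) b <- m else a <- m }
      else           { if (inside) a <- m else b <- m }
    }
    .ne_grid_round(if (side < 0) b else a)
  }
  ci <- c(bound_search(-1), bound_search(1))
  structure(list(ne = mle, ci95 = ci, n_loci = nrow(Y), bounds = bounds,
                 loglik = llmax,
                 at_bound = mle <= bounds[1] || mle >= bounds[2]),
            class = "ne_estimate")
}

#' @export
print.ne_estimate <- function(x, ...) {
  cat(sprintf("Ne (haploid) = %d  [95%% CI %d-%d]  from %d loci%s\n",
              x$ne, x$ci95[1], x$ci95[2], x$n_loci,
              if (x$at_bound) "  (at search bound!)" else ""))
  invisible(x)
}

# Golden-section maximization over an integer grid. Terminates when the
# bracket collapses to the grid resolution (the grid step is 5 above 400,
# so plain width-based stopping would stall there).
.golden_int <- function(f, lo, hi, round_fun = function(x) as.integer(round(x))) {
  phi <- (sqrt(5) - 1) / 2
  a <- lo; b <- hi
  x1 <- round_fun(b - phi * (b - a)); x2 <- round_fun(a + phi * (b - a))
  if (x1 >= x2) { x1 <- round_fun(a); x2 <- round_fun(b) }
  f1 <- f(x1); f2 <- f(x2)
  for (it in 1:60) {
    if (b - a <= 2 || x1 <= a || x2 >= b || x1 >= x2) break
    if (f1 < f2) {
      a <- x1; x1 <- x2; f1 <- f2
      x2 <- round_fun(a + phi * (b - a))
      if (x2 <= x1 || x2 >= b) break
      f2 <- f(x2)
    } else {
      b <- x2; x2 <- x1; f2 <- f1
      x1 <- round_fun(b - phi * (b - a))
      if (x1 >= x2 || x1 <= a) break
      f1 <- f(x1)
    }
  }
  cand <- unique(vapply(seq(floor(a), ceiling(b)), round_fun, 1L))
  cand <- cand[cand >= a - 0.5 & cand <= b + 0.5]
  fv <- vapply(cand, f, 1)
  list(x = cand[which.max(fv)], fx = max(fv))
}

#' Simulated neutral delta-f thresholds
#'
#' Simulates neutral Wright-Fisher loci at the estimated effective size,
#' with initial frequencies resampled from an empirical spectrum and
#' observed through the study's sampling schedule, and returns the
#' (1 - tail) quantile of |delta-f| — the population-specific scan
#' threshold.
#'
#' @param ne An `ne_estimate` or a plain number (haploid N).
#' @param initial_freqs Empirical initial-frequency spectrum to resample
#'   (e.g. the observed first-cohort major-allele frequencies).
#' @param schedule A [sampling_schedule()].
#' @param tail Tail probability (default 0.05).
#' @param n_sim Number of neutral loci to simulate (default 1e4).
#' @param seed Optional integer seed.
#' @return A `neutral_thresholds` list: `threshold`, `delta_f_sample`,
#'   `ne`, `tail`, `n_sim`, `seed`.
#' @export
neutral_thresholds <- function(ne, initial_freqs, schedule = sampling_schedule(),
                               tail = 0.05, n_sim = 10000, seed = NULL) {
  N <- if (inherits(ne, "ne_estimate")) ne$ne else as.integer(round(ne))
  stopifnot(length(initial_freqs) > 0, tail > 0, tail < 1)
  .with_seed(seed, {
    p0 <- sample(initial_freqs, n_sim, replace = TRUE)
    P <- .wf_sim(p0, N, 0, max(schedule$generations),
                 record_at = schedule$generations)
    if (!is.null(schedule$sample_sizes)) {
      n <- schedule$sample_sizes
      for (t in seq_along(n))
        P[, t] <- stats::rbinom(n_sim, n[t], P[, t]) / n[t]
    }
    df <- abs(.delta_f_mat(P, schedule$generations))
    structure(list(threshold = unname(stats::quantile(df, 1 - tail)),
                   delta_f_sample = df, ne = N, tail = tail,
                   n_sim = n_sim, seed = seed),
              class = "neutral_thresholds")
  })
}

#' @export
print.neutral_thresholds <- function(x, ...) {
  cat(sprintf("neutral |delta-f| threshold %.4g (tail %.3g, Ne %d, %d sims)\n",
              x$threshold, x$tail, x$ne, x$n_sim))
  invisible(x)
}
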