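mk_series <- function(freqs, gens = c(0, 15, 25, 35, 45), n = NULL)
  temporal_frequency_series("locus", gens, freqs, sample_sizes = n)

test_that("frequency series are built with haploid counting and filters", {
  # 10 lines: 6 major homozygote, 4 minor -> 0.6; plus HET half-counting
  calls <- matrix(c(rep(1L, 6), rep(0L, 4)), ncol = 1)
  calls <- calls[, rep(1, 60)]
  per_cohort <- rep(2, 5)
  panel <- make_panel(paste0("L", 1:10), mg = "III",
                      year = rep(c(1960, 1975, 1985, 1995, 2005), each = 2))
  calls <- matrix(rep(c(rep(1L, 6), rep(0L, 4)), 60), nrow = 10)
  # interleave cohorts over lines: reorder so each cohort has 2 lines
  g <- make_geno(calls, panel = panel)
  set <- build_frequency_series(g, "MGIII-IV", freq_range = c(0, 1))
  expect_equal(unname(set$generations), c(0, 15, 25, 35, 45))
  # first cohort = lines L1, L2 (both allele1) -> initial major freq 1
  expect_true(all(set$initial_freq == 1))
  # HET counts half, missing drops from the denominator
  calls2 <- matrix(c(1L, 1L, 2L, 0L, NA, 1L, 1L, 1L, 1L, 1L), ncol = 1)
  g2 <- make_geno(calls2[, c(1, 1)], panel = make_panel(
    paste0("L", 1:10), "III", rep(c(1960, 1975, 1985, 1995, 2005), 2)))
  set2 <- build_frequency_series(g2, "MGIII-IV", freq_range = c(0, 1))
  # first cohort lines: L1 (1) and L6 (1) -> freq 1
  expect_equal(set2$freqs[1, 1], 1)
  expect_error(build_frequency_series(g2, "MGV+", freq_range = c(0, 1)),
               "empty population")
})

test_that("initial-frequency filters follow the closed/open bound conventions", {
  sch <- sampling_schedule()
  P <- matrix(c(0.55, 0.7, 0.95, 0.5, 0.6, 0.6, 0.6, 0.6, 0.6, 0.6,
                0.6, 0.6, 0.6, 0.6, 0.6), nrow = 3)
  set <- structure(list(loci = c("a", "b", "c"), generations = sch$generations,
                        freqs = P, sample_sizes = NULL, initial_freq = P[, 1]),
                   class = "frequency_series_set")
  expect_equal(filter_series_set(set, c(0.5, 0.6))$loci, "a")
  expect_equal(filter_series_set(set, c(0.5, 0.95), upper_strict = TRUE)$loci,
               c("a", "b"))
  expect_equal(filter_series_set(set, c(0.5, 0.95))$loci, c("a", "b", "c"))
})

test_that("delta-f matches the OLS oracle and truncates at fixation", {
  expect_equal(as.numeric(delta_f(mk_series(rep(0.5, 5)))), 0)
  s <- mk_series(c(0.5, 0.65, 0.75), gens = c(0, 15, 25))
  # frozen from lm(freqs ~ gens)
  expect_equal(as.numeric(delta_f(s)), 0.01, tolerance = 1e-12)
  s2 <- mk_series(c(0.5, 0.98, 0.99, 1.0), gens = c(0, 15, 25, 35))
  d2 <- delta_f(s2)
  expect_equal(as.numeric(d2), (0.98 - 0.5) / 15)
  expect_equal(attr(d2, "n_used"), 2L)
  # first timepoint already fixed -> flagged zero
  d3 <- delta_f(mk_series(c(0.99, 0.5, 0.5, 0.5, 0.5)))
  expect_equal(as.numeric(d3), 0)
  expect_equal(attr(d3, "n_used"), 1L)
})

test_that("logistic slope recovers a generating curve and flags separation", {
  expect_equal(as.numeric(logistic_beta(mk_series(rep(0.5, 5)))), 0,
               tolerance = 1e-8)
  t <- c(0, 15, 25, 35, 45)
  p <- stats::plogis(-1 + 0.1 * t)
  expect_equal(as.numeric(logistic_beta(mk_series(p, t), weights = "none")),
               0.1, tolerance = 1e-3)
  b <- logistic_beta(mk_series(rep(1, 5)))
  expect_true(is.infinite(b) && b > 0)
  expect_true(attr(b, "separation"))
  # binomial weighting uses the sample sizes
  bw <- logistic_beta(mk_series(p, t, n = c(31, 28, 59, 59, 22)))
  expect_equal(attr(bw, "mode"), "binomial")
  expect_equal(as.numeric(bw), 0.1, tolerance = 1e-3)
})

test_that("temporal Fst follows the homozygosity-contrast formula", {
  expect_equal(as.numeric(temporal_fst(mk_series(c(0.5, 0.5), gens = c(0, 45)))), 0)
  expect_equal(as.numeric(temporal_fst(mk_series(c(0.5, 1.0), gens = c(0, 45)))),
               1 / 3, tolerance = 1e-12)
  expect_equal(as.numeric(temporal_fst(mk_series(c(0.5, 0.0), gens = c(0, 45)))),
               1 / 3, tolerance = 1e-12)
  f <- temporal_fst(mk_series(c(1, 1, 1, 1, 1)))
  expect_equal(as.numeric(f), 0)
  expect_true(attr(f, "degenerate"))
  # near-fixed ends agree -> zero differentiation, but not degenerate
  f2 <- temporal_fst(mk_series(c(0.99, 1, 1, 1, 1)))
  expect_equal(as.numeric(f2), 0)
  expect_false(attr(f2, "degenerate"))
})

test_that("delta-f and beta flip sign under polarity; Fst is invariant", {
  set.seed(5)
  sch <- sampling_schedule()
  set <- simulate_wf_loci(40, 100, 0, function(n) runif(n, 0.3, 0.7), sch,
                          seed = 6)
  flipped <- set
  flipped$freqs <- 1 - set$freqs
  expect_equal(as.numeric(delta_f(flipped)), -as.numeric(delta_f(set)))
  expect_equal(as.numeric(logistic_beta(flipped, weights = "none")),
               -as.numeric(logistic_beta(set, weights = "none")),
               tolerance = 1e-6)
  expect_equal(as.numeric(temporal_fst(flipped)), as.numeric(temporal_fst(set)))
})

test_that("Ne likelihood recovers simulated size and flags degenerate input", {
  sch <- sampling_schedule()
  set <- simulate_wf_loci(1500, 100, 0, function(n) runif(n), sch,
                          polarize_major = TRUE, seed = 7)
  set <- filter_series_set(set, c(0.5, 0.6))
  ne <- suppressWarnings(estimate_ne(set, bounds = c(20, 1000)))
  expect_gt(ne$ne, 80)
  expect_lt(ne$ne, 120)
  expect_true(ne$ci95[1] <= ne$ne && ne$ne <= ne$ci95[2])
  # zero frequency change -> no drift signal -> MLE at the upper bound
  flat <- structure(list(loci = 1:60, generations = sch$generations,
                         freqs = matrix(0.55, 60, 5), sample_sizes = NULL,
                         initial_freq = rep(0.55, 60)),
                    class = "frequency_series_set")
  ne_flat <- suppressWarnings(estimate_ne(flat, bounds = c(20, 400)))
  expect_equal(ne_flat$ne, 400)
  expect_true(ne_flat$at_bound)
  expect_error(estimate_ne(structure(list(freqs = matrix(0, 0, 5)),
                                     class = "frequency_series_set")),
               "no loci")
})

test_that("halving the generation labels roughly halves the Ne estimate", {
  sch <- sampling_schedule(c(0, 16, 26, 36, 46))
  set <- simulate_wf_loci(1200, 200, 0, function(n) runif(n), sch,
                          polarize_major = TRUE, seed = 8)
  set <- filter_series_set(set, c(0.5, 0.6))
  ne_full <- suppressWarnings(estimate_ne(set))
  half <- set
  half$generations <- c(0, 8, 13, 18, 23)
  ne_half <- suppressWarnings(estimate_ne(half))
  expect_lt(abs(ne_half$ne / ne_full$ne - 0.5), 0.12)
})

test_that("the likelihood peaks at the true N against 2N and N/2", {
  sch <- sampling_schedule(sample_sizes = c(31, 28, 59, 59, 22))
  wins <- 0L
  for (r in 1:10) {
    set <- simulate_wf_loci(100, 100, 0, function(n) runif(n, 0.2, 0.8), sch,
                            seed = 100 + r)
    K <- round(set$freqs * matrix(c(31, 28, 59, 59, 22), 100, 5, byrow = TRUE))
    ll <- vapply(c(50, 100, 200), function(N)
      temposcan:::.ne_loglik(N, K, c(31, 28, 59, 59, 22),
                             diff(sch$generations)), numeric(1))
    if (ll[2] > ll[1] && ll[2] > ll[3]) wins <- wins + 1L
  }
  expect_gte(wins, 9L)
})

test_that("neutral thresholds calibrate their tail and shrink with Ne", {
  sch <- sampling_schedule()
  spectrum <- runif(500, 0.5, 0.9)
  thr <- neutral_thresholds(150, spectrum, sch, tail = 0.05, n_sim = 10000,
                            seed = 9)
  # self-consistency on an independent neutral replicate set
  fresh <- neutral_thresholds(150, spectrum, sch, tail = 0.05, n_sim = 10000,
                              seed = 10)
  exceed <- mean(fresh$delta_f_sample > thr$threshold)
  expect_lt(abs(exceed - 0.05), 0.012)
  thr_big <- neutral_thresholds(600, spectrum, sch, tail = 0.05,
                                n_sim = 10000, seed = 11)
  expect_lt(thr_big$threshold, thr$threshold)
  # magnitude matches the study's scan thresholds at comparable Ne
  for (ne in c(115, 172, 273)) {
    t5 <- neutral_thresholds(ne, spectrum, sch, n_sim = 10000, seed = ne)
    expect_gt(t5$threshold, 0.005)
    expect_lt(t5$threshold, 0.03)
  }
})
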