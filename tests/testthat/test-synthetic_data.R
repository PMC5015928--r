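test_that("ancestor panels are homozygous, seeded, and honor duplicate pairs", {
  p <- generate_ancestor_panel(2, 100, maf_spectrum = 0.5, seed = 1)
  expect_equal(dim(p$calls), c(2L, 100L))
  expect_true(all(p$calls %in% c(0L, 1L)))
  expect_identical(generate_ancestor_panel(2, 100, maf_spectrum = 0.5, seed = 1)$calls,
                   p$calls)
  p2 <- generate_ancestor_panel(4, 1000, near_duplicate_pairs = 1, seed = 7)
  expect_gte(ibs_matrix(p2)$values[1, 2], 0.85)
  expect_error(generate_ancestor_panel(4, 100, near_duplicate_pairs = 3),
               "near_duplicate_pairs")
})

test_that("single-ancestor weights clone the ancestor with constant truth", {
  anc <- generate_ancestor_panel(3, 300, seed = 2)
  sim <- simulate_breeding_cohorts(anc, c(ANC2 = 1), c(pre1970s = 5),
                                   het_rate = 0, seed = 3)
  expect_true(all(apply(sim$genotypes$calls, 1,
                        function(r) identical(unname(r), unname(anc$calls[2, ])))))
  expect_true(all(sim$truth == "ANC2"))
})

test_that("zero recombination yields one donor segment per chromosome", {
  anc <- generate_ancestor_panel(4, 200, n_chrom = 2, seed = 4)
  sim <- simulate_breeding_cohorts(anc, c(ANC1 = 1, ANC2 = 1, ANC3 = 1, ANC4 = 1),
                                   c(pre1970s = 20), recomb_per_interval = 0,
                                   het_rate = 0, seed = 5)
  for (ch in unique(anc$map$chrom)) {
    seg <- sim$truth[, anc$map$chrom == ch, drop = FALSE]
    expect_true(all(apply(seg, 1, function(r) length(unique(r)) == 1L)))
  }
})

test_that("mosaic donor fractions track the contribution weights", {
  anc <- generate_ancestor_panel(2, 3000, seed = 6)
  sim <- simulate_breeding_cohorts(anc, c(ANC1 = 0.5, ANC2 = 0.5),
                                   c(pre1970s = 200), het_rate = 0, seed = 7)
  frac <- mean(sim$truth == "ANC1")
  expect_lt(abs(frac - 0.5), 0.05)
  # realized fractions sum to 1 per line over ancestors
  per_line <- rowMeans(sim$truth == "ANC1") + rowMeans(sim$truth == "ANC2")
  expect_equal(per_line, rep(1, 200), ignore_attr = TRUE)
})

test_that("Wright-Fisher trajectories absorb, drift and respond to selection", {
  tr <- wright_fisher_trajectory(200, 0.1, 1, 45, seed = 1)
  expect_equal(tr$p, rep(1, 46))
  expect_error(wright_fisher_trajectory(200, -1.2, 0.5, 10), "s must be")
  expect_error(wright_fisher_trajectory(1, 0, 0.5, 10), "N must be")
  # neutral drift variance matches the closed form at generation 15
  P <- simulate_wf_loci(12000, 200, 0, 0.3, sampling_schedule(c(0, 15)), seed = 2)
  v_theory <- 0.3 * 0.7 * (1 - (1 - 1 / 200)^15)
  expect_lt(abs(var(P$freqs[, 2]) - v_theory) / v_theory, 0.05)
  # selected mean matches the deterministic recursion
  p_det <- 0.2
  for (g in 1:45) p_det <- p_det / (1 - 0.1 + p_det * 0.1)
  P2 <- simulate_wf_loci(10000, 200, 0.1, 0.2, sampling_schedule(c(0, 45)), seed = 3)
  expect_lt(abs(mean(P2$freqs[, 2]) - p_det), 0.05)
})

test_that("schedule observation is exact under census and binomial otherwise", {
  tr <- wright_fisher_trajectory(200, 0, 0.5, 45, seed = 9)
  sch <- sampling_schedule()
  obs <- sample_observed_counts(tr, sch)
  expect_equal(obs$freqs, tr$p[sch$generations + 1])
  # absorbed state samples to zero counts
  tr0 <- wright_fisher_trajectory(200, 0, 0, 45, seed = 1)
  obs0 <- sample_observed_counts(tr0, sampling_schedule(sample_sizes = c(31, 28, 59, 59, 22)),
                                 seed = 2)
  expect_equal(obs0$freqs, rep(0, 5))
  # binomial sampling is unbiased with the expected SE at t0
  sch2 <- sampling_schedule(sample_sizes = c(31, 28, 59, 59, 22))
  many <- simulate_wf_loci(20000, 200, 0, 0.5, sch2, seed = 4)
  expect_lt(abs(mean(many$freqs[, 1]) - 0.5), 0.005)
  expect_lt(abs(sd(many$freqs[, 1]) - sqrt(0.25 / 31)), 0.005)
  expect_error(sample_observed_counts(tr, sampling_schedule(c(0, 50))), "beyond")
})

test_that("generators are deterministic under a fixed seed", {
  sch <- sampling_schedule(sample_sizes = c(31, 28, 59, 59, 22))
  a <- simulate_wf_loci(50, 100, 0.05, 0.4, sch, seed = 11)
  b <- simulate_wf_loci(50, 100, 0.05, 0.4, sch, seed = 11)
  expect_identical(a$freqs, b$freqs)
  c <- simulate_wf_loci(50, 100, 0.05, 0.4, sch, seed = 12)
  expect_false(identical(a$freqs, c$freqs))
})
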