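test_that("a line identical to one ancestor is fully assigned to it", {
  set.seed(1)
  a <- sample(0:1, 120, replace = TRUE)
  b <- a
  b[seq(3, 120, by = 3)] <- 1L - b[seq(3, 120, by = 3)]  # differs every 3rd
  anc <- make_geno(rbind(A = a, B = b))
  row <- assign_marker_ancestry(a, anc, margin_threshold = 5)
  expect_true(all(row$donor == "A"))
  expect_true(all(row$margin > 5))
})

test_that("two identical ancestors leave every marker ambiguous", {
  a <- rep(c(0L, 1L), 50)
  anc <- make_geno(rbind(A = a, B = a))
  row <- assign_marker_ancestry(a, anc)
  expect_true(all(row$donor == "AMBIGUOUS"))
  expect_true(all(row$margin == 0))
  expect_error(assign_marker_ancestry(a, make_geno(matrix(0L, 0, 100))),
               "no ancestors")
})

test_that("margin-rule assignment equals the brute-force extent matcher", {
  set.seed(23)
  anc_calls <- matrix(sample(0:1, 3 * 100, replace = TRUE), nrow = 3,
                      dimnames = list(c("A", "B", "C"), NULL))
  anc <- make_geno(anc_calls, n_chrom = 2)
  line <- anc_calls[1, ]
  sw <- sample(100, 30)
  line[sw] <- anc_calls[2, sw]
  line[sample(100, 3)] <- 2L   # HET wildcards
  line[sample(100, 2)] <- NA   # missing breaks runs
  row <- assign_marker_ancestry(line, anc, margin_threshold = 5)
  expect_equal(row$donor, bf_assign(line, anc$calls, anc$map$chrom, 5))
  # and the best extents match the brute-force expansion
  for (m in c(1, 17, 50, 51, 99, 100)) {
    ext <- vapply(1:3, function(a)
      bf_extent(line, anc$calls[a, ], m, anc$map$chrom), numeric(1))
    expect_equal(row$match_length[m], max(ext))
  }
})

test_that("mosaic assignments recover the simulated truth and weights", {
  anc <- generate_ancestor_panel(2, 3000, seed = 31)
  sim <- simulate_breeding_cohorts(anc, c(ANC1 = 0.7, ANC2 = 0.3),
                                   c(pre1970s = 60), het_rate = 0, seed = 32)
  asg <- assign_ancestry(sim$genotypes, anc, 5)
  ok <- asg$donor != "AMBIGUOUS"
  expect_gte(mean(asg$donor[ok] == sim$truth[ok]), 0.95)
  fc <- fractional_contribution(asg)
  expect_lt(abs(fc$fraction[fc$ancestor == "ANC1"] - 0.7), 0.05)
  expect_lt(abs(fc$fraction[fc$ancestor == "ANC2"] - 0.3), 0.05)
})

test_that("contribution tables tally, sort, and flag founding ancestors", {
  donor <- matrix(c(rep("A", 70), rep("B", 20), rep("AMBIGUOUS", 10)), 1)
  asg <- structure(list(donor = donor, ancestors = c("A", "B", "C")),
                   class = "ancestry_assignment")
  fc <- fractional_contribution(asg)
  expect_equal(fc$ancestor, c("A", "B", "C"))
  expect_equal(fc$fraction, c(70, 20, 0) / 90)
  expect_equal(attr(fc, "ambiguous_fraction"), 0.1)
  expect_equal(founding_ancestors(fc), c("A", "B"))
  # threshold rule on a constructed table
  tab <- data.frame(ancestor = c("A", "B", "C"),
                    fraction = c(0.5, 0.031, 0.02))
  expect_equal(founding_ancestors(tab, 0.03), c("A", "B"))
  expect_equal(founding_ancestors(tab, 0.9), character(0))
  # all ambiguous: flagged, undefined fractions
  asg2 <- structure(list(donor = matrix("AMBIGUOUS", 1, 10),
                         ancestors = c("A", "B")),
                    class = "ancestry_assignment")
  expect_warning(fc2 <- fractional_contribution(asg2), "ambiguous")
  expect_true(attr(fc2, "all_ambiguous"))
  expect_true(all(is.na(fc2$fraction)))
})

test_that("raising the margin threshold never reduces ambiguity", {
  anc <- generate_ancestor_panel(4, 500, near_duplicate_pairs = 1, seed = 41)
  sim <- simulate_breeding_cohorts(anc, c(ANC1 = 1, ANC2 = 1, ANC3 = 1, ANC4 = 1),
                                   c(pre1970s = 10), seed = 42)
  amb <- vapply(c(0, 2, 5, 10, 20), function(th)
    mean(assign_ancestry(sim$genotypes, anc, th)$donor == "AMBIGUOUS"),
    numeric(1))
  expect_true(all(diff(amb) >= 0))
})

test_that("assignment is invariant under ancestor reordering", {
  anc <- generate_ancestor_panel(3, 400, seed = 51)
  sim <- simulate_breeding_cohorts(anc, c(ANC1 = 1, ANC2 = 1, ANC3 = 1),
                                   c(pre1970s = 4), het_rate = 0, seed = 52)
  asg1 <- assign_ancestry(sim$genotypes, anc)
  anc_rev <- subset_genotypes(anc, lines = 3:1)
  asg2 <- assign_ancestry(sim$genotypes, anc_rev)
  expect_identical(asg1$donor, asg2$donor)
})

test_that("zero-recombination lines are exactly attributed where unambiguous", {
  anc <- generate_ancestor_panel(3, 600, n_chrom = 3, seed = 61)
  sim <- simulate_breeding_cohorts(anc, c(ANC1 = 1, ANC2 = 1, ANC3 = 1),
                                   c(pre1970s = 12), recomb_per_interval = 0,
                                   het_rate = 0, seed = 62)
  asg <- assign_ancestry(sim$genotypes, anc)
  ok <- asg$donor != "AMBIGUOUS"
  expect_true(all(asg$donor[ok] == sim$truth[ok]))
})
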