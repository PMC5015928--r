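test_that("window spectra count haplotype strings with exclusions", {
  g <- make_geno(matrix(0L, 6, 50))
  sp <- window_haplotype_spectrum(g)
  expect_equal(sp$spectra[[1]]$freq, 1)
  expect_equal(sp$windows$n_lines, 6L)
  # 10 lines, 3 distinct strings at 5/3/2
  h1 <- rep(0L, 50); h2 <- rep(1L, 50); h3 <- rep(c(0L, 1L), 25)
  g2 <- make_geno(rbind(matrix(h1, 5, 50, byrow = TRUE),
                        matrix(h2, 3, 50, byrow = TRUE),
                        matrix(h3, 2, 50, byrow = TRUE)))
  sp2 <- window_haplotype_spectrum(g2)
  expect_equal(sp2$spectra[[1]]$freq, c(0.5, 0.3, 0.2))
  # lines with HET or missing inside the window are excluded
  calls <- rbind(matrix(h1, 3, 50, byrow = TRUE), h1, h1)
  calls[4, 10] <- 2L; calls[5, 20] <- NA
  sp3 <- window_haplotype_spectrum(make_geno(calls))
  expect_equal(sp3$windows$n_lines, 3L)
  # all excluded -> flagged empty spectrum
  calls4 <- matrix(h1, 2, 50, byrow = TRUE); calls4[, 25] <- NA
  expect_warning(sp4 <- window_haplotype_spectrum(make_geno(calls4)),
                 "no usable line")
  expect_equal(nrow(sp4$spectra[[1]]), 0L)
})

test_that("spectrum frequencies sum to one on random fixtures", {
  set.seed(21)
  calls <- matrix(sample(0:1, 12 * 80, replace = TRUE, prob = c(0.7, 0.3)),
                  nrow = 12)
  sp <- window_haplotype_spectrum(make_geno(calls))
  for (s in sp$spectra) expect_equal(sum(s$freq), 1)
})

test_that("cohort tracking matches identities and measures change", {
  h1 <- rep(0L, 50); h2 <- rep(1L, 50)
  early <- window_haplotype_spectrum(make_geno(
    rbind(matrix(h1, 9, 50, byrow = TRUE), matrix(h2, 1, 50, byrow = TRUE))))
  late_same <- window_haplotype_spectrum(make_geno(
    rbind(matrix(h1, 9, 50, byrow = TRUE), matrix(h2, 1, 50, byrow = TRUE))))
  tr0 <- track_spectra_over_cohorts(early, late_same)
  expect_equal(tr0$windows$max_haplotype_change, 0)
  # rare haplotype rising 0.10 -> 0.78 (constructed): change 0.68
  late <- window_haplotype_spectrum(make_geno(
    rbind(matrix(h2, 39, 50, byrow = TRUE), matrix(h1, 11, 50, byrow = TRUE))))
  tr <- track_spectra_over_cohorts(early, late)
  expect_equal(tr$windows$max_haplotype_change, 0.9 - 11 / 50)
  t1 <- tr$tracked[[1]]
  expect_equal(t1$freq_early[t1$haplotype == paste(h2, collapse = "")], 0.1)
  expect_equal(t1$freq_late[t1$haplotype == paste(h2, collapse = "")], 0.78)
})

test_that("identity ranks lump beyond seven as OTHER", {
  # nine distinct haplotypes in the early cohort
  calls <- vapply(1:9, function(k) { h <- rep(0L, 50); h[k] <- 1L; h },
                  integer(50))
  early <- window_haplotype_spectrum(make_geno(t(calls)))
  tr <- track_spectra_over_cohorts(early, early)
  t1 <- tr$tracked[[1]]
  expect_equal(sum(t1$rank == "OTHER"), 2L)
  expect_setequal(t1$rank[t1$rank != "OTHER"], as.character(1:7))
  # lumped OTHER frequency = sum of the lumped haplotypes
  expect_equal(sum(t1$freq_early[t1$rank == "OTHER"]), 2 / 9)
})

test_that("sneak windows show elevated haplotype/allele change ratios", {
  set.seed(33)
  n <- 60
  calls <- data.frame(window_id = paste0("w", 1:n),
                      category = rep(c("sneak", "neutral"), each = n / 2))
  # constructed: sneaks fix as haplotypes (change ~0.9) with slow alleles
  hap_chg <- c(runif(n / 2, 0.7, 0.95), runif(n / 2, 0.05, 0.3))
  all_chg <- rep(0.5, n)
  res <- sneak_ratio_test(calls, hap_chg, all_chg, n_perm = 2000, seed = 1)
  expect_gt(res$median_sneak, res$median_neutral)
  expect_lt(res$p_value, 0.01)
  # identical groups: null behaviour
  hap0 <- rep(0.4, n)
  res0 <- sneak_ratio_test(calls, hap0, all_chg, n_perm = 2000, seed = 2)
  expect_gt(res0$p_value, 0.05)
  # a haplotype's change cannot exceed 1, so ratios are bounded by 1/all_chg
  expect_lte(res$median_sneak, 1 / 0.5)
  expect_error(sneak_ratio_test(calls[1:12, ], hap_chg[1:12], all_chg[1:12]),
               ">= 10")
})

test_that("H equals hand counts and the brute-force tract oracle", {
  g_same <- make_geno(matrix(0L, 2, 300))
  expect_equal(h_scan(g_same)$H, rep(300, 300))
  a <- rep(0L, 300); b <- a; b[150] <- 1L
  h <- h_scan(make_geno(rbind(a, b)))$H
  expect_equal(h[150], 0)
  expect_equal(h[1], 149)
  expect_equal(h[151], 150)
  set.seed(29)
  calls <- matrix(sample(0:1, 10 * 200, replace = TRUE, prob = c(0.8, 0.2)),
                  nrow = 10)
  g <- make_geno(calls, n_chrom = 2)
  expect_equal(h_scan(g)$H, bf_h_scan(calls, g$map$chrom))
  # adding an identical duplicate line weakly increases mean H
  g_dup <- make_geno(rbind(calls, calls[1, ]), n_chrom = 2)
  expect_gte(mean(h_scan(g_dup)$H), mean(h_scan(g)$H))
  expect_error(h_scan(make_geno(matrix(0L, 1, 10))), "2 lines")
})
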