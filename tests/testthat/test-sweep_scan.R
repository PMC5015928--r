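test_that("top-3 window statistic matches hand values and a sort oracle", {
  map <- make_map(100)
  wins <- window_grid(map, 50, 10)
  df0 <- setNames(rep(0, 100), map$marker)
  expect_equal(window_selection_stats(df0, wins, map)$top3_delta_f,
               rep(0, nrow(wins)))
  vals <- c(0.02, 0.01, 0.01, rep(0.001, 47), rep(0.001, 50))
  dfv <- setNames(vals, map$marker)
  got <- window_selection_stats(dfv, wins, map)
  expect_equal(got$top3_delta_f[1], mean(c(0.02, 0.01, 0.01)))
  set.seed(3)
  rnd <- setNames(rnorm(100, 0, 0.01), map$marker)
  got_rnd <- window_selection_stats(rnd, wins, map)
  for (k in seq_len(nrow(wins))) {
    v <- sort(abs(rnd[wins$col_start[k]:wins$col_stop[k]]), decreasing = TRUE)
    expect_equal(got_rnd$top3_delta_f[k], mean(v[1:3]))
  }
  sparse <- setNames(c(0.01, 0.02, rep(NA, 98)), map$marker)
  expect_warning(ws <- window_selection_stats(sparse, wins, map), "skipped")
  expect_true(all(is.na(ws$top3_delta_f)))
})

test_that("the four-quadrant classifier reproduces the threshold rules", {
  stats <- data.frame(window_id = paste0("w", 1:4),
                      top3_delta_f = c(0.02, 0.02, 0.005, 0.005),
                      log2_ratio = c(-2.5, -0.5, -2.5, -0.5))
  cls <- classify_windows(stats, 0.013, 1.9)
  expect_equal(cls$calls$category, c("hard", "soft", "sneak", "neutral"))
  expect_equal(sum(cls$counts$count), 3)
  expect_error(classify_windows(stats, -1, 1.9), "threshold")
})

test_that("category counts sum and respond monotonically to the threshold", {
  set.seed(11)
  stats <- data.frame(window_id = paste0("w", 1:200),
                      top3_delta_f = abs(rnorm(200, 0, 0.02)),
                      log2_ratio = rnorm(200, -1, 1.5))
  lo <- classify_windows(stats, 0.01, 1.9)
  hi <- classify_windows(stats, 0.03, 1.9)
  tab <- function(cls) table(factor(cls$calls$category,
                                    c("hard", "soft", "sneak", "neutral")))
  expect_equal(sum(tab(lo)), 200)
  # raising the delta-f threshold moves mass from {hard, soft} to {sneak, neutral}
  expect_lte(tab(hi)[["hard"]] + tab(hi)[["soft"]],
             tab(lo)[["hard"]] + tab(lo)[["soft"]])
  expect_gte(tab(hi)[["sneak"]] + tab(hi)[["neutral"]],
             tab(lo)[["sneak"]] + tab(lo)[["neutral"]])
  # order invariance
  perm <- sample(200)
  expect_equal(classify_windows(stats[perm, ], 0.01, 1.9)$calls$category,
               lo$calls$category[perm])
})

test_that("an engineered hard sweep is called hard from raw genotypes", {
  # early cohort: two balanced haplotypes; late cohort: fixed for one,
  # with per-marker frequencies moving 0.5 -> ~1 within 25 generations
  hapA <- rep(0L, 50); hapB <- rep(1L, 50)
  cohorts <- list(pre = 0.5, d70 = 0.9, d80 = 0.98, d90 = 1, d00 = 1)
  calls <- do.call(rbind, lapply(cohorts, function(f) {
    nA <- round(10 * f)
    do.call(rbind, c(rep(list(hapA), nA), rep(list(hapB), 10 - nA)))
  }))
  panel <- make_panel(paste0("L", 1:50), "III",
                      rep(c(1960, 1975, 1985, 1995, 2005), each = 10))
  rownames(calls) <- panel$line_id
  g <- make_geno(calls, panel = panel)
  set <- build_frequency_series(g, "MGIII-IV", freq_range = c(0, 1))
  df <- delta_f(set)
  wins <- window_grid(g$map, 50, 10)
  px <- sliding_pi(subset_genotypes(g, lines = 41:50))  # 2000s: fixed
  pa <- sliding_pi(subset_genotypes(g, lines = 1:10))   # pre: balanced
  ratio <- log2_diversity_ratio(px, pa)
  stats <- window_selection_stats(df, ratio, g$map)
  cls <- classify_windows(stats, 0.013, 1.9)
  expect_equal(cls$calls$category, "hard")
  expect_gte(stats$top3_delta_f[1], 0.013)
  expect_lte(stats$log2_ratio[1], -1.9)
})

test_that("cross-population candidates follow the source/sink fixation logic", {
  mk <- function(df, ff) data.frame(marker = c("m1", "m2", "m3"),
                                    delta_f = df, final_freq = ff,
                                    stringsAsFactors = FALSE)
  stats <- list(A = mk(c(0.02, 0.02, 0), c(0.97, 0.97, 0.5)),
                B = mk(c(0, 0, -0.001), c(0.03, 0.96, 0.96)),
                C = mk(c(0.001, 0, 0.002), c(0.5, 0.5, 0.5)))
  thr <- list(A = 0.013, B = 0.018, C = 0.014)
  out <- cross_population_candidates(stats, thr)
  # m1 rises past threshold in A and is fixed low in B -> candidate
  expect_equal(out$marker, "m1")
  expect_equal(out$source, "A")
  expect_equal(out$sinks, "B")
  expect_equal(out$delta_f_x1000_A, 20)  # presentation convention
  expect_true(out$exceeds_A)
  expect_false(out$exceeds_B)
  bad <- stats; bad$B <- bad$B[c(2, 1, 3), ]
  expect_error(cross_population_candidates(bad, thr), "marker sets")
})
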