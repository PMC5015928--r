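# Configuration-driven orchestration: synthetic (or file-based) inputs
# through ancestry, diversity, Ne, scan, spectra and power stages, with
# TSV outputs, a run log, and deterministic seeding.

#' Default pipeline configuration
#'
#' A self-contained synthetic demonstration: three maturity-group
#' populations bred from a shared 8-ancestor panel (one near-duplicate
#' ancestor pair), five decade cohorts each, 1200 markers on two
#' chromosomes. All analysis thresholds sit at their package defaults
#' (window 50/10, margin 5, founding fraction 0.03, fixation bounds
#' 0.05/0.95, Ne search 20-1000, scan tail 5%).
#'
#' @param seed Master seed; stage seeds are derived from it.
#' @param out_dir Output directory.
#' @return Nested configuration list, editable or writable as YAML.
#' @export
default_config <- function(seed = 1, out_dir = "temposcan_out") {
  list(
    seed = seed, out_dir = out_dir,
    stages = c("ibs", "ancestry", "diversity", "ne", "scan", "spectra",
               "power"),
    window = 50, step = 10,
    margin_threshold = 5, founding_threshold = 0.03,
    fixation_bounds = c(0.05, 0.95),
    generation_map = as.list(default_generation_map),
    ne_bounds = c(20, 1000),
    scan_tail = 0.05, scan_sims = 10000,
    diversity_threshold = 1.9, report_threshold = -2.3,
    power = list(reps = 1000, s_values = c(0.02, 0.05, 0.1),
                 p0_values = c(0.2, 0.5, 0.8), N = 200,
                 sampling = list(census = NULL,
                                 sampled = c(31, 28, 59, 59, 22))),
    inputs = NULL,
    synthetic = list(
      n_ancestors = 8, n_markers = 1200, n_chrom = 2,
      near_duplicate_pairs = 1,
      n_lines_per_cohort = c(pre1970s = 14, `1970s` = 10, `1980s` = 12,
                             `1990s` = 12, `2000s` = 12),
      populations = list(
        `MG0-I` = list(mg = "I",
                       weights = c(ANC1 = 0.5, ANC3 = 0.3, ANC5 = 0.2)),
        `MGIII-IV` = list(mg = "III",
                          weights = c(ANC3 = 0.6, ANC4 = 0.2, ANC6 = 0.2)),
        `MGV+` = list(mg = "V",
                      weights = c(ANC6 = 0.4, ANC7 = 0.4, ANC8 = 0.2)))))
}

.load_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- utils::modifyList(default_config(), config)
  if (is.null(cfg$inputs) && is.null(cfg$synthetic))
    stop("run_full_analysis: either real inputs or a synthetic block is required")
  cfg$generation_map <- unlist(cfg$generation_map)
  cfg
}

.write_tsv <- function(df, path, meta = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(meta)) writeLines(paste0("# ", meta), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

.stage_seed <- function(cfg, k) (cfg$seed * 101L + k * 9973L) %% .Machine$integer.max

#' Run the full temporal population-genomics analysis
#'
#' Executes the configured stages on synthetic or file-based inputs and
#' writes TSV outputs (each with a `#` metadata header naming parameters
#' and seed) plus a run log into the output directory: `ibs_matrix.tsv`,
#' `ancestor_ibs_summary.tsv`, `contributions.tsv`,
#' `low_diversity_regions.tsv`, `ne_estimates.tsv`, `scan_thresholds.tsv`,
#' `sweep_calls.tsv`, `category_counts.tsv`, `candidates.tsv`,
#' `power_grid.tsv` and per-population files under `spectra/`. A failing
#' stage aborts the run (later stages are skipped) with the error in the
#' log.
#'
#' @param config A configuration list (see [default_config()]) or the
#'   path to a YAML file with the same structure; partial configurations
#'   are completed with the defaults.
#' @return Invisibly, a list with the in-memory stage results and the
#'   paths written.
#' @export
run_full_analysis <- function(config = default_config()) {
  cfg <- .load_config(config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(cfg$out_dir, "run_log.txt")
  log_con <- file(log_path, "w")
  on.exit(close(log_con), add = TRUE)
  logmsg <- function(level, ...) {
    line <- sprintf("[%s] %s %s", format(Sys.time(), "%H:%M:%S"), level,
                    paste0(...))
    writeLines(line, log_con)
    flush(log_con)
    message(line)
  }
  res <- list(paths = character())
  emit <- function(df, file, meta) {
    p <- .write_tsv(df, file.path(cfg$out_dir, file),
                    c(sprintf("temposcan %s", as.character(utils::packageVersion("temposcan"))),
                      sprintf("seed=%d", cfg$seed), meta))
    res$paths <<- c(res$paths, p)
    p
  }
  logmsg("INFO", "run started; seed=", cfg$seed,
         "; stages=", paste(cfg$stages, collapse = ","))

  # ---- inputs ----
  t0 <- Sys.time()
  if (!is.null(cfg$inputs)) {
    panel <- read_panel_csv(cfg$inputs$panel)
    g <- read_genotype_table(cfg$inputs$genotypes,
                             format = cfg$inputs$format %||% "hapmap_tsv",
                             panel = panel)
    ancestors <- read_genotype_table(cfg$inputs$ancestors,
                                     format = cfg$inputs$format %||% "hapmap_tsv")
    truth <- NULL
  } else {
    sy <- cfg$synthetic
    ancestors <- generate_ancestor_panel(
      sy$n_ancestors, sy$n_markers,
      near_duplicate_pairs = sy$near_duplicate_pairs,
      n_chrom = sy$n_chrom, seed = .stage_seed(cfg, 1))
    parts <- lapply(seq_along(sy$populations), function(i) {
      p <- sy$populations[[i]]
      sim <- simulate_breeding_cohorts(
        ancestors, unlist(p$weights), unlist(sy$n_lines_per_cohort),
        maturity_group = p$mg, seed = .stage_seed(cfg, 1 + i))
      rownames(sim$genotypes$calls) <-
        paste0(names(sy$populations)[i], "_", rownames(sim$genotypes$calls))
      sim$genotypes$panel$line_id <- rownames(sim$genotypes$calls)
      sim
    })
    calls <- do.call(rbind, lapply(parts, function(s) s$genotypes$calls))
    panel <- do.call(rbind, lapply(parts, function(s) s$genotypes$panel))
    g <- suppressWarnings(genotype_matrix(calls, ancestors$map, panel = panel))
    truth <- do.call(rbind, lapply(parts, function(s) s$truth))
  }
  pops <- setdiff(unique(g$panel$population), "EXCLUDED")
  res$genotypes <- g; res$ancestors <- ancestors; res$truth <- truth
  logmsg("INFO", sprintf("inputs ready: %d lines x %d markers, %d population(s) [%.1fs]",
                         nrow(g$calls), ncol(g$calls), length(pops),
                         as.numeric(Sys.time() - t0, units = "secs")))

  pre <- function(pop) subset_genotypes(
    g, lines = which(g$panel$population == pop & g$panel$cohort == "pre1970s"))
  cohort_sub <- function(pop, coh) subset_genotypes(
    g, lines = which(g$panel$population == pop & g$panel$cohort == coh))

  run_stage <- function(name, fun) {
    if (!name %in% cfg$stages) return(invisible(NULL))
    t0 <- Sys.time()
    tryCatch(fun(), error = function(e) {
      logmsg("ERROR", "stage ", name, " failed: ", conditionMessage(e),
             "; remaining stages skipped")
      stop(e)
    })
    logmsg("INFO", sprintf("stage %s done [%.1fs]", name,
                           as.numeric(Sys.time() - t0, units = "secs")))
  }

  run_stage("ibs", function() {
    ibs <- ibs_matrix(g)
    res$ibs <<- ibs
    write_ibs_tsv(ibs, file.path(cfg$out_dir, "ibs_matrix.tsv"),
                  header = sprintf("seed=%d", cfg$seed))
    res$paths <<- c(res$paths, file.path(cfg$out_dir, "ibs_matrix.tsv"))
    su <- population_ancestor_ibs_summary(g, ancestors)
    emit(su$summary, "ancestor_ibs_summary.tsv", "per-population IBS vs ancestors")
  })

  run_stage("ancestry", function() {
    contrib <- lapply(pops, function(pop) {
      fractional_contribution(
        assign_ancestry(pre(pop), ancestors, cfg$margin_threshold),
        cfg$founding_threshold)
    })
    names(contrib) <- pops
    res$contributions <<- contrib
    res$founders <<- lapply(contrib, founding_ancestors,
                            threshold = cfg$founding_threshold)
    wide <- data.frame(ancestor = contrib[[1]]$ancestor[order(contrib[[1]]$ancestor)],
                       stringsAsFactors = FALSE)
    for (pop in pops) {
      tab <- contrib[[pop]]
      wide[[pop]] <- round(tab$fraction[match(wide$ancestor, tab$ancestor)], 3)
    }
    wide <- wide[order(-rowMeans(wide[-1], na.rm = TRUE)), ]
    emit(wide, "contributions.tsv",
         sprintf("fractional contribution; margin_threshold=%d; founding>%.2f",
                 cfg$margin_threshold, cfg$founding_threshold))
  })

  run_stage("diversity", function() {
    pi_a <- sliding_pi(ancestors, cfg$window, cfg$step)
    res$ratios <<- list()
    regions <- lapply(pops, function(pop) {
      px <- sliding_pi(pre(pop), cfg$window, cfg$step)
      ratio <- log2_diversity_ratio(px, pi_a)
      res$ratios[[pop]] <<- ratio
      founders <- res$founders[[pop]]
      fpanel <- if (length(founders))
        subset_genotypes(ancestors, lines = founders) else NULL
      rep <- low_diversity_report(ratio, pre(pop), fpanel,
                                  threshold = cfg$report_threshold)
      if (nrow(rep)) cbind(population = pop, rep) else NULL
    })
    regions <- do.call(rbind, regions)
    if (is.null(regions))
      regions <- data.frame(population = character(), chrom = character(),
                            midsite_index = integer(), stringsAsFactors = FALSE)
    res$low_diversity <<- regions
    emit(regions, "low_diversity_regions.tsv",
         sprintf("window=%d step=%d threshold=%.2f vs all-ancestor panel",
                 cfg$window, cfg$step, cfg$report_threshold))
  })

  run_stage("ne", function() {
    ne <- lapply(pops, function(pop) {
      set <- build_frequency_series(g, pop, freq_range = c(0.5, 0.6),
                                    generation_map = cfg$generation_map)
      suppressWarnings(estimate_ne(set, bounds = cfg$ne_bounds))
    })
    names(ne) <- pops
    res$ne <<- ne
    emit(do.call(rbind, lapply(pops, function(pop) data.frame(
      population = pop, ne = ne[[pop]]$ne, ci_low = ne[[pop]]$ci95[1],
      ci_high = ne[[pop]]$ci95[2], n_loci = ne[[pop]]$n_loci,
      at_bound = ne[[pop]]$at_bound, stringsAsFactors = FALSE))),
      "ne_estimates.tsv",
      sprintf("exact haploid WF likelihood; bounds=%d-%d; filter initial major freq 0.5-0.6",
              cfg$ne_bounds[1], cfg$ne_bounds[2]))
  })

  run_stage("scan", function() {
    if (is.null(res$ne))
      stop("scan stage requires the ne stage")
    gens <- unname(cfg$generation_map)
    res$scan <<- list()
    for (pop in pops) {
      set <- build_frequency_series(g, pop, freq_range = c(0.5, 0.95),
                                    upper_strict = TRUE,
                                    generation_map = cfg$generation_map)
      n_med <- round(apply(set$sample_sizes, 2, stats::median))
      thr <- neutral_thresholds(
        res$ne[[pop]], set$initial_freq,
        sampling_schedule(gens, n_med), tail = cfg$scan_tail,
        n_sim = cfg$scan_sims, seed = .stage_seed(cfg, 20 + match(pop, pops)))
      df <- delta_f(set, cfg$fixation_bounds)
      res$scan[[pop]] <<- list(set = set, threshold = thr, delta_f = df)
    }
    emit(do.call(rbind, lapply(pops, function(pop) data.frame(
      population = pop, delta_f_threshold = res$scan[[pop]]$threshold$threshold,
      diversity_threshold = cfg$diversity_threshold,
      ne = res$scan[[pop]]$threshold$ne, n_sim = cfg$scan_sims,
      stringsAsFactors = FALSE))), "scan_thresholds.tsv",
      sprintf("neutral simulation tail=%.3g", cfg$scan_tail))

    # sweep classification: 2000s diversity relative to pre-1970s
    calls_all <- counts_all <- NULL
    for (pop in pops) {
      px <- sliding_pi(cohort_sub(pop, "2000s"), cfg$window, cfg$step)
      pa <- sliding_pi(pre(pop), cfg$window, cfg$step)
      ratio <- log2_diversity_ratio(px, pa)
      wstats <- suppressWarnings(window_selection_stats(
        res$scan[[pop]]$delta_f, ratio, g$map))
      cls <- classify_windows(wstats, res$scan[[pop]]$threshold$threshold,
                              cfg$diversity_threshold)
      res$sweeps[[pop]] <<- cls
      calls_all <- rbind(calls_all,
                         cbind(population = pop,
                               cls$calls[c("window_id", "chrom", "start_index",
                                           "stop_index", "top3_delta_f",
                                           "log2_ratio", "category")]))
      counts_all <- rbind(counts_all, cbind(population = pop, cls$counts))
    }
    emit(calls_all, "sweep_calls.tsv",
         "2000s-vs-pre1970s diversity; per-population thresholds")
    emit(counts_all, "category_counts.tsv", "selection-mode counts")

    # cross-population candidates on shared polarity (reference = first pop)
    freqs <- lapply(pops, function(pop)
      .pop_cohort_freqs(g, pop, cfg$generation_map))
    names(freqs) <- pops
    ref_major1 <- freqs[[1]]$f1[, 1] >= 0.5
    stats_by_pop <- lapply(pops, function(pop) {
      f <- freqs[[pop]]$f1
      f[!ref_major1, ] <- 1 - f[!ref_major1, ]
      data.frame(marker = rownames(f),
                 delta_f = .delta_f_mat(f, gens, cfg$fixation_bounds[1],
                                        cfg$fixation_bounds[2]),
                 final_freq = f[, ncol(f)], stringsAsFactors = FALSE)
    })
    names(stats_by_pop) <- pops
    thresholds <- lapply(res$scan, function(s) s$threshold$threshold)
    cand <- cross_population_candidates(stats_by_pop, thresholds,
                                        cfg$fixation_bounds)
    res$candidates <<- cand
    emit(cand, "candidates.tsv",
         "selected in source, fixed opposite in sink; delta-f x1000")
  })

  run_stage("spectra", function() {
    dir.create(file.path(cfg$out_dir, "spectra"), showWarnings = FALSE)
    for (pop in pops) {
      early <- window_haplotype_spectrum(pre(pop), cfg$window, cfg$step)
      late <- window_haplotype_spectrum(cohort_sub(pop, "2000s"),
                                        cfg$window, cfg$step)
      tr <- track_spectra_over_cohorts(early, late)
      res$spectra[[pop]] <<- tr
      long <- do.call(rbind, lapply(seq_len(nrow(tr$windows)), function(k) {
        t <- tr$tracked[[k]]
        if (!nrow(t)) return(NULL)
        cbind(window_id = tr$windows$window_id[k], t)
      }))
      emit(long, file.path("spectra", paste0("spectra_",
                                             gsub("[^A-Za-z0-9]", "", pop), ".tsv")),
           sprintf("population=%s window=%d step=%d", pop, cfg$window, cfg$step))
      h <- h_scan(pre(pop))
      h$H_2000s <- h_scan(cohort_sub(pop, "2000s"))$H
      names(h)[names(h) == "H"] <- "H_pre1970s"
      emit(h, file.path("spectra", paste0("hscan_",
                                          gsub("[^A-Za-z0-9]", "", pop), ".tsv")),
           sprintf("population=%s shared-haplotype length in markers", pop))
    }
  })

  run_stage("power", function() {
    pw <- run_power_grid(
      s_values = cfg$power$s_values, p0_values = cfg$power$p0_values,
      N = cfg$power$N, generations = unname(cfg$generation_map),
      sampling = cfg$power$sampling, reps = cfg$power$reps,
      fpr = cfg$scan_tail, seed = .stage_seed(cfg, 40))
    res$power <<- pw
    emit(pw$grid, "power_grid.tsv",
         sprintf("N=%d reps=%d fpr=%.3g", cfg$power$N, cfg$power$reps,
                 cfg$scan_tail))
  })

  logmsg("INFO", "run complete; ", length(res$paths), " file(s) written")
  invisible(res)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Per-cohort allele1 frequencies for one population (markers x cohorts),
# haploid counting with heterozygotes as half an allele.
.pop_cohort_freqs <- function(g, population, generation_map) {
  keep <- g$panel$population == population
  calls <- g$calls[keep, , drop = FALSE]
  cohorts <- as.character(g$panel$cohort[keep])
  lv <- names(generation_map)
  f1 <- n <- matrix(NA_real_, ncol(calls), length(lv),
                    dimnames = list(colnames(calls), lv))
  for (ci in seq_along(lv)) {
    sub <- calls[cohorts == lv[ci], , drop = FALSE]
    cnt <- colSums(sub == CALL_A1, na.rm = TRUE) +
      0.5 * colSums(sub == CALL_HET, na.rm = TRUE)
    tot <- colSums(!is.na(sub))
    f1[, ci] <- cnt / tot
    n[, ci] <- tot
  }
  list(f1 = f1, n = n)
}
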