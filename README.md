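# temposcan

Temporal population genomics for panels of inbred crop varieties.

Highly autogamous crops such as soybean leave behind "immortalized
genotypes": released varieties, preserved in germplasm banks and typed
at tens of thousands of biallelic SNPs, that sample a breeding program
decade by decade across the last century. Treating the decade cohorts
of a breeding population as sequential samples of one evolving
population turns crop improvement into a time-serial population
genetics experiment. `temposcan` implements that analysis end to end
for researchers in crop population genomics and quantitative breeding:

- **Ancestry tracing by haplotype sharing.** Each marker of each line
  is attributed to the ancestor with the longest run of agreeing
  flanking markers, accepted only when that run beats the runner-up by
  more than a margin (default 5 markers); attributions pool into
  fractional genome contributions, and ancestors contributing more
  than 3% are "founding ancestors".
- **Sliding-window diversity.** Pairwise diversity π (differences per
  marker, 50-marker windows advanced by 10) per cohort, the ratio
  log₂(π_x/π_a) of a focal population to a reference ancestor panel
  (capped at −8, the "all diversity lost" convention), and merged
  low-diversity region reports with the percent of founding ancestors
  carrying each region's major haplotype.
- **Time-serial selection statistics.** Per-locus frequency series
  over the cohort schedule (generations 0, 15, 25, 35, 45) scored by
  Δf (OLS slope of frequency on generation, truncated at the first
  timepoint past the 0.05/0.95 fixation bounds), logistic-regression
  β, and a temporal F_st contrasting within-timepoint versus pooled
  homozygosity of the first and last timepoints.
- **Effective population size.** Maximum-likelihood N_e from temporal
  samples under an exact haploid Wright–Fisher Markov chain (states
  0..N) with binomial sampling at each timepoint, profile-likelihood
  95% CIs, searched on an integer grid between 20 and 1000.
- **Neutral calibration and power.** Forward Wright–Fisher simulation
  (fitness 1 vs 1−s; `p* = p/(1−s+ps)`) generates neutral Δf
  thresholds for scans and a full power study of Δf, logistic β and
  F_st at a 5% false-positive rate across selection coefficients,
  initial frequencies and sampling depths.
- **Sweep-mode classification.** Windows combine top-3 |Δf| with the
  2000s-vs-pre-1970s diversity ratio into hard sweep / soft sweep /
  haplotype sneak / neutral calls, plus cross-population candidate
  alleles (selected in one population, fixed oppositely in another).
- **Haplotype spectra.** Window haplotype frequencies tracked across
  cohorts with stable identities, the haplotype-vs-allele change
  comparison for sneak windows (permutation test), and the H scan
  (average pairwise shared-haplotype tract length per marker).
- **Synthetic data.** Generators for ancestor panels (including
  near-duplicate ancestors), recombinant-inbred mosaic cohorts with
  known per-marker ancestry, and Wright–Fisher trajectories — every
  input the pipeline needs, so the whole analysis runs and is tested
  without any external download.

## Worked example

```r
library(temposcan)

# 1. synthetic study system: 6 ancestors, mosaic descendants over five cohorts
ancestors <- generate_ancestor_panel(n_ancestors = 6, n_markers = 2000,
                                     near_duplicate_pairs = 1, seed = 11)
sim <- simulate_breeding_cohorts(
  ancestors, contributions = c(ANC1 = 0.55, ANC3 = 0.30, ANC5 = 0.15),
  n_lines_per_cohort = c(pre1970s = 25, `1970s` = 20, `1980s` = 20,
                         `1990s` = 20, `2000s` = 20),
  seed = 12)

# 2. trace each marker to its donor ancestor and tally contributions
asg <- assign_ancestry(sim$genotypes, ancestors, margin_threshold = 5)
contrib <- fractional_contribution(asg)
head(contrib, 4)
#>   ancestor  fraction founding
#> 1     ANC1 0.5289933     TRUE
#> 2     ANC3 0.3355048     TRUE
#> 3     ANC5 0.1355019     TRUE
#> 4     ANC2 0.0000000    FALSE
mean((asg$donor == sim$truth)[asg$donor != "AMBIGUOUS"])
#> [1] 0.999
```

The tallied fractions recover the simulated contribution weights
(0.55/0.30/0.15) and 99.9% of unambiguous per-marker attributions
match the simulator's ground truth.

```r
# 3. temporal statistics on one selected locus (s = 0.1, N = 200),
#    observed through the study's per-decade sampling depths
sch <- sampling_schedule(sample_sizes = c(31, 28, 59, 59, 22))
locus <- sample_observed_counts(
  wright_fisher_trajectory(N = 200, s = 0.1, p0 = 0.2, generations = 45,
                           seed = 22), sch, seed = 122)
round(locus$freqs, 3)
#> [1] 0.290 0.464 0.780 0.949 0.909
delta_f(locus); logistic_beta(locus, weights = "none"); temporal_fst(locus)
#> delta-f 0.0157, logistic beta 0.0876, temporal Fst 0.399

# 4. a neutral scan threshold at the population's effective size
thr <- neutral_thresholds(ne = 172, initial_freqs = runif(1000, 0.5, 0.95),
                          schedule = sch, tail = 0.05, n_sim = 10000, seed = 15)
thr
#> neutral |delta-f| threshold 0.01272 (tail 0.05, Ne 172, 10000 sims)
```

The locus's Δf (0.0157 per generation) exceeds the simulated neutral
95% threshold (0.0127), so it would be flagged by the scan. `run_power_grid()`
quantifies how often that happens: at s = 0.1 from initial frequency
0.2 with census observation, Δf detects ~99% of selected loci at a 5%
false-positive rate.

The full pipeline — ancestry, diversity, N_e, scans, spectra, power —
runs from one configuration:

```r
run_full_analysis(default_config(seed = 1, out_dir = "temposcan_out"))
```

or from the shell via the bundled wrapper
`inst/cli/temposcan all --config cfg.yaml --seed 42 --out DIR`
(subcommands `ibs`, `ancestry`, `diversity`, `ne`, `scan`, `spectra`,
`power`). Outputs are TSVs with `#` metadata headers plus a run log.

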