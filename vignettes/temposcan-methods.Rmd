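---
title: "temposcan: models, conventions and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{temposcan: models, conventions and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(temposcan)
```

`temposcan` analyses panels of near-homozygous crop varieties typed at
biallelic SNPs as a time-serial population-genetics experiment: decade
cohorts of released varieties are treated as sequential samples of one
evolving population. This vignette records the models the package
implements, the conventions and defaults it fixes, and the reasoning
behind the choices that were genuinely open.

## Data model and call conventions

Genotypes are coded 0/1 for the two homozygotes, 2 for a heterozygote,
`NA` for missing. Inbred lines carry one effective haplotype, so all
allele counting is haploid: a line contributes one allele, a
heterozygous call contributes half an allele to each, and missing calls
leave the denominator. Residual heterozygosity in real chip data of
this kind is ~0.03% and mostly technical, which motivates three
consistent conventions used throughout:

* **IBS and π**: heterozygote vs homozygote scores a half-match
  (half-difference); heterozygote vs heterozygote a full match. This
  keeps both statistics bounded in [0, 1] without letting a handful of
  technical heterozygotes dominate. The scoring of heterozygotes inside
  an IBS is not something the upstream tools document, so the half-match
  rule is our own documented convention, not an inference.
* **Ancestry matching**: a heterozygous call in a line (or ancestor)
  agrees with either allele — the burden of discriminating donors is
  passed to flanking markers. Missing calls break a match run
  (conservative).
* **Haplotype spectra**: lines with a heterozygous or missing call
  inside a window are excluded from that window's denominator, since a
  partial string is not a haplotype observation.

Maturity groups 00/0/I, III/IV and V+ define three populations; MG II
lines are excluded because they migrate between the flanking clusters
over time. Years of release fold into decade cohorts (`pre1970s`,
`1970s`, ..., `2000s`) mapped to generations 0, 15, 25, 35, 45 — a
pooled three-decade base population followed by roughly one effective
generation per year of modern breeding.

## Ancestry tracing

For each marker of each line, the match extent to an ancestor is the
length (in markers) of the maximal run of agreeing markers containing
that marker; runs truncate at chromosome ends. The marker is attributed
to the ancestor with the longest extent only if it exceeds the second
longest by strictly more than `margin_threshold` (default 5 markers) —
ties and near-ties are `AMBIGUOUS`. Extents are measured in marker
counts with one genome-wide threshold because markers on the emulated
chip were chosen at roughly even genetic spacing (~0.1 cM per
interval). Two conventions were open and are fixed as follows: the
focal marker is counted once in the extent (any double-counting shifts
all extents equally and cannot change an argmax or a margin), and a
run-length two-pass scan computes all extents in O(lines × ancestors ×
markers), with a brute-force per-marker expansion retained in the test
suite as the oracle.

Fractional contributions divide each ancestor's attributed markers by
all unambiguous attributions, pooled over a population's lines;
ambiguous markers are reported separately and are not in the
denominator. Ancestors above a 0.03 fraction are "founding ancestors".

## Diversity windows

π is the mean over line pairs of the proportion of comparable markers
at which the pair differs, in 50-marker windows advanced by 10 (final
partial window dropped). Windows are defined on the per-chromosome
marker index, not bp; bp spans are reported from the first and last
marker positions. The ratio log₂(π_x/π_a) is capped at ±8: a focal
window with π_x = 0 prints the cap (the "< −8" reporting convention),
and a window with π_a = 0 is masked as undefined. Sub-threshold
windows (default threshold −2.3 log₂ units) merge into regions when
overlapping or adjacent; each region reports the minimum-ratio
window's center marker as its midsite and the percent of founding
ancestors whose haplotype matches the focal population's major
50-marker haplotype there.

## Temporal statistics

All three per-locus statistics act on the major allele of the first
cohort (polarity fixed per locus):

* **Δf** is the ordinary least-squares slope of frequency on
  generation. Timepoints are used up to and including the first at
  which the frequency passes the fixation bounds (< 0.05 or > 0.95);
  later points carry no information about the rate of change and are
  dropped. Series left with fewer than two points return 0 with a
  flag.
* **Logistic β** is the slope of a binomial-family regression of
  frequency on generation, over all timepoints (no truncation — the
  logistic link saturates at the boundaries by itself). The package
  fits by iteratively reweighted least squares vectorized across loci
  and reproduces `glm(y ~ x, family = binomial)` on proportions;
  binomial weighting by sample size is available and is the default
  when sample sizes exist, but the power analysis uses unweighted
  proportions, matching the simple regression convention. Complete
  separation (every observed frequency exactly 0 or 1) yields a signed
  infinite sentinel with a flag.
* **Temporal F_st** contrasts homozygosity within the first and last
  (post-truncation) timepoints against the pooled mean frequency:
  with J_t = p_t² + (1−p_t)², J_w = (J_first + J_last)/2, p̄ the mean
  of the end frequencies and J_b = p̄² + (1−p̄)²,
  F_st = (J_w − J_b)/(1 − J_b). The source analysis cites a textbook
  probability-of-identity definition without printing a formula; this
  two-sample homozygosity contrast is our instantiation, stated here
  and used consistently everywhere, including the power study. Both
  ends fixed for the same allele give 0 with a flag.

## Wright–Fisher simulation

The forward simulator is haploid (ploidy 1 — recombinant inbred lines
carry one effective haplotype): each generation applies deterministic
selection then binomial reproduction with `N` haploid individuals.
The selection update gives the favored allele relative fitness 1 and
the alternative 1−s, i.e. `p* = p/(1−s+ps)`. The more common
`p(1+s)/(1+ps)` parameterization differs only at O(s²), but at s = 0.1
over 45 generations the difference is material, and reproducing the
reference power values across all 54 benchmark cells discriminates clearly in
favor of 1-vs-(1−s); the package therefore adopts it and documents s
as selection against the alternative allele. Frequencies absorb at 0
and 1. With s = 0 the simulator matches the closed-form drift variance
p(1−p)(1−(1−1/N)^t) — the primary correctness oracle in the tests.

Sampling draws binomial counts at each scheduled timepoint (census
mode returns population frequencies exactly). Lines are sampled with
replacement in the model; for the cohort sizes involved (~20–60 lines
from populations of hundreds) the with-/without-replacement difference
is negligible.

## Effective population size

The likelihood of one locus is the probability of its observed counts
under an exact neutral haploid Wright–Fisher Markov chain on states
0..N with binomial emissions; the initial state follows its posterior
given the first sample, so the likelihood is conditional on the first
observation (Williamson–Slatkin-style conditioning) and ascertainment
filters applied to the first sample (such as the 0.5–0.6
initial-major-frequency filter) cannot bias it. Loci are independent.
Three numerical points matter:

* **Initial-state prior.** The conditioning posterior needs a prior
  over states. The default is uniform, the right diffuse choice for
  common-variant chip markers whose folded frequency spectra are
  nearly flat. Estimating the prior from the filtered loci themselves
  is circular (the filter collapses the apparent spectrum) and was
  rejected; callers holding the population's unfiltered spectrum can
  pass it via `initial_prior`.
* **Census data.** An observed census frequency pins the chain state
  only up to the candidate grid's resolution. Observations are
  interpolated linearly onto the two flanking states (nearest-state
  rounding aliases the likelihood between adjacent N), and a +log N
  per-observation bin-width term converts state probabilities to
  densities so that likelihoods are comparable across candidate N —
  without it, coarser chains always win.
* **Search.** The likelihood is evaluated on an integer grid (step 1
  up to N = 400, step 5 above, bounds 20–1000). Because each
  evaluation builds (N+1)×(N+1) transition-matrix powers, the grid is
  searched with a memoized golden-section routine started from a
  moment (standardized-variance) estimate and expanded when the
  optimum lands on a bracket edge, rather than scanned exhaustively;
  under the observed smooth unimodal likelihood this finds the same
  grid optimum at a fraction of the cost. The 95% CI comes from the
  likelihood-ratio statistic (χ², 1 df) by bisection on the same
  memoized grid.

Parameter recovery for this estimator is tested at the study's scale:
loci simulated at N = 200 on the cohort schedule with the study's
sampling depths, initial frequencies drawn from a broad uniform
spectrum, then filtered to observed initial major frequency 0.5–0.6 —
5000 loci per replicate, 20 replicates. Reported N is haploid; because
the lines are inbred, one individual carries one effective haplotype,
and no diploid doubling applies.

## Neutral thresholds and power

Scan thresholds are the (1 − tail) quantile of |Δf| over simulated
neutral loci at the estimated N_e, with initial frequencies resampled
from the population's observed spectrum and the cohort sampling depths
applied (default 10⁴ simulations, 5% tail).

The power study simulates, per cell (sampling mode × initial frequency
× selection coefficient), `reps` selected and `reps` neutral loci from
the same initial frequency, computes |statistic| for each, and
calibrates the detection threshold on the neutral arm. Because
sampled-depth statistics are discrete, a neutral atom can sit exactly
at the 5% tail; the package therefore uses the exact randomized test —
threshold at the k-th largest neutral value with fractional counting
of the boundary atom — which achieves exactly the nominal
false-positive rate for discrete statistics and removes threshold
flips between atoms. Fixation truncation applies to Δf and F_st but
not to the logistic fit, and absolute values are used throughout
(polarity of selection is unknown in real data). Default `reps` is
5000 per arm (power SE ≤ 0.7 points); the acceptance script uses
20,000.

Two caveats for interpreting power values near heavy absorption
(initial frequency 0.2 with strong selection): the |β| of a
completely separated logistic fit is an artifact of the fitting
algorithm's stopping rule, so power values for that statistic in
absorption-heavy cells are implementation-defined — the package
matches modern `glm` exactly, which need not match other software; and
in cells where a neutral atom straddles the 5% boundary the power is
intrinsically knife-edge at any replicate count.

## Sweep classification and spectra

A window is `hard` when its top-3 |Δf| (mean of the three largest
per-marker values — one marker is too noisy, fifty too insensitive)
reaches the population's Δf threshold *and* its 2000s-vs-pre-1970s
diversity ratio falls below −(diversity threshold); `soft` with the
allele signal but not the diversity collapse; `sneak` with the
collapse but no fast allele; `neutral` otherwise. Diversity thresholds
are positive magnitudes of log₂ reduction. Cross-population candidates
are markers beyond their source population's threshold whose allele is
fixed (≥ 0.95 or ≤ 0.05, reusing the fixation bounds) in the opposite
direction in another population; their Δf values are exported ×1000
as a presentation convention only.

Haplotype spectra track exact 50-marker strings between cohorts; the
first seven early-cohort identities keep stable ranks and the rest
lump as OTHER for display, but changes are computed on raw strings.
Haplotype change uses the first and last cohorts only, whereas allele
Δf uses all cohorts with truncation — the asymmetry is intentional and
preserved. The sneak-vs-neutral comparison of the ratio
(max haplotype change)/(max single-marker change) uses a label
permutation test on the median difference (default 10⁵ permutations),
chosen because it needs no distributional assumption for a ratio with
a hard upper bound. H (average pairwise shared-tract length containing
a marker) counts a pair as 0 at markers where it differs — the
alternative of skipping such pairs would make H undefined at fixed
differences; lengths are in markers, with a bp mode available.

## Synthetic data: what it does and does not emulate

The generators reproduce the *structure* of the real study system —
ancestor panels with controllable relatedness including near-duplicate
pairs (IBS 0.90), recombinant-inbred crossover mosaics with
weight-proportional expected contributions and full ground truth,
decade cohorts, and drift/selection/sampling on the cohort schedule.
Each simulated line draws two parents (weighted, with replacement) and
one crossover mosaic (Bernoulli(0.001) per marker interval, no
interference), then selfs to homozygosity; cohorts are independent
draws rather than a connected multi-generation pedigree, and no
phenotypic selection acts in the breeding simulator — selection is
exercised through the Wright–Fisher path. Real data additionally
contain linkage disequilibrium between selected and neutral loci,
pedigree correlation between cohorts, ascertainment bias of chip
markers and genotyping error beyond the modeled HET/missing rates; a
passing test suite therefore validates the algorithms and their
implementation, not the biological conclusions one would draw from any
particular real panel.

Test and demonstration problem sizes are deliberately modest (hundreds
of lines, 10³–10⁴ markers, 5000-locus N_e replicates, 5000–20,000
power replicates); all scale linearly except the N_e likelihood
(quadratic-to-cubic in N), and all accept user-chosen sizes.

## Known limitations

* The N_e likelihood assumes unlinked loci; with chip-scale LD the
  effective number of independent loci is smaller and CIs are
  anti-conservative on real data.
* Ancestry tracing assigns one donor per marker; genuinely admixed
  short segments between near-identical ancestors are returned as
  AMBIGUOUS rather than probabilistically split (no HMM).
* The logistic β of fully separated series is implementation-defined
  (see above); comparisons across software will differ in
  absorption-heavy regimes.
* ADMIXTURE-style model-based structure inference, PCA diagnostics and
  ABC estimation of selection coefficients are out of scope.
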