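---
title: "Divisive shuffling: model, parameters, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Divisive shuffling: model, parameters, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vista)
```

## The problem and the inversion

Classifying a heterogeneous cohort by a single clinical cut-point and
testing for differential expression between the resulting groups usually
fails: most clinical characteristics, taken alone, do not align with any
expression axis. Divisive shuffling inverts the direction of inference.
It searches *partition space* for divisions of the cohort that maximize
the number of differentially expressed (DE) genes between two groups, and
only afterwards asks which clinical characteristics the optimized groups
differ in. Because the search is stochastic and restarted many times, it
returns a population of locally optimal divisions rather than one
clustering; the analysis object is that population.

## The optimizer

A division assigns every subject to GROUP1, GROUP2 or a RESERVOIR. The
reservoir (default 40 subjects of a 140-subject cohort) keeps the
comparison groups at roughly the size of an extremes-of-phenotype
comparison — the same power regime as comparing the lowest against the
highest quartile of a clinical variable. With `reservoir_size = 0` the
method degenerates gracefully to two-group shuffling; swaps then exchange
one member of each comparison group.

Each attempt proposes exchanging a uniformly chosen comparison-group
member with a uniformly chosen reservoir member, and accepts the swap if
and only if the DE-gene count strictly increases. Ties are rejected by
default; `accept_ties = TRUE` turns the plateau phases into an unbiased
drift, which explores more but converges less sharply. A run is a fixed
budget of `max_attempts = 2000` proposals. We deliberately did not make a
plateau criterion the default stopping rule — "no improvement for w
attempts" (`plateau_window`) is available, but a fixed budget makes every
run's cost and RNG stream identical, which in turn makes the 500-run sweep
bit-reproducible. Per-run seeds derive from the master seed by a counter
(`master * 1000003 + run_index`, reduced mod 2^31 − 1), so runs share no
state and can be distributed.

## The SAM objective

The objective engine is a two-class unpaired SAM (Significance Analysis of
Microarrays) implementation:

* **Statistic.** `d_i = (mean2_i − mean1_i) / (s_i + s0)` with `s_i` the
  pooled gene-wise standard error. `s0` is selected once per evaluation by
  the percentile search: candidates are the 0, 5, …, 100 percentiles of
  the `s_i`, and the winner minimizes the coefficient of variation of the
  windowed median absolute deviation of `d` across standard-error
  windows (100 windows, reduced so each holds at least ~5 genes; ties go
  to the smallest candidate). `s0_mode = "fixed"` bypasses the search.
* **Calling.** Sorted observed `d` is compared with the expected order
  statistics `dbar` (average of per-permutation sorted `d`, sharing the
  observed `s0`). For a threshold `delta`, the positive cut is the
  smallest observed `d > 0` whose excess over `dbar` reaches `delta`, and
  symmetrically below zero; every gene beyond a cut is called. `delta` is
  scanned on a 0.01 grid.
* **FDR.** At each `delta` the estimate is the mean, over permutations, of
  the number of permuted genes beyond the cuts, divided by the number of
  observed calls, with the null proportion fixed at 1 (conservative). The
  reported division uses the smallest `delta` whose estimate is at or
  below `fdr_threshold`. Per-gene q-values are the smallest estimate at
  any `delta` calling the gene.
* **Permutations.** Group labels are permuted over the combined comparison
  groups; when the requested permutation count reaches the number of
  distinct label assignments, assignments are enumerated exhaustively.
  Inside the optimizer the permutation assignment set is generated **once
  per run** and reused at every swap, so the objective is a deterministic
  function of the partition and accept/reject comparisons are coherent;
  a re-randomized objective would make hill-climbing incoherent.
* **Numerical conventions.** The group orientation is canonicalized (the
  group holding the lexicographically smallest subject id goes first)
  before permutations are drawn, which makes the called set exactly
  invariant under exchanging GROUP1 and GROUP2 while the sign of `d`
  follows the caller. Values within 10⁻⁹ of a cut count as beyond it, so
  a permuted assignment that equals the cut by symmetry but is recomputed
  through a different arithmetic path is not lost to float jitter.

Two estimator choices deserve justification. First, the **mean** (not
median) false-call numerator: the automated smallest-`delta` search
evaluates hundreds of candidate cuts, and a singleton cut at the observed
extreme has *median* false count zero whenever more than half the
permutations fall short of the observed maximum — on pure-noise data that
manufactures one spurious call about half the time, at any permutation
count. The mean numerator never estimates a permutation tail as exactly
zero in that situation and restores near-nominal null behaviour. Second,
even with the mean numerator, automating the `delta` choice is a maximum
over many correlated cuts; on null data small spurious call sets still
appear in roughly 10–20% of data sets at FDR 0.05. The historical practice
of fixing `delta` by inspection does not have this selection effect; an
automated pipeline cannot avoid it, only document it.

The Welch-t/Benjamini–Hochberg engine (`engine = "ttest"`) is a fast
alternative objective: per-gene Welch t-test, BH across genes, calls at
adjusted p ≤ threshold. A gene with zero variance in both groups is
assigned p = 1 rather than an infinite statistic. Defaults: 100
permutations inside the optimizer, 1,000 for reported comparisons — the
permutation analysis dominates run time, exactly as expected for repeated
SAM evaluation.

## Trait testing, co-occurrence, baseline

Each converged division is tested per characteristic: Mann–Whitney U for
continuous **and ordinal** traits (ordinal scores are rank statistics
anyway), Fisher's exact test for binary traits, significance at p ≤ 0.05
inclusive. The Mann–Whitney implementation uses the exact null
distribution when both groups have at most 8 observations and no ties,
and otherwise the midrank normal approximation with tie-corrected
variance and no continuity correction. Missing clinical values simply
drop out of the comparison; a trait unobserved in one whole group is
untestable for that division and never enters the significant set. No
multiple-testing correction is applied across traits or divisions — the
frequency of a trait across divisions is itself the statistic of
interest — but the matrix of raw p-values is exported for users who want
to apply one.

Trait tuples (pairs, triplets, quartets) are counted across runs and
tested against the independence null: with per-trait frequencies
`k_c / R`, the joint probability under independence is their product
`p0`, the expected count is `R·p0`, and the p-value is the upper tail of
`Binomial(R, p0)` — an enrichment test only, since the question is which
combinations appear *more* often than chance. Tuples containing a
never-significant trait are skipped (the null is degenerate there). The
same counting applied to uniformly random divisions of identical group
sizes (default 10,000) gives the chance baseline that optimized divisions
must beat.

## Subtypes, set decomposition, enrichment

`single_trait_analysis()` reproduces the forward direction: split by
clinically motivated bins of one characteristic (cut-points or category
lists; low/high extremes must be disjoint and non-empty) and count DE
genes at the reporting threshold FDR < 0.05. Subtype A/B sides are
config-driven rule expressions over clinical columns rather than
hard-coded cut-points, because extreme-bin definitions are
cohort-specific. Per-subtype DE sets are decomposed into unique sets,
the common core, and all 2^k membership cells, so any convention for
"shared by some but not all" can be read off; the common core can be
overlapped against a reference comparison (e.g. the severity extremes).
Fold changes on log2-scale data are `2^(meanB − meanA)` — a ratio of
geometric means, the natural choice on the log scale — with the ≥ 2-fold
boundary inclusive. Over-representation uses the one-sided Fisher
(hypergeometric upper tail) with the universe fixed to the genes on the
matrix and every pathway clipped to that universe; raw p-values are
reported with a BH column alongside, matching how such tables are usually
presented.

## The synthetic cohort

The generator emulates the structure of the motivating study: 140
subjects in two latent classes of 70 (moderate vs severe airflow
limitation), array-like log2 intensities `N(mu_g + delta_g·class, sd)`
with `mu_g ~ N(8, 1.5)`, a planted subset of genes with a constant class
shift, and a 16-characteristic panel (ordinal severity grade, two
correlated-by-construction emphysema readouts, BMI, phlegm, age, walking
distance, cough, sex, and blood biomarkers) whose association strength
with the latent classes is tunable per trait. Continuous traits are
`strength·class + N(0,1)`; ordinal traits cut that latent variable into
five levels; binary traits flip toward the class with probability
`plogis(strength·(2·class − 1))`. Everything is a deterministic function
of the seed.

What the generator does **not** emulate: gene–gene correlation (beyond an
optional planted block), count-distribution noise, batch effects, probe
artifacts, and sputum cell-composition confounding. Passing tests on this
generator therefore validate the machinery — the statistics, the
bookkeeping, the search contract — not robustness to real-data artifacts.

Test and demonstration sizes are deliberately small: 300–2,000 genes,
24–60 subjects, tens of runs with a few hundred attempts. These sizes were
chosen so that a full validation sweep is an interactive-scale
computation; the `full_scale` scenario (20,000 genes, 500 runs × 2,000
attempts) documents the full-size design without being exercised in the
test suite.

## Known limitations

* **The count objective is a step function.** At desk scale — a few dozen
  subjects, a few hundred genes, sparse planted effects — the DE count at
  a calibrated FDR is exactly zero over most of partition space, and a
  strict-increase hill climb cannot leave a start inside that plateau.
  Measured on the 40-subject scenario with 30 planted genes, most random
  starts never move. On full-scale cohorts with pervasive real signal the
  objective is essentially never zero, which is the regime the method was
  designed for.
* **Saturation.** Strong uniform effects saturate the count: once every
  planted gene is called (which happens well short of full class
  alignment), the objective is flat between partially and perfectly
  aligned divisions, so converged divisions approximate, rather than
  reproduce, a planted labeling. Graded effect profiles do not saturate
  this way.
* **Maximization overfits.** Selecting the division that maximizes a
  data-dependent count inflates it; converged divisions can exceed the
  planted division's own count by co-opting noise genes. The
  random-division baseline exists precisely to quantify what maximization
  alone can achieve.
* **Automated delta selection** carries a selection effect over candidate
  cuts (see above); single-comparison SAM results at FDR 0.05 should be
  read with that ~10–20% per-data-set spurious-call rate in mind — the
  co-occurrence analysis, which aggregates over hundreds of divisions, is
  insensitive to it.
* The manifest records seeds, parameters and input digests but not wall
  time, so that rerunning a configuration reproduces every artifact byte
  for byte.
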