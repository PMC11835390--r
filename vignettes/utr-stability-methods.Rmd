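---
title: "Modelling UTR variant effects on RNA stability: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling UTR variant effects on RNA stability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(utrstab)
```

# The measurement and its model

A reporter library carries thousands of short (75–155 nt) UTR fragments,
each present as a reference (ref) allele and a mutant (mt) allele differing
by a single edit. After transcription stops, the relative abundance of each
oligo is followed by amplicon sequencing over a handful of timepoints with a
few replicates each. Under first-order decay, the log abundance of oligo
$i$, normalized to its baseline, falls linearly in time:

$$\ln\frac{C_i(t)}{C_i(0)} = -\lambda_i t + \epsilon_i,
\qquad t_{1/2} = \frac{\ln 2}{\lambda_i}.$$

`normalize_counts()` divides every replicate's counts by the mean baseline
count of that oligo (the first harvest is re-indexed to $t = 0$), and
`fit_decay()` estimates $\lambda_i$ by weighted least squares through the
origin. Weights are the inverse of the per-timepoint standard deviation of
the log-normalized values across replicates; a timepoint with zero spread
receives the largest finite weight observed for that oligo, and fits pass QC
when $R^2 > 0.5$ and the weighted mean squared error is below 1. For the
no-intercept model $R^2$ is the uncentered version
$1 - \sum w e^2 / \sum w y^2$ (the centered form is undefined without an
intercept); the weighted MSE is $\sum w e^2 / \sum w$.

## Compositional counts and the spike-in anchor

Every sequencing library is sampled to a fixed read depth, so counts are
*compositional*: they carry information about relative, not absolute,
abundance. If all species decay, each timepoint's library is re-scaled by
the surviving total mass $S(t)$, and every naive slope estimate is shifted
by the library-average decay rate — a bias that no per-oligo normalization
can remove, because the absolute scale is simply not identifiable from
proportions. The pair test is immune (both alleles share the shift), but
absolute half-lives are not.

The simulator therefore models a non-decaying spike-in species occupying a
configurable fraction of the baseline reads (`spike_in_fraction`, default
0.2), the same role that 18S rRNA or external spike-ins play in bench decay
assays, and `normalize_counts()` measures every log abundance relative to
the spike-in when a `"spike_in"` row is present. With the anchor in place,
simulated decay rates spanning $\lambda t_{max} \in [0.2, 3]$ at depth
$10^6$ are recovered with a median relative error of about 1%; without it
the median error is roughly 60%. Real libraries lacking any stable
reference should be interpreted on the relative scale only.

# Testing variant effects

For each ref/mt pair the pooled normalized series are fit with a
genotype-by-time interaction:

$$\ln\frac{C_i(t)}{C_i(0)} = \beta t_i + \theta\, t_i G_i + \epsilon_i,$$

with $G = 0$ for ref and $1$ for mt, so $\theta$ is the variant's effect on
the decay rate; `test_pairs()` reports its two-sided p-value,
Benjamini–Hochberg q-values (`adjust_fdr()`; a Storey-type variant with the
fixed-$\lambda = 0.5$ estimate of $\pi_0$ is available), and a
classification into destabilizing ($\theta < 0$), stabilizing or not
significant at a configurable q threshold.

Two implementation choices depart from the textbook form of the model
above, and both exist because the calibration of the test demanded them:

* **Per-allele intercepts.** The baseline normalizer
  $\bar C_i(0)$ is itself a noisy estimate; its error shifts all of an
  allele's log values by a common constant. A through-origin fit cannot
  absorb that shift, and it leaks into the slope and its standard error: in
  null simulations at the study's design scale the nominal 5% test rejected
  27% of the time. Giving each allele its own intercept absorbs the shared
  normalization error and restores the nominal level (4–7% across seeds).
  `intercept = FALSE` recovers the plain printed form for sensitivity
  analysis.
* **Count-based weights.** Per-timepoint standard deviations estimated
  from only three replicates are extremely noisy, and weights correlated
  with the residuals they divide are a classic source of anticonservative
  tests: in drift-free null simulations, inverse-SD weights (even pooled
  across the two alleles) gave 6.8% rejections at the 5% level and a
  two-to-three-fold inflated far tail — precisely the tail that drives
  false discoveries after FDR correction. The default therefore weights
  each observation by its read count, the Poisson inverse variance of a
  log count: fully determined by the data, so the t reference distribution
  stays clean (5.1% at the 5% level, calibrated tail), while still
  downweighting the low-count late timepoints of fast decayers.
  `weights = "pooled_sd"` restores the classical inverse-SD weighting and
  `weights = "none"` disables weighting for sensitivity analysis.

Zero counts after the baseline are replaced by a pseudocount (default 0.5)
before logging; oligos that are all-zero after baseline, or whose baseline
mean is zero, are dropped and itemized rather than raising errors. A
separate, threshold-based rule (`classify_pairs_by_foldchange()`) calls a
pair significant when the half-life ratio in either direction reaches
1.5-fold.

# Feature construction

`build_feature_matrix()` assembles per-oligo features with a category tag
per column: overlapping k-mer ratios for $k \le 3$ (the `UA` 2-mer column
*is* the UA-dinucleotide ratio), GC content, AU-rich element counts (the
AUUUA/W-flanked family plus UUUGUUU, GUUUG and AWUAAA, scanned as IUPAC
patterns with W = A/U), the five Kozak context classes, PWM match counts,
TargetScan-style miRNA seed sites (8mer, 7mer-m8, 7mer-1a; each locus
counted once as its best type), interval-track overlaps (binary presence or
per-position mean score) and user-supplied precomputed columns such as
folding energies — thermodynamic quantities are accepted as inputs, never
computed here. Sequences are normalized to the RNA alphabet on ingest.

PWM scanning counts windows scoring at least a fraction (default 0.9) of
the matrix's maximum attainable score; the threshold is a convention, so it
is exposed as a parameter. IUPAC and plain pattern counting go through
Biostrings; PWM window scoring is computed directly because the package's
definition — a fraction of the maximum attainable score — must hold exactly
for any weight matrix, including negative log-odds entries.

# Collinearity-aware LASSO selection

Composition features are massively redundant. The selection pipeline
(`select_features()`) mirrors a practice that keeps the penalized model
interpretable:

1. `sparse_filter()` removes features that are ≥ 90% zeros.
2. `cluster_features()` builds a single-linkage tree under the distance
   $1 - |\rho_{Spearman}|$.
3. `select_height()` walks a fixed height grid (step 0.01) from 0 upward;
   at each cut, each cluster is represented by its most influential member
   (largest absolute univariate coefficient on the standardized feature,
   i.e. largest $|cor|$ with the response; ties go to the
   lexicographically smallest name), until every representative's VIF
   ($1/(1-R_j^2)$, computed by regressing each representative on the
   others) falls below 5. The fixed grid makes the cut reproducible
   run-to-run; stepping over the tree's own merge heights is available as
   an option.
4. `lasso_fit()` minimizes
   $\sum_i (y_i - \beta_0 - \sum_j \beta_j X_{ij})^2 +
   \lambda \sum_j |\beta_j|$ with $y = \ln t_{1/2}$, choosing $\lambda$ at
   the minimum mean 10-fold cross-validated error. Folds are seeded and
   stratified by response quantile so that repeated runs agree. Confidence
   intervals for the selected coefficients are bootstrap percentile
   intervals (the penalty is held fixed across resamples), and are
   labelled as such.
5. `evaluate_split()` refits on a seeded 2:1 train/test split and reports
   correlation, MAE, RMSE, MAPE (zero-response points excluded and
   counted) and $R^2$ on the held-out third.

# 7-mer motif discovery

`discover_motifs()` regresses log2 half-lives (trimmed to the 1st–99th
percentile; the extreme-value rule is configurable) on the overlapping
7-mer count table, keeping 7-mers occurring at least 20 times in the
library. The regression is repeated over 2000 bootstrap resamples of the
oligos with an L1 penalty re-chosen by cross-validation within each
resample (5-fold by default inside the loop; 10-fold available), and
7-mers selected in more than 80% of resamples (1600 of 2000) advance. Their
coefficient draws are tested against zero by a one-sample sign-flip
permutation test (10,000 flips, seeded) with Bonferroni correction over the
tested 7-mers. Significant 7-mers are split by coefficient sign,
clustered by Levenshtein distance with complete linkage — complete linkage
keeps each cluster's edit-distance diameter within the cut height of 2 —
and each cluster is combined into a PWM whose columns are the
$|$mean coefficient$|$-weighted base frequencies (columns sum to 1).

Two caveats belong here rather than in the API docs:

* The permutation test is a *one-sample sign-flip* construction on the
  bootstrap coefficient draws. The draws of a selected 7-mer are strongly
  dependent (they come from resamples of one dataset), so the p-value
  measures the stability of the sign, not an independent replication.
* Selection counts are a stability measure, not a significance test. A
  cross-validated penalty admits whichever feature happens to be most
  correlated with the response *in the observed data*, and the bootstrap
  preserves that accident: in pure-noise simulations with ~1400 candidate
  7-mers and ~1200 oligos, the most chance-correlated 7-mer exceeds the
  80% selection threshold for both the CV-minimum and the one-SE penalty.
  The procedure is therefore read as ranking motifs by stable effect size,
  with the planted-effect recovery tests showing that real effects of the
  magnitude studied here dominate the chance-correlation floor.

# UA-dinucleotide profiling

`ua_ratio()` is the overlapping UA count over $(\mathrm{len}-1)$;
sequences under 10 nt are excluded. `sliding_profile()` slides a 10-nt
window by 1 nt, then averages the window ratios into 100 position-fraction
bins so that profiles of different lengths align; with fewer than 100
windows, empty bins inherit the nearest non-empty bin's value (a sequence
of exactly 10 nt yields one window replicated across all bins).
`window_correlation()` correlates each bin with half-life (Spearman).
`group_enrichment()` compares a gene group's mean UA ratio with the
background of all transcripts by label permutation (Fisher–Pitman style;
the statistic is the plain mean difference, not a studentized variant),
10,000 seeded draws by default with complete enumeration when feasible,
Bonferroni correction across tested groups, and an adjusted-p threshold of
0.01. Groups need more than 20 qualified members; the permutation pool is
sorted by value, making p-values invariant to how the background was
ordered. `interaction_fit()` fits
$t_{1/2} \sim \mathrm{UA} + \mathrm{GC} + \mathrm{UA}\times\mathrm{GC}$ by
OLS, and `stratified_effect()` reports the UA slope within GC strata (or
vice versa) under median or quartile splits.

# SLAM-seq style in-vivo half-lives

T→C conversion tables are filtered per position (coverage at least 10;
conversion rate at most 0.8, above which a position is treated as a SNP —
both read as strict versions of "less than 10" and "larger than 0.8", so
the boundary values are kept), pooled into per-transcript,
per-timepoint, per-batch rates `ttoc / (ttoc + t_total)`, and transcripts
lacking two batches at any timepoint are dropped. Rates normalized to the
baseline mean then go through *the same* weighted no-intercept fit engine
as the reporter assay, with batches playing the role of replicates. The
conversion-rate signal decays with the labelled transcript, so
$\ln(N(t)/N(0)) = -\lambda t$ estimates the in-vivo decay rate directly;
no compositional anchor is needed because rates are internally normalized
per position.

# The synthetic-data generator

`sim_config()` + `generate_library()` + `simulate_counts()` +
`simulate_conversion_tables()` generate the full study design with known
truth. Defaults mirror the assay: pairs of 75–155 nt fragments differing
by one substitution (1–2 nt indels behind a flag), three timepoints
(30/75/120 min) with the first as baseline, three replicates, and depth
$10^6$. Base composition varies per pair: a GC fraction drawn from
(0.25, 0.65), an A/U balance from (0.35, 0.65), and — crucially — an
independent target UA-dinucleotide ratio from (0.02, 0.12), reached by
boosting the U→A transition probability of a first-order Markov chain.
Under plain i.i.d. sampling the UA ratio is a deterministic mirror of GC
content ($E[\mathrm{UA}] = p_U p_A$), which would confound the two axes of
the rate model; real UTRs vary their UA content largely through base
*ordering*, and the Markov targets reproduce that, cutting the UA–GC rank
correlation from about $-0.7$ to $-0.4$. A single fixed composition vector
remains available (`vary_composition = FALSE`). Per-oligo decay rates
follow a log-linear composition model,

$$\log\lambda = a_0 + a_{ua}\mathrm{UA} + a_{gc}\mathrm{GC}
 + a_{int}\mathrm{UA}\cdot\mathrm{GC} + a_{motif} m + \epsilon,$$

with defaults ($a_{ua} = 3$, $a_{gc} = -1.5$, $a_{int} = 2$,
$\sigma = 0.3$, $a_0 = -4.1$) chosen so UA destabilizes, GC protects, the
protective GC effect weakens at low UA, and half-lives center near an hour
— the qualitative structure the analysis is designed to detect. The noise
draw is shared within a pair by default (`pair_noise`), which makes pairs
exact nulls when all effect coefficients vanish; per-oligo noise is a
flag. Initial abundances are log-normal with `abundance_sdlog` = 0.25 —
the library's true abundance dispersion is not known, so it is an exposed
parameter rather than a guess baked in. Counts are a single multinomial
draw of size `depth` per timepoint/replicate with probabilities
proportional to $m_i e^{-\lambda_i t}$ (plus the spike-in mass), and
conversion tables are binomial draws at the configured coverage from a
baseline conversion rate (default 0.1, required to be inside (0, 0.8))
decaying as $e^{-\lambda t}$.

What the generator does *not* emulate: PCR/UMI artifacts, transfection
efficiency, replicate batch effects beyond multinomial sampling,
cell-line-specific trans factors, secondary-structure-driven decay, or any
coupling between sequence and initial abundance. Passing tests therefore
demonstrate that the estimators and tests are correct and calibrated under
first-order decay with multinomial sampling — not that real libraries meet
those assumptions.

Every stochastic stage takes its seed from the config (with fixed
per-stage offsets, so stages can be re-run independently) or as a `seed`
argument, and is bit-reproducible given it.

# Problem sizes used by the shipped checks

The test-suite simulations use 500 oligos for rate recovery, 2000 pairs for
null calibration, 500 pairs for power, 20 seeds of 500 oligos for the
selection pipeline, 10 seeds of a 1200-oligo library with 2000 bootstrap
refits for motif discovery, 2000 null groups for the enrichment level, 200
datasets for interaction-coefficient coverage, and coverage $10^5$
conversion tables — sizes at which the binomial/multinomial sampling error
is small relative to the effects being measured while the whole suite
remains quick to run. Empirical false-discovery control is measured on
mixed simulations (10% true effects) pooled over 20 seeds: under a global
null the realized false-discovery proportion of any BH analysis is a 0/1
indicator and its 20-seed average is too unstable to assert a meaningful
bound.

# Known limitations

* Absolute half-lives require a stable reference in the sequenced pool;
  without one, everything is relative to the library-average decay.
* The motif stage's selection counts carry the chance-correlation floor
  described above; motif claims should rest on effect sizes and
  replication, not the Bonferroni p alone.
* The weighted fits treat timepoints as independent; residual
  autocorrelation along the time course (e.g. a shared early burst) is not
  modelled.
* Interval features assume all coordinates are on one assembly; no
  liftover is attempted.
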