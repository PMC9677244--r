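---
title: "Quantifying spiking burstiness in working-memory recordings: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying spiking burstiness in working-memory recordings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spikewm)
```

## The scientific setting

`spikewm` analyses trial-structured single-unit recordings from a modified
Sternberg working-memory task. Each 8-s trial starts with 1 s of fixation,
followed by 2 s of encoding (a set of 4, 6 or 8 letters), 3 s of maintenance
(blank screen), and a probe period that ends at the subject's response;
because the recording stops at 8 s, responses later than 2 s after probe
onset leave the tail of the probe period unrecorded. Units carry an
anatomical label (hippocampus, amygdala, entorhinal cortex).

The package asks how *irregular* the spiking is — beyond what firing rates
alone say — and how that irregularity relates to memory load, behaviour and
population coordination. Five analysis layers build on each other:
irregularity of single (and merged) spike trains, change points, population
bursts, mean-matched Fano factors, and burstiness-stratified decoding.

## The LvR statistic

For consecutive inter-spike intervals $I_1,\dots,I_n$ the
refractoriness-corrected local variation is

$$
LvR \;=\; \frac{3}{n-1}\sum_{i=1}^{n-1}
 \left(1-\frac{4 I_i I_{i+1}}{(I_i+I_{i+1})^2}\right)
 \left(1+\frac{4R}{I_i+I_{i+1}}\right),
$$

with $R$ the refractoriness constant — 5 ms for single units, 0 for merged
trains, where a refractory correction makes no physiological sense. LvR is
about 1 for Poisson firing, below 1 for regular and above 1 for bursty
trains; being built from interval *ratios* it is invariant to a common
rescaling of all intervals (and $R$), hence insensitive to slow rate drift.
Values are only computed for windows holding at least 5 spikes
(`min_spikes`); sparser windows are reported as missing, never as zero,
and correlations downstream use pairwise-complete points.

For a stationary gamma-renewal train with shape $\kappa$ the expectation of
the local variation is $3/(2\kappa+1)$ — the calibration oracle used
throughout the tests: shape 1 (Poisson) gives 1, shape 2.5 gives 0.5, shape
0.5 gives 1.5.

## Change points

Sudden rate changes are detected by comparing the empirical cumulative
spike count with the uniform expectation of a perfectly regular,
count-matched train. The earliest time of maximal absolute deviation
(evaluated at spike times) is a candidate, accepted when a two-sided
binomial test of the before/after counts (success probability = the
fraction of the window before the candidate) beats the threshold
$P = 1/(1+10^{\mathrm{logit}})$; the search then recurses on the segment
after the accepted change point. The schedule
$\mathrm{logit} = 1.3, 1.5, \dots, 5.9$ corresponds to $P \approx 0.05$
down to $10^{-6}$ — note this pins the logit to base-10; a natural-log
reading would give $P \approx 0.21$ at the lenient end, inconsistent with
that range. Per unit, the logit is raised along the schedule until the
unit's pooled fixation windows (baseline activity) yield no change points;
adaptation is per unit rather than per unit-and-trial so that a unit's
threshold is estimated from all its baseline data.

A localization caveat, verified by simulation: for a 2→10 Hz step in an 8-s
window (≈48 spikes) the argmax of the cumulative deviation carries
irreducible jitter of a few hundred milliseconds — the expected deviation
falls off by only ≈2 counts over 0.5 s around the true step, comparable to
the binomial noise. About 70% of simulated steps are localized within
±0.3 s; tighter localization at these spike counts would require a
different estimator (e.g. likelihood-based refinement), which we do not
apply because the count-based detector is the method under study.

## Time-resolved irregularity and trial variables

LvR is computed in right-aligned sliding windows (2 s, 50-ms or 250-ms
steps; the time index is the window's right edge). Relations with trial
variables use two statistics:

* **Pearson correlation** between pooled (unit × trial) window LvR and
  response times.
* **Rank dissimilarity** between two trial classes (set size 4 vs 6–8, or
  wrong vs correct): pooled values are rank-transformed ascending (average
  ranks on ties), each class's empirical CDF is evaluated on the integer
  ranks $1..N$, and the statistic is the *signed* sum of point-wise CDF
  differences — the area between the curves keeping its sign, which makes
  it direction-aware unlike the earth-mover's distance, and rank-invariant
  to any monotone transform of the values.

Significance always comes from a trial-structure-preserving permutation:
within each session one permutation of the trial variables is drawn per
iteration and shared by all simultaneously recorded units, so the
dependence structure between simultaneous units survives under the null.
Two-sided p-values use the $(1+k)/(n_\mathrm{perm}+1)$ convention so p is
never 0. Merged-train (2- and 3-unit) analyses subsample, per session, as
many combined points as the single-unit pool holds, repeat the test 100
times, and report the median p — keeping the effective sample size
comparable across combination orders.

## Population bursts

Per trial, unit rasters are convolved with a 25-ms Gaussian kernel and
sampled on a 10-ms grid; the population rate is the across-unit mean.
Kernel edges are truncated without renormalization (naive convolution),
which depresses estimates within ~2 bandwidths of 0 and 8 s; we accept this
because events of interest sit well inside the trial. The detection
threshold is the mean plus three standard deviations (sample s.d., $n-1$)
of the per-trial unit-averaged whole-window rates. Runs above threshold
lasting ≥100 ms become events; of two events closer than 150 ms
(tail-to-head) the one with the lower *peak* rate is discarded
(peak rather than mean, switchable), scanning left-to-right with re-checks.

Each event gets a composition vector $w$ (per-unit mean smoothed rate in
the event window), a sparsity

$$\mathrm{sparsity}(w) = 1-\frac{\sqrt{n}-\sum_i |\hat w_i|}{\sqrt{n}-1},
\qquad \hat w = w / \lVert w\rVert_2,$$

which is 0 for a one-hot composition and 1 for a uniform one, a
composition-weighted mean of the single-unit LvR values, and a period
assignment: the unique trial period containing at least 80% (inclusive) of
the event, with the probe period's right edge at the response time. Burst
density — the fraction of trials with an ongoing event per 10-ms bin —
carries a percentile bootstrap band over trials (1000 resamples);
response-aligned densities drop trials with responses later than 2 s,
whose probe recordings are truncated.

A calibration caveat: on synthetic stationary populations the per-trial
*mean* rates barely vary across trials, so the threshold lands only a
fraction of an instantaneous standard deviation above the population mean
and the detector reports events on most null trials. On recorded data,
trial-to-trial rate drift inflates the across-trial s.d. and the same
recipe is conservative. `burst_threshold(sd_source = "rate_series")`
offers the pooled-sample alternative (s.d. of the population-rate samples
themselves), which is calibrated on stationary data; the default stays the
trial-means convention.

## Mean-matched Fano factors

Spike counts in sliding 500-ms windows (50-ms steps) give, per
unit × condition × window, an across-trial mean and variance. Because rate
differences alone move the variance, windows are first equalized on their
mean-count distribution: a histogram (bin 0.5) of mean counts is formed per
window, the *greatest common distribution* keeps the bin-wise minimum over
windows, and each window is randomly downsampled to it. The Fano factor is
then the slope of the zero-intercept weighted regression of variance on
mean, weights $1/(0.01 + \mathrm{SE(variance)})$ with the normal-theory
$\mathrm{SE} = \mathrm{var}\cdot\sqrt{2/(n-1)}$ (the estimator is not
stated by the method's sources; this is the standard choice). The random
matching is repeated 50 times; the mean and a 95% percentile interval over
repeats are reported. Direct condition comparisons (set size 4 vs 6–8)
first undersample the larger condition per unit × window, and the common
distribution is then taken over condition × window cells so either
condition can match it alone.

At desk scale the common distribution can be empty when few points populate
each window (bins wobble across windows); the functions then return missing
FF values with a warning rather than fabricating a slope. Comparisons of FF
time courses use a cluster-based permutation test: window-wise two-sample
t statistics on the repeat distributions (the statistic is a documented
choice, switchable in principle), clusters of contiguous supra-threshold
windows scored by summed |t|, and a max-cluster-mass null from permuting
replicate labels between the two series.

## Decoding

Decoding uses maintenance-period activity only: 12 non-overlapping 250-ms
bins of `[3, 6)` s, z-scored per unit over all its bins × trials (no
smoothing). The z-scoring happens once before cross-validation, mirroring
the pipeline order of the source analyses; the mild train/test leakage this
induces is shared by observed and shuffled runs and therefore cancels in
the permutation comparison. Sessions are combined into a pseudo-population:
per session the per-class trial minimum is found, sessions below 5 are
discarded, the global minimum $n_T$ fixes the per-class sample, and unit
columns are concatenated across sessions aligned by sampled-trial index —
$12\times2\times n_T$ samples. A linear SVM (cost 1, balanced class
weights) is scored by stratified 10-fold cross-validation; per-fold
accuracies are kept for the sensitivity index.

The whole construction is repeated over bootstrap cycles (fresh
alignments); within each cycle the class labels are shuffled at the
trial-slot level — all 12 bins of a trial move together, respecting the
within-trial dependence — 500 times for a one-tailed p, and the median p
over the 50 cycles is the summary. On effect-bearing data the slot-level
null sits slightly above 0.5 (the classifier can exploit within-trial
feature correlation), which is exactly why the observed statistic must be
compared against it rather than against a sample-level shuffle.

Burstiness stratification: per cycle, units are ranked by their mean LvR
over that cycle's sampled trials (whole-trial LvR; the windowing is not
pinned down by the source, so the whole trial is used and flagged here) and
split into equal-size (±1) n-tiles, ties broken by unit id. Each tile is
ablated in turn and the full and reduced populations are decoded on the
same samples and folds; the sensitivity loss is

$$d' = \frac{\mu_{Full}-\mu_{Red}}
 {\sqrt{0.5\,(\sigma^2_{Full}+\sigma^2_{Red})}},$$

from the means and variances of the 10 fold accuracies, summarized across
cycles by mean ± SEM, a one-sample t test against 0 and BH adjustment
across tiles. Complementary single-unit tests compare maintenance firing
rates between classes per unit (two-sample t), reporting the significant
fractions by sign and a binomial test of the sign split.

## The synthetic-session generator

The generator exists so that every stage is testable without clinical
data. It emulates: the trial geometry above; set sizes uniform over
{4, 6, 8} except forced to 4 after a wrong response (the task's motivation
rule); truncated log-normal response times (median 0.8 s, `sdlog` 0.4,
clipped to 0.3–2.5 s — typical probe-response latencies for this task);
units with base rates uniform on 2–15 Hz and gamma-renewal shapes uniform
on 0.4–3.0, spanning LvR ≈ 1.7 down to ≈ 0.4. Spike trains are
inhomogeneous gamma-renewal processes built by time-rescaling a unit-rate
equilibrium renewal train through the cumulative rate, so window counts are
unbiased for the rate integral at any shape. The equilibrium start (first
interval from the length-biased residual distribution) makes windowed
statistics stationary from $t=0$.

Three injectable effects mirror the phenomena the analyses target, all
multiplicative on rate (so LvR and FF consequences emerge mechanistically
rather than by construction):

* `setsize_gain` (default 1.3) on a random quarter of units for set sizes
  6 and 8 — a memory-load code;
* `probe_burst_gain` (default 3) on `[6, 6.5]` s for amygdala/entorhinal
  units — probe-locked population bursts;
* `rt_lvr_coupling` (default 0 = off; 0.3 in the power checks): a standard
  normal trial latent $z_t$, shared by all units of a session, scales each
  unit's log-shape (`latent_shape_scale`, default 0.3 — burstier trials
  when $z_t>0$) and, when the coupling is on, multiplies the response time
  by $e^{c\,z_t}$.

Cohort defaults are 4 sessions of 5 units per region and 50 trials — a
deliberately desk-scale version of a multi-session clinical cohort
(tens of sessions, ~40 units each). What the generator does **not**
emulate: slow nonstationarities and electrode drift, refractory periods,
spike-sorting contamination and cross-talk (sessions are generated clean;
the cross-talk filter is tested on constructed duplicates), seizure
artifacts, and any spatial or waveform structure. Passing tests therefore
demonstrate the *statistical machinery* — calibration of nulls, recovery
of injected effects — not robustness to those recording pathologies. One
consequence is documented in the population-burst section: the absence of
trial-to-trial rate drift makes the trial-means threshold convention
degenerate on synthetic nulls.

## Numerical conventions and degenerate inputs

* Time is in seconds, trial-relative, all windows half-open `[start, end)`;
  sliding windows are right-aligned and indexed by their right edge.
* Exact duplicate spike times in merged trains collapse to one spike
  (zero intervals would break the LvR ratio terms).
* Ranking ties get average ranks; n-tile and cross-talk ties break by unit
  id (after firing rate, for cross-talk) for determinism.
* Permutation/shuffle p-values use +1 smoothing; missing windowed values
  propagate as `NA` and are excluded pairwise.
* Zero-variance decoding features are set to 0 with a warning; zero-variance
  correlation inputs return missing.
* The rate filter is a strict `> 1` Hz on pooled counts over total recorded
  time; with fixed 8-s trials this equals the per-trial-average convention,
  which is still exposed as `per_trial = TRUE`.

## Problem sizes used in the checks

The test-suite and acceptance computations are sized for a single CPU:
LvR calibration uses 500 trains of 8 s at 5 Hz; FF calibration a
200-unit × 60-trial Poisson population over the maintenance window;
permutation calibration 200 replicate runs at 99 permutations; decoding
power checks 3 bootstrap cycles at 59 shuffles on the default 4-session
cohort (the full 50 × 500 contract is the production default of
`bootstrap_decode`); burst and change-point recovery 200 simulations each.

## Known limitations

* Change-point localization at low spike counts has a few-hundred-ms
  floor (see above); counts of change points are reliable, individual
  times are approximate.
* The trial-means burst threshold is degenerate on stationary data;
  use `sd_source = "rate_series"` for simulated or drift-free inputs.
* Mean matching needs enough points per window for a non-empty common
  distribution; with few units, pool conditions or sessions first.
* The pseudo-population assumes exchangeable trials within class across
  sessions; any session-specific temporal structure is destroyed by
  design.
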