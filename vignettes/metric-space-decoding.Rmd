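---
title: "Metric-space decoding of task epochs from spike trains"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Metric-space decoding of task epochs from spike trains}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vpdecode)
```

## The problem

During a trial-and-error problem-solving task, frontal neurons fire after
each feedback event — an exploration error, the first reward that signals
the switch to repetition, or a repetition reward.  The question the package
addresses is *how much of the message is in the timing of the spikes*: can
a downstream decoder that is sensitive to spike times within the first
second after feedback discriminate the task epochs better than a pure
spike-count integrator, and does the temporal structure of individual
trials predict the animal's upcoming behavior?

`vpdecode` implements the complete analysis chain: a binless spike-train
metric with tunable temporal sensitivity, a leave-one-out classifier read
out through bias-corrected mutual information, permutation significance,
shuffle controls that isolate which statistical features of the data carry
the information, paired-unit decoding, and a deviation-from-prototype
analysis linking single-trial firing to response times.  A seeded
synthetic-session generator emulates the statistical structure of such
recordings so that every stage can be exercised, calibrated and
stress-tested without any external data.

## The metric

The dissimilarity between two spike trains is the minimal total cost of
transforming one into the other with three elementary operations:

* inserting or deleting a spike, cost $D_{max}/2 = 1$;
* shifting a spike by $dt$ seconds, cost $q\,|dt|$;
* (two-unit trains) moving a spike to the other unit, cost $k$.

The temporal sensitivity $q$ (units 1/s) is the decoder's time scale: at
$q = 0$ the distance collapses to the absolute spike-count difference; at
large $q$ only nearly synchronous spikes can be matched.  Since a matched
pair costing $\ge 2$ can always be replaced by a deletion plus an
insertion, $2/q$ is the largest interspike interval registered as a
*temporal coincidence* — 200 ms at $q = 10$/s, which corresponds to the
pairwise summation range of postsynaptic potentials decaying with a 100 ms
time constant (`coincidence_range()`, `equivalent_tau()`).  The
unit-distinction cost $k \in [0, 2]$ interpolates between decoding the
merged, label-blind trains ($k = 0$) and fully separate per-unit decoding
($k = 2$).

Both distances are computed exactly by dynamic programming (`vp_distance()`,
`vp_distance_labeled()`; the two-unit version runs over per-unit
consumption indices).  Spike times are kept as doubles in seconds — the
metric is binless by construction — and windows are half-open
$[t_0, t_1)$, which makes nested-window restriction exact.  The test suite
validates both programs against an exhaustive enumeration of all injective
spike matchings.

Two numerical conventions make derived quantities deterministic:

* a pair is matched only when its cost is *strictly* below 2; at exact
  equality the delete+insert alternative is taken.  This never changes the
  distance and gives an unambiguous coincident-pair count;
* among equal-cost alignments the one maximizing the number of matched
  pairs is reported, with a fixed backtrace order breaking residual ties.

The coincidence-normalized distance $d^*_q$ divides the distance by the
number of coincident pairs (or 1 if none), so it does not scale with the
number of emitted spikes.  At $q = 0$ "coincident" is undefined (all
shifts are free); we define the matched count as $\min(n_a, n_b)$, making
$d^*_0 = |n_a - n_b| / \max(1, \min(n_a, n_b))$ — the normalized count
difference, continuous with the $q \to 0$ limit of the alignment.

## The decoder

`decode_epochs()` classifies every trial, leave-one-out, into the epoch
whose other trials are globally most similar; the default summary is the
median of the pairwise distances (a `nearest_neighbor` option, the mean of
the $m$ smallest distances, biases the decision toward close neighbors and
is exposed for robustness checks only).  Exact summary ties are broken by
a seeded uniform draw and counted.  The confusion matrix is summarized by
plug-in mutual information in nats, normalized by the entropy of the
empirical epoch proportions — the unique maximum of the plug-in
information under perfect prediction with fixed marginals — so 1 means
perfect (possibly permuted) prediction and 0 chance.

Information is estimated on 16 nested windows starting 1 ms post-feedback
(ending 50–600 ms in 50 ms steps, then 700–1000 ms in 100 ms steps) and
summarized by $\langle I \rangle_t$, the mean over the 10 windows ending
100 ms–1 s.  The small-sample bias is estimated by fully re-decoding
`n_perm` label-permuted datasets (group sizes preserved) and subtracting
the permutation mean, clipping slightly negative values at 0.  The same
permutation ensemble yields the significance statistic $N_w$: the maximal
number of consecutive windows (maximized over the parameter grid) whose
information strictly exceeds the permutation 95th percentile; a dataset is
significant when its $N_w$ strictly exceeds the 95th percentile of the
permuted $N_w$ values (each permutation being scored against the others).

Numerical choices worth stating:

* the percentile is the ceiling empirical (type-1) order statistic.  It
  admits an exact $O(1)$ leave-one-out update across permutations, which
  the per-permutation $N_w$ scoring needs; with 200–1000 permutations the
  difference from interpolated estimators is negligible against the
  discreteness of $N_w$ itself;
* because the statistic is discrete and the exceedance strict, the
  permutation test is conservative by construction.  On null synthetic
  populations the measured type-I rate is at the nominal 5% (the
  acceptance suite measures it over 200 replicate sessions);
* the 0-clipping of the bias correction leaves a small positive residual
  mean on null data at very small trial counts; at the trial counts
  typical of real sessions (a few tens per epoch) the residual is well
  below 0.02.

Grid comparisons use a Friedman ANOVA across datasets with post-hoc
mean-rank comparisons at Tukey's honestly-significant-difference critical
value (`compare_parameter_grid()`).  Optimal parameters are the mean of
the arg-max set of $\langle I \rangle_t$ (`grid_optimum()`); exact ties
are averaged — a profile maximal at both 5 and 10/s reports 7.5/s.  The
default grids are $q \in \{0, 0.5, 1, 5, 10, 15, 20, 30, 40\}$/s, covering
integrator-like to over-sensitive decoding, and $k \in \{0, 0.25, \dots,
2\}$.

## Shuffle controls

Two PETH-preserving surrogates separate the statistical origin of the
information (`shuffle_preserve_peth()`, `shuffle_preserve_counts()`):

1. *Shuffle 1* pools each epoch's spikes and reassigns each to a uniformly
   random trial.  The trial-averaged rate (PETH) is conserved exactly;
   per-trial counts become Binomial, i.e. near-Poisson, so the surrogate
   embodies the hypothesis of a single time-varying firing probability.
   Sub-window surrogates are obtained by pruning the full-window shuffle.
2. *Shuffle 2* permutes spike times across trials while returning to every
   trial exactly its original count in the analysis window, independently
   per window, epoch and replicate.  PETH *and* spike-count variability
   are conserved; only within-trial temporal correlations beyond the rate
   are destroyed.  Spike-count decoding of the surrogate is therefore
   bit-identical to the original, a property the tests assert exactly.

Information changes are measured as the original information minus the
median over the shuffle ensemble, without re-estimating the bias: both
terms share the same trial counts, so the bias cancels in the difference.
Trial-count dispersion is diagnosed by the Fano factor (unbiased variance
over mean), which exceeds 1 at long windows when a multiplicative trial
gain is present and drops below 1 at short windows under refractoriness.

## Paired units

`pair_info_surface()` runs the full pipeline on the joint labeled trains
over the $(q, k)$ grid.  Derived statistics: the information gain of the
pair over its best single unit, the information imbalance between units,
the gain of merging ($k = 0$ versus $k = 2$, defined only for pairs whose
optimum is at $k = 0$), and the between-neuron coincidence index — the
excess proportion of within-epoch trial comparisons in which cross-unit
matching strictly lowered the distance, relative to between-epoch
comparisons.  "Strictly lowered" is detected by comparing
$d_{q,k_{opt}}$ with $d_{q,k=2}$ (the distance is non-decreasing in $k$)
rather than by inspecting alignment backtraces: it is unambiguous under
cost ties and cheaper.  Trial pairs are unordered.  Spike-count
correlations between units default to Pearson (counts are near-Gaussian at
these rates); a rank-based alternative is exposed.

## Behavioral prediction

For each first-reward trial the deviation from the epoch's prototypical
discharge is the leave-one-out median of $d^*_q$ to all other first-reward
trains.  Trials are split at the median response time (strict
inequalities; exact ties are excluded and reported, and neurons with fewer
than five usable trials are excluded).  $\bar D$ is the slow-minus-fast
difference in mean deviation, computed for windows ending 100 ms–1 s;
$\bar D_{rate}$ is the analogous firing-rate difference, the quantity a
neural integrator would act on.  Across neurons, each window receives a
two-sided signed-rank p-value — computed exactly for $n \le 25$ without
ties, since it enters through a logarithm — and a direction from the rank
sums; the bias score is $b = \sum_{+} -\log_{10} p + \sum_{-} \log_{10} p$.
Significance comes from sign-flip surrogates: each neuron's whole window
profile flips sign with probability ½, and the p-value is the fraction of
surrogates with $|b|$ at least the observed value.

## The synthetic generator

`simulate_session()` emulates the task and the firing statistics the
analysis assumes: problems of exploration errors (the rewarded target
found by trial and error among four, so 0–3 search errors), one first
reward, and a repetition period of three trials in 90% of problems (7–11
otherwise); the trial filters (`filter_trials()`) keep first and second
search errors, first rewards preceded by fewer than three errors,
repetitions 1–3, and discard everything from a post-discovery omission
onward.  Spike trains superpose an alpha-shaped inhomogeneous-Poisson
background (peaking ~150–250 ms post-feedback, a face-valid transient
shape; no quantitative profile is prescribed, and it is fully
configurable), scaled by a lognormal mean-1 trial gain, with an optional
jittered template — one of several reliable spike patterns per epoch,
spikes deleted with probability `p_del` and jittered with SD
`sigma_jitter` — and an absolute refractory period enforced by deleting
the later spike.  Response times follow $RT = \mu + \beta z + \epsilon$
where $z$ standardizes a weighted combination of the absolute count
deviation and the mean absolute template jitter; the weights let tests
couple behavior to count-only, timing-only or mixed deviations.  All
draws flow through counter-based substreams of one master seed, so a
session is bit-reproducible from `(config, seed)`.

Default study conditions (chosen once for face validity): baseline 3 Hz
plus transients of 4–10 Hz peak; four-spike templates with 30 ms jitter
and 15% deletions in the behavioral-adaptation epochs; gain sdlog 0.4
(long-window Fano ≈ 1.5–2); refractory 3 ms; $\mu_{RT} = 0.5$ s,
$\beta = 0.05$ s/SD, $\sigma_\epsilon = 0.1$ s; 90% three-repetition
problems, 1% omissions.

What the generator does *not* emulate: non-stationarity across a session,
bursting beyond refractoriness, spike-sorting artifacts, eye-movement
covariates, and cross-epoch count correlations.  Passing tests therefore
demonstrate the correctness and calibration of the estimators under the
assumed statistical structure, not the substantive conclusions one would
draw from real recordings.

A special test configuration deserves mention because the choice was
genuinely open: to verify that shuffle 2 removes the advantage of temporal
sensitivity, the two contrasted epochs must carry *identical* PETHs and
counts (otherwise rate-borne timing information survives any
PETH-preserving surrogate).  The tests use template sets drawn from six
shared time slots in complementary pairings — each epoch uses every slot
equally often, but which slots co-occur within a trial differs — so all
$q > 0$ information lives in within-trial slot pairings and provably dies
under count-preserving shuffling.

## Problem sizes and runtime choices

The test and acceptance suites run the estimators at reduced but honest
sizes, stated here as package choices: permutation counts of 60–200
(default 1000), 200 replicate sessions for the type-I calibrations, 15
replicate sessions for the recovery/shuffle property, sessions of 6–16
problems, and the 10-window schedule where the fine 50 ms schedule is not
itself under test.  The exhaustive-oracle comparison covers over 1000
random instances with up to 4 spikes per unit.

## Known limitations

* Decoding is strictly pairwise (the three epoch contrasts); no
  multi-class confusion matrices.
* At most two simultaneous units; no triplets or larger ensembles.
* The labeled (two-unit) distance exposes no alignment backtrace; the
  coincidence index deliberately uses the distance-comparison criterion.
* The exact nearest-neighbor weighting used as a robustness variant
  elsewhere is specified only at the contract level ("biased toward
  smaller dissimilarities"); the implementation uses the mean of the $m$
  smallest distances and is excluded from calibrated claims.
* Sign-flip surrogate p-values have resolution $1/n_{surrogate}$ and, for
  small populations, a discrete floor of order $2^{-n_{neurons}}$.
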