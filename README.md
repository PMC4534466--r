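# vpdecode

Metric-space decoding of trial-structured spike trains: does the *timing*
of spikes fired after a behavioral feedback event carry information that a
pure spike-count integrator would miss, and does single-trial temporal
structure predict upcoming behavior?

The package is aimed at systems neuroscientists analyzing task recordings
in which each trial yields one spike train per unit, aligned to a feedback
event and labeled with a task epoch (exploration `error`, `first_reward`,
`repetition`).  It implements the full analysis chain — spike-train metric,
decoder, controls, pair analysis, behavioral correlation — plus a seeded
synthetic-session generator so the pipeline runs and is calibrated with no
external data.

## The method

**Victor–Purpura distance.** The dissimilarity between spike trains is the
minimal cost of transforming one into the other by inserting/deleting
spikes (cost `D_max/2 = 1` each), shifting a spike by `dt` (cost `q·|dt|`),
and — for two-unit trains — reassigning a spike to the other unit (cost
`k ∈ [0, 2]`).  The temporal sensitivity `q` (1/s) sets the decoder's time
scale: `q = 0` is pure spike-count decoding, and a matched pair costs less
than deletion+insertion only when the interval is below `2/q` (200 ms at
`q = 10`/s), the *coincidence-detection* range.  Computed exactly by
dynamic programming (`vp_distance()`, `vp_distance_labeled()`), validated
against exhaustive matching enumeration in the tests.

**Decoder.** `decode_epochs()` classifies each trial, leave-one-out, to the
epoch with the smallest median distance to its trials, over 16 nested
post-feedback windows and a grid of `q` (and `k`).  Confusion matrices are
summarized by plug-in mutual information, normalized by the label entropy,
bias-corrected by fully re-decoding label-permuted datasets, and tested
via `N_w` — the longest run of consecutive windows beating the permutation
95th percentile.  `⟨I⟩_t` averages information over the 10 windows ending
0.1–1 s.

**Controls.** Two PETH-preserving shuffles (`shuffle_preserve_peth()`,
`shuffle_preserve_counts()`) test whether information relies on
time-varying rates, trial-count variability, or within-trial temporal
correlations; Fano factors diagnose the count dispersion.

**Pairs.** `pair_info_surface()` decodes joint two-unit trains over
`(q, k)`; derived statistics quantify the pair's gain over its best unit,
the inter-unit information imbalance, and a between-neuron spike
coincidence index.

**Behavior.** Per-trial deviation from the epoch's prototypical discharge
(leave-one-out median of the coincidence-normalized distance `d*_q`) is
compared between slow and fast response-time trials (`D̄`), against the
firing-rate analogue (`D̄_rate`); population effects are scored by the
signed-log-p bias score `b` with a per-neuron sign-flip surrogate test.

## Worked example

```r
library(vpdecode)

vp_distance(c(0.10, 0.25), c(0.12, 0.31), q = 10)
#> [1] 0.8        # two shifts: 10*(0.02 + 0.06)

session <- simulate_session(generator_config(n_problems = 20), seed = 43)
dataset <- filter_trials(session)        # task trial-selection rules
dataset
#> epoch_dataset: 105 trials, 1 unit(s) [ u1 ]
#>   window [0.001,1) s;  trials per epoch: error=32, first_reward=13, repetition=60

fit <- decode_epochs(dataset, contrast = c("first_reward", "repetition"),
                     q_grid = c(0, 1, 5, 10, 20, 40), n_perm = 200, seed = 1)
fit
#> Metric-space epoch decoder (first_reward vs repetition)
#>   unit u1; rule: median
#>   trials: first_reward=13, repetition=60 | permutations: 200
#>   q_opt = 10 1/s
#>   N_w = 15 consecutive windows; significant (permutation test)
#>   max <I>_t = 0.1731 ; classification ties: 608

round(setNames(fit$It[, 1], fit$q_grid), 3)
#>     0     1     5    10    20    40
#> 0.120 0.106 0.127 0.173 0.137 0.070
```

The fit says: this (simulated) unit discriminates first-reward from
repetition epochs well above chance (information exceeds the permutation
threshold in 15 consecutive windows), and decoding is best at a temporal
sensitivity of 10/s — time-shifting spikes by more than ~200 ms is as bad
as deleting them — where the time-averaged information (0.173, as a
fraction of its maximum) beats spike-count decoding (`q = 0`, 0.120).
The bell shape over `q` is the signature of temporal coding at a
preferred time scale.

The behavioral stage asks whether trials that deviate from the unit's
prototypical first-reward discharge precede slower responses:

```r
fr <- dataset$trials[dataset$trials$epoch == "first_reward", ]
sp <- split_by_response_time(fr)
dev <- deviation_from_prototype(dataset, q = 10, window = 1)
dbar(dev, sp)        # slow-minus-fast mean deviation:  0.128
```

`run_pipeline()` chains the stages and writes CSV outputs plus a JSON
manifest that makes the run reproducible.

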