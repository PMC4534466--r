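# Programmatic fixtures: small trial-structured datasets built in code.

poisson_train <- function(rate, window = c(0.001, 1)) {
  n <- stats::rpois(1, rate * diff(window))
  sort(stats::runif(n, window[1], window[2]))
}

# two-epoch dataset with homogeneous Poisson units at given rates (Hz)
rate_dataset <- function(n_per_epoch = 20, rates = c(first_reward = 20, repetition = 2),
                         seed = 1, window = c(0.001, 1)) {
  set.seed(seed)
  epochs <- rep(names(rates), each = n_per_epoch)
  trains <- lapply(epochs, function(e) poisson_train(rates[[e]], window))
  epoch_dataset(
    data.frame(trial_id = seq_along(epochs), epoch = epochs),
    list(u1 = trains), window)
}

# dataset from explicit per-trial trains
trains_dataset <- function(trains, epochs, window = c(0.001, 1), units = NULL) {
  if (is.null(units)) {
    spikes <- list(u1 = trains)
  } else spikes <- trains          # named list of units
  epoch_dataset(data.frame(trial_id = seq_along(epochs), epoch = epochs),
                spikes, window)
}

# generator configuration with two epochs drawn from the same six time
# slots in complementary pairings: identical PETHs and identical per-trial
# counts across epochs, so every bit of q > 0 information lives in
# within-trial slot pairings (and shuffle 2 destroys it).
antiphase_config <- function(n_problems = 16, sigma_jitter = 0.005,
                             p_del = 0.03, baseline = 0.5, sigma_gain = 0.1,
                             rt_beta = 0, ...) {
  s <- c(0.08, 0.22, 0.36, 0.50, 0.64, 0.78)
  fr <- list(s[c(1, 2)], s[c(3, 4)], s[c(5, 6)])
  rp <- list(s[c(2, 3)], s[c(4, 5)], s[c(1, 6)])
  mk <- function(pats) list(patterns = pats, sigma_jitter = sigma_jitter,
                            p_del = p_del)
  generator_config(
    n_problems = n_problems,
    epochs = list(
      error = list(baseline = baseline, amp = 0, peak = 0.2, templates = NULL),
      first_reward = list(baseline = baseline, amp = 0, peak = 0.2,
                          templates = mk(fr)),
      repetition = list(baseline = baseline, amp = 0, peak = 0.2,
                        templates = mk(rp))),
    sigma_gain = sigma_gain,
    refractory = 0.002,
    rt = list(mu = 0.5, beta = rt_beta, sigma = 0.1),
    ...)
}

# null generator: epochs statistically identical, no templates, no RT coupling
null_config <- function(n_problems = 6, sigma_gain = 0.3,
                        rt = list(mu = 0.5, beta = 0, sigma = 0.1), ...) {
  prof <- list(baseline = 5, amp = 5, peak = 0.2, templates = NULL)
  generator_config(
    n_problems = n_problems,
    epochs = list(error = prof, first_reward = prof, repetition = prof),
    sigma_gain = sigma_gain, rt = rt, ...)
}

# reduced window schedule (the 10 averaging windows only): cuts test
# runtime where the fine 50 ms schedule is not under test
short_windows <- function() {
  list(start = 0.001, analysis_ends = seq(0.1, 1, by = 0.1),
       averaging_ends = seq(0.1, 1, by = 0.1))
}
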