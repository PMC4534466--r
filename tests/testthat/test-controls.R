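test_that("PETH-preserving shuffle conserves the pooled spike multiset", {
  ds <- rate_dataset(n_per_epoch = 8, rates = c(first_reward = 15, repetition = 5),
                     seed = 3)
  sh <- shuffle_preserve_peth(ds, seed = 9)
  for (e in c("first_reward", "repetition")) {
    rows <- ds$trials$epoch == e
    expect_equal(sort(unlist(ds$spikes$u1[rows])),
                 sort(unlist(sh$spikes$u1[rows])))
  }
  ## trains remain valid (sorted, in-window)
  expect_s3_class(epoch_dataset(sh$trials, sh$spikes, sh$window),
                  "epoch_dataset")
  ## single-trial epoch: shuffle is the identity
  one <- subset_trials(ds, idx = c(1, 9, 10))
  sh1 <- shuffle_preserve_peth(one, epochs = "first_reward", seed = 2)
  expect_identical(sh1$spikes$u1[[1]], one$spikes$u1[[1]])
})

test_that("shuffle-1 per-trial counts follow Binomial(N, 1/n_trials)", {
  set.seed(21)
  n_trials <- 4
  trains <- lapply(1:n_trials, function(i) poisson_train(10))
  ds <- trains_dataset(c(trains, list(c(0.5))),
                       c(rep("first_reward", n_trials), "repetition"))
  N <- sum(lengths(trains))
  counts <- vapply(1:1000, function(s)
    length(shuffle_preserve_peth(ds, epochs = "first_reward",
                                 seed = s)$spikes$u1[[1]]),
    integer(1))
  ## goodness of fit against the Binomial pmf at alpha = 0.01
  kmax <- max(counts)
  obs <- tabulate(counts + 1L, kmax + 1L)
  p <- stats::dbinom(0:kmax, N, 1 / n_trials)
  p[kmax + 1] <- p[kmax + 1] + stats::pbinom(kmax, N, 1 / n_trials,
                                             lower.tail = FALSE)
  keep <- p * 1000 >= 5
  chi <- sum((obs[keep] - 1000 * p[keep])^2 / (1000 * p[keep]))
  pval <- stats::pchisq(chi, sum(keep) - 1, lower.tail = FALSE)
  expect_gt(pval, 0.01)
})

test_that("count-preserving shuffle conserves counts, PETH and q=0 decoding", {
  ds <- rate_dataset(n_per_epoch = 10, rates = c(first_reward = 12, repetition = 6),
                     seed = 5)
  win <- c(0.001, 0.5)
  sh <- shuffle_preserve_counts(ds, window = win, seed = 13)
  expect_equal(lengths(sh$spikes$u1),
               lengths(lapply(ds$spikes$u1, vpdecode:::restrict_window,
                              window = win)))
  for (e in c("first_reward", "repetition")) {
    rows <- ds$trials$epoch == e
    orig <- sort(unlist(lapply(ds$spikes$u1[rows], vpdecode:::restrict_window,
                               window = win)))
    expect_equal(sort(unlist(sh$spikes$u1[rows])), orig)
  }
  ## q = 0 distances depend only on counts: decoding is bit-identical
  cm0 <- confusion_matrix(subset_trials(ds), q = 0, window = win, seed = 7)
  cm1 <- confusion_matrix(sh, q = 0, window = win, seed = 7)
  expect_identical(cm0, cm1)
})

test_that("sub-window pruning of shuffle-1 matches direct sub-window shuffling", {
  set.seed(33)
  trains <- lapply(1:5, function(i) poisson_train(12))
  ds <- trains_dataset(c(trains, list(0.5)),
                       c(rep("first_reward", 5), "repetition"))
  win <- c(0.001, 0.3)
  pruned <- vapply(1:300, function(s) {
    sh <- shuffle_preserve_peth(ds, epochs = "first_reward", seed = s)
    length(vpdecode:::restrict_window(sh$spikes$u1[[1]], win))
  }, integer(1))
  direct <- vapply(1:300, function(s) {
    ds2 <- ds
    ds2$spikes$u1 <- lapply(ds2$spikes$u1, vpdecode:::restrict_window,
                            window = win)
    sh <- shuffle_preserve_peth(ds2, epochs = "first_reward", seed = 5000 + s)
    length(sh$spikes$u1[[1]])
  }, integer(1))
  expect_gt(suppressWarnings(stats::ks.test(pruned, direct)$p.value), 0.01)
})

test_that("Fano factor formula and Poisson limit", {
  expect_equal(fano_factor(c(3, 3, 3, 3)), 0)
  expect_equal(fano_factor(c(2, 4)), 2 / 3)
  expect_error(fano_factor(c(0, 0, 0)), "undefined")
  expect_error(fano_factor(3), ">= 2")
  set.seed(2)
  expect_equal(fano_factor(rpois(10000, 7)), 1, tolerance = 0.05)
})

test_that("trial gains give super-Poisson long-window counts; refractoriness sub-Poisson short-window counts", {
  cfg_gain <- null_config(n_problems = 10, sigma_gain = 0.5, refractory = 0)
  f_long <- vapply(1:25, function(r) {
    s <- simulate_session(cfg_gain, seed = 200 + r)
    epoch_fano(s$dataset, epoch = "repetition")
  }, numeric(1))
  expect_gt(median(f_long), 1)
  ## gains off, strong refractoriness: sub-Poisson at short windows
  prof <- list(baseline = 40, amp = 0, peak = 0.2, templates = NULL)
  cfg_ref <- generator_config(n_problems = 10,
                              epochs = list(error = prof, first_reward = prof,
                                            repetition = prof),
                              sigma_gain = 0, refractory = 0.02,
                              rt = list(mu = 0.5, beta = 0, sigma = 0.1))
  f_short <- vapply(1:25, function(r) {
    s <- simulate_session(cfg_ref, seed = 300 + r)
    epoch_fano(s$dataset, epoch = "repetition", window = c(0.001, 0.2))
  }, numeric(1))
  expect_lt(median(f_short), 1)
})

test_that("count-preserving shuffle leaves q=0 information exactly unchanged", {
  ds <- rate_dataset(n_per_epoch = 8, rates = c(first_reward = 14, repetition = 6),
                     seed = 8)
  del <- shuffle_information_delta(ds, q_grid = c(0, 10), kind = "counts",
                                   windows = short_windows(),
                                   n_shuffles = 6, seed = 4)
  expect_equal(unname(del$delta["0", ]), rep(0, 10))
})

test_that("shuffle deltas: zero for rate-only data, positive for temporal templates", {
  ## rate-only: no within-trial correlations to destroy
  d_rate <- vapply(1:6, function(r) {
    ds <- rate_dataset(n_per_epoch = 12,
                       rates = c(first_reward = 14, repetition = 6),
                       seed = 500 + r)
    del <- shuffle_information_delta(ds, q_grid = 10, kind = "counts",
                                     windows = short_windows(),
                                     n_shuffles = 12, seed = r)
    mean(del$delta)
  }, numeric(1))
  expect_lt(abs(median(d_rate)), 0.06)
  expect_gt(vpdecode:::signed_rank_p(d_rate), 0.01)
  ## anti-phase templates: q=20 information collapses under shuffle 2
  d_tpl <- vapply(1:6, function(r) {
    sess <- simulate_session(antiphase_config(), seed = 700 + r)
    ds <- filter_trials(sess)
    del <- shuffle_information_delta(ds, q_grid = 20, kind = "counts",
                                     windows = short_windows(),
                                     n_shuffles = 12, seed = r)
    mean(del$delta)
  }, numeric(1))
  expect_gt(median(d_tpl), 0.05)
})
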