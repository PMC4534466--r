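test_that("identical seed and config reproduce the session bit-identically", {
  cfg <- generator_config(n_problems = 6)
  s1 <- simulate_session(cfg, seed = 42)
  s2 <- simulate_session(cfg, seed = 42)
  expect_identical(s1$dataset$spikes, s2$dataset$spikes)
  expect_identical(s1$dataset$trials, s2$dataset$trials)
  expect_identical(s1$ground_truth, s2$ground_truth)
  s3 <- simulate_session(cfg, seed = 43)
  expect_false(identical(s1$dataset$spikes, s3$dataset$spikes))
})

test_that("problem structure matches the task statistics", {
  cfg <- generator_config()
  pr <- simulate_problem_structure(10000, cfg, seed = 7)
  frac3 <- mean(pr$n_reps == 3)
  expect_gt(frac3, 0.88)
  expect_lt(frac3, 0.92)
  expect_true(all(pr$n_reps %in% c(3, 7:11)))
  ## trial-and-error among 4 targets: 0..3 exploration errors, uniform-ish
  expect_true(all(pr$n_errors %in% 0:3))
  expect_gt(min(table(pr$n_errors)) / 10000, 0.2)
  ## omissions occur at the configured rate
  expect_equal(mean(!is.na(pr$omission_at)), cfg$p_omission, tolerance = 0.5)
})

test_that("invalid configurations are rejected with the offending fields", {
  expect_error(generator_config(p_three_rep = 1.2), "p_three_rep")
  expect_error(generator_config(sigma_gain = -1), "sigma_gain")
  expect_error(generator_config(rho_shared = 2), "rho_shared")
  prof <- list(baseline = -1, amp = 1, peak = 0.2, templates = NULL)
  expect_error(generator_config(epochs = list(error = prof,
                                              first_reward = prof,
                                              repetition = prof)),
               "rates >= 0")
})

test_that("trial-selection filters implement all task rules", {
  mk_trials <- function(epochs, rep_index, n_prec, omission) {
    n <- length(epochs)
    data.frame(trial_id = seq_len(n), problem_id = 1L,
               position_in_problem = seq_len(n), epoch = epochs,
               rep_index = rep_index, n_preceding_errors = n_prec,
               omission = omission)
  }
  as_ds <- function(tr) epoch_dataset(tr, list(u1 = rep(list(numeric(0)),
                                                        nrow(tr))))
  ## [err, err, firstR, rep x3] -> keep all six
  t1 <- mk_trials(c("error", "error", "first_reward", rep("repetition", 3)),
                  c(NA, NA, NA, 1:3), c(0, 1, 2, 2, 2, 2), rep(FALSE, 6))
  expect_equal(filter_trials(as_ds(t1))$trials$trial_id, 1:6)
  ## [err x3, firstR, rep x3] -> keep err1, err2, rep1-3; drop err3, firstR
  t2 <- mk_trials(c(rep("error", 3), "first_reward", rep("repetition", 3)),
                  c(NA, NA, NA, NA, 1:3), c(0:2, 3, 3, 3, 3), rep(FALSE, 7))
  expect_equal(filter_trials(as_ds(t2))$trials$trial_id, c(1, 2, 5, 6, 7))
  ## 7 repetitions -> only rep 1-3 kept
  t3 <- mk_trials(c("first_reward", rep("repetition", 7)),
                  c(NA, 1:7), rep(0, 8), rep(FALSE, 8))
  expect_equal(filter_trials(as_ds(t3))$trials$trial_id, 1:4)
  ## omission at rep 2: omission and following trials discarded
  t4 <- mk_trials(c("first_reward", "repetition", "error", "repetition"),
                  c(NA, 1, 2, 3), rep(0, 4), c(FALSE, FALSE, TRUE, FALSE))
  expect_equal(filter_trials(as_ds(t4))$trials$trial_id, 1:2)
  ## malformed problem structure is rejected
  bad <- data.frame(trial_id = 1:2, epoch = c("error", "repetition"))
  expect_error(filter_trials(as_ds(bad)), "malformed|missing")
})

test_that("empirical PETH converges to the configured intensity profile", {
  prof <- list(baseline = 4, amp = 10, peak = 0.2, templates = NULL)
  cfg <- generator_config(n_problems = 110,
                          epochs = list(error = prof, first_reward = prof,
                                        repetition = prof),
                          sigma_gain = 0.2, refractory = 0,
                          rt = list(mu = 0.5, beta = 0, sigma = 0.1))
  s <- simulate_session(cfg, seed = 12)
  reps <- which(s$dataset$trials$epoch == "repetition")
  spk <- unlist(s$dataset$spikes$u1[reps])
  br <- seq(0, 1, by = 0.05)
  emp <- hist(spk, breaks = br, plot = FALSE)$density * length(spk) /
    length(reps)
  mid <- br[-1] - 0.025
  lam <- prof$baseline + prof$amp * (mid / prof$peak) * exp(1 - mid / prof$peak)
  expect_lt(mean(abs(emp - lam)) / mean(lam), 0.15)
})

test_that("template spikes are shared across pair units as configured", {
  tplcfg <- list(baseline = 0, amp = 0.01, peak = 0.2,
                 templates = list(patterns = list(c(0.1, 0.3, 0.5, 0.7)),
                                  sigma_jitter = 0, p_del = 0))
  cfg1 <- generator_config(n_problems = 4,
                           epochs = list(error = tplcfg, first_reward = tplcfg,
                                         repetition = tplcfg),
                           sigma_gain = 0, refractory = 0, rho_shared = 1,
                           rt = list(mu = 0.5, beta = 0, sigma = 0.1))
  s <- simulate_pair_session(cfg1, seed = 5)
  shared <- mapply(function(a, b) length(intersect(a, b)) >= 3,
                   s$dataset$spikes$u1, s$dataset$spikes$u2)
  expect_gt(mean(shared), 0.9)
  cfg0 <- generator_config(n_problems = 4,
                           epochs = list(error = tplcfg, first_reward = tplcfg,
                                         repetition = tplcfg),
                           sigma_gain = 0, refractory = 0, rho_shared = 0,
                           rt = list(mu = 0.5, beta = 0, sigma = 0.1))
  s0 <- simulate_pair_session(cfg0, seed = 5)
  shared0 <- mapply(function(a, b) length(intersect(a, b)),
                    s0$dataset$spikes$u1, s0$dataset$spikes$u2)
  expect_equal(max(shared0), 0)
})

test_that("response-time model recovery: regression returns beta within 2 SE", {
  beta <- 0.08
  cfg <- null_config(n_problems = 150, sigma_gain = 0.5,
                     rt = list(mu = 0.5, beta = beta, sigma = 0.1))
  s <- simulate_session(cfg, seed = 77)
  fr <- which(s$dataset$trials$epoch == "first_reward")
  fitlm <- stats::lm(s$dataset$trials$response_time[fr] ~ s$ground_truth$u1$z[fr])
  est <- summary(fitlm)$coefficients[2, ]
  expect_lt(abs(est["Estimate"] - beta), 2 * est["Std. Error"] + 1e-9)
})

test_that("refractoriness never leaves inter-spike intervals below the period", {
  cfg <- null_config(n_problems = 8, refractory = 0.01)
  s <- simulate_session(cfg, seed = 3)
  isis <- unlist(lapply(s$dataset$spikes$u1, diff))
  expect_true(all(isis >= 0.01))
})

test_that("decoder-level recovery: information grows with template reliability", {
  ## jitter-matched q beats spike count on anti-phase template sessions
  wins <- vapply(1:6, function(r) {
    ds <- filter_trials(simulate_session(antiphase_config(),
                                         seed = 1000 + r))
    fit <- decode_epochs(ds, q_grid = c(0, 20), windows = short_windows(),
                         n_perm = 60, seed = r)
    fit$It[2, 1] - fit$It[1, 1]
  }, numeric(1))
  expect_gte(mean(wins > 0), 0.8)
})
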