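test_that("raw and normalized information match hand-computed values", {
  expect_equal(raw_information(matrix(c(10, 0, 0, 10), 2, byrow = TRUE)),
               log(2))
  expect_equal(raw_information(matrix(c(5, 5, 5, 5), 2, byrow = TRUE)), 0)
  N <- matrix(c(8, 2, 3, 7), 2, byrow = TRUE)
  ## direct evaluation of the plug-in formula
  expect_equal(raw_information(N), 0.1325, tolerance = 1e-3)
  expect_equal(normalized_information(N), 0.1325 / log(2), tolerance = 1e-3)
  ## perfect prediction normalizes to 1 for any class proportions
  expect_equal(normalized_information(matrix(c(3, 0, 0, 17), 2)), 1)
  expect_equal(normalized_information(matrix(c(0, 3, 17, 0), 2)), 1)  # anti-diagonal
  expect_equal(normalized_information(matrix(c(5, 5, 5, 5), 2)), 0)
  expect_error(normalized_information(matrix(c(5, 5, 0, 0), 2, byrow = TRUE)),
               "undefined")
  ## zero rows/columns contribute zero, no error
  expect_equal(raw_information(matrix(c(10, 0, 5, 0), 2, byrow = TRUE)), 0)
})

test_that("bias correction subtracts the permutation mean and clips at 0", {
  expect_equal(bias_corrected_information(0.30, rep(0.05, 10)), 0.25)
  expect_equal(bias_corrected_information(0.02, rep(0.05, 10)), 0)
  expect_error(bias_corrected_information(0.3, numeric(0)), "non-empty")
})

test_that("time-averaged information is the mean over the 10 averaging windows", {
  ws <- window_schedule()
  expect_length(ws$analysis_ends, 16)
  expect_length(ws$averaging_ends, 10)
  i_const <- rep(0.4, 16)
  expect_equal(time_averaged_information(i_const, ws$analysis_ends), 0.4)
  i_lin <- seq(0, 0.9, length.out = 10)
  expect_equal(time_averaged_information(i_lin, ws$averaging_ends), 0.45)
  expect_error(time_averaged_information(rep(1, 3), c(0.1, 0.2, 0.3)),
               "missing averaging window")
})

test_that("grid optimum averages ties and flags flat profiles", {
  q <- c(0, 5, 10, 20)
  expect_equal(grid_optimum(c(0.1, 0.2, 0.5, 0.3), q), 10)
  expect_equal(grid_optimum(c(0.1, 0.5, 0.5, 0.3), q), 7.5)  # tie 5 and 10
  expect_warning(out <- grid_optimum(rep(0.2, 4), q), "flat")
  expect_equal(out, mean(q))
})

test_that("longest run counts only consecutive exceedances", {
  expect_equal(longest_run(c(TRUE, FALSE, TRUE, FALSE, TRUE)), 1)
  expect_equal(longest_run(c(FALSE, TRUE, TRUE, TRUE, FALSE)), 3)
  expect_equal(longest_run(rep(FALSE, 4)), 0)
})

test_that("leave-one-out classification separates trivially separable epochs", {
  ## epoch A: dense regular trains; epoch B: a single early spike
  tA <- lapply(1:5, function(i) seq(0.1, 0.9, by = 0.1) + i * 1e-4)
  tB <- lapply(1:5, function(i) 0.05 + i * 1e-4)
  ds <- trains_dataset(c(tA, tB), rep(c("first_reward", "repetition"), each = 5))
  for (tr in 1:10)
    expect_equal(as.character(classify_trial(ds, tr, q = 5)),
                 ds$trials$epoch[tr])
  cm <- confusion_matrix(ds, q = 5)
  expect_equal(unname(diag(cm)), c(5, 5))
  expect_equal(unname(rowSums(cm)), c(5, 5))
})

test_that("confusion matrix row sums equal per-epoch trial counts", {
  ds <- rate_dataset(n_per_epoch = 10, seed = 2)
  ds2 <- subset_trials(ds, idx = c(1:10, 11:30))  # no-op here, sizes 10/20
  ds3 <- rate_dataset(10, seed = 3)
  ds3$trials <- ds3$trials[c(1:10, 11:20), ]
  cm <- confusion_matrix(ds, q = 0)
  expect_equal(unname(rowSums(cm)), c(10, 10))
  set.seed(5)
  big <- rate_dataset(n_per_epoch = 15, seed = 5)
  small <- subset_trials(big, idx = c(1:10, 16:30))
  cm2 <- confusion_matrix(small, q = 0)
  expect_equal(unname(rowSums(cm2)), c(10, 15))
})

test_that("classification excludes the trial from its own reference set", {
  ## trial 1 (0 spikes) sits in first_reward next to a 10-spike train;
  ## repetition trials have 7 spikes.  Correct leave-one-out classifies it
  ## to repetition (7 < 10); including the trial itself would flip the
  ## decision (5 < 7).
  tr <- c(list(numeric(0), seq(0.05, 0.95, length.out = 10)),
          lapply(1:3, function(i) seq(0.1, 0.9, length.out = 7) + i * 1e-4))
  ds <- trains_dataset(tr, c("first_reward", "first_reward",
                             rep("repetition", 3)))
  expect_equal(as.character(classify_trial(ds, 1, q = 0)), "repetition")
})

test_that("rate-separated epochs are decoded almost perfectly at q = 0", {
  ds <- rate_dataset(n_per_epoch = 20, rates = c(first_reward = 20, repetition = 2),
                     seed = 11)
  cm <- confusion_matrix(ds, q = 0)
  expect_gte(sum(diag(cm)) / sum(cm), 0.9)
})

test_that("the decoder pipeline returns a coherent fit object", {
  ds <- rate_dataset(n_per_epoch = 12, rates = c(first_reward = 18, repetition = 4),
                     seed = 21)
  fit <- decode_epochs(ds, q_grid = c(0, 10), n_perm = 60, seed = 4)
  expect_s3_class(fit, "epoch_decoder")
  expect_true(all(fit$info >= 0 & fit$info <= 1))
  expect_true(all(fit$info_raw <= 1 + 1e-12))
  expect_equal(dim(fit$info), c(2, 1, 16))
  ## time average consistency
  expect_equal(fit$It[1, 1],
               time_averaged_information(fit$info[1, 1, ],
                                         fit$windows$analysis_ends))
  ## strong rate separation: significant with long N_w, informative at q=0
  expect_true(fit$significant)
  expect_gte(fit$nw, 10)
  expect_gt(fit$It[1, 1], 0.5)
  ## determinism: same seed, same fit
  fit2 <- decode_epochs(ds, q_grid = c(0, 10), n_perm = 60, seed = 4)
  expect_identical(fit$info, fit2$info)
  expect_identical(fit$nw_null, fit2$nw_null)
  ## print/summary/plot do not error
  expect_output(print(fit), "q_opt")
  expect_output(df <- summary(fit), "Time-averaged")
  expect_equal(nrow(df), 2)
  tmp <- tempfile(fileext = ".png")
  grDevices::png(tmp); plot(fit); grDevices::dev.off()
  expect_true(file.exists(tmp))
  unlink(tmp)
  ## predict assigns obvious new trains correctly
  expect_equal(predict(fit, poisson_train(20), q = 0), "first_reward")
  expect_equal(predict(fit, poisson_train(2), q = 0), "repetition")
})

test_that("label-shuffled data carry no corrected information", {
  ## trial counts representative of real sessions (a few tens per epoch):
  ## at very small n the 0-clipping of the correction leaves a small
  ## positive residual by construction
  its <- vapply(1:8, function(r) {
    ds <- rate_dataset(n_per_epoch = 25, rates = c(first_reward = 10, repetition = 10),
                       seed = 100 + r)
    fit <- decode_epochs(ds, q_grid = c(0, 10), windows = short_windows(),
                         n_perm = 150, seed = r)
    mean(fit$It)
  }, numeric(1))
  expect_lt(mean(its), 0.02)
})

test_that("nearest-neighbor rule is available and biased toward close trains", {
  ds <- rate_dataset(n_per_epoch = 10, rates = c(first_reward = 15, repetition = 3),
                     seed = 31)
  fit <- decode_epochs(ds, q_grid = 0, windows = short_windows(),
                       n_perm = 30, rule = "nearest_neighbor", m_nearest = 3,
                       seed = 2)
  expect_gt(max(fit$It), 0.2)
})

test_that("Friedman comparison ranks settings and controls type I error", {
  ## all datasets rank column 3 highest
  set.seed(9)
  It <- cbind(runif(8, 0, 0.2), runif(8, 0.2, 0.4), runif(8, 0.6, 0.9))
  out <- compare_parameter_grid(It)
  expect_equal(out$top, 3)
  expect_lt(out$p_value, 0.01)
  expect_true(out$differs_from_top[1])
  ## i.i.d. noise: rejection rate around the nominal 5%
  set.seed(10)
  rej <- mean(replicate(400, {
    compare_parameter_grid(matrix(rnorm(8 * 3), 8, 3))$p_value < 0.05
  }))
  expect_gt(rej, 0.015)
  expect_lt(rej, 0.10)
  ## constant ranks are degenerate, no difference reported
  out2 <- compare_parameter_grid(matrix(rep(c(1, 2, 3), each = 6), 6, 3))
  expect_false(any(out2$differs_from_top[out2$top]))
})

test_that("classification ties are broken reproducibly and logged", {
  ## two identical epochs of identical trains: every decision is a tie
  tr <- rep(list(c(0.2, 0.5)), 8)
  ds <- trains_dataset(tr, rep(c("first_reward", "repetition"), each = 4))
  fit <- decode_epochs(ds, q_grid = 0,
                       windows = list(start = 0.001, analysis_ends = 1,
                                      averaging_ends = 1),
                       n_perm = 10, seed = 6)
  expect_gt(fit$ties, 0)
  fit2 <- decode_epochs(ds, q_grid = 0,
                        windows = list(start = 0.001, analysis_ends = 1,
                                       averaging_ends = 1),
                        n_perm = 10, seed = 6)
  expect_identical(fit$info_raw, fit2$info_raw)
})

test_that("degenerate datasets are rejected", {
  ds <- rate_dataset(2, seed = 40)
  one <- subset_trials(ds, idx = c(1, 3, 4))  # 1 trial in first epoch
  expect_error(decode_epochs(one, q_grid = 0, n_perm = 5), ">= 2 trials")
  expect_error(decode_epochs(ds, contrast = c("first_reward"), n_perm = 5),
               "exactly 2")
})
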