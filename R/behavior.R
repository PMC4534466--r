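#' Median split of trials by response time
#'
#' Splits trials with a defined response time (the time between the "go"
#' signal following the first reward and the subsequent target touch) at
#' the median: `T_plus` holds trials with RT strictly above the median,
#' `T_minus` strictly below.  Trials exactly at the median are excluded
#' (and reported), as are interrupted trials when requested.  Fewer than 5
#' usable trials is an error (the neuron is excluded from the analysis).
#'
#' @param trials data.frame with columns `trial_id`, `response_time` and
#'   optionally `interrupted`.
#' @param exclude_interrupted drop trials flagged as interrupted first.
#' @return list with `r_tilde` (median RT, seconds), `T_plus`, `T_minus`
#'   (trial-id vectors) and `excluded_at_median`.
#' @export
split_by_response_time <- function(trials, exclude_interrupted = FALSE) {
  stopifnot(is.data.frame(trials), "response_time" %in% names(trials))
  keep <- !is.na(trials$response_time)
  if (exclude_interrupted && "interrupted" %in% names(trials))
    keep <- keep & !isTRUE_vec(trials$interrupted)
  tr <- trials[keep, , drop = FALSE]
  if (nrow(tr) < 5)
    stop("fewer than 5 trials with a response time: neuron excluded")
  r_tilde <- median(tr$response_time)
  at_median <- tr$response_time == r_tilde
  list(r_tilde = r_tilde,
       T_plus = tr$trial_id[tr$response_time > r_tilde],
       T_minus = tr$trial_id[tr$response_time < r_tilde],
       excluded_at_median = tr$trial_id[at_median])
}

isTRUE_vec <- function(x) !is.na(x) & as.logical(x)

#' Per-trial deviation from the epoch's prototypical spike train
#'
#' For each trial of the epoch, the median of the coincidence-normalized
#' distances d* ([vp_dstar()]) between its spike train and every other
#' trial of the same epoch (leave-one-out).  A trial whose train resembles
#' the epoch's typical firing pattern scores low; both an abnormally sparse
#' train and a dense train with badly timed spikes score high.
#'
#' @param dataset an [epoch_dataset()].
#' @param q temporal sensitivity (1/s).
#' @param window analysis window `(start, end)` or end time (seconds).
#' @param epoch epoch whose prototype is taken (default `first_reward`).
#' @param unit unit id.
#' @return named numeric vector of deviations (names = trial ids).
#' @export
deviation_from_prototype <- function(dataset, q, window = NULL,
                                     epoch = "first_reward", unit = NULL) {
  ds <- subset_trials(dataset, epochs = epoch)
  if (nrow(ds$trials) < 2) stop("need >= 2 trials in the epoch")
  if (is.null(window)) window <- ds$window
  if (length(window) == 1) window <- c(ds$window[1], window)
  tr <- unit_trains(ds, unit, window)
  D <- cpp_vp_dstar_matrix(tr, q)
  dev <- vapply(seq_along(tr), function(i) median(D[i, -i]), numeric(1))
  names(dev) <- ds$trials$trial_id
  dev
}

#' Response-time difference in deviation from prototype (D-bar)
#'
#' Mean deviation from the prototypical first-reward discharge over the
#' slow-response-time trials (`T_plus`) minus the mean over the fast ones
#' (`T_minus`).  Positive values mean that trials deviating more from the
#' prototype were followed by slower responses.
#'
#' @param deviations named vector from [deviation_from_prototype()].
#' @param split a [split_by_response_time()] result.
#' @return signed real.
#' @export
dbar <- function(deviations, split) {
  ip <- intersect(split$T_plus, names(deviations))
  im <- intersect(split$T_minus, names(deviations))
  if (!length(ip) || !length(im)) stop("empty response-time group")
  mean(deviations[ip]) - mean(deviations[im])
}

#' Response-time difference in mean firing rate (D-bar rate)
#'
#' Mean firing rate (spikes/s in the analysis window) over slow-response
#' trials minus fast-response trials — the prediction a downstream neural
#' integrator would act on.  Optionally reverses the sign for
#' repetition-preferring neurons (`reverse_sign = TRUE`), emulating
#' inhibitory coupling into the integrator.
#'
#' @inheritParams deviation_from_prototype
#' @param split a [split_by_response_time()] result.
#' @param reverse_sign negate the result (repetition-preferring neurons).
#' @return signed rate difference, Hz.
#' @export
dbar_rate <- function(dataset, split, window = NULL,
                      epoch = "first_reward", unit = NULL,
                      reverse_sign = FALSE) {
  ds <- subset_trials(dataset, epochs = epoch)
  if (is.null(window)) window <- ds$window
  if (length(window) == 1) window <- c(ds$window[1], window)
  cnt <- spike_counts(ds, unit, window) / diff(window)
  names(cnt) <- ds$trials$trial_id
  ip <- intersect(split$T_plus, names(cnt))
  im <- intersect(split$T_minus, names(cnt))
  if (!length(ip) || !length(im)) stop("empty response-time group")
  out <- mean(cnt[ip]) - mean(cnt[im])
  if (reverse_sign) -out else out
}

#' Population bias score across analysis windows
#'
#' For each analysis window, a two-sided signed-rank test across neurons
#' decides whether the D-bar values are biased away from zero, and the sum
#' of ranks of positive versus negative values gives the window's bias
#' direction.  The bias score is
#' `b = sum_{positive windows} -log10(p) + sum_{negative windows} log10(p)`:
#' large positive `b` means deviations from prototype consistently predict
#' slower responses.
#'
#' @param dbar_matrix numeric matrix, neurons in rows, analysis windows in
#'   columns, of D-bar (or D-bar-rate) values.
#' @return list of class `bias_score`: `b`, per-window `p` and `direction`
#'   (+1/-1/0).
#' @export
bias_score <- function(dbar_matrix) {
  dbar_matrix <- as.matrix(dbar_matrix)
  if (nrow(dbar_matrix) < 5) stop("need >= 5 neurons")
  W <- ncol(dbar_matrix)
  p <- dir <- numeric(W)
  for (w in seq_len(W)) {
    x <- dbar_matrix[, w]
    x <- x[!is.na(x)]
    nz <- x[x != 0]
    if (!length(nz)) { p[w] <- 1; dir[w] <- 0; next }
    r <- rank(abs(nz))
    vplus <- sum(r[nz > 0]); vminus <- sum(r[nz < 0])
    dir[w] <- sign(vplus - vminus)
    p[w] <- signed_rank_p(x)
  }
  b <- sum(dir * (-log10(p)))
  structure(list(b = b, p = p, direction = dir), class = "bias_score")
}

#' @export
print.bias_score <- function(x, ...) {
  cat("bias score b =", format(x$b, digits = 4), "over", length(x$p),
      "windows (", sum(x$direction > 0), "positive,",
      sum(x$direction < 0), "negative )\n")
  invisible(x)
}

## two-sided signed-rank p across a population; exact for n <= 25 without
## ties (the p enters the bias score through a log, so precision matters at
## small n), normal approximation with continuity correction otherwise
signed_rank_p <- function(x) {
  x <- x[!is.na(x) & x != 0]
  n <- length(x)
  if (n == 0) return(1)
  exact <- n <= 25 && !any(duplicated(abs(x)))
  suppressWarnings(
    stats::wilcox.test(x, mu = 0, exact = exact, correct = TRUE)$p.value
  )
}

#' Sign-flip surrogate test of the bias score
#'
#' Builds surrogate populations in which, independently for each neuron,
#' the sign of its whole D-bar window profile is flipped with probability
#' 1/2 (jointly across windows, preserving the within-neuron time course),
#' recomputes the bias score, and returns the fraction of surrogates with
#' `|b| >= |b_real|`.
#'
#' @inheritParams bias_score
#' @param n_surrogate number of surrogate populations.
#' @param seed RNG seed.
#' @return list: `p`, `b_real`, `b_surrogate` (vector).
#' @export
surrogate_pvalue <- function(dbar_matrix, n_surrogate = 1000, seed = 1) {
  dbar_matrix <- as.matrix(dbar_matrix)
  b_real <- bias_score(dbar_matrix)$b
  set.seed(seed)
  bs <- vapply(seq_len(n_surrogate), function(s) {
    flip <- sample(c(1, -1), nrow(dbar_matrix), replace = TRUE)
    bias_score(dbar_matrix * flip)$b
  }, numeric(1))
  list(p = mean(abs(bs) >= abs(b_real)), b_real = b_real, b_surrogate = bs)
}

#' Compare D-bar between two temporal sensitivities
#'
#' Time-averages each neuron's D-bar profile over the averaging windows and
#' applies a paired two-sided signed-rank test between the two `q` values
#' (typically the population optimum against spike count, `q = 0`).
#'
#' @param dbar_q1,dbar_q0 neuron x window D-bar matrices at the two `q`
#'   values, computed on identical trials and windows.
#' @return list: `p`, `differences` (per-neuron time-averaged difference).
#' @export
compare_dbar_q <- function(dbar_q1, dbar_q0) {
  dbar_q1 <- as.matrix(dbar_q1); dbar_q0 <- as.matrix(dbar_q0)
  stopifnot(all(dim(dbar_q1) == dim(dbar_q0)))
  d <- rowMeans(dbar_q1) - rowMeans(dbar_q0)
  list(p = signed_rank_p(d), differences = d)
}

#' Confidence interval on the median
#'
#' `median +/- IQR / (1.075 * sqrt(n))`, the approximate median confidence
#' interval used for population error bars.
#'
#' @param values numeric vector (n >= 2).
#' @return numeric `c(lo, hi)` with attribute `"median"`.
#' @export
median_confidence_interval <- function(values) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n < 2) stop("need n >= 2")
  m <- median(values)
  half <- stats::IQR(values) / (1.075 * sqrt(n))
  structure(c(lo = m - half, hi = m + half), median = m)
}

#' Population response-time analysis over a set of neurons
#'
#' Convenience wrapper running the full behavioral pipeline for a list of
#' single-unit datasets: median RT split per neuron, deviations from the
#' first-reward prototype per window (d*-based), the D-bar and D-bar-rate
#' window profiles, the population bias scores and their sign-flip
#' surrogate p-values, and the comparison of D-bar between `q` and
#' spike-count (`q = 0`).
#'
#' @param datasets list of [epoch_dataset()]s (one neuron each, with
#'   response times on first-reward trials).
#' @param q temporal sensitivity used for the deviation analysis.
#' @param window_ends analysis-window end times for the D-bar profiles.
#' @param exclude_interrupted passed to [split_by_response_time()].
#' @param n_surrogate,seed surrogate-test parameters.
#' @return list with `dbar` and `dbar_rate` (neuron x window matrices),
#'   `dbar_q0`, bias scores, surrogate p-values, `compare_q_vs_count`, and
#'   the indices of neurons excluded for having fewer than five RT trials.
#' @export
behavior_analysis <- function(datasets, q = 10,
                              window_ends = window_schedule()$averaging_ends,
                              exclude_interrupted = FALSE,
                              n_surrogate = 1000, seed = 1) {
  start <- 0.001
  n <- length(datasets)
  W <- length(window_ends)
  Dq <- D0 <- Dr <- matrix(NA_real_, n, W)
  excluded <- integer(0)
  for (i in seq_len(n)) {
    ds <- datasets[[i]]
    fr <- ds$trials[ds$trials$epoch == "first_reward", , drop = FALSE]
    sp <- tryCatch(split_by_response_time(fr, exclude_interrupted),
                   error = function(e) NULL)
    if (is.null(sp)) { excluded <- c(excluded, i); next }
    for (w in seq_len(W)) {
      win <- c(start, window_ends[w])
      devq <- deviation_from_prototype(ds, q, win)
      dev0 <- deviation_from_prototype(ds, 0, win)
      Dq[i, w] <- dbar(devq, sp)
      D0[i, w] <- dbar(dev0, sp)
      Dr[i, w] <- dbar_rate(ds, sp, win)
    }
  }
  keep <- setdiff(seq_len(n), excluded)
  if (length(keep) < 5) stop("fewer than 5 usable neurons")
  Dq <- Dq[keep, , drop = FALSE]
  D0 <- D0[keep, , drop = FALSE]
  Dr <- Dr[keep, , drop = FALSE]
  list(dbar = Dq, dbar_q0 = D0, dbar_rate = Dr,
       bias = bias_score(Dq),
       bias_q0 = bias_score(D0),
       bias_rate = bias_score(Dr),
       surrogate = surrogate_pvalue(Dq, n_surrogate, seed),
       surrogate_rate = surrogate_pvalue(Dr, n_surrogate,
                                         substream_seed(seed, 3L, 1L)),
       compare_q_vs_count = compare_dbar_q(Dq, D0),
       excluded_neurons = excluded)
}
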