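#' Two-unit (q, k) information surface
#'
#' Runs the full decoder pipeline ([decode_epochs()]) on the joint labeled
#' spike trains of a two-unit dataset over a grid of temporal sensitivities
#' `q` and unit-distinction costs `k`.  At `k = 0` this is exactly decoding
#' of the merged, label-blind trains; at `k = 2` it is decoding with the
#' sum of the per-unit distances.
#'
#' @inheritParams decode_epochs
#' @return an `epoch_decoder` with `pair = TRUE`.
#' @export
pair_info_surface <- function(dataset,
                              contrast = c("first_reward", "repetition"),
                              q_grid = default_q_grid(),
                              k_grid = default_k_grid(),
                              windows = window_schedule(),
                              n_perm = 1000,
                              rule = c("median", "nearest_neighbor"),
                              m_nearest = 3, seed = 1, keep_null = FALSE) {
  decode_epochs(dataset, contrast = contrast, pair = TRUE,
                q_grid = q_grid, k_grid = k_grid, windows = windows,
                n_perm = n_perm, rule = match.arg(rule),
                m_nearest = m_nearest, seed = seed, keep_null = keep_null)
}

#' Information gain of the pair relative to the best single unit
#'
#' `(max_{q,k} <I_pair>_t - max_{unit,q} <I_single>_t) / max(of the two)`:
#' positive when joint decoding beats the pair's most informative unit.
#'
#' @param pair_It `q x k` matrix of time-averaged information of the pair
#'   (or an `epoch_decoder` from [pair_info_surface()]).
#' @param single_It1,single_It2 time-averaged information profiles over `q`
#'   of the two units decoded alone (or their `epoch_decoder`s).
#' @return dimensionless gain in `(-Inf, 1]`.
#' @export
pair_gain <- function(pair_It, single_It1, single_It2) {
  mp <- max(extract_It(pair_It))
  ms <- max(max(extract_It(single_It1)), max(extract_It(single_It2)))
  den <- max(mp, ms)
  if (den == 0) {
    warning("all informations are zero: gain undefined")
    return(NA_real_)
  }
  (mp - ms) / den
}

#' Information imbalance between the two units of a pair
#'
#' `|max_q <I_1>_t - max_q <I_2>_t| / max(of the two)`, in `[0, 1]`.
#'
#' @inheritParams pair_gain
#' @export
information_imbalance <- function(single_It1, single_It2) {
  m1 <- max(extract_It(single_It1)); m2 <- max(extract_It(single_It2))
  den <- max(m1, m2)
  if (den == 0) {
    warning("both units carry zero information: imbalance undefined")
    return(NA_real_)
  }
  abs(m1 - m2) / den
}

#' Information gain when not distinguishing between neurons
#'
#' For pairs whose optimal distinction degree is `k_opt = 0`:
#' `(max_q <I_{k=0}>_t - max_q <I_{k=2}>_t) / max_q <I_{k=0}>_t`.
#'
#' @param fit an `epoch_decoder` from [pair_info_surface()] whose `k_grid`
#'   contains 0 and 2.
#' @return dimensionless gain, or an error when `k_opt != 0`
#'   (not applicable).
#' @export
gain_no_distinction <- function(fit) {
  stopifnot(inherits(fit, "epoch_decoder"), fit$pair)
  if (fit$k_opt != 0)
    stop("k_opt = ", fit$k_opt, " != 0: gain without distinction not applicable")
  i0 <- match(0, fit$k_grid); i2 <- match(2, fit$k_grid)
  if (is.na(i0) || is.na(i2)) stop("k_grid must contain 0 and 2")
  m0 <- max(fit$It[, i0]); m2 <- max(fit$It[, i2])
  if (m0 == 0) stop("zero information at k = 0")
  (m0 - m2) / m0
}

#' Between-neuron spike coincidence index
#'
#' For every unordered pair of trials, a comparison is said to be impacted
#' by between-neuron spike matching when the two-unit distance at
#' `(q_opt, k_opt)` is strictly smaller than at `(q_opt, k = 2)` (cross-unit
#' matching lowered the cost; the distance is non-decreasing in `k`).  The
#' index is the larger of the two within-epoch impact proportions minus the
#' between-epoch proportion, in `[-1, 1]`.  Evaluated at the analysis
#' window maximizing the pair information.
#'
#' @param dataset two-unit [epoch_dataset()].
#' @param q_opt,k_opt parameter values (typically from
#'   [pair_info_surface()]).
#' @param window analysis window `(start, end)`; typically the information-
#'   maximizing window of the pair fit.
#' @param contrast the two epochs compared.
#' @param tol strict-improvement tolerance guarding against float noise.
#' @return index in `[-1, 1]`, with attribute `"proportions"`; identically
#'   0 (flagged by a warning) when `k_opt = 2`.
#' @export
coincidence_index <- function(dataset, q_opt, k_opt, window = NULL,
                              contrast = c("first_reward", "repetition"),
                              tol = 1e-9) {
  stopifnot(inherits(dataset, "epoch_dataset"), length(dataset$units) == 2)
  ds <- subset_trials(dataset, epochs = contrast)
  if (is.null(window)) window <- ds$window
  if (k_opt == 2) warning("k_opt = 2: coincidence index is 0 by construction")
  t1 <- unit_trains(ds, ds$units[1], window)
  t2 <- unit_trains(ds, ds$units[2], window)
  Dk <- cpp_vp_dist_matrix_labeled(t1, t2, q_opt, k_opt)
  D2 <- cpp_vp_dist_matrix_labeled(t1, t2, q_opt, 2)
  impact <- (D2 - Dk) > tol
  lab <- ds$trials$epoch
  up <- upper.tri(impact)
  same1 <- outer(lab == contrast[1], lab == contrast[1], "&") & up
  same2 <- outer(lab == contrast[2], lab == contrast[2], "&") & up
  inter <- outer(lab, lab, "!=") & up
  p1 <- mean(impact[same1]); p2 <- mean(impact[same2])
  pi_ <- mean(impact[inter])
  out <- max(p1, p2) - pi_
  attr(out, "proportions") <- c(intra1 = p1, intra2 = p2, inter = pi_)
  out
}

#' Trial spike-count correlation between the two units of a pair
#'
#' Correlation, per analysis window, between the two units' spike counts
#' across trials of one epoch, and its time average over the averaging
#' windows.
#'
#' @inheritParams coincidence_index
#' @param epoch epoch label.
#' @param windows window schedule.
#' @param method `"pearson"` (counts are near-Gaussian at these rates) or
#'   `"spearman"`.
#' @return list with `by_window` (named vector) and `time_average`.
#' @export
spike_count_correlation <- function(dataset, epoch,
                                    windows = window_schedule(),
                                    method = c("pearson", "spearman")) {
  method <- match.arg(method)
  stopifnot(length(dataset$units) == 2)
  ds <- subset_trials(dataset, epochs = epoch)
  if (nrow(ds$trials) < 5) stop("need >= 5 trials")
  ends <- windows$averaging_ends
  r <- vapply(ends, function(e) {
    c1 <- spike_counts(ds, ds$units[1], c(windows$start, e))
    c2 <- spike_counts(ds, ds$units[2], c(windows$start, e))
    if (stats::sd(c1) == 0 || stats::sd(c2) == 0) return(NA_real_)
    stats::cor(c1, c2, method = method)
  }, numeric(1))
  names(r) <- ends
  if (all(is.na(r)))
    warning("zero-variance counts in every window: correlation undefined")
  list(by_window = r, time_average = mean(r, na.rm = TRUE))
}

extract_It <- function(x) {
  if (inherits(x, "epoch_decoder")) return(x$It)
  as.matrix(x)
}
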