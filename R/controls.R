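#' PETH-preserving spike shuffle (shuffle 1)
#'
#' For each requested epoch of one unit, pools every spike emitted in the
#' full analysis window across that epoch's trials and reassigns each spike
#' independently to a uniformly random trial.  The pooled spike-time
#' multiset — hence the peri-event time histogram — is conserved exactly,
#' while within-trial temporal correlations and the trial-to-trial count
#' structure are destroyed: per-trial counts become
#' Binomial(N_spikes, 1/n_trials), i.e. near-Poisson.  Shuffled data for
#' smaller analysis windows are obtained downstream by pruning this
#' full-window shuffle (counts restricted to a sub-window of a Poisson
#' process are again Poisson).
#'
#' @param dataset an [epoch_dataset()].
#' @param unit unit to shuffle (default: the only unit).
#' @param epochs epoch labels to shuffle (default: all present).
#' @param seed RNG seed.
#' @return A new `epoch_dataset` with shuffled trains for `unit`.
#' @export
shuffle_preserve_peth <- function(dataset, unit = NULL, epochs = NULL,
                                  seed = 1) {
  stopifnot(inherits(dataset, "epoch_dataset"))
  unit <- pick_unit(dataset, unit)
  if (is.null(epochs)) epochs <- unique(dataset$trials$epoch)
  set.seed(seed)
  sp <- dataset$spikes[[unit]]
  for (e in epochs) {
    rows <- which(dataset$trials$epoch == e)
    if (length(rows) < 1) next
    pool <- unlist(sp[rows], use.names = FALSE)
    if (anyDuplicated(pool))
      stop("pooled spike times are not unique; cannot shuffle without ",
           "creating duplicate times within a trial")
    assign_to <- sample(length(rows), length(pool), replace = TRUE)
    for (r in seq_along(rows))
      sp[[rows[r]]] <- sort(pool[assign_to == r])
  }
  dataset$spikes[[unit]] <- sp
  dataset
}

#' Count-preserving spike shuffle (shuffle 2)
#'
#' Within each epoch of one unit and one analysis window, randomly permutes
#' all available spike times across trials and deals back to every trial
#' exactly its original number of spikes (without replacement).  Both the
#' pooled spike-time multiset (PETH) and every trial's spike count in the
#' window are conserved bit-exactly, so spike-count (`q = 0`) decoding of
#' the shuffled data is identical to the original; only within-trial
#' temporal correlations beyond the PETH are destroyed.  The shuffle is
#' performed independently per analysis window, epoch, unit and replicate.
#'
#' @inheritParams shuffle_preserve_peth
#' @param window analysis window `(start, end)`; spikes outside it are
#'   dropped from the returned dataset (each analysis window gets its own
#'   shuffle).
#' @return A new `epoch_dataset` restricted to `window` with shuffled
#'   trains for `unit`.
#' @export
shuffle_preserve_counts <- function(dataset, unit = NULL, epochs = NULL,
                                    window = NULL, seed = 1) {
  stopifnot(inherits(dataset, "epoch_dataset"))
  unit <- pick_unit(dataset, unit)
  if (is.null(epochs)) epochs <- unique(dataset$trials$epoch)
  if (is.null(window)) window <- dataset$window
  set.seed(seed)
  for (u in dataset$units)
    dataset$spikes[[u]] <- lapply(dataset$spikes[[u]], restrict_window,
                                  window = window)
  sp <- dataset$spikes[[unit]]
  for (e in epochs) {
    rows <- which(dataset$trials$epoch == e)
    if (length(rows) < 2) next
    counts <- lengths(sp[rows])
    pool <- unlist(sp[rows], use.names = FALSE)
    if (anyDuplicated(pool))
      stop("pooled spike times are not unique; cannot shuffle without ",
           "creating duplicate times within a trial")
    pool <- sample(pool)
    stop_at <- cumsum(counts)
    start_at <- c(0L, stop_at[-length(stop_at)]) + 1L
    for (r in seq_along(rows))
      sp[[rows[r]]] <- if (counts[r] > 0)
        sort(pool[start_at[r]:stop_at[r]]) else numeric(0)
  }
  dataset$spikes[[unit]] <- sp
  dataset$window <- as.numeric(window)
  dataset
}

#' Fano factor of trial spike counts
#'
#' Unbiased sample variance of the per-trial spike counts divided by their
#' mean.  Equals 1 for a Poisson process; values above 1 indicate
#' super-Poisson trial-to-trial variability (e.g. a trial-specific gain),
#' values below 1 sub-Poisson variability (e.g. refractoriness).
#'
#' @param counts integer vector of spike counts, one per trial (>= 2).
#' @return dimensionless Fano factor.
#' @export
fano_factor <- function(counts) {
  if (length(counts) < 2) stop("need >= 2 trials")
  m <- mean(counts)
  if (m == 0) stop("zero mean count: Fano factor undefined")
  stats::var(counts) / m
}

#' @rdname fano_factor
#' @inheritParams shuffle_preserve_peth
#' @param epoch epoch label.
#' @param window analysis window.
#' @export
epoch_fano <- function(dataset, unit = NULL, epoch, window = NULL) {
  ds <- subset_trials(dataset, epochs = epoch)
  if (is.null(window)) window <- ds$window
  fano_factor(spike_counts(ds, unit, window))
}

#' Information change induced by spike shuffling
#'
#' Decodes the original dataset and an ensemble of shuffled datasets with
#' the same (uncorrected) normalized-information pipeline, and returns the
#' per-(q, window) difference between original information and the median
#' information across shuffles.  Because both shuffles preserve the trial
#' counts per epoch, the finite-sample bias is common to both terms and
#' cancels in the difference, so it is not re-estimated here.
#'
#' @inheritParams decode_epochs
#' @param kind `"peth"` (shuffle 1, [shuffle_preserve_peth()], pruned per
#'   window) or `"counts"` (shuffle 2, [shuffle_preserve_counts()],
#'   re-shuffled independently per window).
#' @param n_shuffles shuffle replicates.
#' @return list with `delta` (`q x window` matrix of
#'   `I_original - median(I_shuffled)`), `info_original`, `info_shuffled`
#'   (`q x window x n_shuffles`), grids and windows.
#' @export
shuffle_information_delta <- function(dataset, unit = NULL,
                                      contrast = c("first_reward", "repetition"),
                                      kind = c("counts", "peth"),
                                      q_grid = default_q_grid(),
                                      windows = window_schedule(),
                                      n_shuffles = 1000,
                                      rule = c("median", "nearest_neighbor"),
                                      m_nearest = 3, seed = 1) {
  kind <- match.arg(kind); rule <- match.arg(rule)
  stopifnot(inherits(dataset, "epoch_dataset"))
  unit <- pick_unit(dataset, unit)
  ds <- subset_trials(dataset, epochs = contrast)
  ends <- windows$analysis_ends
  i0 <- info_surface_raw(ds, unit, contrast, q_grid, windows, rule,
                         m_nearest, seed)
  ish <- array(NA_real_, c(length(q_grid), length(ends), n_shuffles),
               dimnames = list(q = q_grid, window = ends, NULL))
  for (s in seq_len(n_shuffles)) {
    sseed <- substream_seed(seed, 7L, s)
    if (kind == "peth") {
      shd <- shuffle_preserve_peth(ds, unit, seed = sseed)
      ish[, , s] <- info_surface_raw(shd, unit, contrast, q_grid, windows,
                                     rule, m_nearest, seed)
    } else {
      ## independent shuffle per analysis window
      for (w in seq_along(ends)) {
        shd <- shuffle_preserve_counts(ds, unit,
                                       window = c(windows$start, ends[w]),
                                       seed = substream_seed(sseed, 11L, w))
        ish[, w, s] <- info_surface_raw(shd, unit, contrast, q_grid,
                                        list(start = windows$start,
                                             analysis_ends = ends[w]),
                                        rule, m_nearest, seed)
      }
    }
  }
  med <- apply(ish, c(1, 2), median)
  list(delta = i0 - med, info_original = i0, info_shuffled = ish,
       q_grid = q_grid, windows = windows, kind = kind)
}

## normalized (uncorrected) information per (q, window) for one unit
info_surface_raw <- function(ds, unit, contrast, q_grid, windows, rule,
                             m_nearest, seed) {
  lab <- factor(ds$trials$epoch, levels = contrast)
  L <- matrix(as.integer(lab) - 1L, ncol = 1)
  n <- nrow(L)
  set.seed(seed)
  tie_u <- matrix(runif(n), n, 1)
  Hmax <- label_entropy(L[, 1])
  ends <- windows$analysis_ends
  out <- matrix(NA_real_, length(q_grid), length(ends),
                dimnames = list(q = q_grid, window = ends))
  for (w in seq_along(ends)) {
    tr <- unit_trains(ds, unit, c(windows$start, ends[w]))
    for (qi in seq_along(q_grid)) {
      D <- cpp_vp_dist_matrix(tr, q_grid[qi])
      cl <- cpp_classify(D, L, 2L, if (rule == "median") 0L else 1L,
                         m_nearest, tie_u)
      out[qi, w] <- info_columns(L, cl$pred) / Hmax
    }
  }
  out
}

## deterministic substream seed derivation (kept below 2^31)
substream_seed <- function(seed, stream, index) {
  as.integer((as.numeric(seed) * 48271 + stream * 1299709 + index * 15485863) %%
               2147483647)
}
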