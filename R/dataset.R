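#' Trial-structured spike dataset grouped by task epoch
#'
#' Container for all trials of one recording (or simulated session): a trial
#' table with task-epoch labels and behavior metadata, plus per-unit spike
#' times aligned to feedback onset.  The task epoch is the `[0.001, 1]` s
#' interval after a feedback event, labeled `error`, `first_reward` or
#' `repetition`.
#'
#' @param trials data.frame with at least columns `trial_id` (unique) and
#'   `epoch` (one of `"error"`, `"first_reward"`, `"repetition"`).  Optional
#'   columns used downstream: `response_time` (seconds, `NA` where
#'   undefined), `interrupted` (logical), `problem_id`,
#'   `position_in_problem`, `n_preceding_errors`.
#' @param spikes named list, one element per unit; each element is a list of
#'   numeric spike-time vectors (seconds relative to feedback onset),
#'   parallel to the rows of `trials`.  Empty trains are allowed.
#' @param window analysis window `(t_start, t_end)`, half-open
#'   `[t_start, t_end)`; spikes must lie inside it.
#' @return An object of class `epoch_dataset`.
#' @export
epoch_dataset <- function(trials, spikes, window = c(0.001, 1)) {
  stopifnot(is.data.frame(trials), is.list(spikes), length(window) == 2)
  if (!all(c("trial_id", "epoch") %in% names(trials)))
    stop("`trials` needs columns `trial_id` and `epoch`")
  if (anyDuplicated(trials$trial_id))
    stop("duplicate trial ids")
  bad <- setdiff(unique(trials$epoch), c("error", "first_reward", "repetition"))
  if (length(bad))
    stop("unknown epoch label(s): ", paste(bad, collapse = ", "))
  if (is.null(names(spikes)) || any(names(spikes) == ""))
    stop("`spikes` must be a named list (one element per unit)")
  for (u in names(spikes)) {
    if (length(spikes[[u]]) != nrow(trials))
      stop("unit ", u, ": spikes must have one train per trial")
    spikes[[u]] <- lapply(spikes[[u]], function(t) {
      t <- check_train(t)
      if (length(t) && (min(t) < window[1] || max(t) >= window[2]))
        stop("unit ", u, ": spike time outside the half-open window [",
             window[1], ", ", window[2], ")")
      t
    })
  }
  structure(list(trials = trials, spikes = spikes,
                 units = names(spikes), window = as.numeric(window)),
            class = "epoch_dataset")
}

#' @export
print.epoch_dataset <- function(x, ...) {
  tab <- table(x$trials$epoch)
  cat("epoch_dataset:", nrow(x$trials), "trials,",
      length(x$units), "unit(s) [", paste(x$units, collapse = ", "), "]\n")
  cat("  window [", x$window[1], ",", x$window[2], ") s;  trials per epoch: ",
      paste(names(tab), tab, sep = "=", collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Subset an epoch_dataset by trial index or epoch
#'
#' @param dataset an [epoch_dataset()].
#' @param idx integer/logical index into trials, or `NULL`.
#' @param epochs keep only these epoch labels (applied after `idx`).
#' @return A new `epoch_dataset`.
#' @export
subset_trials <- function(dataset, idx = NULL, epochs = NULL) {
  stopifnot(inherits(dataset, "epoch_dataset"))
  keep <- seq_len(nrow(dataset$trials))
  if (!is.null(idx)) keep <- keep[idx]
  if (!is.null(epochs))
    keep <- keep[dataset$trials$epoch[keep] %in% epochs]
  dataset$trials <- dataset$trials[keep, , drop = FALSE]
  rownames(dataset$trials) <- NULL
  dataset$spikes <- lapply(dataset$spikes, function(s) s[keep])
  dataset
}

#' Spike trains of one unit restricted to an analysis window
#'
#' @inheritParams subset_trials
#' @param unit unit id (default: the only unit).
#' @param window `(t_start, t_end)`; defaults to the dataset window.
#' @return list of numeric vectors, one per trial.
#' @export
unit_trains <- function(dataset, unit = NULL, window = NULL) {
  stopifnot(inherits(dataset, "epoch_dataset"))
  unit <- pick_unit(dataset, unit)
  if (is.null(window)) return(dataset$spikes[[unit]])
  lapply(dataset$spikes[[unit]], restrict_window, window = window)
}

#' Per-trial spike counts of one unit in a window
#'
#' @inheritParams unit_trains
#' @return integer vector parallel to trials.
#' @export
spike_counts <- function(dataset, unit = NULL, window = NULL) {
  lengths(unit_trains(dataset, unit, window))
}

pick_unit <- function(dataset, unit) {
  if (is.null(unit)) {
    if (length(dataset$units) != 1)
      stop("dataset has ", length(dataset$units),
           " units; specify `unit`")
    return(dataset$units[1])
  }
  if (!unit %in% dataset$units) stop("unknown unit: ", unit)
  unit
}

#' Analysis-window schedule
#'
#' All windows start 1 ms after feedback onset (avoiding delivery
#' artifacts).  The 16 analysis windows end at 50-600 ms in 50 ms steps and
#' then 700-1000 ms in 100 ms steps; the 10 averaging windows used for the
#' time-averaged information end at 100 ms to 1 s in 100 ms steps.
#'
#' @return list with `start`, `analysis_ends` (16 values) and
#'   `averaging_ends` (10 values), in seconds.
#' @export
window_schedule <- function() {
  list(start = 0.001,
       analysis_ends = c(seq(0.05, 0.60, by = 0.05), seq(0.70, 1.00, by = 0.10)),
       averaging_ends = seq(0.10, 1.00, by = 0.10))
}

#' Default parameter grids for the decoder
#'
#' The temporal-sensitivity grid spans spike-count decoding (`q = 0`),
#' near-integrator sensitivities (0.5, 1/s), the optimum region (5-20/s) and
#' clearly over-sensitive values (30, 40/s).  The unit-distinction grid
#' spans merged decoding (`k = 0`) to fully separate units (`k = 2`) in
#' steps of 0.25.
#'
#' @return numeric vector of grid values.
#' @export
default_q_grid <- function() c(0, 0.5, 1, 5, 10, 15, 20, 30, 40)

#' @rdname default_q_grid
#' @export
default_k_grid <- function() seq(0, 2, by = 0.25)
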