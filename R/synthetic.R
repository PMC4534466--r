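#' Configuration of the synthetic session generator
#'
#' Defines the statistical structure of a simulated recording session of
#' the trial-and-error problem-solving task: the animal searches among 4
#' targets (exploration errors), finds the rewarded one (first reward) and
#' then repeats it.  In 90% of problems the repetition period lasts three
#' trials after the first reward; in the remaining 10% it lasts 7-11
#' trials.  Per task epoch, spike trains are the superposition of (i) an
#' inhomogeneous-Poisson background whose intensity is an alpha-shaped
#' transient over a baseline, scaled by a lognormal trial gain
#' (super-Poisson counts at long windows), and (ii) an optional jittered
#' template: one of possibly several reliable spike-time patterns, each
#' spike kept with probability `1 - p_del` and jittered by a zero-mean
#' Gaussian.  An absolute refractory period removes violating spikes
#' (keeping the earlier one), producing sub-Poisson counts at short
#' windows.  Response times on the trial following the first reward are
#' coupled to the trial's deviation from the epoch's typical firing via
#' `RT = mu + beta * z + eps`, where `z` is a standardized combination of
#' the absolute count deviation and the mean absolute template jitter.
#'
#' Epoch rate profiles are `lambda(t) = baseline + amp * (t/peak) *
#' exp(1 - t/peak)` (alpha function peaking at `peak` seconds with maximum
#' `amp`), a face-valid shape for post-feedback transients.
#'
#' @param n_problems number of problems per session.
#' @param p_three_rep probability that the repetition period lasts exactly
#'   three trials (otherwise 7-11, uniform).
#' @param long_rep_range inclusive range of long repetition counts.
#' @param n_targets number of targets searched during exploration.
#' @param p_omission probability that a problem contains a post-discovery
#'   omission error (that trial and the following ones are discarded by
#'   [filter_trials()]).
#' @param p_interrupt probability that the response-time trial is
#'   interrupted.
#' @param epochs named list (`error`, `first_reward`, `repetition`) of
#'   lists with `baseline` (Hz), `amp` (Hz), `peak` (s) and optional
#'   `templates = list(patterns = list(<numeric times>), sigma_jitter,
#'   p_del, pattern_probs)`.
#' @param sigma_gain lognormal sdlog of the multiplicative trial gain
#'   (meanlog is set so the gain has mean 1); 0 disables gain variability.
#' @param refractory absolute refractory period (s); 0 disables it.
#' @param rho_shared for two-unit sessions, fraction of template spikes
#'   shared (same base times) between the units.
#' @param shared_gain for two-unit sessions, draw one common trial gain.
#' @param rt list `mu`, `beta`, `sigma`: response-time model (seconds);
#'   `beta` multiplies the standardized deviation `z`.
#' @param dev_weights weights `c(count, jitter)` of the two components of
#'   the deviation summary `z`.
#' @param window task-epoch analysis window (s post-feedback).
#' @return object of class `generator_config`.
#' @export
generator_config <- function(n_problems = 40,
                             p_three_rep = 0.90,
                             long_rep_range = c(7, 11),
                             n_targets = 4,
                             p_omission = 0.01,
                             p_interrupt = 0.05,
                             epochs = default_epoch_profiles(),
                             sigma_gain = 0.4,
                             refractory = 0.003,
                             rho_shared = 0,
                             shared_gain = FALSE,
                             rt = list(mu = 0.5, beta = 0.05, sigma = 0.1),
                             dev_weights = c(count = 1, jitter = 1),
                             window = c(0.001, 1)) {
  cfg <- list(n_problems = n_problems, p_three_rep = p_three_rep,
              long_rep_range = long_rep_range, n_targets = n_targets,
              p_omission = p_omission, p_interrupt = p_interrupt,
              epochs = epochs, sigma_gain = sigma_gain,
              refractory = refractory, rho_shared = rho_shared,
              shared_gain = shared_gain, rt = rt,
              dev_weights = dev_weights, window = window)
  validate_generator_config(cfg)
  class(cfg) <- "generator_config"
  cfg
}

#' @rdname generator_config
#' @export
default_epoch_profiles <- function() {
  list(
    error = list(baseline = 3, amp = 10, peak = 0.15,
                 templates = list(patterns = list(c(0.06, 0.13, 0.22, 0.40)),
                                  sigma_jitter = 0.030, p_del = 0.15)),
    first_reward = list(baseline = 3, amp = 8, peak = 0.20,
                        templates = list(patterns = list(c(0.09, 0.21, 0.34, 0.55)),
                                         sigma_jitter = 0.030, p_del = 0.15)),
    repetition = list(baseline = 3, amp = 4, peak = 0.25, templates = NULL))
}

validate_generator_config <- function(cfg) {
  bad <- character(0)
  chk <- function(ok, msg) if (!isTRUE(ok)) bad <<- c(bad, msg)
  chk(cfg$n_problems >= 1, "n_problems >= 1")
  chk(cfg$p_three_rep >= 0 && cfg$p_three_rep <= 1, "p_three_rep in [0,1]")
  chk(cfg$p_omission >= 0 && cfg$p_omission <= 1, "p_omission in [0,1]")
  chk(cfg$p_interrupt >= 0 && cfg$p_interrupt <= 1, "p_interrupt in [0,1]")
  chk(cfg$rho_shared >= 0 && cfg$rho_shared <= 1, "rho_shared in [0,1]")
  chk(cfg$sigma_gain >= 0, "sigma_gain >= 0")
  chk(cfg$refractory >= 0, "refractory >= 0")
  chk(cfg$n_targets >= 2, "n_targets >= 2")
  chk(all(cfg$long_rep_range >= 1) && diff(cfg$long_rep_range) >= 0,
      "long_rep_range increasing, >= 1")
  chk(cfg$rt$sigma >= 0, "rt$sigma >= 0")
  chk(all(c("error", "first_reward", "repetition") %in% names(cfg$epochs)),
      "epochs must define error, first_reward, repetition")
  for (e in names(cfg$epochs)) {
    ep <- cfg$epochs[[e]]
    chk(ep$baseline >= 0 && ep$amp >= 0 && ep$peak > 0,
        paste0("epochs$", e, ": rates >= 0, peak > 0"))
    if (!is.null(ep$templates)) {
      chk(ep$templates$sigma_jitter >= 0,
          paste0("epochs$", e, ": sigma_jitter >= 0"))
      chk(ep$templates$p_del >= 0 && ep$templates$p_del <= 1,
          paste0("epochs$", e, ": p_del in [0,1]"))
    }
  }
  if (length(bad))
    stop("invalid generator config: ", paste(bad, collapse = "; "))
  invisible(cfg)
}

#' Simulate the outcome structure of task problems
#'
#' Draws, per problem, the number of exploration errors (the rewarded
#' target is found by trial-and-error among `n_targets` without repeating
#' choices, so the error count is uniform on `0..n_targets-1`), the length
#' of the repetition period (3 with probability `p_three_rep`, otherwise
#' uniform on `long_rep_range`) and whether a post-discovery omission error
#' occurs (uniform position within the repetition period).
#'
#' @param n_problems number of problems.
#' @param config a [generator_config()].
#' @param seed RNG seed.
#' @return data.frame with `problem_id`, `n_errors`, `n_reps`,
#'   `omission_at` (repetition index of the omission, `NA` if none).
#' @export
simulate_problem_structure <- function(n_problems, config = generator_config(),
                                       seed = 1) {
  set.seed(substream_seed(seed, 1L, 0L))
  n_err <- sample.int(config$n_targets, n_problems, replace = TRUE) - 1L
  long <- runif(n_problems) >= config$p_three_rep
  n_reps <- ifelse(long,
                   sample(seq(config$long_rep_range[1], config$long_rep_range[2]),
                          n_problems, replace = TRUE),
                   3L)
  has_om <- runif(n_problems) < config$p_omission
  om_at <- ifelse(has_om, 1L + floor(runif(n_problems) * n_reps), NA_integer_)
  data.frame(problem_id = seq_len(n_problems), n_errors = n_err,
             n_reps = as.integer(n_reps), omission_at = as.integer(om_at))
}

#' Simulate a task session of spike trains with ground truth
#'
#' Generates a full session under a [generator_config()]: the problem
#' structure, per-trial spike trains for `n_units` units, response times on
#' first-reward trials (measured on the following touch) and the ground
#' truth needed for parameter-recovery tests.  All randomness flows from
#' counter-based substreams of `seed` keyed by problem, trial and unit, so
#' identical `(config, seed)` reproduce the session bit-identically.
#'
#' @param config a [generator_config()].
#' @param seed master seed.
#' @param n_units 1 or 2 simultaneously recorded units.
#' @return object of class `vp_session`: list with `dataset` (an
#'   [epoch_dataset()] carrying all generated trials and problem metadata),
#'   `ground_truth` (per unit: data.frame of trial gain, pattern index,
#'   kept template spikes, mean absolute jitter, count and deviation `z`),
#'   `problems` and `config`.
#' @export
simulate_session <- function(config = generator_config(), seed = 1,
                             n_units = 1) {
  stopifnot(inherits(config, "generator_config"), n_units %in% 1:2)
  probs <- simulate_problem_structure(config$n_problems, config, seed)
  units <- paste0("u", seq_len(n_units))
  templates <- lapply(seq_len(n_units), function(u)
    unit_templates(config, u, seed))

  rows <- list(); tid <- 0L
  for (p in seq_len(nrow(probs))) {
    E <- probs$n_errors[p]; R <- probs$n_reps[p]; om <- probs$omission_at[p]
    pos <- 0L
    for (i in seq_len(E)) {
      pos <- pos + 1L; tid <- tid + 1L
      rows[[tid]] <- data.frame(trial_id = tid, problem_id = p,
                                position_in_problem = pos, epoch = "error",
                                rep_index = NA_integer_,
                                n_preceding_errors = i - 1L,
                                omission = FALSE)
    }
    pos <- pos + 1L; tid <- tid + 1L
    rows[[tid]] <- data.frame(trial_id = tid, problem_id = p,
                              position_in_problem = pos, epoch = "first_reward",
                              rep_index = NA_integer_,
                              n_preceding_errors = E, omission = FALSE)
    for (r in seq_len(R)) {
      pos <- pos + 1L; tid <- tid + 1L
      is_om <- !is.na(om) && r == om
      rows[[tid]] <- data.frame(trial_id = tid, problem_id = p,
                                position_in_problem = pos,
                                epoch = if (is_om) "error" else "repetition",
                                rep_index = r,
                                n_preceding_errors = E, omission = is_om)
    }
  }
  trials <- do.call(rbind, rows)
  n <- nrow(trials)
  trials$response_time <- NA_real_
  trials$interrupted <- FALSE

  spikes <- rep(list(vector("list", n)), n_units)
  names(spikes) <- units
  gt <- lapply(units, function(u)
    data.frame(trial_id = trials$trial_id, gain = NA_real_,
               pattern = NA_integer_, n_template = NA_integer_,
               mean_abs_jitter = NA_real_, count = NA_integer_,
               z = NA_real_))
  names(gt) <- units

  for (i in seq_len(n)) {
    ep <- trials$epoch[i]
    epc <- config$epochs[[ep]]
    ## pattern choice and gain can be shared across the two units
    set.seed(substream_seed(seed, 30L, trials$trial_id[i]))
    shared_pattern <- if (!is.null(epc$templates)) {
      pp <- epc$templates$pattern_probs
      np <- length(epc$templates$patterns)
      if (is.null(pp)) sample.int(np, 1) else sample.int(np, 1, prob = pp)
    } else NA_integer_
    shared_g <- if (config$sigma_gain > 0)
      rlnorm(1, -config$sigma_gain^2 / 2, config$sigma_gain) else 1
    for (u in seq_len(n_units)) {
      set.seed(substream_seed(seed, 40L + u, trials$trial_id[i]))
      g <- if (config$shared_gain || config$sigma_gain == 0) shared_g
           else rlnorm(1, -config$sigma_gain^2 / 2, config$sigma_gain)
      sim <- simulate_trial_train(epc, templates[[u]][[ep]], shared_pattern,
                                  g, config)
      spikes[[u]][[i]] <- sim$times
      gt[[u]]$gain[i] <- g
      gt[[u]]$pattern[i] <- shared_pattern
      gt[[u]]$n_template[i] <- sim$n_template
      gt[[u]]$mean_abs_jitter[i] <- sim$mean_abs_jitter
      gt[[u]]$count[i] <- length(sim$times)
    }
  }

  ## deviation summary z and response times on first-reward trials
  fr <- which(trials$epoch == "first_reward")
  for (u in seq_len(n_units)) {
    mu_n <- expected_count(config, "first_reward")
    zc <- abs(gt[[u]]$count[fr] - mu_n)
    zj <- gt[[u]]$mean_abs_jitter[fr]
    zj[is.na(zj)] <- 0
    z <- config$dev_weights[["count"]] * standardize(zc) +
      config$dev_weights[["jitter"]] * standardize(zj)
    gt[[u]]$z[fr] <- standardize(z)
  }
  set.seed(substream_seed(seed, 50L, 0L))
  zrt <- gt[[1]]$z[fr]
  trials$response_time[fr] <- config$rt$mu + config$rt$beta * zrt +
    rnorm(length(fr), 0, config$rt$sigma)
  trials$response_time[fr] <- pmax(0.05, trials$response_time[fr])
  trials$interrupted[fr] <- runif(length(fr)) < config$p_interrupt

  ds <- epoch_dataset(trials, spikes, config$window)
  structure(list(dataset = ds, ground_truth = gt, problems = probs,
                 config = config, seed = seed),
            class = "vp_session")
}

#' @export
print.vp_session <- function(x, ...) {
  cat("Synthetic task session:", nrow(x$problems), "problems,",
      nrow(x$dataset$trials), "trials,", length(x$dataset$units), "unit(s)\n")
  print(x$dataset)
  invisible(x)
}

#' @rdname simulate_session
#' @export
simulate_pair_session <- function(config = generator_config(), seed = 1) {
  simulate_session(config, seed, n_units = 2)
}

## per-unit template sets; unit 2 shares a fraction rho_shared of each
## pattern's base times with unit 1, the rest are redrawn (seeded).
unit_templates <- function(config, u, seed) {
  out <- list()
  for (e in names(config$epochs)) {
    tpl <- config$epochs[[e]]$templates
    if (is.null(tpl)) { out[[e]] <- NULL; next }
    if (u == 2) {
      set.seed(substream_seed(seed, 20L, match(e, names(config$epochs))))
      tpl$patterns <- lapply(tpl$patterns, function(pat) {
        n <- length(pat)
        n_shared <- round(config$rho_shared * n)
        keep <- seq_len(n_shared)
        new_times <- sort(runif(n - n_shared, config$window[1] + 0.02,
                                config$window[2] - 0.05))
        sort(c(pat[keep], new_times))
      })
    }
    out[[e]] <- tpl
  }
  out
}

## one trial's spike train: thinned inhomogeneous Poisson background scaled
## by the trial gain, plus the jittered/thinned template, with absolute
## refractoriness enforced by deleting the later spike.
simulate_trial_train <- function(epc, tpl, pattern_idx, gain, config) {
  w <- config$window
  dur <- w[2] - w[1]
  lam_max <- gain * (epc$baseline + epc$amp)
  bg <- numeric(0)
  if (lam_max > 0) {
    m <- rpois(1, lam_max * dur)
    if (m > 0) {
      tt <- sort(runif(m, w[1], w[2]))
      lam <- gain * (epc$baseline +
                       epc$amp * (tt / epc$peak) * exp(1 - tt / epc$peak))
      bg <- tt[runif(m) < lam / lam_max]
    }
  }
  n_template <- 0L; mean_abs_jitter <- NA_real_
  tsp <- numeric(0)
  if (!is.null(tpl) && !is.na(pattern_idx)) {
    base <- tpl$patterns[[pattern_idx]]
    kept <- runif(length(base)) >= tpl$p_del
    jit <- rnorm(sum(kept), 0, tpl$sigma_jitter)
    tsp <- base[kept] + jit
    tsp <- tsp[tsp >= w[1] & tsp < w[2]]
    n_template <- length(tsp)
    mean_abs_jitter <- if (n_template > 0) mean(abs(jit)) else NA_real_
  }
  times <- sort(c(bg, tsp))
  times <- unique(times)
  if (config$refractory > 0 && length(times) > 1) {
    keep <- rep(TRUE, length(times))
    last <- times[1]
    for (j in 2:length(times)) {
      if (times[j] - last < config$refractory) keep[j] <- FALSE
      else last <- times[j]
    }
    times <- times[keep]
  }
  list(times = times, n_template = n_template,
       mean_abs_jitter = mean_abs_jitter)
}

## expected spike count of one trial of an epoch (unit gain)
expected_count <- function(config, epoch) {
  epc <- config$epochs[[epoch]]
  w <- config$window
  f <- function(t) epc$baseline + epc$amp * (t / epc$peak) * exp(1 - t / epc$peak)
  bgn <- stats::integrate(f, w[1], w[2])$value
  tpl <- epc$templates
  tn <- if (is.null(tpl)) 0
  else mean(lengths(tpl$patterns)) * (1 - tpl$p_del)
  bgn + tn
}

standardize <- function(x) {
  s <- stats::sd(x)
  if (is.na(s) || s == 0) return(rep(0, length(x)))
  (x - mean(x)) / s
}

#' Apply the trial-selection filters of the task analysis
#'
#' Keeps: only the first and second erroneous touches of each search;
#' first rewards preceded by fewer than three errors; repetition trials
#' 1-3 that followed a search with at most three errors.  In problems with
#' a post-discovery omission, the omission trial and all following trials
#' of the problem are discarded (previous trials are kept).
#'
#' @param x a `vp_session` or an [epoch_dataset()] whose trial table has
#'   `problem_id`, `position_in_problem`, `epoch`, `rep_index`,
#'   `n_preceding_errors` and `omission` columns.
#' @return the filtered [epoch_dataset()].
#' @export
filter_trials <- function(x) {
  ds <- if (inherits(x, "vp_session")) x$dataset else x
  stopifnot(inherits(ds, "epoch_dataset"))
  tr <- ds$trials
  need <- c("problem_id", "position_in_problem", "epoch", "rep_index",
            "n_preceding_errors", "omission")
  if (!all(need %in% names(tr)))
    stop("malformed problem structure: missing column(s) ",
         paste(setdiff(need, names(tr)), collapse = ", "))
  keep <- rep(FALSE, nrow(tr))
  for (p in unique(tr$problem_id)) {
    idx <- which(tr$problem_id == p)
    sub <- tr[idx, , drop = FALSE]
    om_pos <- sub$position_in_problem[sub$omission]
    before_om <- if (length(om_pos)) sub$position_in_problem < min(om_pos)
                 else rep(TRUE, nrow(sub))
    is_search_err <- sub$epoch == "error" & !sub$omission
    err_rank <- cumsum(is_search_err) * is_search_err
    k <- rep(FALSE, nrow(sub))
    k[is_search_err & err_rank <= 2] <- TRUE
    k[sub$epoch == "first_reward" & sub$n_preceding_errors < 3] <- TRUE
    k[sub$epoch == "repetition" & !is.na(sub$rep_index) &
        sub$rep_index <= 3 & sub$n_preceding_errors <= 3] <- TRUE
    keep[idx] <- k & before_om
  }
  subset_trials(ds, keep)
}
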