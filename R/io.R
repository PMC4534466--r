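#' Write a dataset to plain CSV tables
#'
#' The canonical interchange format is a pair of CSVs: a spike table with
#' one row per spike (`session_id, unit_id, trial_id, epoch, spike_time_s`)
#' and a trial table with one row per trial (`session_id, trial_id,
#' problem_id, position_in_problem, epoch, response_time_s, interrupted,
#' n_preceding_errors`).
#'
#' @param dataset an [epoch_dataset()].
#' @param spikes_path,trials_path output CSV paths.
#' @param session_id identifier written in both tables.
#' @return invisibly, the two paths.
#' @export
write_session <- function(dataset, spikes_path, trials_path,
                          session_id = "s1") {
  stopifnot(inherits(dataset, "epoch_dataset"))
  tr <- dataset$trials
  rows <- list()
  for (u in dataset$units) {
    sp <- dataset$spikes[[u]]
    nsp <- lengths(sp)
    if (sum(nsp) == 0) next
    rows[[u]] <- data.frame(session_id = session_id, unit_id = u,
                            trial_id = rep(tr$trial_id, nsp),
                            epoch = rep(tr$epoch, nsp),
                            spike_time_s = unlist(sp, use.names = FALSE))
  }
  spikes_df <- if (length(rows)) do.call(rbind, rows)
  else data.frame(session_id = character(0), unit_id = character(0),
                  trial_id = character(0), epoch = character(0),
                  spike_time_s = numeric(0))
  write.csv(spikes_df, spikes_path, row.names = FALSE)
  out <- data.frame(session_id = session_id,
                    trial_id = tr$trial_id,
                    problem_id = if ("problem_id" %in% names(tr)) tr$problem_id else NA,
                    position_in_problem = if ("position_in_problem" %in% names(tr))
                      tr$position_in_problem else NA,
                    epoch = tr$epoch,
                    response_time_s = if ("response_time" %in% names(tr))
                      tr$response_time else NA,
                    interrupted = if ("interrupted" %in% names(tr))
                      tr$interrupted else FALSE,
                    n_preceding_errors = if ("n_preceding_errors" %in% names(tr))
                      tr$n_preceding_errors else NA)
  write.csv(out, trials_path, row.names = FALSE)
  invisible(c(spikes = spikes_path, trials = trials_path))
}

#' Read a dataset from plain CSV tables
#'
#' Joins and validates a spike table and a trial table (see
#' [write_session()] for the layout).  Spikes outside the analysis window
#' are dropped with a message reporting the count; duplicate trial ids,
#' non-increasing spike times within a trial and unknown epoch labels are
#' rejected with descriptive errors.
#'
#' @param spikes_path,trials_path input CSV paths.
#' @param window analysis window, half-open.
#' @return an [epoch_dataset()].
#' @export
read_session <- function(spikes_path, trials_path, window = c(0.001, 1)) {
  sp <- read.csv(spikes_path, stringsAsFactors = FALSE)
  tr <- read.csv(trials_path, stringsAsFactors = FALSE)
  need_sp <- c("unit_id", "trial_id", "spike_time_s")
  if (!all(need_sp %in% names(sp)))
    stop("spike table must have columns ", paste(need_sp, collapse = ", "))
  if (!all(c("trial_id", "epoch") %in% names(tr)))
    stop("trial table must have columns trial_id, epoch")
  if (anyDuplicated(tr$trial_id))
    stop("duplicate trial ids in the trial table")
  bad <- setdiff(unique(tr$epoch), c("error", "first_reward", "repetition"))
  if (length(bad)) stop("unknown epoch label(s): ", paste(bad, collapse = ", "))
  unknown <- setdiff(unique(sp$trial_id), tr$trial_id)
  if (length(unknown))
    stop("spike table references unknown trial id(s): ",
         paste(utils::head(unknown, 5), collapse = ", "))
  inside <- sp$spike_time_s >= window[1] & sp$spike_time_s < window[2]
  if (any(!inside))
    message(sum(!inside), " spike(s) outside [", window[1], ", ", window[2],
            ") dropped")
  sp <- sp[inside, , drop = FALSE]
  units <- sort(unique(sp$unit_id))
  if (!length(units)) units <- "u1"
  spikes <- lapply(units, function(u) {
    su <- sp[sp$unit_id == u, , drop = FALSE]
    lapply(tr$trial_id, function(tid) {
      t <- su$spike_time_s[su$trial_id == tid]
      if (length(t) > 1 && any(diff(t) <= 0)) {
        t2 <- sort(t)
        if (any(diff(t2) == 0))
          stop("duplicate spike times in unit ", u, ", trial ", tid)
        t <- t2
      }
      t
    })
  })
  names(spikes) <- units
  trials <- data.frame(trial_id = tr$trial_id, epoch = tr$epoch)
  colmap <- c(problem_id = "problem_id",
              position_in_problem = "position_in_problem",
              response_time = "response_time_s",
              interrupted = "interrupted",
              n_preceding_errors = "n_preceding_errors")
  for (dst in names(colmap))
    if (colmap[[dst]] %in% names(tr)) trials[[dst]] <- tr[[colmap[[dst]]]]
  epoch_dataset(trials, spikes, window)
}

#' Run the full analysis pipeline on one (possibly simulated) session
#'
#' Orchestrates the stages on a single configuration: simulate (or read) a
#' session, apply the trial filters, decode the requested contrast,
#' optionally run the shuffle controls, the pair surface (two-unit
#' sessions) and the behavioral response-time analysis, and write all
#' outputs (long-format information CSV, delta and Fano tables, D-bar
#' tables) plus a JSON run manifest capturing the configuration and seeds.
#'
#' @param config list with elements: `seed`; either `generator` (a
#'   [generator_config()]) or `spikes_path`/`trials_path`; `stages`
#'   (subset of `c("decode", "controls", "pairs", "behavior")`);
#'   `contrast`; `q_grid`; `k_grid`; `n_perm`; `n_shuffles`;
#'   `n_surrogate`; `rule`.
#' @param out_dir output directory (created if missing).
#' @return invisibly, a list with the stage results and the manifest.
#' @export
run_pipeline <- function(config, out_dir) {
  defaults <- list(seed = 1, stages = "decode",
                   contrast = c("first_reward", "repetition"),
                   q_grid = default_q_grid(), k_grid = default_k_grid(),
                   n_perm = 200, n_shuffles = 100, n_surrogate = 1000,
                   rule = "median", n_units = 1)
  config <- utils::modifyList(defaults, config)
  bad <- setdiff(config$stages, c("decode", "controls", "pairs", "behavior"))
  if (length(bad))
    stop("unknown stage(s): ", paste(bad, collapse = ", "))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  logf <- file.path(out_dir, "run.log")
  logline <- function(...) cat(format(Sys.time(), "%H:%M:%S"), ...,
                               "\n", file = logf, append = TRUE)
  results <- list()

  if (!is.null(config$generator)) {
    sess <- simulate_session(config$generator, config$seed,
                             n_units = config$n_units)
    ds_full <- sess$dataset
    logline("simulated session:", nrow(ds_full$trials), "trials")
    ds <- filter_trials(sess)
    logline("filters kept", nrow(ds$trials), "of", nrow(ds_full$trials),
            "trials")
    write_session(ds_full, file.path(out_dir, "spikes.csv"),
                  file.path(out_dir, "trials.csv"))
  } else if (!is.null(config$spikes_path)) {
    ds <- read_session(config$spikes_path, config$trials_path)
    logline("read session:", nrow(ds$trials), "trials")
  } else stop("config must provide `generator` or `spikes_path`/`trials_path`")
  results$dataset <- ds

  if ("decode" %in% config$stages) {
    fit <- decode_epochs(ds, contrast = config$contrast,
                         unit = ds$units[1],
                         q_grid = config$q_grid, n_perm = config$n_perm,
                         rule = config$rule, seed = config$seed)
    results$decode <- fit
    write.csv(info_surface_long(fit), file.path(out_dir, "info_surface.csv"),
              row.names = FALSE)
    logline("decode: q_opt =", fit$q_opt, "N_w =", fit$nw,
            "significant =", fit$significant, "ties =", fit$ties)
  }
  if ("controls" %in% config$stages) {
    del <- shuffle_information_delta(ds, unit = ds$units[1],
                                     contrast = config$contrast,
                                     kind = "counts",
                                     q_grid = config$q_grid,
                                     n_shuffles = config$n_shuffles,
                                     seed = config$seed)
    results$controls <- del
    ft <- do.call(rbind, lapply(config$contrast, function(e)
      data.frame(epoch = e,
                 fano = epoch_fano(ds, ds$units[1], e))))
    write.csv(ft, file.path(out_dir, "fano.csv"), row.names = FALSE)
    dl <- as.data.frame(as.table(del$delta))
    names(dl) <- c("q", "window_end", "delta")
    write.csv(dl, file.path(out_dir, "shuffle_delta.csv"), row.names = FALSE)
    logline("controls: median delta =", median(del$delta))
  }
  if ("pairs" %in% config$stages) {
    if (length(ds$units) != 2) stop("pairs stage needs a 2-unit session")
    pf <- pair_info_surface(ds, contrast = config$contrast,
                            q_grid = config$q_grid, k_grid = config$k_grid,
                            n_perm = config$n_perm, seed = config$seed)
    results$pairs <- pf
    write.csv(info_surface_long(pf), file.path(out_dir, "pair_surface.csv"),
              row.names = FALSE)
    logline("pairs: q_opt =", pf$q_opt, "k_opt =", pf$k_opt)
  }
  if ("behavior" %in% config$stages) {
    if (is.null(ds$trials$response_time) || all(is.na(ds$trials$response_time)))
      stop("behavior stage requested but no response times are available")
    fr <- ds$trials[ds$trials$epoch == "first_reward", , drop = FALSE]
    sp <- split_by_response_time(fr)
    ends <- window_schedule()$averaging_ends
    db <- vapply(ends, function(e)
      dbar(deviation_from_prototype(ds, q = 10, window = c(0.001, e)), sp),
      numeric(1))
    dbr <- vapply(ends, function(e)
      dbar_rate(ds, sp, window = c(0.001, e)), numeric(1))
    results$behavior <- list(split = sp, dbar = db, dbar_rate = dbr)
    write.csv(data.frame(window_end = ends, dbar = db, dbar_rate = dbr),
              file.path(out_dir, "dbar.csv"), row.names = FALSE)
    logline("behavior: split at", sp$r_tilde, "s;",
            length(sp$excluded_at_median), "trial(s) at the median excluded")
  }

  manifest <- list(package_version = as.character(utils::packageVersion("vpdecode")),
                   seed = config$seed, stages = config$stages,
                   contrast = config$contrast, q_grid = config$q_grid,
                   n_perm = config$n_perm, rule = config$rule,
                   created = format(Sys.time()))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  results$manifest <- manifest
  invisible(results)
}

#' Long-format export of an information surface
#'
#' @param fit an `epoch_decoder`.
#' @return data.frame with columns `q`, `k`, `window_end`, `info_raw`,
#'   `bias`, `info`, plus the fit-level `nw` and `significant`.
#' @export
info_surface_long <- function(fit) {
  stopifnot(inherits(fit, "epoch_decoder"))
  g <- expand.grid(q = fit$q_grid, k = fit$k_grid,
                   window_end = fit$windows$analysis_ends)
  g$info_raw <- as.vector(fit$info_raw)
  g$bias <- as.vector(fit$bias)
  g$info <- as.vector(fit$info)
  g$nw <- fit$nw
  g$significant <- fit$significant
  g
}
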