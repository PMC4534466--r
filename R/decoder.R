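#' Metric-space decoding of task epochs from spike trains
#'
#' The central estimator of the package.  Every trial's spike train is
#' classified, leave-one-out, into the task epoch whose other trials are
#' globally most similar under the Victor-Purpura distance; the confusion
#' matrix is summarized by normalized mutual information; the small-sample
#' information bias is estimated by fully re-decoding label-permuted
#' datasets and subtracted (clipping at 0); and a dataset is flagged
#' significant when its maximal run of consecutive analysis windows with
#' above-chance information (`N_w`) beats the same statistic in the
#' permuted data.  The whole procedure runs on a grid of temporal
#' sensitivities `q` (and, for two-unit decoding, unit-distinction costs
#' `k`) over the incremental window schedule.
#'
#' Classification rule `"median"` assigns a trial to the epoch minimizing
#' the median of its pairwise distances to that epoch's other trials;
#' `"nearest_neighbor"` uses the mean of the `m_nearest` smallest distances
#' instead, biasing the decision toward close neighbors.  Exact summary
#' ties are broken by a seeded uniform draw and counted in `$ties`.
#'
#' @param dataset an [epoch_dataset()].
#' @param contrast character vector of exactly two epoch labels to
#'   discriminate (decoding is always pairwise).
#' @param unit unit to decode (single-unit decoding; default the only unit).
#' @param pair if `TRUE`, decode the joint labeled trains of the dataset's
#'   two units over `k_grid`.
#' @param q_grid temporal sensitivities (1/s), see [default_q_grid()].
#' @param k_grid unit-distinction costs (pair decoding only).
#' @param windows window schedule, see [window_schedule()].
#' @param n_perm number of label permutations for bias estimation and the
#'   `N_w` null (the same ensemble serves both).
#' @param rule classification rule, `"median"` or `"nearest_neighbor"`.
#' @param m_nearest number of neighbors for the nearest-neighbor rule.
#' @param seed master seed; permutations and tie-breaks derive from it.
#' @param keep_null keep the full per-permutation null information array in
#'   the returned object (memory-hungry for large grids).
#' @return An object of class `epoch_decoder` with, among others: `info`
#'   (bias-corrected normalized information, `q x k x window` array),
#'   `info_raw`, `bias`, `It` (time-averaged information per `(q, k)`),
#'   `q_opt`, `k_opt`, `nw`, `significant`, `ties`.
#' @seealso [summary.epoch_decoder()], [predict.epoch_decoder()],
#'   [compare_parameter_grid()]
#' @export
decode_epochs <- function(dataset,
                          contrast = c("first_reward", "repetition"),
                          unit = NULL, pair = FALSE,
                          q_grid = default_q_grid(),
                          k_grid = default_k_grid(),
                          windows = window_schedule(),
                          n_perm = 1000,
                          rule = c("median", "nearest_neighbor"),
                          m_nearest = 3, seed = 1,
                          keep_null = FALSE) {
  stopifnot(inherits(dataset, "epoch_dataset"))
  rule <- match.arg(rule)
  if (length(contrast) != 2)
    stop("decoding is pairwise: `contrast` must name exactly 2 epochs")
  if (n_perm < 1) stop("`n_perm` must be >= 1")
  ds <- subset_trials(dataset, epochs = contrast)
  lab <- factor(ds$trials$epoch, levels = contrast)
  if (any(table(lab) < 2))
    stop("each epoch of the contrast needs >= 2 trials")
  n <- length(lab)
  L0 <- as.integer(lab) - 1L

  if (pair) {
    if (length(ds$units) != 2) stop("pair decoding needs a 2-unit dataset")
    ks <- k_grid
    if (any(ks < 0 | ks > 2)) stop("`k_grid` values must lie in [0, 2]")
  } else {
    unit <- pick_unit(ds, unit)
    ks <- NA_real_
  }
  Q <- length(q_grid); K <- length(ks)
  ends <- windows$analysis_ends; W <- length(ends)
  start <- windows$start

  set.seed(seed)
  Lmat <- cbind(L0, vapply(seq_len(n_perm), function(p) sample(L0), integer(n)))
  storage.mode(Lmat) <- "integer"
  tie_u <- matrix(runif(n * (n_perm + 1L)), n)

  info_raw <- bias <- info <- array(NA_real_, c(Q, K, W))
  null <- array(NA_real_, c(Q, K, W, n_perm))
  ties <- 0L
  Hmax <- label_entropy(L0)
  rule_i <- if (rule == "median") 0L else 1L

  for (w in seq_len(W)) {
    win <- c(start, ends[w])
    if (pair) {
      t1 <- unit_trains(ds, ds$units[1], win)
      t2 <- unit_trains(ds, ds$units[2], win)
    } else tr <- unit_trains(ds, unit, win)
    for (qi in seq_len(Q)) for (ki in seq_len(K)) {
      D <- if (pair) cpp_vp_dist_matrix_labeled(t1, t2, q_grid[qi], ks[ki])
           else cpp_vp_dist_matrix(tr, q_grid[qi])
      cl <- cpp_classify(D, Lmat, 2L, rule_i, m_nearest, tie_u)
      ties <- ties + cl$ties[1]
      iv <- info_columns(Lmat, cl$pred) / Hmax
      info_raw[qi, ki, w] <- iv[1]
      null[qi, ki, w, ] <- iv[-1]
      bias[qi, ki, w] <- mean(iv[-1])
      info[qi, ki, w] <- max(0, iv[1] - bias[qi, ki, w])
    }
  }

  sig <- nw_significance(info_raw, null)
  avg_idx <- match(round(windows$averaging_ends, 6), round(ends, 6))
  if (anyNA(avg_idx)) stop("averaging windows must be a subset of analysis windows")
  It <- apply(info[, , avg_idx, drop = FALSE], c(1, 2), mean)
  prof_q <- apply(It, 1, max)
  prof_k <- apply(It, 2, max)

  out <- list(info = info, info_raw = info_raw, bias = bias,
              It = It, q_grid = q_grid, k_grid = ks,
              q_opt = suppressWarnings(grid_optimum(prof_q, q_grid)),
              k_opt = if (pair) suppressWarnings(grid_optimum(prof_k, ks))
                      else NA_real_,
              flat_profile = length(unique(as.vector(It))) == 1,
              nw = sig$nw, nw_null = sig$nw_null, significant = sig$significant,
              ties = ties, windows = windows, contrast = contrast,
              rule = rule, m_nearest = m_nearest, n_perm = n_perm, seed = seed,
              pair = pair, unit = if (pair) NULL else unit,
              n_trials = as.vector(table(lab)), reference = ds,
              call = match.call())
  if (keep_null) out$null <- null
  class(out) <- "epoch_decoder"
  out
}

## entropy (nats) of the empirical label distribution: the maximum of the
## plug-in mutual information under perfect prediction with these marginals
label_entropy <- function(L0) {
  p <- tabulate(L0 + 1L) / length(L0)
  p <- p[p > 0]
  -sum(p * log(p))
}

## raw plug-in mutual information (nats) for every label/prediction column
info_columns <- function(Lmat, pred) {
  n00 <- colSums(Lmat == 0L & pred == 0L)
  n01 <- colSums(Lmat == 0L & pred == 1L)
  n10 <- colSums(Lmat == 1L & pred == 0L)
  n11 <- colSums(Lmat == 1L & pred == 1L)
  N <- n00 + n01 + n10 + n11
  r0 <- n00 + n01; r1 <- n10 + n11
  c0 <- n00 + n10; c1 <- n01 + n11
  term <- function(nij, ri, cj) {
    t <- rep(0, length(nij))
    ok <- nij > 0
    t[ok] <- nij[ok] * log(nij[ok] * N[ok] / (ri[ok] * cj[ok]))
    t
  }
  (term(n00, r0, c0) + term(n01, r0, c1) +
     term(n10, r1, c0) + term(n11, r1, c1)) / N
}

## N_w statistic and its permutation significance.
## info_raw: Q x K x W; null: Q x K x W x P.
nw_significance <- function(info_raw, null) {
  dm <- dim(null); Q <- dm[1]; K <- dm[2]; W <- dm[3]; P <- dm[4]
  exceed_real <- array(FALSE, c(Q, K, W))
  exceed_perm <- array(FALSE, c(Q, K, W, P))
  idx_all <- ceiling(0.95 * P)
  idx_loo <- ceiling(0.95 * (P - 1))
  for (qi in seq_len(Q)) for (ki in seq_len(K)) for (w in seq_len(W)) {
    v <- null[qi, ki, w, ]
    o <- order(v)
    s <- v[o]
    pos <- integer(P); pos[o] <- seq_len(P)
    exceed_real[qi, ki, w] <- info_raw[qi, ki, w] > s[idx_all]
    thr <- s[idx_loo + (pos <= idx_loo)]
    exceed_perm[qi, ki, w, ] <- v > thr
  }
  runmax <- function(x) {
    r <- rle(x)
    m <- r$lengths[r$values]
    if (length(m)) max(m) else 0L
  }
  nw_grid <- apply(exceed_real, c(1, 2), runmax)
  nw <- max(nw_grid)
  nw_null <- vapply(seq_len(P), function(p)
    max(apply(exceed_perm[, , , p, drop = FALSE], c(1, 2),
              function(x) runmax(as.vector(x)))), numeric(1))
  thr_nw <- sort(nw_null)[ceiling(0.95 * P)]
  list(nw = nw, nw_null = nw_null, significant = nw > thr_nw)
}

#' Longest run of consecutive TRUE values
#'
#' The consecutive-window statistic underlying `N_w`: the number of
#' consecutive analysis windows in which information strictly exceeds its
#' permutation threshold.
#'
#' @param x logical vector (ordered as the window schedule).
#' @return integer.
#' @export
longest_run <- function(x) {
  r <- rle(as.logical(x))
  m <- r$lengths[r$values]
  if (length(m)) max(m) else 0L
}

#' Mean of the arg-max set of a profile over a parameter grid
#'
#' Exact ties are averaged, so a profile maximal at both q = 5 and q = 10
#' yields 7.5.  A completely flat profile returns the grid mean with a
#' warning (uninformative profile).
#'
#' @param values profile values (e.g. time-averaged information).
#' @param grid parameter values, same length.
#' @return scalar.
#' @export
grid_optimum <- function(values, grid) {
  stopifnot(length(values) == length(grid))
  if (length(unique(values)) == 1 && length(values) > 1)
    warning("flat profile: optimum is uninformative")
  mean(grid[values == max(values)])
}

#' Leave-one-out classification of a single trial
#'
#' Assigns trial `trial` of `dataset` to the task epoch containing the most
#' similar responses, excluding the trial itself from its epoch's reference
#' set.  Used trial-by-trial by [confusion_matrix()] and [decode_epochs()].
#'
#' @inheritParams decode_epochs
#' @param trial trial index (row of `dataset$trials`) or trial id.
#' @param q temporal sensitivity (1/s).
#' @param k unit-distinction cost (pair decoding).
#' @param window analysis window; default the dataset window.
#' @return epoch label (character), with attribute `"tie"` if the decision
#'   was a seeded tie-break.
#' @export
classify_trial <- function(dataset, trial, q, k = NULL,
                           contrast = c("first_reward", "repetition"),
                           window = NULL,
                           rule = c("median", "nearest_neighbor"),
                           m_nearest = 3, seed = 1, unit = NULL) {
  rule <- match.arg(rule)
  cm <- loo_predictions(dataset, contrast, q, k, window, rule, m_nearest,
                        seed, unit)
  i <- if (is.character(trial)) match(trial, cm$trial_id)
       else match(trial, cm$row_in_dataset)
  if (is.na(i)) stop("trial not found in the contrast subset")
  out <- cm$pred[i]
  attr(out, "tie") <- cm$tied[i]
  out
}

#' Leave-one-out confusion matrix
#'
#' Counts `N(i, j)` of trials belonging to task epoch `i` and classified in
#' task epoch `j` under leave-one-out metric-space classification.
#'
#' @inheritParams classify_trial
#' @return integer matrix with epoch labels as dimnames (rows = true).
#' @export
confusion_matrix <- function(dataset, q, k = NULL,
                             contrast = c("first_reward", "repetition"),
                             window = NULL,
                             rule = c("median", "nearest_neighbor"),
                             m_nearest = 3, seed = 1, unit = NULL) {
  rule <- match.arg(rule)
  cm <- loo_predictions(dataset, contrast, q, k, window, rule, m_nearest,
                        seed, unit)
  out <- table(factor(cm$truth, levels = contrast),
               factor(cm$pred, levels = contrast))
  m <- matrix(as.integer(out), 2, 2, dimnames = dimnames(out))
  names(dimnames(m)) <- c("true", "classified")
  m
}

loo_predictions <- function(dataset, contrast, q, k, window, rule,
                            m_nearest, seed, unit) {
  stopifnot(inherits(dataset, "epoch_dataset"))
  ds <- subset_trials(dataset, epochs = contrast)
  lab <- factor(ds$trials$epoch, levels = contrast)
  if (any(table(lab) < 2))
    stop("each epoch of the contrast needs >= 2 trials")
  if (is.null(window)) window <- ds$window
  n <- length(lab)
  pairmode <- !is.null(k)
  if (pairmode) {
    D <- cpp_vp_dist_matrix_labeled(unit_trains(ds, ds$units[1], window),
                                    unit_trains(ds, ds$units[2], window), q, k)
  } else {
    D <- cpp_vp_dist_matrix(unit_trains(ds, pick_unit(ds, unit), window), q)
  }
  set.seed(seed)
  tie_u <- matrix(runif(n), n, 1)
  L <- matrix(as.integer(lab) - 1L, n, 1)
  cl <- cpp_classify(D, L, 2L, if (rule == "median") 0L else 1L,
                     m_nearest, tie_u)
  list(trial_id = ds$trials$trial_id,
       row_in_dataset = match(ds$trials$trial_id, dataset$trials$trial_id),
       truth = as.character(lab),
       pred = contrast[cl$pred[, 1] + 1L],
       tied = rep(cl$ties[1] > 0, n))
}

#' Raw mutual information of a confusion matrix
#'
#' Plug-in mutual information (nats) between true and predicted epoch:
#' `I = (1/N) * sum_ij N(i,j) * ln(N(i,j) * N / (row_i * col_j))`, with
#' zero cells contributing zero.  Accounts for unequal trial numbers
#' between epochs and tends to zero for chance prediction on large samples.
#'
#' @param cm confusion matrix of counts (true epochs in rows).
#' @return information in nats.
#' @export
raw_information <- function(cm) {
  cm <- as.matrix(cm)
  N <- sum(cm)
  if (N <= 0) stop("empty confusion matrix")
  r <- rowSums(cm); co <- colSums(cm)
  tot <- 0
  for (i in seq_len(nrow(cm))) for (j in seq_len(ncol(cm)))
    if (cm[i, j] > 0)
      tot <- tot + cm[i, j] * log(cm[i, j] * N / (r[i] * co[j]))
  tot / N
}

#' Normalized mutual information of a confusion matrix
#'
#' [raw_information()] divided by its maximum under perfect prediction with
#' the observed epoch proportions, i.e. the entropy (nats) of the empirical
#' true-epoch distribution.  Equals 1 exactly when the confusion matrix is
#' a (row-permuted) diagonal.
#'
#' @inheritParams raw_information
#' @return fraction of maximum in `[0, 1]`.
#' @export
normalized_information <- function(cm) {
  cm <- as.matrix(cm)
  p <- rowSums(cm) / sum(cm)
  p <- p[p > 0]
  H <- -sum(p * log(p))
  if (H == 0) stop("single-epoch dataset: normalization undefined")
  raw_information(cm) / H
}

#' Permutation bias correction of an information value
#'
#' Subtracts the mean information of label-permuted datasets (the empirical
#' small-sample bias) and clips slightly negative values at 0.
#'
#' @param i normalized information of the original data.
#' @param null vector of normalized information values from label-permuted
#'   datasets.
#' @return corrected information in `[0, 1]`.
#' @export
bias_corrected_information <- function(i, null) {
  if (!length(null)) stop("`null` must be non-empty")
  pmax(0, i - mean(null))
}

#' Time-averaged information
#'
#' Mean of the (bias-corrected, normalized) information over the 10
#' averaging windows ending 100 ms to 1 s post-feedback, which favors
#' neither early nor late information.
#'
#' @param info information per analysis window.
#' @param ends analysis-window end times matching `info`.
#' @param averaging_ends window ends to average over.
#' @return scalar mean.
#' @export
time_averaged_information <- function(info, ends,
                                      averaging_ends = window_schedule()$averaging_ends) {
  idx <- match(round(averaging_ends, 6), round(ends, 6))
  if (anyNA(idx)) stop("missing averaging window(s): ",
                       paste(averaging_ends[is.na(idx)], collapse = ", "))
  mean(info[idx])
}

#' Friedman comparison of time-averaged information across parameters
#'
#' Non-parametric Friedman ANOVA across datasets (blocks) comparing
#' parameter settings, followed by post-hoc mean-rank comparisons with
#' Tukey's honestly-significant-difference criterion: settings whose mean
#' rank differs from the top-ranked setting by more than
#' `qtukey(1-alpha, k, Inf)/sqrt(2) * sqrt(k(k+1)/(12 n))` are flagged.
#'
#' @param It numeric matrix, datasets in rows, parameter settings in
#'   columns (e.g. time-averaged information per `q`).
#' @param alpha family-wise error level of the post-hoc comparison.
#' @return list with `statistic`, `p_value`, `mean_ranks`, `top` (column
#'   index of the best mean rank), `differs_from_top` (logical per
#'   setting), `crit` (the HSD half-width), `degenerate` (all-constant
#'   ranks).
#' @export
compare_parameter_grid <- function(It, alpha = 0.05) {
  It <- as.matrix(It)
  n <- nrow(It); k <- ncol(It)
  if (k < 2) stop("need >= 2 parameter settings")
  if (n < 2) stop("need >= 2 datasets")
  ranks <- t(apply(It, 1, rank))
  mr <- colMeans(ranks)
  if (length(unique(round(as.vector(ranks), 10))) == 1 ||
      all(apply(ranks, 2, function(x) length(unique(x))) == 1) &&
      length(unique(mr)) == 1) {
    return(list(statistic = 0, p_value = 1, mean_ranks = mr,
                top = 1L, differs_from_top = rep(FALSE, k),
                crit = NA_real_, degenerate = TRUE))
  }
  ft <- stats::friedman.test(It)
  crit <- stats::qtukey(1 - alpha, k, Inf) / sqrt(2) * sqrt(k * (k + 1) / (12 * n))
  top <- which.max(mr)
  list(statistic = unname(ft$statistic), p_value = ft$p.value,
       mean_ranks = mr, top = top,
       differs_from_top = abs(mr - mr[top]) > crit,
       crit = crit, degenerate = FALSE)
}

## ---- S3 methods for epoch_decoder -----------------------------------------

#' @export
print.epoch_decoder <- function(x, ...) {
  cat("Metric-space epoch decoder (", paste(x$contrast, collapse = " vs "),
      ")\n", sep = "")
  cat("  ", if (x$pair) "two-unit (labeled) decoding" else
    paste0("unit ", x$unit), "; rule: ", x$rule, "\n", sep = "")
  cat("  trials:", paste(x$contrast, x$n_trials, sep = "=", collapse = ", "),
      "| permutations:", x$n_perm, "\n")
  cat("  q_opt =", x$q_opt, "1/s",
      if (x$pair) paste("; k_opt =", x$k_opt) else "", "\n")
  cat("  N_w =", x$nw, "consecutive windows;",
      if (x$significant) "significant" else "not significant",
      "(permutation test)\n")
  cat("  max <I>_t =", format(max(x$It), digits = 4),
      "; classification ties:", x$ties, "\n")
  invisible(x)
}

#' Summary of an epoch decoder fit
#'
#' @param object an `epoch_decoder`.
#' @param ... unused.
#' @return A data.frame of time-averaged information per parameter setting
#'   (invisibly), after printing the fit overview.
#' @export
summary.epoch_decoder <- function(object, ...) {
  print(object)
  if (object$pair) {
    df <- expand.grid(q = object$q_grid, k = object$k_grid)
    df$It <- as.vector(object$It)
  } else {
    df <- data.frame(q = object$q_grid, It = object$It[, 1])
  }
  cat("\nTime-averaged information:\n")
  print(df, row.names = FALSE, digits = 4)
  invisible(df)
}

#' Plot information time courses of an epoch decoder
#'
#' Bias-corrected normalized information versus analysis-window end, one
#' curve per temporal sensitivity `q` (pair decoders: at the best `k`).
#'
#' @param x an `epoch_decoder`.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.epoch_decoder <- function(x, ...) {
  ki <- if (x$pair) which.max(apply(x$It, 2, max)) else 1L
  m <- t(x$info[, ki, ])
  graphics::matplot(x$windows$analysis_ends, m, type = "l", lty = 1,
                    xlab = "window end (s post-feedback)",
                    ylab = "information (fraction of max)", ...)
  graphics::legend("topleft", legend = paste0("q=", x$q_grid), lty = 1,
                   col = seq_along(x$q_grid), cex = 0.7, bty = "n")
  invisible(x)
}

#' Classify new spike trains with a fitted epoch decoder
#'
#' Assigns new spike trains to the epoch with the smallest global
#' dissimilarity to the decoder's reference trials (no leave-one-out, since
#' new trials are not part of the reference set).
#'
#' @param object an `epoch_decoder`.
#' @param newdata a spike-time vector, a list of spike-time vectors, or for
#'   pair decoders a list of two-element labeled trains.
#' @param q,k parameter values (defaults: grid values nearest the optimum).
#' @param window analysis window end (seconds); default 1 s.
#' @param seed tie-break seed.
#' @param ... unused.
#' @return character vector of epoch labels.
#' @export
predict.epoch_decoder <- function(object, newdata, q = NULL, k = NULL,
                                  window = NULL, seed = 1, ...) {
  if (is.null(q)) q <- object$q_grid[which.min(abs(object$q_grid - object$q_opt))]
  if (object$pair && is.null(k))
    k <- object$k_grid[which.min(abs(object$k_grid - object$k_opt))]
  ds <- object$reference
  if (is.null(window)) window <- ds$window
  if (length(window) == 1) window <- c(object$windows$start, window)
  lab <- factor(ds$trials$epoch, levels = object$contrast)
  single_input <- (object$pair && is.list(newdata) && length(newdata) == 2 &&
                     is.numeric(newdata[[1]])) ||
    (!object$pair && is.numeric(newdata))
  if (single_input) newdata <- list(newdata)
  set.seed(seed)
  out <- vapply(newdata, function(s) {
    if (object$pair) {
      s <- check_labeled(s)
      s <- lapply(s, restrict_window, window = window)
      t1 <- unit_trains(ds, ds$units[1], window)
      t2 <- unit_trains(ds, ds$units[2], window)
      d <- vapply(seq_along(t1), function(j)
        cpp_vp_dist_labeled(s[[1]], s[[2]], t1[[j]], t2[[j]], q, k), numeric(1))
    } else {
      s <- restrict_window(check_train(s), window)
      tr <- unit_trains(ds, object$unit, window)
      d <- vapply(tr, function(t) cpp_vp_dist(s, t, q), numeric(1))
    }
    g <- vapply(object$contrast, function(e) {
      v <- d[lab == e]
      if (object$rule == "median") median(v)
      else mean(sort(v)[seq_len(min(object$m_nearest, length(v)))])
    }, numeric(1))
    tied <- which(g == min(g))
    if (length(tied) > 1) tied <- sample(tied, 1)
    object$contrast[tied[1]]
  }, character(1))
  out
}
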