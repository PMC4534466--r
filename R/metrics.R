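#' @useDynLib vpdecode, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats median quantile runif rnorm rpois rlnorm qtukey wilcox.test
#'   friedman.test cor pnorm var sd setNames
#' @importFrom utils read.csv write.csv
NULL

#' Victor-Purpura distance between two spike trains
#'
#' Minimal cost to transform one spike train into the other using three
#' operations: inserting or deleting a spike (cost 1 each, i.e. half the
#' maximum dissimilarity `D_max = 2`) and shifting a spike by `dt` seconds
#' (cost `q * |dt|`).  `q` (in 1/s) sets the temporal sensitivity of the
#' metric: at `q = 0` the distance reduces to the absolute spike-count
#' difference, while large `q` penalizes timing mismatches so strongly that
#' only near-coincident spikes are matched.  Two spikes can only usefully be
#' matched when `q * |dt| < 2`, the cost of deleting one and re-inserting it;
#' `2/q` is therefore the maximal interspike interval registered as a
#' temporal coincidence (see [coincidence_range()]).
#'
#' @param a,b numeric vectors of strictly increasing spike times (seconds).
#' @param q temporal sensitivity, 1/s, `q >= 0`.
#' @return Non-negative distance (dimensionless; units of `D_max/2 = 1`).
#' @examples
#' vp_distance(numeric(0), 0.3, q = 10)        # one insertion -> 1
#' vp_distance(0.10, 0.15, q = 10)             # shift 50 ms    -> 0.5
#' vp_distance(0.1, 0.5, q = 10)               # shift too costly -> 2
#' @export
vp_distance <- function(a, b, q) {
  a <- check_train(a); b <- check_train(b)
  check_q(q)
  cpp_vp_dist(a, b, q)
}

#' Two-unit (labeled-line) Victor-Purpura distance
#'
#' Extension of [vp_distance()] to spike trains pooled from two
#' simultaneously recorded units.  A fourth operation is available:
#' changing the unit that fired a spike, at cost `k` (dimensionless,
#' `0 <= k <= 2`).  Matching a spike of unit 1 in one train to a spike of
#' unit 2 in the other therefore costs `q*|dt| + k`.  At `k = 0` the units
#' are indistinguishable and the distance equals the single-unit distance on
#' the merged trains; at `k = 2` cross-unit matching can never beat
#' delete+insert, and the distance is the sum of the per-unit distances.
#'
#' @param a,b labeled spike trains: lists of two numeric vectors (one per
#'   unit, same order in both trains), each strictly increasing.
#' @param q temporal sensitivity, 1/s.
#' @param k unit-distinction cost in `[0, 2]`.
#' @return Non-negative distance.
#' @examples
#' a <- list(u1 = 0.1, u2 = numeric(0))
#' b <- list(u1 = numeric(0), u2 = 0.1)
#' vp_distance_labeled(a, b, q = 10, k = 0)  # merge-blind -> 0
#' vp_distance_labeled(a, b, q = 10, k = 2)  # per-unit sum -> 2
#' @export
vp_distance_labeled <- function(a, b, q, k) {
  a <- check_labeled(a); b <- check_labeled(b)
  check_q(q)
  if (!is.numeric(k) || length(k) != 1 || is.na(k) || k < 0 || k > 2)
    stop("`k` must be a single value in [0, 2]")
  cpp_vp_dist_labeled(a[[1]], a[[2]], b[[1]], b[[2]], q, k)
}

#' Optimal alignment (edit transcript) between two spike trains
#'
#' Backtraces one optimal sequence of operations realizing the
#' Victor-Purpura distance.  Among cost ties the alignment maximizing the
#' number of matched pairs is returned, and matched pairs always have shift
#' cost strictly below 2 (at equality delete+insert is preferred), so the
#' result is deterministic.  Remaining ties are resolved by a fixed
#' backtrace order (match, then delete from `a`, then insert), which yields
#' the lexicographically earliest matching in the pair indices.
#'
#' @inheritParams vp_distance
#' @return An object of class `vp_alignment`: list with `matched_pairs`
#'   (data.frame `i`, `j`, `shift_cost`), `unmatched_a`, `unmatched_b`
#'   (integer index vectors), `relabel_count` (0 for single-unit trains) and
#'   `total_cost`.
#' @export
vp_alignment <- function(a, b, q) {
  a <- check_train(a); b <- check_train(b)
  check_q(q)
  n <- length(a); m <- length(b)
  cost <- matrix(0, n + 1, m + 1)
  mat  <- matrix(0L, n + 1, m + 1)
  cost[1, ] <- 0:m
  cost[, 1] <- 0:n
  if (n > 0 && m > 0) {
    for (i in 1:n) for (j in 1:m) {
      cdel <- cost[i, j + 1] + 1; mdel <- mat[i, j + 1]
      cins <- cost[i + 1, j] + 1; mins <- mat[i + 1, j]
      cc <- cdel; mm <- mdel
      if (cins < cc || (cins == cc && mins > mm)) { cc <- cins; mm <- mins }
      shift <- q * abs(a[i] - b[j])
      if (shift < 2) {
        cmat <- cost[i, j] + shift; mmat <- mat[i, j] + 1L
        if (cmat < cc || (cmat == cc && mmat > mm)) { cc <- cmat; mm <- mmat }
      }
      cost[i + 1, j + 1] <- cc; mat[i + 1, j + 1] <- mm
    }
  }
  ## backtrace, preferring match > delete > insert at ties
  i <- n; j <- m
  pairs <- list()
  while (i > 0 || j > 0) {
    if (i > 0 && j > 0) {
      shift <- q * abs(a[i] - b[j])
      if (shift < 2 &&
          isTRUE(all.equal(cost[i + 1, j + 1], cost[i, j] + shift)) &&
          mat[i + 1, j + 1] == mat[i, j] + 1L) {
        pairs[[length(pairs) + 1L]] <- c(i, j, shift)
        i <- i - 1; j <- j - 1
        next
      }
    }
    if (i > 0 && isTRUE(all.equal(cost[i + 1, j + 1], cost[i, j + 1] + 1)) &&
        mat[i + 1, j + 1] == mat[i, j + 1]) {
      i <- i - 1
      next
    }
    j <- j - 1
  }
  mp <- if (length(pairs))
    as.data.frame(do.call(rbind, rev(pairs)), col.names = c("i", "j", "shift_cost"))
  else data.frame(i = integer(0), j = integer(0), shift_cost = numeric(0))
  names(mp) <- c("i", "j", "shift_cost")
  out <- list(matched_pairs = mp,
              unmatched_a = setdiff(seq_len(n), mp$i),
              unmatched_b = setdiff(seq_len(m), mp$j),
              relabel_count = 0L,
              total_cost = cost[n + 1, m + 1])
  class(out) <- "vp_alignment"
  out
}

#' @export
print.vp_alignment <- function(x, ...) {
  cat("Victor-Purpura alignment: cost", format(x$total_cost, digits = 6),
      "|", nrow(x$matched_pairs), "matched,",
      length(x$unmatched_a) + length(x$unmatched_b), "unmatched\n")
  invisible(x)
}

#' Number of coincident spike pairs between two trains
#'
#' Matched pairs in the tie-broken optimal alignment; each matched pair has
#' shift cost strictly smaller than `D_max = 2`, the definition of a
#' temporal coincidence.  At `q = 0` every shift is free, and the matched
#' count equals `min(n_a, n_b)`.
#'
#' @inheritParams vp_distance
#' @return Non-negative integer.
#' @export
coincident_pair_count <- function(a, b, q) {
  a <- check_train(a); b <- check_train(b)
  check_q(q)
  as.integer(cpp_vp_dist_match(a, b, q)[2])
}

#' Coincidence-normalized spike-train distance d*
#'
#' The Victor-Purpura distance divided by the number of coincident spike
#' pairs between the two trains (or by 1 when no pair is coincident).  For
#' `q > 0` this quantifies the mean jitter of coincident spikes plus a cost
#' for unmatched spikes; for `q = 0` it is the absolute spike-count
#' difference divided by `max(1, min(n_a, n_b))`, a normalized count
#' difference.  Unlike the raw distance, `d*` does not scale with the number
#' of emitted spikes, so both a nearly empty train and a full train with
#' badly jittered spikes score a large deviation.
#'
#' @inheritParams vp_distance
#' @return Non-negative real.
#' @export
vp_dstar <- function(a, b, q) {
  a <- check_train(a); b <- check_train(b)
  check_q(q)
  dm <- cpp_vp_dist_match(a, b, q)
  dm[1] / max(1, dm[2])
}

#' Pairwise distance matrices over a set of trains
#'
#' @param trains list of spike-time vectors (single unit), or, for
#'   `vp_distance_matrix_labeled`, two parallel lists `trains1`, `trains2`
#'   holding each trial's spikes for the two units.
#' @inheritParams vp_distance
#' @param k unit-distinction cost (labeled version only).
#' @return Symmetric numeric matrix of distances (`vp_dstar_matrix`: of
#'   normalized distances d*).
#' @export
vp_distance_matrix <- function(trains, q) {
  check_q(q)
  trains <- lapply(trains, check_train)
  cpp_vp_dist_matrix(trains, q)
}

#' @rdname vp_distance_matrix
#' @param trains1,trains2 per-trial spike times of unit 1 and unit 2.
#' @export
vp_distance_matrix_labeled <- function(trains1, trains2, q, k) {
  check_q(q)
  if (length(trains1) != length(trains2))
    stop("`trains1` and `trains2` must have one entry per trial")
  cpp_vp_dist_matrix_labeled(lapply(trains1, check_train),
                             lapply(trains2, check_train), q, k)
}

#' @rdname vp_distance_matrix
#' @export
vp_dstar_matrix <- function(trains, q) {
  check_q(q)
  trains <- lapply(trains, check_train)
  cpp_vp_dstar_matrix(trains, q)
}

#' Coincidence range and equivalent EPSP decay constant of a sensitivity q
#'
#' `coincidence_range(q) = 2/q` is the largest interspike interval whose
#' shift cost stays below `D_max = 2`, i.e. the range of spike-time jitters
#' registered as a temporal coincidence (200 ms at `q = 10`/s).
#' `equivalent_tau(q) = 1/q` is the decay time constant of the exponential
#' postsynaptic potential whose pairwise summation has a matching
#' sensitivity to interspike intervals (100 ms at `q = 10`/s).
#'
#' @param q temporal sensitivity, 1/s, strictly positive.
#' @return seconds.
#' @export
coincidence_range <- function(q) {
  check_q(q)
  if (q == 0) return(Inf)
  2 / q
}

#' @rdname coincidence_range
#' @export
equivalent_tau <- function(q) {
  check_q(q)
  if (q == 0) return(Inf)
  1 / q
}

## ---- internal validation helpers ------------------------------------------

check_train <- function(x) {
  if (is.null(x)) return(numeric(0))
  if (!is.numeric(x)) stop("spike times must be numeric")
  if (anyNA(x)) stop("spike times contain NA")
  if (length(x) > 1 && any(diff(x) <= 0))
    stop("spike times must be strictly increasing within one unit")
  as.numeric(x)
}

check_labeled <- function(x) {
  if (!is.list(x) || length(x) > 2)
    stop("a labeled train holds the spikes of at most 2 units (a list of 2 vectors)")
  if (length(x) < 2) x <- c(x, list(numeric(0)))
  lapply(x, check_train)
}

check_q <- function(q) {
  if (!is.numeric(q) || length(q) != 1 || is.na(q) || q < 0)
    stop("`q` must be a single non-negative number (1/s)")
  invisible(q)
}

restrict_window <- function(times, window) {
  times[times >= window[1] & times < window[2]]
}
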