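# Independent brute-force oracles for the spike-train metric: enumerate
# every injective matching between the two trains (no monotonicity
# assumption), match cost q*|dt| (+ k when labels differ), unmatched spikes
# cost 1 each.  Exponential, usable up to ~6 spikes per train.

bf_vp_distance <- function(a, b, q) {
  rec <- function(a, b) {
    if (!length(a)) return(length(b))
    best <- 1 + rec(a[-1], b)
    for (j in seq_along(b)) {
      best <- min(best, q * abs(a[1] - b[j]) + rec(a[-1], b[-j]))
    }
    best
  }
  rec(a, b)
}

bf_vp_distance_labeled <- function(ta, tb, q, k) {
  a <- c(ta[[1]], ta[[2]]); la <- rep(1:2, c(length(ta[[1]]), length(ta[[2]])))
  b <- c(tb[[1]], tb[[2]]); lb <- rep(1:2, c(length(tb[[1]]), length(tb[[2]])))
  rec <- function(a, la, b, lb) {
    if (!length(a)) return(length(b))
    best <- 1 + rec(a[-1], la[-1], b, lb)
    for (j in seq_along(b)) {
      cost <- q * abs(a[1] - b[j]) + if (la[1] != lb[j]) k else 0
      best <- min(best, cost + rec(a[-1], la[-1], b[-j], lb[-j]))
    }
    best
  }
  rec(a, la, b, lb)
}

# (min cost, max matched pairs among min-cost matchings with every matched
# pair strictly below cost 2)
bf_vp_alignment <- function(a, b, q) {
  rec <- function(a, b) {
    if (!length(a)) return(c(length(b), 0))
    best <- rec(a[-1], b) + c(1, 0)
    for (j in seq_along(b)) {
      sc <- q * abs(a[1] - b[j])
      if (sc >= 2) next
      cand <- rec(a[-1], b[-j]) + c(sc, 1)
      if (cand[1] < best[1] - 1e-12 ||
          (abs(cand[1] - best[1]) <= 1e-12 && cand[2] > best[2]))
        best <- cand
    }
    best
  }
  rec(a, b)
}

rand_train <- function(n_max = 4, span = c(0, 1)) {
  n <- sample(0:n_max, 1)
  sort(runif(n, span[1], span[2]))
}

rand_labeled_train <- function(n_max = 3, span = c(0, 1)) {
  list(rand_train(n_max, span), rand_train(n_max, span))
}
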