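// Victor-Purpura spike-train metric: exact dynamic programs and the
// leave-one-out classification loops used by the decoder.
//
// Cost model: insert/delete = 1 (= D_max/2), shift by dt = q*|dt| (<= D_max),
// relabel across the two units of a pair = k.  A matched pair is only ever
// part of the alignment we report when its cost is strictly below D_max = 2;
// at equality, delete+insert is chosen instead (same total cost, and it keeps
// coincident-pair counts well defined).

#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

static const double DMAX = 2.0;

// Single-unit distance, O(n*m) time, O(m) memory.
static double vp_dist_core(const std::vector<double>& a,
                           const std::vector<double>& b, double q) {
  const int n = a.size(), m = b.size();
  if (n == 0) return (double)m;
  if (m == 0) return (double)n;
  if (q == 0.0) return std::abs(n - m);
  std::vector<double> prev(m + 1), cur(m + 1);
  for (int j = 0; j <= m; ++j) prev[j] = j;
  for (int i = 1; i <= n; ++i) {
    cur[0] = i;
    for (int j = 1; j <= m; ++j) {
      double shift = q * std::abs(a[i - 1] - b[j - 1]);
      double best = std::min(prev[j] + 1.0, cur[j - 1] + 1.0);
      double match = prev[j - 1] + shift;  // never better than best when shift >= 2
      cur[j] = std::min(best, match);
    }
    std::swap(prev, cur);
  }
  return prev[m];
}

// [[Rcpp::export]]
double cpp_vp_dist(NumericVector a, NumericVector b, double q) {
  std::vector<double> av = as<std::vector<double>>(a);
  std::vector<double> bv = as<std::vector<double>>(b);
  return vp_dist_core(av, bv, q);
}

// Distance plus the number of matched (coincident) pairs in the optimal
// alignment that, among cost ties, maximizes matched pairs.  Matching is
// only allowed when its cost is strictly < 2, which never changes the
// minimal cost (delete+insert achieves 2).
// [[Rcpp::export]]
NumericVector cpp_vp_dist_match(NumericVector a, NumericVector b, double q) {
  const int n = a.size(), m = b.size();
  std::vector<double> cost((n + 1) * (m + 1));
  std::vector<int> mat((n + 1) * (m + 1));
  auto id = [m](int i, int j) { return i * (m + 1) + j; };
  for (int j = 0; j <= m; ++j) { cost[id(0, j)] = j; mat[id(0, j)] = 0; }
  for (int i = 1; i <= n; ++i) { cost[id(i, 0)] = i; mat[id(i, 0)] = 0; }
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      double cdel = cost[id(i - 1, j)] + 1.0;  int mdel = mat[id(i - 1, j)];
      double cins = cost[id(i, j - 1)] + 1.0;  int mins = mat[id(i, j - 1)];
      double c = cdel; int mm = mdel;
      if (cins < c || (cins == c && mins > mm)) { c = cins; mm = mins; }
      double shift = q * std::abs(a[i - 1] - b[j - 1]);
      if (shift < DMAX) {
        double cmat = cost[id(i - 1, j - 1)] + shift;
        int mmat = mat[id(i - 1, j - 1)] + 1;
        if (cmat < c || (cmat == c && mmat > mm)) { c = cmat; mm = mmat; }
      }
      cost[id(i, j)] = c; mat[id(i, j)] = mm;
    }
  }
  return NumericVector::create(cost[id(n, m)], (double)mat[id(n, m)]);
}

// Two-unit labeled distance: DP over per-unit consumption indices
// (published fast multiunit algorithm; 4-index state).  a1,a2 are the two
// units' spikes of train a; b1,b2 of train b; relabel cost k in [0,2].
// [[Rcpp::export]]
double cpp_vp_dist_labeled(NumericVector a1, NumericVector a2,
                           NumericVector b1, NumericVector b2,
                           double q, double k) {
  const int n1 = a1.size(), n2 = a2.size(), m1 = b1.size(), m2 = b2.size();
  const int d2 = n2 + 1, d3 = m1 + 1, d4 = m2 + 1;
  std::vector<double> G((n1 + 1) * d2 * d3 * d4);
  auto id = [d2, d3, d4](int i1, int i2, int j1, int j2) {
    return ((i1 * d2 + i2) * d3 + j1) * d4 + j2;
  };
  for (int i1 = 0; i1 <= n1; ++i1)
    for (int i2 = 0; i2 <= n2; ++i2)
      for (int j1 = 0; j1 <= m1; ++j1)
        for (int j2 = 0; j2 <= m2; ++j2) {
          if (i1 + i2 + j1 + j2 == 0) { G[id(0, 0, 0, 0)] = 0.0; continue; }
          double best = R_PosInf;
          if (i1 > 0) best = std::min(best, G[id(i1 - 1, i2, j1, j2)] + 1.0);
          if (i2 > 0) best = std::min(best, G[id(i1, i2 - 1, j1, j2)] + 1.0);
          if (j1 > 0) best = std::min(best, G[id(i1, i2, j1 - 1, j2)] + 1.0);
          if (j2 > 0) best = std::min(best, G[id(i1, i2, j1, j2 - 1)] + 1.0);
          if (i1 > 0 && j1 > 0) {
            double c = q * std::abs(a1[i1 - 1] - b1[j1 - 1]);
            if (c < DMAX)
              best = std::min(best, G[id(i1 - 1, i2, j1 - 1, j2)] + c);
          }
          if (i2 > 0 && j2 > 0) {
            double c = q * std::abs(a2[i2 - 1] - b2[j2 - 1]);
            if (c < DMAX)
              best = std::min(best, G[id(i1, i2 - 1, j1, j2 - 1)] + c);
          }
          if (i1 > 0 && j2 > 0) {
            double c = q * std::abs(a1[i1 - 1] - b2[j2 - 1]) + k;
            if (c < DMAX)
              best = std::min(best, G[id(i1 - 1, i2, j1, j2 - 1)] + c);
          }
          if (i2 > 0 && j1 > 0) {
            double c = q * std::abs(a2[i2 - 1] - b1[j1 - 1]) + k;
            if (c < DMAX)
              best = std::min(best, G[id(i1, i2 - 1, j1 - 1, j2)] + c);
          }
          G[id(i1, i2, j1, j2)] = best;
        }
  return G[id(n1, n2, m1, m2)];
}

// [[Rcpp::export]]
NumericMatrix cpp_vp_dist_matrix(List trains, double q) {
  const int n = trains.size();
  std::vector<std::vector<double>> tv(n);
  for (int i = 0; i < n; ++i)
    tv[i] = as<std::vector<double>>(trains[i]);
  NumericMatrix D(n, n);
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j)
      D(i, j) = D(j, i) = vp_dist_core(tv[i], tv[j], q);
  return D;
}

// [[Rcpp::export]]
NumericMatrix cpp_vp_dist_matrix_labeled(List t1, List t2, double q, double k) {
  const int n = t1.size();
  NumericMatrix D(n, n);
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j)
      D(i, j) = D(j, i) = cpp_vp_dist_labeled(t1[i], t2[i], t1[j], t2[j], q, k);
  return D;
}

// Matrix of normalized distances d* = d / max(1, coincident pairs).
// [[Rcpp::export]]
NumericMatrix cpp_vp_dstar_matrix(List trains, double q) {
  const int n = trains.size();
  NumericMatrix D(n, n);
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      NumericVector dm = cpp_vp_dist_match(trains[i], trains[j], q);
      double den = std::max(1.0, dm[1]);
      D(i, j) = D(j, i) = dm[0] / den;
    }
  return D;
}

// Leave-one-out classification of every trial under every label column.
// D: n x n distance matrix; labels: n x P integer matrix with values in
// 0..G-1 (column 1 usually the observed labels, the rest permutations);
// rule 0 = median of distances to each group, rule 1 = mean of the m
// smallest; tie_u: n x P uniforms used to break exact ties deterministically.
// Returns list(pred = n x P predicted labels (0-based), ties = per-column
// count of exact summary ties resolved by tie_u).
// [[Rcpp::export]]
List cpp_classify(NumericMatrix D, IntegerMatrix labels, int G,
                  int rule, int m, NumericMatrix tie_u) {
  const int n = D.nrow(), P = labels.ncol();
  IntegerMatrix pred(n, P);
  IntegerVector nties(P);
  std::vector<double> buf;
  buf.reserve(n);
  for (int p = 0; p < P; ++p) {
    for (int i = 0; i < n; ++i) {
      double best = R_PosInf;
      std::vector<int> tied;
      for (int g = 0; g < G; ++g) {
        buf.clear();
        for (int j = 0; j < n; ++j)
          if (j != i && labels(j, p) == g) buf.push_back(D(i, j));
        if (buf.empty()) stop("a candidate epoch has <2 trials (degenerate dataset)");
        double s;
        if (rule == 0) {
          const size_t sz = buf.size(), h = sz / 2;
          std::nth_element(buf.begin(), buf.begin() + h, buf.end());
          if (sz % 2 == 1) s = buf[h];
          else {
            double hi = buf[h];
            double lo = *std::max_element(buf.begin(), buf.begin() + h);
            s = 0.5 * (lo + hi);
          }
        } else {
          const int mm = std::min((size_t)m, buf.size());
          std::partial_sort(buf.begin(), buf.begin() + mm, buf.end());
          s = 0.0;
          for (int t = 0; t < mm; ++t) s += buf[t];
          s /= mm;
        }
        if (s < best) { best = s; tied.clear(); tied.push_back(g); }
        else if (s == best) tied.push_back(g);
      }
      int pick = 0;
      if (tied.size() > 1) {
        ++nties[p];
        pick = (int)std::floor(tie_u(i, p) * tied.size());
        if (pick >= (int)tied.size()) pick = tied.size() - 1;
      }
      pred(i, p) = tied[pick];
    }
  }
  return List::create(_["pred"] = pred, _["ties"] = nties);
}
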