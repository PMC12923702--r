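#include <Rcpp.h>
using namespace Rcpp;

// All-pairs plug-in mutual information (bits) from pre-binned codes.
// codes: T x R integer matrix, entries in 0..n_bins-1 (quantile bin index).
// Returns R x R symmetric matrix, diagonal set to 0 by convention.
// [[Rcpp::export]]
NumericMatrix mi_allpairs_cpp(const IntegerMatrix& codes, int n_bins) {
  const int T = codes.nrow(), R = codes.ncol();
  const double lT = std::log2((double)T);
  NumericMatrix out(R, R);
  // marginal counts
  std::vector<std::vector<int>> marg(R, std::vector<int>(n_bins, 0));
  for (int r = 0; r < R; ++r)
    for (int t = 0; t < T; ++t) marg[r][codes(t, r)]++;
  std::vector<int> joint(n_bins * n_bins);
  for (int i = 0; i < R; ++i) {
    for (int j = i + 1; j < R; ++j) {
      std::fill(joint.begin(), joint.end(), 0);
      for (int t = 0; t < T; ++t) joint[codes(t, i) * n_bins + codes(t, j)]++;
      double mi = 0.0;
      for (int a = 0; a < n_bins; ++a) {
        if (marg[i][a] == 0) continue;
        for (int b = 0; b < n_bins; ++b) {
          int nij = joint[a * n_bins + b];
          if (nij == 0 || marg[j][b] == 0) continue;
          // log2(nij*T/(ni*nj)) = log2(nij)+log2(T)-log2(ni)-log2(nj)
          mi += (double)nij / T *
            (std::log2((double)nij) + lT -
             std::log2((double)marg[i][a]) - std::log2((double)marg[j][b]));
        }
      }
      if (mi < 0) mi = 0;  // guard against fp round-off
      out(i, j) = mi;
      out(j, i) = mi;
    }
  }
  return out;
}

// Pooled-variance two-sample t per column (group a - group b).
// data: n_subj x n_feat; ga: 0-based indices of group a rows.
static void pooled_t(const NumericMatrix& data, const std::vector<int>& ga,
                     std::vector<double>& tout) {
  const int n = data.nrow(), m = data.ncol();
  const int n1 = (int)ga.size(), n0 = n - n1;
  std::vector<char> isa(n, 0);
  for (int k : ga) isa[k] = 1;
  for (int e = 0; e < m; ++e) {
    double s1 = 0, q1 = 0, s0 = 0, q0 = 0;
    for (int s = 0; s < n; ++s) {
      double v = data(s, e);
      if (isa[s]) { s1 += v; q1 += v * v; } else { s0 += v; q0 += v * v; }
    }
    double m1 = s1 / n1, m0 = s0 / n0;
    double ss1 = q1 - n1 * m1 * m1, ss0 = q0 - n0 * m0 * m0;
    double sp2 = (ss1 + ss0) / (n1 + n0 - 2);
    double den = std::sqrt(sp2 * (1.0 / n1 + 1.0 / n0));
    tout[e] = den > 0 ? (m1 - m0) / den : 0.0;
  }
}

// max-T permutation null for edge-wise two-group comparison.
// data: n_subj x n_edges; ga_obs: 0-based rows of group a;
// perms: n_perm x n_a matrix of 0-based row indices forming permuted group a.
// Returns list(t_obs = per-edge t, max_t = per-permutation max |t|).
// [[Rcpp::export]]
List maxt_perm_cpp(const NumericMatrix& data, const IntegerVector& ga_obs,
                   const IntegerMatrix& perms) {
  const int n = data.nrow(), m = data.ncol();
  const int n1 = ga_obs.size(), n0 = n - n1;
  const int P = perms.nrow();
  std::vector<double> t_obs(m);
  std::vector<int> ga(ga_obs.begin(), ga_obs.end());
  pooled_t(data, ga, t_obs);

  // per-edge totals for the permutation pass
  std::vector<double> tot(m, 0.0), totq(m, 0.0);
  for (int e = 0; e < m; ++e)
    for (int s = 0; s < n; ++s) { double v = data(s, e); tot[e] += v; totq[e] += v * v; }

  NumericVector max_t(P);
  const double df = n1 + n0 - 2;
  for (int p = 0; p < P; ++p) {
    double mx = 0.0;
    for (int e = 0; e < m; ++e) {
      double s1 = 0, q1 = 0;
      for (int k = 0; k < n1; ++k) {
        double v = data(perms(p, k), e);
        s1 += v; q1 += v * v;
      }
      double s0 = tot[e] - s1, q0 = totq[e] - q1;
      double m1 = s1 / n1, m0 = s0 / n0;
      double sp2 = ((q1 - n1 * m1 * m1) + (q0 - n0 * m0 * m0)) / df;
      double den = std::sqrt(sp2 * (1.0 / n1 + 1.0 / n0));
      double t = den > 0 ? std::fabs(m1 - m0) / den : 0.0;
      if (t > mx) mx = t;
    }
    max_t[p] = mx;
  }
  return List::create(_["t_obs"] = NumericVector(t_obs.begin(), t_obs.end()),
                      _["max_t"] = max_t);
}

// Lempel-Ziv 1976 phrase count, exhaustive-history (Kaspar-Schuster) parsing.
// bits: vector of 0/1.
// [[Rcpp::export]]
int lz76_cpp(const IntegerVector& bits) {
  const int n = bits.size();
  if (n == 0) stop("empty sequence");
  for (int k = 0; k < n; ++k)
    if (bits[k] != 0 && bits[k] != 1) stop("non-binary symbol at position %d", k + 1);
  if (n == 1) return 1;
  // Kaspar & Schuster's exhaustive-history parsing, 1-based indices mapped
  // to 0-based storage: l = start of current phrase, i = candidate copy
  // origin, k = current match length, kmax = longest match from any origin
  int c = 1, l = 1, i = 0, k = 1, kmax = 1;
  while (true) {
    if (bits[i + k - 1] == bits[l + k - 1]) {
      ++k;
      if (l + k > n) { ++c; break; }   // phrase runs off the end
    } else {
      if (k > kmax) kmax = k;
      ++i;
      if (i == l) {                    // every origin tried -> close phrase
        ++c;
        l += kmax;
        if (l + 1 > n) break;
        i = 0; k = 1; kmax = 1;
      } else {
        k = 1;
      }
    }
  }
  return c;
}
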