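#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <cmath>

using namespace Rcpp;

// Simplex-projection cross-map sweep over all sliding library windows of one
// size. The R front end (cross_map_skill) precomputes the manifold distance
// matrix once per (E, tau); this routine is the hot loop shared by every
// library size and every tau_p.
//
// dist:       P x P Euclidean distances between manifold points (of M_y)
// time_index: length P, 1-based series index of each point's leading coord
// x:          the opposing (putative cause) series, length N
// k:          number of neighbours (E + 1)
// tau_p:      causal lag; manifold point at time t predicts x[t - tau_p]
// L:          library window size (consecutive manifold points)
// theiler:    temporal exclusion radius around the target (0 = target only)
//
// Returns per-window rho (NA when fewer than 3 prediction pairs), the number
// of skipped targets per window, and a zero-variance flag per window.
// [[Rcpp::export]]
List cpp_window_sweep(const NumericMatrix& dist,
                      const IntegerVector& time_index,
                      const NumericVector& x,
                      int k, int tau_p, int L, int theiler) {
  const int P = dist.nrow();
  const int N = x.size();
  if (L < 2 || L > P) stop("library size L out of range");
  const int n_win = P - L + 1;

  NumericVector rho(n_win);
  IntegerVector skipped(n_win);
  LogicalVector zero_var(n_win);

  std::vector<int> cand;
  cand.reserve(L);
  std::vector<double> obs_v, pred_v;
  obs_v.reserve(L);
  pred_v.reserve(L);

  for (int s = 0; s < n_win; ++s) {
    obs_v.clear();
    pred_v.clear();
    int n_skip = 0;

    for (int i = s; i < s + L; ++i) {
      const int ti = time_index[i];
      const int oi = ti - tau_p;      // 1-based index into x
      if (oi < 1 || oi > N) { ++n_skip; continue; }

      cand.clear();
      for (int j = s; j < s + L; ++j) {
        if (std::abs(time_index[j] - ti) <= theiler) continue; // leave-one-out
        const int oj = time_index[j] - tau_p;
        if (oj < 1 || oj > N) continue;
        cand.push_back(j);
      }
      if ((int)cand.size() < k) { ++n_skip; continue; }

      // k nearest by (distance, earlier time) -- deterministic tie-break
      const double* di = &dist(0, i);
      std::partial_sort(cand.begin(), cand.begin() + k, cand.end(),
                        [&](int a, int b) {
                          const double da = di[a], db = di[b];
                          if (da != db) return da < db;
                          return time_index[a] < time_index[b];
                        });

      // exponential simplex weights u = exp(-d/d1); degenerate d1 == 0 ->
      // uniform over the zero-distance neighbours
      double w[64];  // k = E + 1 <= 64 enforced by the R caller
      const double d1 = di[cand[0]];
      double wsum = 0.0;
      if (d1 == 0.0) {
        for (int q = 0; q < k; ++q) {
          w[q] = (di[cand[q]] == 0.0) ? 1.0 : 0.0;
          wsum += w[q];
        }
      } else {
        for (int q = 0; q < k; ++q) {
          w[q] = std::exp(-di[cand[q]] / d1);
          wsum += w[q];
        }
      }

      double pred = 0.0;
      for (int q = 0; q < k; ++q)
        pred += (w[q] / wsum) * x[time_index[cand[q]] - tau_p - 1];

      obs_v.push_back(x[oi - 1]);
      pred_v.push_back(pred);
    }

    skipped[s] = n_skip;
    const int n = obs_v.size();
    if (n < 3) {
      rho[s] = NA_REAL;
      zero_var[s] = false;
      continue;
    }
    // Pearson correlation of held-out vs predicted
    double mo = 0.0, mp = 0.0;
    for (int q = 0; q < n; ++q) { mo += obs_v[q]; mp += pred_v[q]; }
    mo /= n; mp /= n;
    double sxy = 0.0, sxx = 0.0, syy = 0.0;
    for (int q = 0; q < n; ++q) {
      const double a = obs_v[q] - mo, b = pred_v[q] - mp;
      sxy += a * b; sxx += a * a; syy += b * b;
    }
    if (sxx <= 0.0 || syy <= 0.0) {
      rho[s] = 0.0;       // zero-variance convention: defined as 0, flagged
      zero_var[s] = true;
    } else {
      rho[s] = sxy / std::sqrt(sxx * syy);
      zero_var[s] = false;
    }
  }

  return List::create(_["rho"] = rho,
                      _["skipped"] = skipped,
                      _["zero_variance"] = zero_var);
}
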