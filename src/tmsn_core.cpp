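#include <Rcpp.h>
using namespace Rcpp;

// All-pairs shortest paths on a dense length matrix (R_PosInf = no edge).
// Predecessor matrix uses 0-based node indices, -1 = none. Ties are broken
// deterministically: an intermediate node only replaces the incumbent path
// on strict improvement, with intermediates scanned in ascending index order.
static void fw_core(const double* len, int n, double* d, int* pred) {
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < n; ++j) {
      double l = len[i + n * j];
      d[i + n * j] = (i == j) ? 0.0 : l;
      pred[i + n * j] = (i != j && R_finite(l)) ? i : -1;
    }
  }
  for (int k = 0; k < n; ++k) {
    for (int i = 0; i < n; ++i) {
      double dik = d[i + n * k];
      if (!R_finite(dik)) continue;
      for (int j = 0; j < n; ++j) {
        double cand = dik + d[k + n * j];
        if (cand < d[i + n * j]) {
          d[i + n * j] = cand;
          pred[i + n * j] = pred[k + n * j];
        }
      }
    }
  }
}

// [[Rcpp::export]]
List cpp_floyd_warshall(NumericMatrix len) {
  int n = len.nrow();
  NumericMatrix d(n, n);
  IntegerMatrix pred(n, n);
  fw_core(len.begin(), n, d.begin(), pred.begin());
  return List::create(_["d"] = d, _["pred"] = pred);
}

// Count, for every ordered (baseline i, follow-up j) pair with a finite
// shortest path, the strictly interior nodes of the reconstructed path.
static void lb_core(const double* d, const int* pred, int n,
                    const int* bidx, int nb, const int* fidx, int nf,
                    double* counts) {
  for (int a = 0; a < nb; ++a) {
    int i = bidx[a];
    for (int b = 0; b < nf; ++b) {
      int j = fidx[b];
      if (i == j) continue;
      if (!R_finite(d[i + n * j])) continue;
      int k = pred[i + n * j];
      while (k != -1 && k != i) {
        counts[k] += 1.0;
        k = pred[i + n * k];
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_longitudinal_betweenness(NumericMatrix d, IntegerMatrix pred,
                                           IntegerVector base_idx0,
                                           IntegerVector fup_idx0) {
  int n = d.nrow();
  NumericVector counts(n);
  lb_core(d.begin(), pred.begin(), n, base_idx0.begin(), base_idx0.size(),
          fup_idx0.begin(), fup_idx0.size(), counts.begin());
  return counts;
}

// Edge-reshuffling null: each draw keeps the multiset of edge lengths and the
// edge count, re-assigning edges to uniformly sampled distinct unordered node
// pairs (no self-loops, symmetric placement). Returns the longitudinal
// betweenness of every node in every null network. Uses R's RNG.
// [[Rcpp::export]]
NumericMatrix cpp_null_betweenness(int n, NumericVector edge_lengths,
                                   IntegerVector base_idx0,
                                   IntegerVector fup_idx0, int n_null) {
  int m = edge_lengths.size();
  int npairs = n * (n - 1) / 2;
  if (m > npairs) stop("more edges than node pairs");
  std::vector<int> pair_i(npairs), pair_j(npairs), pool(npairs);
  int c = 0;
  for (int i = 0; i < n - 1; ++i)
    for (int j = i + 1; j < n; ++j) { pair_i[c] = i; pair_j[c] = j; ++c; }
  std::vector<double> len(n * n), d(n * n);
  std::vector<int> pred(n * n);
  NumericMatrix out(n_null, n);
  std::vector<double> counts(n);
  for (int r = 0; r < n_null; ++r) {
    for (int k = 0; k < npairs; ++k) pool[k] = k;
    // partial Fisher-Yates: first m entries are a uniform sample w/o replacement
    for (int k = 0; k < m; ++k) {
      int idx = k + (int)(unif_rand() * (npairs - k));
      if (idx >= npairs) idx = npairs - 1;
      std::swap(pool[k], pool[idx]);
    }
    std::fill(len.begin(), len.end(), R_PosInf);
    for (int k = 0; k < m; ++k) {
      int i = pair_i[pool[k]], j = pair_j[pool[k]];
      len[i + n * j] = edge_lengths[k];
      len[j + n * i] = edge_lengths[k];
    }
    fw_core(len.data(), n, d.data(), pred.data());
    std::fill(counts.begin(), counts.end(), 0.0);
    lb_core(d.data(), pred.data(), n, base_idx0.begin(), base_idx0.size(),
            fup_idx0.begin(), fup_idx0.size(), counts.data());
    for (int k = 0; k < n; ++k) out(r, k) = counts[k];
    if (r % 64 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}

// Explicit-Euler clamped diffusion: x <- x - gamma*step*L*x, then clamped
// entries are overwritten with their boundary values; stops when the max-abs
// change over free entries drops below tol.
// [[Rcpp::export]]
List cpp_clamped_diffusion(NumericMatrix L, NumericVector x0,
                           LogicalVector clamped, double gamma, double step,
                           double tol, int max_iter) {
  int n = L.nrow();
  std::vector<double> x(x0.begin(), x0.end()), xn(n);
  double delta = R_PosInf, prev_delta = R_PosInf;
  int grow_run = 0, it = 0;
  bool converged = false, diverged = false;
  double gs = gamma * step;
  for (it = 0; it < max_iter; ++it) {
    for (int i = 0; i < n; ++i) {
      double acc = 0.0;
      const double* Li = &L[0] + i;       // row i, stride n
      for (int j = 0; j < n; ++j) acc += Li[(R_xlen_t)n * j] * x[j];
      xn[i] = x[i] - gs * acc;
    }
    delta = 0.0;
    for (int i = 0; i < n; ++i) {
      if (clamped[i]) { xn[i] = x0[i]; continue; }
      double ch = std::fabs(xn[i] - x[i]);
      if (ch > delta) delta = ch;
    }
    x = xn;
    if (delta < tol) { converged = true; ++it; break; }
    grow_run = (delta > prev_delta) ? grow_run + 1 : 0;
    prev_delta = delta;
    if (grow_run >= 100) { diverged = true; ++it; break; }
    if (it % 4096 == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["x"] = NumericVector(x.begin(), x.end()),
                      _["iterations"] = it, _["delta"] = delta,
                      _["converged"] = converged, _["diverged"] = diverged);
}
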