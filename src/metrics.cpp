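// Compiled kernels for weighted graph metrics: all-pairs shortest path
// lengths (Floyd-Warshall on lengths 1/w) and nodal local efficiency
// (global efficiency of each node's neighborhood subgraph). These run once
// per graph per threshold per random reference, so they dominate the cost
// of the network-metric stage.

#include <Rcpp.h>
#include <vector>
#include <limits>

using namespace Rcpp;

static void fw_inplace(std::vector<double>& d, int n) {
  for (int k = 0; k < n; ++k) {
    const double* dk = &d[(size_t)k * n];
    for (int i = 0; i < n; ++i) {
      double dik = d[(size_t)i * n + k];
      if (!R_finite(dik)) continue;
      double* di = &d[(size_t)i * n];
      for (int j = 0; j < n; ++j) {
        double v = dik + dk[j];
        if (v < di[j]) di[j] = v;
      }
    }
  }
}

// [[Rcpp::export]]
NumericMatrix cpp_path_lengths(NumericMatrix w) {
  int n = w.nrow();
  const double inf = std::numeric_limits<double>::infinity();
  std::vector<double> d((size_t)n * n, inf);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < n; ++j)
      if (w(i, j) > 0) d[(size_t)i * n + j] = 1.0 / w(i, j);
    d[(size_t)i * n + i] = 0.0;
  }
  fw_inplace(d, n);
  NumericMatrix out(n, n);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j) out(i, j) = d[(size_t)i * n + j];
  return out;
}

// mean of 1/d over ordered pairs of a subgraph (disconnected pairs -> 0)
static double subgraph_efficiency(const NumericMatrix& w,
                                  const std::vector<int>& nodes) {
  int m = (int)nodes.size();
  if (m < 2) return 0.0;
  const double inf = std::numeric_limits<double>::infinity();
  std::vector<double> d((size_t)m * m, inf);
  for (int a = 0; a < m; ++a) {
    for (int b = 0; b < m; ++b) {
      double ww = w(nodes[a], nodes[b]);
      if (a != b && ww > 0) d[(size_t)a * m + b] = 1.0 / ww;
    }
    d[(size_t)a * m + a] = 0.0;
  }
  fw_inplace(d, m);
  double s = 0.0;
  for (int a = 0; a < m; ++a)
    for (int b = 0; b < m; ++b) {
      if (a == b) continue;
      double v = d[(size_t)a * m + b];
      if (R_finite(v) && v > 0) s += 1.0 / v;
    }
  return s / ((double)m * (m - 1));
}

// [[Rcpp::export]]
NumericVector cpp_local_efficiency(NumericMatrix w) {
  int n = w.nrow();
  NumericVector out(n);
  std::vector<int> nb;
  for (int i = 0; i < n; ++i) {
    nb.clear();
    for (int j = 0; j < n; ++j)
      if (j != i && w(i, j) > 0) nb.push_back(j);
    out[i] = (nb.size() >= 2) ? subgraph_efficiency(w, nb) : 0.0;
  }
  return out;
}
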