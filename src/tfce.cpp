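#include <Rcpp.h>
using namespace Rcpp;

// Union-find with path halving.
static int uf_find(std::vector<int>& parent, int i) {
  while (parent[i] != i) {
    parent[i] = parent[parent[i]];
    i = parent[i];
  }
  return i;
}

// Threshold-free cluster enhancement on an arbitrary graph.
//
// For every bin, integrates extent(h)^e * h^hexp * dh over thresholds
// h = (j - 0.5) * dh, j = 1..n_steps, dh = max|t| / n_steps, where extent
// is the size of the connected component of supra-threshold bins (same
// sign as the bin) containing it. Positive and negative values are
// enhanced separately (sign-symmetric) and the sign is reattached.
//
// adj is a list of integer vectors of 0-based neighbour indices.
// [[Rcpp::export(name = ".tfce_enhance_cpp")]]
NumericVector tfce_enhance_cpp(NumericVector t, List adj, int n_steps,
                               double e_exponent, double h_exponent) {
  const int n = t.size();
  if (n == 0) stop("empty statistic map");
  if (n_steps <= 0) stop("n_steps must be positive");

  std::vector<std::vector<int> > nb(n);
  for (int i = 0; i < n; ++i) {
    IntegerVector v = adj[i];
    nb[i].assign(v.begin(), v.end());
  }

  NumericVector out(n);
  double tmax = 0.0;
  for (int i = 0; i < n; ++i) tmax = std::max(tmax, std::fabs(t[i]));
  if (tmax == 0.0) return out;
  const double dh = tmax / n_steps;

  std::vector<int> parent(n), csize(n);
  std::vector<char> active(n);

  for (int sign = -1; sign <= 1; sign += 2) {
    for (int j = 1; j <= n_steps; ++j) {
      const double h = (j - 0.5) * dh;
      bool any = false;
      for (int i = 0; i < n; ++i) {
        active[i] = (sign > 0 ? t[i] : -t[i]) >= h;
        if (active[i]) { parent[i] = i; csize[i] = 1; any = true; }
      }
      if (!any) break;  // higher thresholds are empty too
      for (int i = 0; i < n; ++i) {
        if (!active[i]) continue;
        for (size_t k = 0; k < nb[i].size(); ++k) {
          const int m = nb[i][k];
          if (m <= i || !active[m]) continue;
          int ri = uf_find(parent, i), rm = uf_find(parent, m);
          if (ri != rm) {
            if (csize[ri] < csize[rm]) std::swap(ri, rm);
            parent[rm] = ri;
            csize[ri] += csize[rm];
          }
        }
      }
      const double hterm = std::pow(h, h_exponent) * dh;
      for (int i = 0; i < n; ++i) {
        if (active[i]) {
          const int ext = csize[uf_find(parent, i)];
          out[i] += sign * std::pow((double)ext, e_exponent) * hterm;
        }
      }
    }
  }
  return out;
}
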