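#include <Rcpp.h>
using namespace Rcpp;

// Bernoulli sampling of non-backbone contacts.
//
// Sampling contract (documented in ?build_connectivity): one uniform draw is
// consumed for every pair (i, j) with 0 <= i < j <= L and j - i >= 2, visited
// in row-major order (i ascending, then j ascending), and compared against the
// pair's contact probability.  p_by_sep[s - 1] holds P_c(s) for s = 1..L;
// pairs touching bead 0 or bead L are additionally scaled by boundary_factor.
// [[Rcpp::export]]
IntegerMatrix cpp_sample_bonds(int L, NumericVector p_by_sep,
                               double boundary_factor) {
  std::vector<int> ei, ej;
  for (int i = 0; i <= L - 2; ++i) {
    for (int j = i + 2; j <= L; ++j) {
      double p = p_by_sep[j - i - 1];
      if (i == 0 || j == L) p *= boundary_factor;
      double u = unif_rand();
      if (u < p) {
        ei.push_back(i);
        ej.push_back(j);
      }
    }
  }
  IntegerMatrix out(ei.size(), 2);
  for (int k = 0; k < (int)ei.size(); ++k) {
    out(k, 0) = ei[k];
    out(k, 1) = ej[k];
  }
  return out;
}

// Exact annealed transition kernel W[i][j] = E[C_ij / N_i] under a fresh
// redraw of all non-backbone contacts each step.  For an interior site i the
// two backbone bonds are always present, so N_i = 2 + K with K the
// Poisson-binomial count of realised non-backbone contacts of i.  The pmf of
// K is built by dynamic programming; conditioning on C_ij = 1 removes bond j
// from the pool (deconvolution of one Bernoulli factor) and shifts the
// denominator to 3 + K'.
//
// Rows 0 and L (absorbing) and the diagonal are left at zero; only interior
// rows are filled.  Each interior row sums to 1 up to truncation error.
// [[Rcpp::export]]
NumericMatrix cpp_annealed_kernel(int L, NumericVector p_by_sep,
                                  double boundary_factor) {
  int n = L + 1;
  NumericMatrix W(n, n);
  std::vector<double> p;  // success probs of eligible partners of site i
  std::vector<int> part;  // partner ids
  std::vector<double> f, g;

  for (int i = 1; i <= L - 1; ++i) {
    p.clear();
    part.clear();
    for (int j = 0; j <= L; ++j) {
      if (std::abs(j - i) < 2) continue;
      double pj = p_by_sep[std::abs(j - i) - 1];
      if (j == 0 || j == L) pj *= boundary_factor;
      if (pj > 0.0) {
        if (pj > 1.0) pj = 1.0;
        p.push_back(pj);
        part.push_back(j);
      }
    }
    int m = p.size();
    // pmf of K = sum of Bernoulli(p_k); truncated support [0, hi]
    f.assign(m + 1, 0.0);
    f[0] = 1.0;
    int hi = 0;
    for (int k = 0; k < m; ++k) {
      double pk = p[k], qk = 1.0 - pk;
      int newhi = std::min(hi + 1, m);
      for (int s = newhi; s >= 1; --s) f[s] = f[s] * qk + f[s - 1] * pk;
      f[0] *= qk;
      hi = newhi;
      // drop negligible tail to keep the DP narrow
      while (hi > 0 && f[hi] < 1e-16) --hi;
    }
    // backbone moves: E[1 / (2 + K)]
    double wb = 0.0;
    for (int s = 0; s <= hi; ++s) wb += f[s] / (2.0 + s);
    W(i, i - 1) = wb;
    W(i, i + 1) = wb;
    // non-backbone moves: p_j * E[1 / (3 + K_{-j})]
    g.assign(hi + 1, 0.0);
    for (int k = 0; k < m; ++k) {
      double pk = p[k], qk = 1.0 - pk;
      if (pk >= 1.0) {
        // bond always present: K_{-j} = K - 1
        for (int s = 0; s <= hi - 1; ++s) g[s] = f[s + 1];
        if (hi >= 0) g[hi] = 0.0;
      } else if (pk <= 0.5) {
        // forward deconvolution, stable for small p
        g[0] = f[0] / qk;
        for (int s = 1; s <= hi; ++s) g[s] = (f[s] - pk * g[s - 1]) / qk;
      } else {
        // backward deconvolution, stable for large p:
        // f[s] = qk * g[s] + pk * g[s-1]  =>  g[s-1] = (f[s] - qk*g[s]) / pk
        double ftop = (hi + 1 <= m) ? f[hi + 1] : 0.0;
        g[hi] = ftop / pk;  // g[hi+1] taken as 0 beyond the truncated support
        for (int s = hi; s >= 1; --s) g[s - 1] = (f[s] - qk * g[s]) / pk;
      }
      double w = 0.0;
      for (int s = 0; s <= hi; ++s) {
        double gv = g[s];
        if (gv > 0.0) w += gv / (3.0 + s);
      }
      W(i, part[k]) = pk * w;
    }
  }
  return W;
}
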