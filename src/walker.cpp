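#include <Rcpp.h>
using namespace Rcpp;

namespace {

// adjacency list for beads 0..L; backbone bonds always included
void build_adj(std::vector<std::vector<int> > &adj, int L,
               const IntegerMatrix &bonds) {
  adj.assign(L + 1, std::vector<int>());
  for (int i = 0; i < L; ++i) {
    adj[i].push_back(i + 1);
    adj[i + 1].push_back(i);
  }
  for (int k = 0; k < bonds.nrow(); ++k) {
    int i = bonds(k, 0), j = bonds(k, 1);
    adj[i].push_back(j);
    adj[j].push_back(i);
  }
}

// redraw all non-backbone contacts in place (same Bernoulli scheme as
// cpp_sample_bonds, without materialising an edge matrix)
void resample_adj(std::vector<std::vector<int> > &adj, int L,
                  const NumericVector &p_by_sep, double bf) {
  for (int i = 0; i <= L; ++i) {
    adj[i].clear();
    if (i > 0) adj[i].push_back(i - 1);
    if (i < L) adj[i].push_back(i + 1);
  }
  for (int i = 0; i <= L - 2; ++i) {
    for (int j = i + 2; j <= L; ++j) {
      double p = p_by_sep[j - i - 1];
      if (i == 0 || j == L) p *= bf;
      if (p > 0.0 && unif_rand() < p) {
        adj[i].push_back(j);
        adj[j].push_back(i);
      }
    }
  }
}

inline int draw_site(int L) {
  int s = (int)(unif_rand() * (L + 1));
  if (s > L) s = L;
  return s;
}

}  // namespace

// First-passage times of random walks on a contact network with sliding,
// intersegmental hops, and bulk unbinding/rebinding.
//
// Per step at site i: with probability p_off the walker unbinds (cost
// tau + tau_f) and rebinds uniformly over all L+1 sites (landing on 0 or L
// counts as absorption); otherwise it moves to a uniformly chosen bonded
// neighbour, costing tau for a backbone move (|delta| == 1) and t_jump for a
// hop.  t_switch > 0 (finite) reshuffles the non-backbone bonds every
// t_switch walker moves; t_switch == 1 is handled by redrawing the current
// site's bonds lazily each step, which is distributionally identical.
// t_switch <= 0 means static.
// [[Rcpp::export]]
NumericVector cpp_simulate_walks(IntegerMatrix bonds, int L, int n_walks,
                                 double p_off, double tau, double t_jump,
                                 double tau_f, int start, double t_switch,
                                 NumericVector p_by_sep,
                                 double boundary_factor) {
  NumericVector times(n_walks);
  bool dynamic_full = (t_switch > 1.5) && R_finite(t_switch);
  bool dynamic_lazy = (t_switch > 0.5 && t_switch <= 1.5);
  long long switch_every = dynamic_full ? (long long)(t_switch + 0.5) : 0;

  std::vector<std::vector<int> > adj;
  if (!dynamic_lazy) build_adj(adj, L, bonds);

  std::vector<int> row;
  row.reserve(64);

  for (int w = 0; w < n_walks; ++w) {
    if (dynamic_full && w > 0) {
      // every trajectory starts from the supplied initial configuration;
      // the network then evolves within the trajectory
      build_adj(adj, L, bonds);
    }
    double t = 0.0;
    int pos = start;
    long long moves = 0;
    while (true) {
      if (p_off > 0.0 && unif_rand() < p_off) {
        t += tau + tau_f;
        pos = draw_site(L);
      } else if (dynamic_lazy) {
        row.clear();
        row.push_back(pos - 1);
        row.push_back(pos + 1);
        for (int j = 0; j <= L; ++j) {
          int d = j - pos;
          if (d < 2 && d > -2) continue;
          double p = p_by_sep[(d > 0 ? d : -d) - 1];
          if (j == 0 || j == L) p *= boundary_factor;
          if (p > 0.0 && unif_rand() < p) row.push_back(j);
        }
        int k = (int)(unif_rand() * row.size());
        if (k >= (int)row.size()) k = row.size() - 1;
        int nxt = row[k];
        t += (std::abs(nxt - pos) == 1) ? tau : t_jump;
        pos = nxt;
      } else {
        const std::vector<int> &nb = adj[pos];
        int k = (int)(unif_rand() * nb.size());
        if (k >= (int)nb.size()) k = nb.size() - 1;
        int nxt = nb[k];
        t += (std::abs(nxt - pos) == 1) ? tau : t_jump;
        pos = nxt;
      }
      if (pos == 0 || pos == L) break;
      ++moves;
      if (dynamic_full && moves % switch_every == 0)
        resample_adj(adj, L, p_by_sep, boundary_factor);
      if (moves % 1048576 == 0) Rcpp::checkUserInterrupt();
    }
    times[w] = t;
  }
  return times;
}
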