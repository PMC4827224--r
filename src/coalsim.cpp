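#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Backward-in-time Kingman coalescent over demes with a timed event
// schedule.  Lineages coalesce within demes at pairwise rate 1/G_d per
// generation, G_d the deme's current gene-copy number.  Event codes:
//   0 split   : all lineages of deme e1 move into deme e2
//   1 admix   : each lineage of deme e1 moves to e2 with prob r, else e3
//   2 resize  : deme e1's gene-copy number becomes r
// Events must be sorted by time.  Uses R's RNG (set.seed-reproducible).
//
// [[Rcpp::export]]
List cpp_simulate_genealogy(IntegerVector tip_deme,
                            NumericVector deme_sizes,
                            NumericMatrix events) {
  const int n = tip_deme.size();
  const int n_demes = deme_sizes.size();
  if (n < 2) stop("need at least 2 sampled lineages");

  std::vector<double> G(deme_sizes.begin(), deme_sizes.end());
  for (int d = 0; d < n_demes; ++d)
    if (!(G[d] > 0)) stop("non-positive deme size");

  std::vector< std::vector<int> > live(n_demes);
  for (int i = 0; i < n; ++i) {
    int d = tip_deme[i];
    if (d < 0 || d >= n_demes) stop("tip deme index out of range");
    live[d].push_back(i);
  }

  const int n_nodes = 2 * n - 1;
  IntegerVector parent(n_nodes, -1);
  NumericVector node_time(n_nodes, 0.0);
  int next_node = n;

  double t = 0.0;
  int ev = 0, n_live = n;
  const int n_ev = events.nrow();

  while (n_live > 1) {
    double rate = 0.0;
    for (int d = 0; d < n_demes; ++d) {
      double k = (double) live[d].size();
      if (k >= 2) rate += k * (k - 1.0) / (2.0 * G[d]);
    }
    double t_ev = (ev < n_ev) ? events(ev, 0) : R_PosInf;

    double dt = (rate > 0) ? R::rexp(1.0 / rate) : R_PosInf;
    if (t + dt < t_ev) {
      // a coalescence happens before the next demographic event
      t += dt;
      double u = unif_rand() * rate, acc = 0.0;
      int d_hit = -1;
      for (int d = 0; d < n_demes; ++d) {
        double k = (double) live[d].size();
        if (k >= 2) {
          acc += k * (k - 1.0) / (2.0 * G[d]);
          if (u <= acc) { d_hit = d; break; }
        }
      }
      if (d_hit < 0) {  // numeric edge: take last eligible deme
        for (int d = n_demes - 1; d >= 0; --d)
          if (live[d].size() >= 2) { d_hit = d; break; }
      }
      std::vector<int> &L = live[d_hit];
      int k = (int) L.size();
      int i = (int) std::floor(unif_rand() * k); if (i >= k) i = k - 1;
      int j = (int) std::floor(unif_rand() * (k - 1)); if (j >= k - 1) j = k - 2;
      if (j >= i) ++j;
      int a = L[i], b = L[j];
      int anc = next_node++;
      parent[a] = anc; parent[b] = anc;
      node_time[anc] = t;
      L[i] = anc;                 // replace a by anc, drop b
      L.erase(L.begin() + j);
      --n_live;
    } else {
      if (ev >= n_ev)
        stop("lineages cannot coalesce: no remaining events and zero rate");
      t = t_ev;
      int kind = (int) events(ev, 1);
      int e1 = (int) events(ev, 2);
      int e2 = (int) events(ev, 3);
      int e3 = (int) events(ev, 4);
      double r = events(ev, 5);
      if (kind == 0) {            // split: e1 -> e2
        for (size_t q = 0; q < live[e1].size(); ++q)
          live[e2].push_back(live[e1][q]);
        live[e1].clear();
      } else if (kind == 1) {     // admixture: e1 -> e2 w.p. r else e3
        for (size_t q = 0; q < live[e1].size(); ++q) {
          if (unif_rand() < r) live[e2].push_back(live[e1][q]);
          else                 live[e3].push_back(live[e1][q]);
        }
        live[e1].clear();
      } else if (kind == 2) {     // resize
        if (!(r > 0)) stop("resize to non-positive size");
        G[e1] = r;
      } else stop("unknown event kind");
      ++ev;
    }
  }

  return List::create(_["parent"] = parent, _["node_time"] = node_time);
}

// Evolve L sites down a genealogy under a reversible 4-state model given
// by its eigendecomposition (Q = U diag(lambda) Uinv, scaled to mean rate
// 1).  Branch lengths in expected substitutions are mu * generations.
// Returns an n_tips x L integer matrix of states 0..3 (A,C,G,T).
//
// [[Rcpp::export]]
IntegerMatrix cpp_evolve_sites(IntegerVector parent,
                               NumericVector node_time,
                               int n_tips, int L,
                               NumericMatrix U, NumericMatrix Uinv,
                               NumericVector lambda,
                               NumericVector pi, double mu) {
  const int n_nodes = parent.size();
  std::vector<int> ord(n_nodes);
  for (int i = 0; i < n_nodes; ++i) ord[i] = i;
  // process parents before children: sort by node_time descending
  std::sort(ord.begin(), ord.end(), [&](int a, int b) {
    if (node_time[a] != node_time[b]) return node_time[a] > node_time[b];
    return a > b;  // internal nodes created later are older on ties
  });

  IntegerMatrix states(n_nodes, L);
  double cpi[4] = { pi[0], pi[0] + pi[1], pi[0] + pi[1] + pi[2], 1.0 };

  for (int oi = 0; oi < n_nodes; ++oi) {
    int v = ord[oi];
    if (parent[v] < 0) {                       // root: draw from pi
      for (int s = 0; s < L; ++s) {
        double u = unif_rand();
        int st = 0; while (st < 3 && u > cpi[st]) ++st;
        states(v, s) = st;
      }
      continue;
    }
    double d = mu * (node_time[parent[v]] - node_time[v]);
    if (d < 0) d = 0;
    // P(d) = U exp(lambda d) Uinv, cumulative by row
    double P[4][4];
    double e[4];
    for (int k = 0; k < 4; ++k) {
      double x = lambda[k] * d;
      e[k] = (x < -700) ? 0.0 : std::exp(x);
    }
    for (int a = 0; a < 4; ++a) {
      double rowsum = 0.0;
      for (int b = 0; b < 4; ++b) {
        double p = 0.0;
        for (int k = 0; k < 4; ++k) p += U(a, k) * e[k] * Uinv(k, b);
        if (p < 0) p = 0;
        P[a][b] = p; rowsum += p;
      }
      double c = 0.0;
      for (int b = 0; b < 4; ++b) { c += P[a][b] / rowsum; P[a][b] = c; }
      P[a][3] = 1.0;
    }
    for (int s = 0; s < L; ++s) {
      int ps = states(parent[v], s);
      double u = unif_rand();
      int st = 0; while (st < 3 && u > P[ps][st]) ++st;
      states(v, s) = st;
    }
  }

  IntegerMatrix tips(n_tips, L);
  for (int i = 0; i < n_tips; ++i)
    for (int s = 0; s < L; ++s) tips(i, s) = states(i, s);
  return tips;
}

// Generalized stepwise mutation of a microsatellite repeat count down a
// genealogy.  Mutations are Poisson(mu * branch length); each steps the
// count by k*s with s = +/-1 equiprobable and k = 1 w.p. 1 - p_geom,
// else 1 + Geometric(p_geom).  Steps leaving [amin, amax] are redrawn.
//
// [[Rcpp::export]]
IntegerVector cpp_evolve_msat(IntegerVector parent,
                              NumericVector node_time,
                              int n_tips, int root_allele,
                              double mu, double p_geom,
                              int amin, int amax) {
  const int n_nodes = parent.size();
  std::vector<int> ord(n_nodes);
  for (int i = 0; i < n_nodes; ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(), [&](int a, int b) {
    if (node_time[a] != node_time[b]) return node_time[a] > node_time[b];
    return a > b;
  });

  IntegerVector allele(n_nodes);
  for (int oi = 0; oi < n_nodes; ++oi) {
    int v = ord[oi];
    if (parent[v] < 0) { allele[v] = root_allele; continue; }
    double brlen = node_time[parent[v]] - node_time[v];
    if (brlen < 0) brlen = 0;
    int a = allele[parent[v]];
    int n_mut = (int) R::rpois(mu * brlen);
    for (int m = 0; m < n_mut; ++m) {
      for (int attempt = 0; attempt < 1000; ++attempt) {
        int k = 1;
        if (p_geom > 0 && unif_rand() < p_geom)
          k = 2 + (int) R::rgeom(1.0 - p_geom);
        int s = (unif_rand() < 0.5) ? 1 : -1;
        int cand = a + k * s;
        if (cand >= amin && cand <= amax) { a = cand; break; }
        if (attempt == 999) break;  // range saturated; keep current allele
      }
    }
    allele[v] = a;
  }

  IntegerVector tips(n_tips);
  for (int i = 0; i < n_tips; ++i) tips[i] = allele[i];
  return tips;
}
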