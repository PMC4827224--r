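#include <Rcpp.h>
#include <vector>
#include <map>
#include <cmath>
using namespace Rcpp;

// Fast summary statistics for simulated data (no missing calls).
// Mirrors the R reference implementations; the test suite asserts
// equality of the two routes on shared inputs.

// Per-deme mtDNA statistics + per-pair Hudson F_ST / dxy from an
// integer state matrix (states 0..3), deme index 0..D-1 per row.
// Returns: per_deme (D x 4: nhap, S, h, pi), pairs (npair x 2: fst,
// dxy), fst_defined (npair).
// [[Rcpp::export]]
List cpp_mt_stats(IntegerMatrix states, IntegerVector deme, int D) {
  const int n = states.nrow(), L = states.ncol();
  std::vector<int> nd(D, 0);
  for (int i = 0; i < n; ++i) nd[deme[i]]++;

  // per-deme per-site state counts
  std::vector< std::vector<int> > cnt(D, std::vector<int>(L * 4, 0));
  for (int i = 0; i < n; ++i) {
    int d = deme[i];
    for (int s = 0; s < L; ++s) cnt[d][s * 4 + states(i, s)]++;
  }

  NumericMatrix per_deme(D, 4);
  for (int d = 0; d < D; ++d) {
    int ndk = nd[d];
    double pi = 0.0; int S = 0;
    std::vector<int> var_sites;
    for (int s = 0; s < L; ++s) {
      long sq = 0;
      for (int b = 0; b < 4; ++b) {
        long c = cnt[d][s * 4 + b];
        sq += c * c;
      }
      if (sq < (long) ndk * ndk) {
        ++S;
        var_sites.push_back(s);
        pi += ((double) ndk * ndk - sq) / ((double) ndk * (ndk - 1));
      }
    }
    pi /= L;
    // haplotypes over this deme's variable sites
    int nhap; double h;
    if (var_sites.empty()) { nhap = 1; h = 0.0; }
    else {
      std::map< std::vector<int>, int > tab;
      for (int i = 0; i < n; ++i) {
        if (deme[i] != d) continue;
        std::vector<int> key(var_sites.size());
        for (size_t q = 0; q < var_sites.size(); ++q)
          key[q] = states(i, var_sites[q]);
        tab[key]++;
      }
      nhap = (int) tab.size();
      double sump2 = 0.0;
      for (std::map< std::vector<int>, int >::iterator it = tab.begin();
           it != tab.end(); ++it) {
        double p = (double) it->second / ndk;
        sump2 += p * p;
      }
      h = (double) ndk * (1.0 - sump2) / (ndk - 1);
    }
    per_deme(d, 0) = nhap; per_deme(d, 1) = S;
    per_deme(d, 2) = h; per_deme(d, 3) = pi;
  }

  int npair = D * (D - 1) / 2;
  NumericMatrix pairs(npair, 2);
  LogicalVector fst_def(npair);
  int q = 0;
  for (int a = 0; a < D - 1; ++a) for (int b = a + 1; b < D; ++b, ++q) {
    double dxy = 0.0;
    long na = nd[a], nb = nd[b];
    for (int s = 0; s < L; ++s) {
      long cross = 0;
      for (int st = 0; st < 4; ++st)
        cross += (long) cnt[a][s * 4 + st] * cnt[b][s * 4 + st];
      dxy += ((double) na * nb - cross) / ((double) na * nb);
    }
    dxy /= L;
    pairs(q, 1) = dxy;
    if (dxy > 0) {
      double hw = (per_deme(a, 3) + per_deme(b, 3)) / 2.0;
      pairs(q, 0) = 1.0 - hw / dxy;
      fst_def[q] = true;
    } else { pairs(q, 0) = 0.0; fst_def[q] = false; }
  }
  return List::create(_["per_deme"] = per_deme, _["pairs"] = pairs,
                      _["fst_defined"] = fst_def);
}

// Per-deme microsatellite panel + per-pair Weir-Cockerham theta and
// (delta mu)^2 from a complete (no-NA) genotype matrix (2 columns per
// locus), deme index per individual.
// Returns: per_deme (D x 4: mean A, mean unbiased He, mean allele-size
// variance, mean Garza-Williamson M), pairs (npair x 2), defined flags.
// [[Rcpp::export]]
List cpp_msat_stats(IntegerMatrix geno, IntegerVector deme, int D,
                    int amin, int amax) {
  const int n = geno.nrow();
  const int L = geno.ncol() / 2;
  const int W = amax - amin + 1;
  std::vector<int> nd(D, 0);
  for (int i = 0; i < n; ++i) nd[deme[i]]++;

  NumericMatrix per_deme(D, 4);
  int npair = D * (D - 1) / 2;
  NumericVector fst_num(npair), fst_den(npair), dmu2(npair);
  IntegerVector dmu_n(npair);

  std::vector<int> ccount(D * W), hcount(D * W);
  std::vector<double> msum(D);

  for (int l = 0; l < L; ++l) {
    std::fill(ccount.begin(), ccount.end(), 0);
    std::fill(hcount.begin(), hcount.end(), 0);
    std::fill(msum.begin(), msum.end(), 0.0);
    for (int i = 0; i < n; ++i) {
      int d = deme[i];
      int a1 = geno(i, 2 * l) - amin, a2 = geno(i, 2 * l + 1) - amin;
      ccount[d * W + a1]++; ccount[d * W + a2]++;
      if (a1 != a2) { hcount[d * W + a1]++; hcount[d * W + a2]++; }
      msum[d] += (double) (a1 + a2);
    }
    // per-deme panel contributions
    for (int d = 0; d < D; ++d) {
      int n2 = 2 * nd[d];
      int A = 0, lo = -1, hi = -1;
      double sump2 = 0.0, mean = msum[d] / n2, varacc = 0.0;
      for (int a = 0; a < W; ++a) {
        int c = ccount[d * W + a];
        if (c > 0) {
          ++A; if (lo < 0) lo = a; hi = a;
          double p = (double) c / n2;
          sump2 += p * p;
          varacc += c * ((double) a - mean) * ((double) a - mean);
        }
      }
      double he = (n2 > 1) ? ((double) n2 / (n2 - 1)) * (1.0 - sump2) : 0.0;
      double va = (n2 > 1) ? varacc / (n2 - 1) : 0.0;
      per_deme(d, 0) += A;
      per_deme(d, 1) += he;
      per_deme(d, 2) += va;
      per_deme(d, 3) += (double) A / (hi - lo + 1);
    }
    // per-pair W&C components and (delta mu)^2
    int q = 0;
    for (int x = 0; x < D - 1; ++x) for (int y = x + 1; y < D; ++y, ++q) {
      double n1 = nd[x], n2_ = nd[y];
      double nbar = (n1 + n2_) / 2.0, rn = n1 + n2_;
      double nc = (rn - (n1 * n1 + n2_ * n2_) / rn);  // r - 1 = 1
      bool poly = false;
      for (int a = 0; a < W; ++a) {
        int cx = ccount[x * W + a], cy = ccount[y * W + a];
        if (cx + cy == 0) continue;
        if (cx + cy == (int) (2 * rn)) continue;   // allele fixed in both
        poly = true;
        double px = cx / (2.0 * n1), py = cy / (2.0 * n2_);
        double hx = hcount[x * W + a] / n1, hy = hcount[y * W + a] / n2_;
        double pbar = (n1 * px + n2_ * py) / rn;
        double hbar = (n1 * hx + n2_ * hy) / rn;
        double s2 = (n1 * (px - pbar) * (px - pbar) +
                     n2_ * (py - pbar) * (py - pbar)) / nbar;
        double inner = pbar * (1.0 - pbar) - s2 / 2.0;
        double aa = (nbar / nc) * (s2 - (inner - hbar / 4.0) / (nbar - 1.0));
        double bb = (nbar / (nbar - 1.0)) *
          (inner - (2.0 * nbar - 1.0) / (4.0 * nbar) * hbar);
        double cc = hbar / 2.0;
        fst_num[q] += aa;
        fst_den[q] += aa + bb + cc;
      }
      if (poly) {
        double d0 = msum[x] / (2.0 * n1) - msum[y] / (2.0 * n2_);
        dmu2[q] += d0 * d0;
        dmu_n[q]++;
      } else {
        // monomorphic locus still contributes to (delta mu)^2 (it is 0)
        dmu2[q] += 0.0;
        dmu_n[q]++;
      }
    }
  }
  for (int d = 0; d < D; ++d)
    for (int k = 0; k < 4; ++k) per_deme(d, k) /= L;

  NumericMatrix pairs(npair, 2);
  LogicalVector fst_def(npair), dmu_def(npair);
  for (int q = 0; q < npair; ++q) {
    if (fst_den[q] > 0) { pairs(q, 0) = fst_num[q] / fst_den[q]; fst_def[q] = true; }
    else { pairs(q, 0) = 0.0; fst_def[q] = false; }
    if (dmu_n[q] > 0) { pairs(q, 1) = dmu2[q] / dmu_n[q]; dmu_def[q] = true; }
    else { pairs(q, 1) = 0.0; dmu_def[q] = false; }
  }
  return List::create(_["per_deme"] = per_deme, _["pairs"] = pairs,
                      _["fst_defined"] = fst_def,
                      _["dmu_defined"] = dmu_def);
}
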