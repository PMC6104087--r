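#include <Rcpp.h>
#include <vector>
#include <set>
#include <cmath>
using namespace Rcpp;

// squared distance from point p to the segment a-b; also reports whether the
// nearest point is strictly interior (t in (0,1))
static double seg_dist2(const double* p, const double* a, const double* b) {
  double ab[3], ap[3];
  double ab2 = 0.0, t = 0.0;
  for (int d = 0; d < 3; ++d) {
    ab[d] = b[d] - a[d];
    ap[d] = p[d] - a[d];
    ab2 += ab[d] * ab[d];
    t += ap[d] * ab[d];
  }
  if (ab2 > 0.0) t /= ab2; else t = 0.0;
  if (t < 0.0) t = 0.0;
  if (t > 1.0) t = 1.0;
  double d2 = 0.0;
  for (int d = 0; d < 3; ++d) {
    double diff = p[d] - (a[d] + t * ab[d]);
    d2 += diff * diff;
  }
  return d2;
}

// Shadow-screened residue contact pairs.
// xyz: heavy-atom coordinates; rid: 1-based residue index per atom;
// chain_of_atom: 1-based chain id per atom; res_chain / res_no: per-residue
// chain id and residue number. A residue pair is returned when at least one
// atomic candidate pair (distance <= cutoff, separation rule satisfied)
// survives occlusion by every third atom (sphere of shadow_radius centred on
// the third atom intersecting the open segment between the pair).
// [[Rcpp::export]]
IntegerMatrix cpp_shadow_pairs(NumericMatrix xyz, IntegerVector rid,
                               IntegerVector chain_of_atom,
                               IntegerVector res_chain, IntegerVector res_no,
                               double cutoff, double shadow_radius,
                               int min_seq_sep) {
  const int na = xyz.nrow();
  const double cut2 = cutoff * cutoff;
  const double rad2 = shadow_radius * shadow_radius;
  std::vector<double> X(3 * na);
  for (int i = 0; i < na; ++i) {
    X[3 * i] = xyz(i, 0); X[3 * i + 1] = xyz(i, 1); X[3 * i + 2] = xyz(i, 2);
  }
  int nres = res_no.size();
  std::set<long long> found;
  // occluder prescreen: an occluding sphere must lie within cutoff +
  // shadow_radius of both endpoints (segment length <= cutoff)
  const double occ_reach = cutoff + shadow_radius;
  const double occ_reach2 = occ_reach * occ_reach;
  for (int i = 0; i < na; ++i) {
    for (int j = i + 1; j < na; ++j) {
      int ri = rid[i] - 1, rj = rid[j] - 1;
      if (ri == rj) continue;
      if (res_chain[ri] == res_chain[rj] &&
          std::abs(res_no[ri] - res_no[rj]) < min_seq_sep) continue;
      long long key = (long long)std::min(ri, rj) * nres + std::max(ri, rj);
      if (found.count(key)) continue;  // residue pair already established
      double d2 = 0.0;
      for (int d = 0; d < 3; ++d) {
        double diff = X[3 * i + d] - X[3 * j + d];
        d2 += diff * diff;
      }
      if (d2 > cut2) continue;
      bool occluded = false;
      if (shadow_radius > 0.0) {
        for (int k = 0; k < na && !occluded; ++k) {
          if (k == i || k == j) continue;  // an atom never occludes itself
          double dki = 0.0;
          for (int d = 0; d < 3; ++d) {
            double diff = X[3 * k + d] - X[3 * i + d];
            dki += diff * diff;
          }
          if (dki > occ_reach2) continue;
          if (seg_dist2(&X[3 * k], &X[3 * i], &X[3 * j]) < rad2)
            occluded = true;
        }
      }
      if (!occluded) found.insert(key);
    }
  }
  IntegerMatrix out(found.size(), 2);
  int r = 0;
  for (long long key : found) {
    out(r, 0) = (int)(key / nres) + 1;
    out(r, 1) = (int)(key % nres) + 1;
    ++r;
  }
  return out;
}

// Count inter-set atom pairs closer than dist (steric clash check).
// [[Rcpp::export]]
int cpp_count_clashes(NumericMatrix a, NumericMatrix b, double dist) {
  const double d2lim = dist * dist;
  int count = 0;
  for (int i = 0; i < a.nrow(); ++i)
    for (int j = 0; j < b.nrow(); ++j) {
      double d2 = 0.0;
      for (int d = 0; d < 3; ++d) {
        double diff = a(i, d) - b(j, d);
        d2 += diff * diff;
      }
      if (d2 < d2lim) ++count;
    }
  return count;
}

// Bead pairs within cutoff honouring the intra-chain separation rule.
// [[Rcpp::export]]
IntegerMatrix cpp_cutoff_pairs(NumericMatrix xyz, IntegerVector chain_id,
                               IntegerVector resno, double cutoff,
                               int min_seq_sep) {
  const int n = xyz.nrow();
  const double cut2 = cutoff * cutoff;
  std::vector<int> ia, ib;
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      if (chain_id[i] == chain_id[j] &&
          std::abs(resno[i] - resno[j]) < min_seq_sep) continue;
      double d2 = 0.0;
      for (int d = 0; d < 3; ++d) {
        double diff = xyz(i, d) - xyz(j, d);
        d2 += diff * diff;
      }
      if (d2 <= cut2) { ia.push_back(i + 1); ib.push_back(j + 1); }
    }
  }
  IntegerMatrix out(ia.size(), 2);
  for (size_t r = 0; r < ia.size(); ++r) {
    out(r, 0) = ia[r]; out(r, 1) = ib[r];
  }
  return out;
}
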