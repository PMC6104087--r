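// C-alpha structure-based model with Gaussian native contacts:
//   bond      V = kb (r - r0)^2
//   angle     V = ka (th - th0)^2
//   dihedral  V = kd [(1 - cos(ph - ph0)) + 1/2 (1 - cos 3(ph - ph0))]
//   contact   V = eps [(1 + (rex/r)^12)(1 - exp(-(r - r0)^2 / (2 s^2))) - 1]
//   excluded  V = (rex/r)^12 - (rex/rc)^12   for r < rc (truncated, shifted)
// Reduced units: energy eps = 1, mass 1, kB = 1, length in Angstrom.
#include <Rcpp.h>
#include <vector>
#include <unordered_set>
#include <cmath>
#include <limits>
#include <random>
using namespace Rcpp;

struct FF {
  int n;
  std::vector<int> b_i, b_j; std::vector<double> b_r0, b_k;
  std::vector<int> a_i, a_j, a_k; std::vector<double> a_t0, a_ka;
  std::vector<int> d_i, d_j, d_k, d_l; std::vector<double> d_p0, d_kd;
  std::vector<int> c_i, c_j; std::vector<double> c_r0, c_eps, c_sig;
  double rex, ev_cut, ev_shift;
  // excluded-volume pair eligibility
  std::vector<int> seg, pos;
  std::unordered_set<long long> skip;  // contact pairs, never double counted
  long long key(int i, int j) const {
    if (i > j) std::swap(i, j);
    return (long long)i * n + j;
  }
  bool ev_pair(int i, int j) const {
    if (seg[i] == seg[j] && std::abs(pos[i] - pos[j]) < 4) return false;
    return !skip.count(key(i, j));
  }
};

static FF parse_ff(const List& ff) {
  FF f;
  f.n = as<int>(ff["n"]);
  IntegerMatrix B = ff["bonds"];
  NumericVector br0 = ff["bond_r0"], bk = ff["bond_k"];
  for (int r = 0; r < B.nrow(); ++r) {
    f.b_i.push_back(B(r, 0) - 1); f.b_j.push_back(B(r, 1) - 1);
    f.b_r0.push_back(br0[r]); f.b_k.push_back(bk[r]);
  }
  IntegerMatrix A = ff["angles"];
  NumericVector at0 = ff["angle_t0"], aka = ff["angle_k"];
  for (int r = 0; r < A.nrow(); ++r) {
    f.a_i.push_back(A(r, 0) - 1); f.a_j.push_back(A(r, 1) - 1);
    f.a_k.push_back(A(r, 2) - 1);
    f.a_t0.push_back(at0[r]); f.a_ka.push_back(aka[r]);
  }
  IntegerMatrix D = ff["dihedrals"];
  NumericVector dp0 = ff["dihedral_p0"], dkd = ff["dihedral_k"];
  for (int r = 0; r < D.nrow(); ++r) {
    f.d_i.push_back(D(r, 0) - 1); f.d_j.push_back(D(r, 1) - 1);
    f.d_k.push_back(D(r, 2) - 1); f.d_l.push_back(D(r, 3) - 1);
    f.d_p0.push_back(dp0[r]); f.d_kd.push_back(dkd[r]);
  }
  IntegerMatrix C = ff["contacts"];
  NumericVector cr0 = ff["contact_r0"], ce = ff["contact_eps"],
                cs = ff["contact_sigma"];
  for (int r = 0; r < C.nrow(); ++r) {
    f.c_i.push_back(C(r, 0) - 1); f.c_j.push_back(C(r, 1) - 1);
    f.c_r0.push_back(cr0[r]); f.c_eps.push_back(ce[r]);
    f.c_sig.push_back(cs[r]);
    f.skip.insert(f.key(C(r, 0) - 1, C(r, 1) - 1));
  }
  f.rex = as<double>(ff["r_ex"]);
  f.ev_cut = as<double>(ff["ev_cutoff"]);
  f.ev_shift = std::pow(f.rex / f.ev_cut, 12.0);
  IntegerVector seg = ff["seg_id"], pos = ff["seq_pos"];
  f.seg.assign(seg.begin(), seg.end());
  f.pos.assign(pos.begin(), pos.end());
  return f;
}

static inline double torsion(const double* x, int i, int j, int k, int l,
                             double b1[3], double b2[3], double b3[3],
                             double m[3], double nn[3]) {
  for (int d = 0; d < 3; ++d) {
    b1[d] = x[3 * j + d] - x[3 * i + d];
    b2[d] = x[3 * k + d] - x[3 * j + d];
    b3[d] = x[3 * l + d] - x[3 * k + d];
  }
  m[0] = b1[1] * b2[2] - b1[2] * b2[1];
  m[1] = b1[2] * b2[0] - b1[0] * b2[2];
  m[2] = b1[0] * b2[1] - b1[1] * b2[0];
  nn[0] = b2[1] * b3[2] - b2[2] * b3[1];
  nn[1] = b2[2] * b3[0] - b2[0] * b3[2];
  nn[2] = b2[0] * b3[1] - b2[1] * b3[0];
  double nb2 = std::sqrt(b2[0] * b2[0] + b2[1] * b2[1] + b2[2] * b2[2]);
  double xnum = 0.0, xden = 0.0;
  double cx[3] = {m[1] * nn[2] - m[2] * nn[1], m[2] * nn[0] - m[0] * nn[2],
                  m[0] * nn[1] - m[1] * nn[0]};
  for (int d = 0; d < 3; ++d) {
    xnum += cx[d] * b2[d];
    xden += m[d] * nn[d];
  }
  return std::atan2(xnum / nb2, xden);
}

// Verlet neighbour list for excluded-volume pairs
struct NbrList {
  std::vector<int> pi, pj;
  std::vector<double> xref;
  double skin;
  void build(const FF& f, const double* x, double list_cut) {
    pi.clear(); pj.clear();
    double c2 = list_cut * list_cut;
    for (int i = 0; i < f.n; ++i)
      for (int j = i + 1; j < f.n; ++j) {
        if (!f.ev_pair(i, j)) continue;
        double d2 = 0.0;
        for (int d = 0; d < 3; ++d) {
          double dd = x[3 * i + d] - x[3 * j + d];
          d2 += dd * dd;
        }
        if (d2 <= c2) { pi.push_back(i); pj.push_back(j); }
      }
    xref.assign(x, x + 3 * f.n);
  }
  bool stale(const FF& f, const double* x) const {
    double lim2 = 0.25 * skin * skin;
    for (int i = 0; i < f.n; ++i) {
      double d2 = 0.0;
      for (int d = 0; d < 3; ++d) {
        double dd = x[3 * i + d] - xref[3 * i + d];
        d2 += dd * dd;
      }
      if (d2 > lim2) return true;
    }
    return false;
  }
};

// energy (by term class) and forces; either output may be skipped
static void eval_ff(const FF& f, const double* x, const NbrList* nl,
                    double* E, double* F) {
  double Eb = 0, Ea = 0, Ed = 0, Ec = 0, Ee = 0;
  if (F) std::fill(F, F + 3 * f.n, 0.0);
  // bonds
  for (size_t t = 0; t < f.b_i.size(); ++t) {
    int i = f.b_i[t], j = f.b_j[t];
    double dx[3], r2 = 0.0;
    for (int d = 0; d < 3; ++d) {
      dx[d] = x[3 * i + d] - x[3 * j + d];
      r2 += dx[d] * dx[d];
    }
    double r = std::sqrt(r2);
    if (r < 1e-10) stop("coincident bonded beads (r = 0)");
    double dr = r - f.b_r0[t];
    Eb += f.b_k[t] * dr * dr;
    if (F) {
      double fmag = -2.0 * f.b_k[t] * dr / r;  // F = -dV/dr * unit
      for (int d = 0; d < 3; ++d) {
        F[3 * i + d] += fmag * dx[d];
        F[3 * j + d] -= fmag * dx[d];
      }
    }
  }
  // angles
  for (size_t t = 0; t < f.a_i.size(); ++t) {
    int i = f.a_i[t], j = f.a_j[t], k = f.a_k[t];
    double u[3], v[3], nu = 0.0, nv = 0.0, dot = 0.0;
    for (int d = 0; d < 3; ++d) {
      u[d] = x[3 * i + d] - x[3 * j + d];
      v[d] = x[3 * k + d] - x[3 * j + d];
      nu += u[d] * u[d]; nv += v[d] * v[d]; dot += u[d] * v[d];
    }
    nu = std::sqrt(nu); nv = std::sqrt(nv);
    double ct = dot / (nu * nv);
    if (ct > 1.0) ct = 1.0;
    if (ct < -1.0) ct = -1.0;
    double th = std::acos(ct);
    double dth = th - f.a_t0[t];
    Ea += f.a_ka[t] * dth * dth;
    if (F) {
      double st = std::sqrt(1.0 - ct * ct);
      if (st < 1e-8) st = 1e-8;
      double coef = 2.0 * f.a_ka[t] * dth / st;  // = dV/dth / sin(th)
      for (int d = 0; d < 3; ++d) {
        double fi = coef * (v[d] / nv - ct * u[d] / nu) / nu;
        double fk = coef * (u[d] / nu - ct * v[d] / nv) / nv;
        F[3 * i + d] += fi;
        F[3 * k + d] += fk;
        F[3 * j + d] -= fi + fk;
      }
    }
  }
  // dihedrals
  for (size_t t = 0; t < f.d_i.size(); ++t) {
    int i = f.d_i[t], j = f.d_j[t], k = f.d_k[t], l = f.d_l[t];
    double b1[3], b2[3], b3[3], m[3], nn[3];
    double ph = torsion(x, i, j, k, l, b1, b2, b3, m, nn);
    double dp = ph - f.d_p0[t];
    Ed += f.d_kd[t] * ((1.0 - std::cos(dp)) + 0.5 * (1.0 - std::cos(3.0 * dp)));
    if (F) {
      double dV = f.d_kd[t] * (std::sin(dp) + 1.5 * std::sin(3.0 * dp));
      double nb2 = std::sqrt(b2[0] * b2[0] + b2[1] * b2[1] + b2[2] * b2[2]);
      double m2 = m[0] * m[0] + m[1] * m[1] + m[2] * m[2];
      double n2 = nn[0] * nn[0] + nn[1] * nn[1] + nn[2] * nn[2];
      if (m2 < 1e-12 || n2 < 1e-12) continue;  // collinear: zero torque
      // dphi/dx_i = -|b2|/|m|^2 m ; dphi/dx_l = |b2|/|n|^2 n ;
      // inner beads via p = b1.b2/|b2|^2, q = b3.b2/|b2|^2
      double Gi[3], Gl[3];
      for (int d = 0; d < 3; ++d) {
        Gi[d] = -nb2 / m2 * m[d];
        Gl[d] = nb2 / n2 * nn[d];
      }
      double p = (b1[0] * b2[0] + b1[1] * b2[1] + b1[2] * b2[2]) / (nb2 * nb2);
      double q = (b3[0] * b2[0] + b3[1] * b2[1] + b3[2] * b2[2]) / (nb2 * nb2);
      for (int d = 0; d < 3; ++d) {
        F[3 * i + d] += -dV * Gi[d];
        F[3 * j + d] += -dV * (-(1.0 + p) * Gi[d] + q * Gl[d]);
        F[3 * k + d] += -dV * (p * Gi[d] - (1.0 + q) * Gl[d]);
        F[3 * l + d] += -dV * Gl[d];
      }
    }
  }
  // contacts (fixed list, no cutoff)
  for (size_t t = 0; t < f.c_i.size(); ++t) {
    int i = f.c_i[t], j = f.c_j[t];
    double dx[3], r2 = 0.0;
    for (int d = 0; d < 3; ++d) {
      dx[d] = x[3 * i + d] - x[3 * j + d];
      r2 += dx[d] * dx[d];
    }
    double r = std::sqrt(r2);
    if (r < 1e-10) stop("coincident contact beads (r = 0)");
    double q2 = f.rex * f.rex / r2, q6 = q2 * q2 * q2;
    double R = q6 * q6;
    double s2 = f.c_sig[t] * f.c_sig[t];
    double dr = r - f.c_r0[t];
    double G = std::exp(-dr * dr / (2.0 * s2));
    Ec += f.c_eps[t] * ((1.0 + R) * (1.0 - G) - 1.0);
    if (F) {
      double dR = -12.0 * R / r;
      double dG = -G * dr / s2;
      double dV = f.c_eps[t] * (dR * (1.0 - G) - (1.0 + R) * dG);
      double fmag = -dV / r;
      for (int d = 0; d < 3; ++d) {
        F[3 * i + d] += fmag * dx[d];
        F[3 * j + d] -= fmag * dx[d];
      }
    }
  }
  // excluded volume over the neighbour list (or all eligible pairs)
  double c2 = f.ev_cut * f.ev_cut;
  size_t np = nl ? nl->pi.size() : 0;
  for (size_t t = 0; t < (nl ? np : (size_t)f.n * f.n); ++t) {
    int i, j;
    if (nl) { i = nl->pi[t]; j = nl->pj[t]; }
    else {
      i = (int)(t / f.n); j = (int)(t % f.n);
      if (j <= i) continue;
      if (!f.ev_pair(i, j)) continue;
    }
    double dx[3], r2 = 0.0;
    for (int d = 0; d < 3; ++d) {
      dx[d] = x[3 * i + d] - x[3 * j + d];
      r2 += dx[d] * dx[d];
    }
    if (r2 > c2) continue;
    double r = std::sqrt(r2);
    if (r < 1e-10) stop("coincident non-bonded beads (r = 0)");
    double q2 = f.rex * f.rex / r2, q6 = q2 * q2 * q2;
    double R = q6 * q6;
    Ee += R - f.ev_shift;
    if (F) {
      double fmag = 12.0 * R / r2;  // -dV/dr / r with dV/dr = -12 R / r
      for (int d = 0; d < 3; ++d) {
        F[3 * i + d] += fmag * dx[d];
        F[3 * j + d] -= fmag * dx[d];
      }
    }
  }
  if (E) {
    E[0] = Eb; E[1] = Ea; E[2] = Ed; E[3] = Ec; E[4] = Ee;
    E[5] = Eb + Ea + Ed + Ec + Ee;
  }
}

// [[Rcpp::export]]
List cpp_sbm_energy(NumericMatrix xyz, List ff) {
  FF f = parse_ff(ff);
  if (xyz.nrow() != f.n) stop("coordinate count does not match forcefield");
  std::vector<double> x(3 * f.n);
  for (int i = 0; i < f.n; ++i)
    for (int d = 0; d < 3; ++d) x[3 * i + d] = xyz(i, d);
  double E[6];
  eval_ff(f, x.data(), nullptr, E, nullptr);
  return List::create(_["bond"] = E[0], _["angle"] = E[1],
                      _["dihedral"] = E[2], _["contact"] = E[3],
                      _["excluded"] = E[4], _["total"] = E[5]);
}

// [[Rcpp::export]]
NumericMatrix cpp_sbm_forces(NumericMatrix xyz, List ff) {
  FF f = parse_ff(ff);
  if (xyz.nrow() != f.n) stop("coordinate count does not match forcefield");
  std::vector<double> x(3 * f.n), F(3 * f.n);
  for (int i = 0; i < f.n; ++i)
    for (int d = 0; d < 3; ++d) x[3 * i + d] = xyz(i, d);
  eval_ff(f, x.data(), nullptr, nullptr, F.data());
  NumericMatrix out(f.n, 3);
  for (int i = 0; i < f.n; ++i)
    for (int d = 0; d < 3; ++d) out(i, d) = F[3 * i + d];
  return out;
}

// Steepest descent with backtracking line search; stops at max|F| < tol.
// [[Rcpp::export]]
List cpp_sbm_minimize(NumericMatrix xyz, List ff, double tol, int max_iter,
                      double step0) {
  FF f = parse_ff(ff);
  if (xyz.nrow() != f.n) stop("coordinate count does not match forcefield");
  std::vector<double> x(3 * f.n), F(3 * f.n), xt(3 * f.n);
  for (int i = 0; i < f.n; ++i)
    for (int d = 0; d < 3; ++d) x[3 * i + d] = xyz(i, d);
  double E[6], Et[6];
  eval_ff(f, x.data(), nullptr, E, F.data());
  std::vector<double> xp(3 * f.n), Fp(3 * f.n);
  int it = 0;
  double fmax = 0.0;
  double alpha = step0;
  bool have_prev = false;
  double best_fmax = std::numeric_limits<double>::infinity();
  int since_improve = 0;
  for (it = 0; it < max_iter; ++it) {
    fmax = 0.0;
    for (int t = 0; t < 3 * f.n; ++t)
      fmax = std::max(fmax, std::abs(F[t]));
    if (fmax < tol) break;
    // floating-point plateau: stop when the residual force stalls
    if (fmax < 0.99 * best_fmax) {
      best_fmax = fmax;
      since_improve = 0;
    } else if (++since_improve > 500) break;
    if (have_prev) {
      // Barzilai-Borwein step length from the last accepted move
      double sy = 0.0, yy = 0.0;
      for (int t = 0; t < 3 * f.n; ++t) {
        double s = x[t] - xp[t];
        double y = Fp[t] - F[t];  // gradient difference (g = -F)
        sy += s * y; yy += y * y;
      }
      if (yy > 0.0 && sy > 0.0) alpha = sy / yy;
    }
    // keep the largest single-bead displacement physically small
    alpha = std::min(std::max(alpha, 1e-8), 0.5 / fmax);
    bool accepted = false;
    for (int bt = 0; bt < 60; ++bt) {
      for (int t = 0; t < 3 * f.n; ++t)
        xt[t] = x[t] + alpha * F[t];
      eval_ff(f, xt.data(), nullptr, Et, nullptr);
      if (std::isfinite(Et[5]) && Et[5] <= E[5]) { accepted = true; break; }
      alpha *= 0.5;
    }
    if (!accepted) break;  // cannot reduce energy further at machine step
    xp = x; Fp = F;
    have_prev = true;
    x = xt;
    eval_ff(f, x.data(), nullptr, E, F.data());
    if (!std::isfinite(E[5])) stop("minimisation diverged (energy NaN)");
  }
  NumericMatrix out(f.n, 3);
  for (int i = 0; i < f.n; ++i)
    for (int d = 0; d < 3; ++d) out(i, d) = x[3 * i + d];
  return List::create(_["coords"] = out, _["energy"] = E[5],
                      _["max_force"] = fmax, _["iterations"] = it,
                      _["converged"] = fmax < tol);
}

// BAOAB Langevin leapfrog in reduced units (mass 1, kB = 1). gamma = 0 and
// T = 0 reduce to velocity Verlet. Deterministic for a given seed.
// [[Rcpp::export]]
List cpp_langevin_run(NumericMatrix xyz, List ff, double dt, double gamma,
                      double temp, double steps_d, int stride, int seed,
                      double list_cutoff, double skin) {
  FF f = parse_ff(ff);
  if (xyz.nrow() != f.n) stop("coordinate count does not match forcefield");
  long long steps = (long long)steps_d;
  std::vector<double> x(3 * f.n), v(3 * f.n, 0.0), F(3 * f.n);
  for (int i = 0; i < f.n; ++i)
    for (int d = 0; d < 3; ++d) x[3 * i + d] = xyz(i, d);
  std::mt19937_64 rng((unsigned long long)seed * 0x9E3779B97F4A7C15ULL + 1ULL);
  std::normal_distribution<double> gauss(0.0, 1.0);
  if (temp > 0.0) {
    double sv = std::sqrt(temp);
    for (int t = 0; t < 3 * f.n; ++t) v[t] = sv * gauss(rng);
  }
  const double c1 = std::exp(-gamma * dt);
  const double c2 = (temp > 0.0 && gamma > 0.0)
                      ? std::sqrt(temp * (1.0 - c1 * c1)) : 0.0;
  NbrList nl;
  nl.skin = skin;
  nl.build(f, x.data(), list_cutoff + skin);
  double E[6];
  eval_ff(f, x.data(), &nl, E, F.data());
  long long nframes = steps / stride + 1;
  NumericMatrix frames(nframes, 3 * f.n);
  NumericVector energies(nframes), e_contact(nframes), e_kin(nframes);
  for (int t = 0; t < 3 * f.n; ++t) frames(0, t) = x[t];
  energies[0] = E[5];
  e_contact[0] = E[3];
  {
    double ke = 0.0;
    for (int t = 0; t < 3 * f.n; ++t) ke += 0.5 * v[t] * v[t];
    e_kin[0] = ke;
  }
  long long rec = 1;
  const double half = 0.5 * dt;
  for (long long s = 1; s <= steps; ++s) {
    for (int t = 0; t < 3 * f.n; ++t) {
      v[t] += half * F[t];
      x[t] += half * v[t];
    }
    if (c2 > 0.0 || c1 != 1.0) {
      for (int t = 0; t < 3 * f.n; ++t)
        v[t] = c1 * v[t] + c2 * gauss(rng);
    }
    for (int t = 0; t < 3 * f.n; ++t) x[t] += half * v[t];
    if (nl.stale(f, x.data())) nl.build(f, x.data(), list_cutoff + skin);
    bool record = (s % stride == 0);
    eval_ff(f, x.data(), &nl, record ? E : nullptr, F.data());
    for (int t = 0; t < 3 * f.n; ++t) v[t] += half * F[t];
    if (record) {
      if (!std::isfinite(E[5]) || std::abs(E[5]) > 1e9)
        stop("energy divergence at step " + std::to_string(s) +
             " (V = " + std::to_string(E[5]) + ")");
      for (int t = 0; t < 3 * f.n; ++t) frames(rec, t) = x[t];
      energies[rec] = E[5];
      e_contact[rec] = E[3];
      double ke = 0.0;
      for (int t = 0; t < 3 * f.n; ++t) ke += 0.5 * v[t] * v[t];
      e_kin[rec] = ke;
      ++rec;
      if (rec % 64 == 0) Rcpp::checkUserInterrupt();
    }
  }
  NumericMatrix xf(f.n, 3), vf(f.n, 3);
  for (int i = 0; i < f.n; ++i)
    for (int d = 0; d < 3; ++d) {
      xf(i, d) = x[3 * i + d];
      vf(i, d) = v[3 * i + d];
    }
  return List::create(_["frames"] = frames, _["energy"] = energies,
                      _["contact_energy"] = e_contact,
                      _["kinetic_energy"] = e_kin,
                      _["final_coords"] = xf, _["final_velocities"] = vf);
}
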