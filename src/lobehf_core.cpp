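// Hot loops of the lobe-function Hartree-Fock engine: density-relevance
// matrix, screened ERI task list, primitive-pair tables, contracted ERI
// evaluation, Fock assembly and the two-electron gradient. Everything is
// in atomic units; all basis functions are contractions of s-type
// Gaussian primitives, so a single integral formula covers all shells.
#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Abramowitz-Stegun 7.1.26 rational approximation of erf with the
// large-argument shortcut erf(x >= 4) = 1 (1 - erf(4) ~ 1.5e-8).
static inline double erf_as(double x) {
  if (x >= 4.0) return 1.0;
  const double c0 = 0.3275911, c1 = 0.254829592, c2 = -0.284496736,
               c3 = 1.421413741, c4 = -1.453152027, c5 = 1.061405429;
  double t = 1.0 / (1.0 + c0 * x);
  double poly = t * (c1 + t * (c2 + t * (c3 + t * (c4 + t * c5))));
  return 1.0 - poly * std::exp(-x * x);
}

// [[Rcpp::export]]
NumericVector cpp_erf_approx(NumericVector x) {
  NumericVector out(x.size());
  for (R_xlen_t i = 0; i < x.size(); ++i) out[i] = erf_as(x[i]);
  return out;
}

// 1F1(1/2, 3/2, -x) = sqrt(pi) erf(sqrt(x)) / (2 sqrt(x)); series at 0.
static inline double f11h(double x) {
  if (x < 1e-8) return 1.0 - x / 3.0 + x * x / 10.0;
  double s = std::sqrt(x);
  return 0.886226925452758014 * std::erf(s) / s;  // sqrt(pi)/2 * erf/sqrt
}
// derivative of f11h
static inline double f11h_d(double x) {
  if (x < 1e-8) return -1.0 / 3.0 + x / 5.0 - x * x / 14.0;
  return (std::exp(-x) - f11h(x)) / (2.0 * x);
}

// [[Rcpp::export]]
NumericVector cpp_f11_half(NumericVector x) {
  NumericVector out(x.size());
  for (R_xlen_t i = 0; i < x.size(); ++i) out[i] = f11h(x[i]);
  return out;
}

// ---- density relevance ----------------------------------------------------
// Integral over the absolute-valued product of two basis functions, using
// the all-positive (per-lobe) Gaussian representations with general
// symmetric quadratic forms M (6 packed components xx,yy,zz,xy,xz,yz).

static inline double det3(const double M[6]) {
  return M[0] * (M[1] * M[2] - M[5] * M[5]) -
         M[3] * (M[3] * M[2] - M[5] * M[4]) +
         M[4] * (M[3] * M[5] - M[1] * M[4]);
}

// solve S y = b for symmetric positive definite S (packed), 3x3 Cramer
static inline void solve3(const double S[6], const double b[3], double y[3]) {
  double det = det3(S);
  double a11 = S[0], a22 = S[1], a33 = S[2], a12 = S[3], a13 = S[4], a23 = S[5];
  double i11 = (a22 * a33 - a23 * a23) / det;
  double i12 = (a13 * a23 - a12 * a33) / det;
  double i13 = (a12 * a23 - a13 * a22) / det;
  double i22 = (a11 * a33 - a13 * a13) / det;
  double i23 = (a13 * a12 - a11 * a23) / det;
  double i33 = (a11 * a22 - a12 * a12) / det;
  y[0] = i11 * b[0] + i12 * b[1] + i13 * b[2];
  y[1] = i12 * b[0] + i22 * b[1] + i23 * b[2];
  y[2] = i13 * b[0] + i23 * b[1] + i33 * b[2];
}

// [[Rcpp::export]]
NumericMatrix cpp_relevance_matrix(int n_bf, NumericVector relA,
                                   NumericMatrix relM, NumericMatrix relC,
                                   IntegerVector rel_ptr) {
  NumericMatrix R(n_bf, n_bf);
  const double pi32 = std::pow(M_PI, 1.5);
  for (int i = 0; i < n_bf; ++i) {
    for (int j = 0; j <= i; ++j) {
      double acc = 0.0;
      for (int a = rel_ptr[i]; a < rel_ptr[i + 1]; ++a) {
        double M1[6], c1[3];
        for (int q = 0; q < 6; ++q) M1[q] = relM(a, q);
        for (int q = 0; q < 3; ++q) c1[q] = relC(a, q);
        for (int b = rel_ptr[j]; b < rel_ptr[j + 1]; ++b) {
          double S[6], d[3], m2d[3], y[3];
          for (int q = 0; q < 6; ++q) S[q] = M1[q] + relM(b, q);
          for (int q = 0; q < 3; ++q) d[q] = c1[q] - relC(b, q);
          // quadratic form d' (M2 - M2 S^-1 M2) d  ==  d' M1 S^-1 M2 d
          double M2[6];
          for (int q = 0; q < 6; ++q) M2[q] = relM(b, q);
          m2d[0] = M2[0] * d[0] + M2[3] * d[1] + M2[4] * d[2];
          m2d[1] = M2[3] * d[0] + M2[1] * d[1] + M2[5] * d[2];
          m2d[2] = M2[4] * d[0] + M2[5] * d[1] + M2[2] * d[2];
          solve3(S, m2d, y);
          double quad = d[0] * m2d[0] + d[1] * m2d[1] + d[2] * m2d[2] -
                        (m2d[0] * y[0] + m2d[1] * y[1] + m2d[2] * y[2]);
          double dt = det3(S);
          acc += relA[a] * relA[b] * pi32 / std::sqrt(dt) * std::exp(-quad);
        }
      }
      R(i, j) = acc;
      R(j, i) = acc;
    }
  }
  return R;
}

// ---- primitive pair table -------------------------------------------------
// For each surviving basis-function pair, precompute for every primitive
// product the pair overlap factor O, the composite center r_ab and the
// exponent sum; O and r_ab are the only per-pair quantities the ERI
// formula needs.

// [[Rcpp::export]]
List cpp_pair_table(IntegerVector pair_i, IntegerVector pair_j,
                    NumericVector coef, NumericVector alpha,
                    NumericMatrix center, IntegerVector fn_ptr,
                    double floor_O) {
  int npair = pair_i.size();
  std::vector<int> ptr(npair + 1, 0);
  std::vector<double> O, rx, ry, rz, ps;
  std::vector<int> pa, pb;
  const double pref = std::sqrt(2.0) * std::pow(M_PI, 1.25);
  for (int q = 0; q < npair; ++q) {
    int i = pair_i[q] - 1, j = pair_j[q] - 1;
    for (int a = fn_ptr[i]; a < fn_ptr[i + 1]; ++a) {
      for (int b = fn_ptr[j]; b < fn_ptr[j + 1]; ++b) {
        double p = alpha[a] + alpha[b];
        double dx = center(a, 0) - center(b, 0);
        double dy = center(a, 1) - center(b, 1);
        double dz = center(a, 2) - center(b, 2);
        double d2 = dx * dx + dy * dy + dz * dz;
        double K = std::exp(-alpha[a] * alpha[b] / p * d2);
        double Ov = pref * coef[a] * coef[b] / (p * std::sqrt(p)) * K;
        if (std::fabs(Ov) < floor_O) continue;
        O.push_back(Ov);
        double ia = alpha[a] / p, ib = alpha[b] / p;
        rx.push_back(ia * center(a, 0) + ib * center(b, 0));
        ry.push_back(ia * center(a, 1) + ib * center(b, 1));
        rz.push_back(ia * center(a, 2) + ib * center(b, 2));
        ps.push_back(p);
        pa.push_back(a);
        pb.push_back(b);
      }
    }
    ptr[q + 1] = O.size();
  }
  return List::create(_["ptr"] = wrap(ptr), _["O"] = wrap(O),
                      _["rx"] = wrap(rx), _["ry"] = wrap(ry),
                      _["rz"] = wrap(rz), _["p"] = wrap(ps),
                      _["pa"] = wrap(pa), _["pb"] = wrap(pb));
}

// ---- task list ------------------------------------------------------------
// Canonical quadruples over the (pre-screened, canonically ordered) pair
// list: pair index a >= b; distance between pair centers below the upper
// Coulomb cut-off; optional combined relevance/distance test; smoothing
// weight from the cubic switching function f(x) = 1 + 2x^3 - 3x^2.

static inline double switch_w(double d, double rcl, double rcu) {
  if (d <= rcl) return 1.0;
  if (d >= rcu) return 0.0;
  double x = (d - rcl) / (rcu - rcl);
  return 1.0 + 2.0 * x * x * x - 3.0 * x * x;
}

// [[Rcpp::export]]
List cpp_build_tasks(NumericMatrix pc, NumericVector rel,
                     double rcl, double rcu, double tau_f, double d_floor) {
  int npair = pc.nrow();
  std::vector<int> t1, t2;
  std::vector<double> w;
  double rcu2 = rcu * rcu;
  for (int a = 0; a < npair; ++a) {
    for (int b = 0; b <= a; ++b) {
      double dx = pc(a, 0) - pc(b, 0);
      double dy = pc(a, 1) - pc(b, 1);
      double dz = pc(a, 2) - pc(b, 2);
      double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 > rcu2) continue;
      double d = std::sqrt(d2);
      if (tau_f > 0.0) {
        double dd = d < d_floor ? d_floor : d;
        if (rel[a] * rel[b] / dd < tau_f) continue;
      }
      t1.push_back(a + 1);
      t2.push_back(b + 1);
      w.push_back(switch_w(d, rcl, rcu));
    }
  }
  return List::create(_["p1"] = wrap(t1), _["p2"] = wrap(t2),
                      _["w"] = wrap(w));
}

// ---- contracted ERI values ------------------------------------------------
// (ij|kl) = sum_mn O_m O_n sqrt(P) 1F1(1/2,3/2,-P d^2), P = p_m p_n/(p_m+p_n).

// [[Rcpp::export]]
NumericVector cpp_eri_values(IntegerVector t1, IntegerVector t2, List pt) {
  IntegerVector ptr = pt["ptr"];
  NumericVector O = pt["O"], rx = pt["rx"], ry = pt["ry"], rz = pt["rz"],
                ps = pt["p"];
  R_xlen_t nt = t1.size();
  NumericVector out(nt);
  for (R_xlen_t q = 0; q < nt; ++q) {
    int a = t1[q] - 1, b = t2[q] - 1;
    double acc = 0.0;
    for (int m = ptr[a]; m < ptr[a + 1]; ++m) {
      double Om = O[m], pm = ps[m];
      double x1 = rx[m], y1 = ry[m], z1 = rz[m];
      for (int n = ptr[b]; n < ptr[b + 1]; ++n) {
        double pn = ps[n];
        double P = pm * pn / (pm + pn);
        double dx = x1 - rx[n], dy = y1 - ry[n], dz = z1 - rz[n];
        double x = P * (dx * dx + dy * dy + dz * dz);
        acc += Om * O[n] * std::sqrt(P) * f11h(x);
      }
    }
    out[q] = acc;
  }
  return out;
}

// ---- Fock (two-electron) matrix -------------------------------------------
// G_ij = sum_kl P_kl [ (ij|kl) - 1/2 (ik|jl) ], assembled from the
// canonical weighted task list with the standard 8-fold permutation
// bookkeeping.

// [[Rcpp::export]]
NumericMatrix cpp_fock(NumericMatrix P, IntegerVector fi, IntegerVector fj,
                       IntegerVector fk, IntegerVector fl, NumericVector v) {
  int n = P.nrow();
  NumericMatrix J(n, n), K(n, n);
  R_xlen_t nt = fi.size();
  for (R_xlen_t q = 0; q < nt; ++q) {
    int i = fi[q] - 1, j = fj[q] - 1, k = fk[q] - 1, l = fl[q] - 1;
    double e = v[q];
    bool dij = (i != j), dkl = (k != l),
         dpq = (i != k || j != l);
    // distinct permutations of the canonical quadruple
    int pp[8][4];
    int np = 0;
    pp[np][0] = i; pp[np][1] = j; pp[np][2] = k; pp[np][3] = l; ++np;
    if (dij) { pp[np][0] = j; pp[np][1] = i; pp[np][2] = k; pp[np][3] = l; ++np; }
    if (dkl) { pp[np][0] = i; pp[np][1] = j; pp[np][2] = l; pp[np][3] = k; ++np; }
    if (dij && dkl) { pp[np][0] = j; pp[np][1] = i; pp[np][2] = l; pp[np][3] = k; ++np; }
    if (dpq) {
      pp[np][0] = k; pp[np][1] = l; pp[np][2] = i; pp[np][3] = j; ++np;
      if (dkl) { pp[np][0] = l; pp[np][1] = k; pp[np][2] = i; pp[np][3] = j; ++np; }
      if (dij) { pp[np][0] = k; pp[np][1] = l; pp[np][2] = j; pp[np][3] = i; ++np; }
      if (dij && dkl) { pp[np][0] = l; pp[np][1] = k; pp[np][2] = j; pp[np][3] = i; ++np; }
    }
    for (int t = 0; t < np; ++t) {
      int a = pp[t][0], b = pp[t][1], c = pp[t][2], d = pp[t][3];
      J(a, b) += P(c, d) * e;
      K(a, c) += P(b, d) * e;
    }
  }
  // no symmetrization here: for a symmetric density G comes out
  // symmetric up to round-off, but the propagation layer also feeds the
  // antisymmetric imaginary part of a Hermitian density, whose exchange
  // term is legitimately antisymmetric
  NumericMatrix G(n, n);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j) G(i, j) = J(i, j) - 0.5 * K(i, j);
  return G;
}

// ---- two-electron gradient ------------------------------------------------
// dE2/dR from the weighted task list: for each canonical quadruple the
// density prefactor Gamma = sum over distinct permutations of
// [1/2 P_pq P_rs - 1/4 P_pr P_qs]; the force contribution is
// Gamma * (w * grad(e) + e * grad(w)). grad(e) differentiates the pair
// overlap factors and the 1F1 kernel; grad(w) differentiates the cubic
// switching function through the pair-midpoint distance.

// [[Rcpp::export]]
NumericMatrix cpp_eri_gradient(NumericMatrix P,
                               IntegerVector t1, IntegerVector t2,
                               IntegerVector fi, IntegerVector fj,
                               IntegerVector fk, IntegerVector fl,
                               NumericVector val, NumericVector wgt,
                               List pt,
                               NumericVector alpha, NumericMatrix center,
                               IntegerVector prim_atom,
                               NumericMatrix pc, IntegerVector pair_a1,
                               IntegerVector pair_a2,
                               double rcl, double rcu, int natom) {
  IntegerVector ptr = pt["ptr"];
  NumericVector O = pt["O"], rx = pt["rx"], ry = pt["ry"], rz = pt["rz"],
                ps = pt["p"];
  IntegerVector pa = pt["pa"], pb = pt["pb"];
  NumericMatrix F(natom, 3);
  R_xlen_t nt = t1.size();
  for (R_xlen_t q = 0; q < nt; ++q) {
    int i = fi[q] - 1, j = fj[q] - 1, k = fk[q] - 1, l = fl[q] - 1;
    // density prefactor over distinct permutations
    bool dij = (i != j), dkl = (k != l), dpq = (i != k || j != l);
    int pp[8][4]; int np = 0;
    pp[np][0] = i; pp[np][1] = j; pp[np][2] = k; pp[np][3] = l; ++np;
    if (dij) { pp[np][0] = j; pp[np][1] = i; pp[np][2] = k; pp[np][3] = l; ++np; }
    if (dkl) { pp[np][0] = i; pp[np][1] = j; pp[np][2] = l; pp[np][3] = k; ++np; }
    if (dij && dkl) { pp[np][0] = j; pp[np][1] = i; pp[np][2] = l; pp[np][3] = k; ++np; }
    if (dpq) {
      pp[np][0] = k; pp[np][1] = l; pp[np][2] = i; pp[np][3] = j; ++np;
      if (dkl) { pp[np][0] = l; pp[np][1] = k; pp[np][2] = i; pp[np][3] = j; ++np; }
      if (dij) { pp[np][0] = k; pp[np][1] = l; pp[np][2] = j; pp[np][3] = i; ++np; }
      if (dij && dkl) { pp[np][0] = l; pp[np][1] = k; pp[np][2] = j; pp[np][3] = i; ++np; }
    }
    double gamma = 0.0;
    for (int t = 0; t < np; ++t) {
      int a = pp[t][0], b = pp[t][1], c = pp[t][2], d = pp[t][3];
      gamma += 0.5 * P(a, b) * P(c, d) - 0.25 * P(a, c) * P(b, d);
    }
    if (gamma == 0.0) continue;
    int A = t1[q] - 1, B = t2[q] - 1;
    double w = wgt[q];
    // grad(e) part
    if (w != 0.0) {
      double gw = gamma * w;
      for (int m = ptr[A]; m < ptr[A + 1]; ++m) {
        double Om = O[m], pm = ps[m];
        int am = pa[m], bm = pb[m];
        double mu_m = alpha[am] * alpha[bm] / pm;
        double dmx = center(am, 0) - center(bm, 0);
        double dmy = center(am, 1) - center(bm, 1);
        double dmz = center(am, 2) - center(bm, 2);
        for (int n = ptr[B]; n < ptr[B + 1]; ++n) {
          double pn = ps[n];
          int an = pa[n], bn = pb[n];
          double Pmn = pm * pn / (pm + pn);
          double ddx = rx[m] - rx[n], ddy = ry[m] - ry[n], ddz = rz[m] - rz[n];
          double x = Pmn * (ddx * ddx + ddy * ddy + ddz * ddz);
          double Fv = f11h(x), Fd = f11h_d(x);
          double sq = std::sqrt(Pmn);
          double e_mn = Om * O[n] * sq * Fv;
          // dO_m: dO/dr_a = -2 mu (r_a - r_b) O
          double cO = gw * O[n] * sq * Fv;  // d e / d O_m
          double gx = -2.0 * mu_m * dmx * Om * cO;
          double gy = -2.0 * mu_m * dmy * Om * cO;
          double gz = -2.0 * mu_m * dmz * Om * cO;
          F(prim_atom[am], 0) += gx; F(prim_atom[am], 1) += gy; F(prim_atom[am], 2) += gz;
          F(prim_atom[bm], 0) -= gx; F(prim_atom[bm], 1) -= gy; F(prim_atom[bm], 2) -= gz;
          // dO_n
          double mu_n = alpha[an] * alpha[bn] / pn;
          double dnx = center(an, 0) - center(bn, 0);
          double dny = center(an, 1) - center(bn, 1);
          double dnz = center(an, 2) - center(bn, 2);
          double cOn = gw * Om * sq * Fv;
          gx = -2.0 * mu_n * dnx * O[n] * cOn;
          gy = -2.0 * mu_n * dny * O[n] * cOn;
          gz = -2.0 * mu_n * dnz * O[n] * cOn;
          F(prim_atom[an], 0) += gx; F(prim_atom[an], 1) += gy; F(prim_atom[an], 2) += gz;
          F(prim_atom[bn], 0) -= gx; F(prim_atom[bn], 1) -= gy; F(prim_atom[bn], 2) -= gz;
          // kernel part through d^2: de/dr_ab = O O sqrt(P) F' * P * 2(r_ab-r_cd)
          double cK = gw * Om * O[n] * sq * Fd * Pmn * 2.0;
          double kx = cK * ddx, ky = cK * ddy, kz = cK * ddz;
          double fa = alpha[am] / pm, fb = alpha[bm] / pm;
          F(prim_atom[am], 0) += kx * fa; F(prim_atom[am], 1) += ky * fa; F(prim_atom[am], 2) += kz * fa;
          F(prim_atom[bm], 0) += kx * fb; F(prim_atom[bm], 1) += ky * fb; F(prim_atom[bm], 2) += kz * fb;
          double fc = alpha[an] / pn, fd = alpha[bn] / pn;
          F(prim_atom[an], 0) -= kx * fc; F(prim_atom[an], 1) -= ky * fc; F(prim_atom[an], 2) -= kz * fc;
          F(prim_atom[bn], 0) -= kx * fd; F(prim_atom[bn], 1) -= ky * fd; F(prim_atom[bn], 2) -= kz * fd;
          (void)e_mn;
        }
      }
    }
    // grad(w) part
    double dx = pc(A, 0) - pc(B, 0), dy = pc(A, 1) - pc(B, 1),
           dz = pc(A, 2) - pc(B, 2);
    double d = std::sqrt(dx * dx + dy * dy + dz * dz);
    if (d > rcl && d < rcu) {
      double xw = (d - rcl) / (rcu - rcl);
      double dwdd = (6.0 * xw * xw - 6.0 * xw) / (rcu - rcl);
      double c = gamma * val[q] * dwdd / d;
      double gx = c * dx * 0.5, gy = c * dy * 0.5, gz = c * dz * 0.5;
      int a1 = pair_a1[A] - 1, a2 = pair_a2[A] - 1;
      int b1 = pair_a1[B] - 1, b2 = pair_a2[B] - 1;
      F(a1, 0) += gx; F(a1, 1) += gy; F(a1, 2) += gz;
      F(a2, 0) += gx; F(a2, 1) += gy; F(a2, 2) += gz;
      F(b1, 0) -= gx; F(b1, 1) -= gy; F(b1, 2) -= gz;
      F(b2, 0) -= gx; F(b2, 1) -= gy; F(b2, 2) -= gz;
    }
  }
  return F;
}
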