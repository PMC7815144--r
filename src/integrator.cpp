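// Core numerical engine: per-cell glycolysis ODEs integrated with an
// adaptive Dormand-Prince 5(4) scheme. Accepted steps whose metabolite
// concentrations fall barely below zero (within the tolerance band
// -(atol_c + |c| rtol_c) < c < 0) are projected to zero; steps leaving any
// larger negative concentration are rejected and retried with a smaller
// step size.

#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

struct Kin {
  double KM_glc, KM_atp, Ki_atp, a_tot, KM_fbp, KM_adp, KM_p;
  double Pivmax, Kvac, m;
};

struct Phys {
  double ug, ud, vatp_m;
};

struct Tol {
  double atol_c, rtol_c, atol_v, rtol_v, atol_h, rtol_h;
};

static Kin kinFromList(const List& k) {
  Kin K;
  K.KM_glc = as<double>(k["KM_glc"]);
  K.KM_atp = as<double>(k["KM_atp"]);
  K.Ki_atp = as<double>(k["Ki_atp"]);
  K.a_tot  = as<double>(k["a_tot"]);
  K.KM_fbp = as<double>(k["KM_fbp"]);
  K.KM_adp = as<double>(k["KM_adp"]);
  K.KM_p   = as<double>(k["KM_p"]);
  K.Pivmax = as<double>(k["Pi_vac_max"]);
  K.Kvac   = as<double>(k["K_vac"]);
  K.m      = as<double>(k["m"]);
  return K;
}

static Phys physFromList(const List& p) {
  Phys ph;
  ph.ug = as<double>(p["u_g"]);
  ph.ud = as<double>(p["u_d"]);
  ph.vatp_m = as<double>(p["vatp_m"]);
  return ph;
}

static Tol tolFromList(const List& t) {
  Tol tl;
  tl.atol_c = as<double>(t["atol_c"]);
  tl.rtol_c = as<double>(t["rtol_c"]);
  tl.atol_v = as<double>(t["atol_v"]);
  tl.rtol_v = as<double>(t["rtol_v"]);
  tl.atol_h = as<double>(t["atol_h"]);
  tl.rtol_h = as<double>(t["rtol_h"]);
  return tl;
}

// Right-hand side for one cell. y = {FBP, ATP, Pi, V, H}; gp = genotype
// {vmax_up, vmax_lo, k_atp, k_p}. Transient slightly-negative inputs are
// clamped to zero before kinetic evaluation (the integrator-level projection
// is the authoritative non-negativity mechanism).
static inline void cellDeriv(const double* y, double glc, const double* gp,
                             double vatpe, double Hmax, const Kin& K,
                             const Phys& ph, double* dy, double* vupOut) {
  double F = y[0] > 0.0 ? y[0] : 0.0;
  double A = y[1] > 0.0 ? y[1] : 0.0;
  if (A > K.a_tot) A = K.a_tot;
  double P = y[2] > 0.0 ? y[2] : 0.0;
  double G = glc > 0.0 ? glc : 0.0;
  double V = y[3];
  double H = y[4];

  double ADP = K.a_tot - A;
  double vup = gp[0] * G * A /
    ((K.KM_glc + G) * (K.KM_atp + A * (1.0 + A / K.Ki_atp)));
  double vlo = gp[1] * F * ADP * P /
    ((K.KM_fbp + F) * (K.KM_adp + ADP) * (K.KM_p + P));
  double vatp = gp[2] * A;
  double Ptot = P + 2.0 * F + A;
  double r = Ptot / K.Kvac;
  double rm;
  if (K.m == 4.0) { double r2 = r * r; rm = r2 * r2; }
  else rm = std::pow(r, K.m);
  double pivac = K.Pivmax / (1.0 + rm);
  double vp = gp[3] * (pivac - P);

  double vatpg = vatp - (vatpe + ph.vatp_m);
  bool atmax = H >= Hmax - 1e-12;
  double g = (atmax && vatpg > 0.0) ? ph.ug * vatpg : 0.0;

  dy[0] = vup - vlo - F * g;
  dy[1] = -2.0 * vup + 4.0 * vlo - vatp - A * g;
  dy[2] = -2.0 * vlo + vatp + vp - P * g;
  dy[3] = g * V;
  dy[4] = (vatpg <= 0.0) ? -ph.ud * vatpg
                         : (atmax ? 0.0 : ph.ug * vatpg);
  if (vupOut) *vupOut = vup;
}

// Dormand-Prince 5(4) coefficients.
static const double C2 = 1.0 / 5, C3 = 3.0 / 10, C4 = 4.0 / 5, C5 = 8.0 / 9;
static const double A21 = 1.0 / 5;
static const double A31 = 3.0 / 40, A32 = 9.0 / 40;
static const double A41 = 44.0 / 45, A42 = -56.0 / 15, A43 = 32.0 / 9;
static const double A51 = 19372.0 / 6561, A52 = -25360.0 / 2187,
                    A53 = 64448.0 / 6561, A54 = -212.0 / 729;
static const double A61 = 9017.0 / 3168, A62 = -355.0 / 33,
                    A63 = 46732.0 / 5247, A64 = 49.0 / 176,
                    A65 = -5103.0 / 18656;
static const double B1 = 35.0 / 384, B3 = 500.0 / 1113, B4 = 125.0 / 192,
                    B5 = -2187.0 / 6784, B6 = 11.0 / 84;
static const double E1 = 71.0 / 57600, E3 = -71.0 / 16695, E4 = 71.0 / 1920,
                    E5 = -17253.0 / 339200, E6 = 22.0 / 525, E7 = -1.0 / 40;

// Reusable integrator workspace (avoids per-call allocations on the
// per-cell hot path).
struct DPWork {
  std::vector<double> k1, k2, k3, k4, k5, k6, k7, yt, y1;
  void resize(int n) {
    k1.resize(n); k2.resize(n); k3.resize(n); k4.resize(n); k5.resize(n);
    k6.resize(n); k7.resize(n); yt.resize(n); y1.resize(n);
  }
};

// Generic DP45 driver. Deriv is called as deriv(t, y, dy). projIdx lists the
// components subject to the non-negativity projection (metabolite-like).
// atol/rtol are per-component. Returns false on step-size underflow.
template <class Deriv>
static bool dp45(Deriv deriv, std::vector<double>& y, double t0, double t1,
                 const std::vector<double>& atol,
                 const std::vector<double>& rtol,
                 const std::vector<int>& projIdx, double& h, DPWork& w) {
  const int n = (int)y.size();
  w.resize(n);
  std::vector<double>&k1 = w.k1, &k2 = w.k2, &k3 = w.k3, &k4 = w.k4,
                     &k5 = w.k5, &k6 = w.k6, &k7 = w.k7, &yt = w.yt,
                     &y1 = w.y1;
  double t = t0;
  const double hmin = 1e-10;
  if (h <= 0.0 || h > t1 - t0) h = t1 - t0;
  bool haveK1 = false;
  long guard = 0;

  while (t < t1 - 1e-12) {
    if (++guard > 5000000L) return false;
    if (h > t1 - t) h = t1 - t;
    if (h < hmin) return false;

    if (!haveK1) deriv(t, y.data(), k1.data());
    for (int i = 0; i < n; ++i) yt[i] = y[i] + h * A21 * k1[i];
    deriv(t + C2 * h, yt.data(), k2.data());
    for (int i = 0; i < n; ++i)
      yt[i] = y[i] + h * (A31 * k1[i] + A32 * k2[i]);
    deriv(t + C3 * h, yt.data(), k3.data());
    for (int i = 0; i < n; ++i)
      yt[i] = y[i] + h * (A41 * k1[i] + A42 * k2[i] + A43 * k3[i]);
    deriv(t + C4 * h, yt.data(), k4.data());
    for (int i = 0; i < n; ++i)
      yt[i] = y[i] + h * (A51 * k1[i] + A52 * k2[i] + A53 * k3[i] +
                          A54 * k4[i]);
    deriv(t + C5 * h, yt.data(), k5.data());
    for (int i = 0; i < n; ++i)
      yt[i] = y[i] + h * (A61 * k1[i] + A62 * k2[i] + A63 * k3[i] +
                          A64 * k4[i] + A65 * k5[i]);
    deriv(t + h, yt.data(), k6.data());
    for (int i = 0; i < n; ++i)
      y1[i] = y[i] + h * (B1 * k1[i] + B3 * k3[i] + B4 * k4[i] +
                          B5 * k5[i] + B6 * k6[i]);
    deriv(t + h, y1.data(), k7.data());

    // Embedded error estimate.
    double errsq = 0.0;
    for (int i = 0; i < n; ++i) {
      double e = h * (E1 * k1[i] + E3 * k3[i] + E4 * k4[i] + E5 * k5[i] +
                      E6 * k6[i] + E7 * k7[i]);
      double ay = std::fabs(y[i]), ay1 = std::fabs(y1[i]);
      double sc = atol[i] + rtol[i] * (ay > ay1 ? ay : ay1);
      double q = e / sc;
      errsq += q * q;
    }
    double err = std::sqrt(errsq / n);

    if (err > 1.0) {
      double fac = 0.9 * std::pow(err, -0.2);
      if (fac < 0.1) fac = 0.1;
      h *= fac;
      continue;
    }

    // Non-negativity projection on metabolite-like components.
    bool rejectNeg = false;
    for (size_t j = 0; j < projIdx.size(); ++j) {
      int i = projIdx[j];
      if (y1[i] < 0.0) {
        double band = atol[i] + std::fabs(y1[i]) * rtol[i];
        if (y1[i] > -band) y1[i] = 0.0; else { rejectNeg = true; break; }
      }
    }
    if (rejectNeg) {
      h *= 0.5;
      haveK1 = false;
      continue;
    }

    t += h;
    y.swap(y1);
    k1.swap(k7);  // FSAL
    haveK1 = true;
    double fac = 0.9 * std::pow(err > 1e-10 ? err : 1e-10, -0.2);
    if (fac > 5.0) fac = 5.0;
    if (fac < 0.2) fac = 0.2;
    h *= fac;
  }
  return true;
}

// Imposed glucose (no competition): within a supply segment starting at ts
// with inflow concentration g0 and chamber glucose gi at ts, the chamber
// concentration follows the closed form g0 + (gi - g0) exp(-D (t - ts)).
struct GlcSegs {
  const double* ts;
  const double* g0;
  const double* gi;
  int n;
  double D;
  double at(double t) const {
    int j = n - 1;
    while (j > 0 && ts[j] > t + 1e-12) --j;
    if (D <= 0.0) return gi[j];
    double x = D * (t - ts[j]);
    if (x > 40.0) return g0[j];
    return g0[j] + (gi[j] - g0[j]) * std::exp(-x);
  }
};

// [[Rcpp::export]]
List cppIntegrateNCG(NumericMatrix st, NumericMatrix gen, NumericVector vatpe,
                     NumericVector hmax, List kinL, List physL, List tolL,
                     double t0, NumericVector breaks, LogicalVector isSample,
                     LogicalVector isSeg, NumericVector segT,
                     NumericVector segG0, NumericVector segGi, double Denv,
                     IntegerVector trackedIdx) {
  const Kin K = kinFromList(kinL);
  const Phys ph = physFromList(physL);
  const Tol tl = tolFromList(tolL);
  const int N = st.nrow();
  const int nb = breaks.size();
  const double t1 = breaks[nb - 1];

  GlcSegs gs;
  gs.ts = segT.begin(); gs.g0 = segG0.begin(); gs.gi = segGi.begin();
  gs.n = segT.size(); gs.D = Denv;

  std::vector<double> atol = {tl.atol_c, tl.atol_c, tl.atol_c, tl.atol_v,
                              tl.atol_h};
  std::vector<double> rtol = {tl.rtol_c, tl.rtol_c, tl.rtol_c, tl.rtol_v,
                              tl.rtol_h};
  std::vector<int> projIdx = {0, 1, 2};

  int nSamp = 0;
  for (int b = 0; b < nb; ++b) if (isSample[b]) ++nSamp;
  const int nTr = trackedIdx.size();
  NumericVector samples(nTr > 0 ? (R_xlen_t)nTr * nSamp * 6 : 0);
  std::vector<int> trackPos(N, -1);
  for (int j = 0; j < nTr; ++j) trackPos[trackedIdx[j]] = j;

  NumericMatrix out(clone(st));
  bool ok = true;
  int badCell = -1;
  double badT = NA_REAL;
  DPWork work;
  std::vector<double> y(5);

  for (int i = 0; i < N && ok; ++i) {
    y.resize(5);
    for (int c = 0; c < 5; ++c) y[c] = out(i, c);
    const double gp[4] = {gen(i, 0), gen(i, 1), gen(i, 2), gen(i, 3)};
    const double ve = vatpe[i], Hm = hmax[i];
    const int tp = trackPos[i];
    auto deriv = [&](double t, const double* yy, double* dy) {
      cellDeriv(yy, gs.at(t), gp, ve, Hm, K, ph, dy, nullptr);
    };
    double h = 0.0;
    double tcur = t0;
    for (int b = 0; b < nb; ++b) {
      bool need = isSeg[b] || b == nb - 1 || (tp >= 0 && isSample[b]);
      if (!need) continue;
      if (breaks[b] > tcur + 1e-12) {
        if (!dp45(deriv, y, tcur, breaks[b], atol, rtol, projIdx, h, work)) {
          ok = false; badCell = i; badT = tcur;
          break;
        }
        tcur = breaks[b];
        if (y[4] > Hm) y[4] = Hm;
      }
      if (tp >= 0 && isSample[b]) {
        int s = 0;
        for (int bb = 0; bb <= b; ++bb) if (isSample[bb]) ++s;
        --s;
        R_xlen_t base = (R_xlen_t)tp + (R_xlen_t)s * nTr;
        for (int c = 0; c < 5; ++c)
          samples[base + (R_xlen_t)c * nTr * nSamp] = y[c];
        samples[base + (R_xlen_t)5 * nTr * nSamp] = gs.at(breaks[b]);
      }
    }
    if (ok) {
      if (y[4] > Hm) y[4] = Hm;
      for (int c = 0; c < 5; ++c) out(i, c) = y[c];
    }
  }

  if (nTr > 0) samples.attr("dim") = IntegerVector::create(nTr, nSamp, 6);
  return List::create(_["ok"] = ok, _["states"] = out,
                      _["samples"] = samples,
                      _["glcEnd"] = gs.at(t1),
                      _["badCell"] = badCell + 1, _["badT"] = badT);
}

// [[Rcpp::export]]
List cppIntegrateChemostat(NumericMatrix st, NumericMatrix gen,
                           NumericVector vatpe, NumericVector hmax, List kinL,
                           List physL, List tolL, double glc, double Vch,
                           double D, double t0, NumericVector breaks,
                           LogicalVector isSample, NumericVector swT,
                           NumericVector swG0, IntegerVector trackedIdx) {
  const Kin K = kinFromList(kinL);
  const Phys ph = physFromList(physL);
  const Tol tl = tolFromList(tolL);
  const int N = st.nrow();
  const int nb = breaks.size();
  const int n = 1 + 5 * N;
  const int nsw = swT.size();
  const double* swt = swT.begin();
  const double* swg = swG0.begin();

  std::vector<double> y(n);
  y[0] = glc;
  for (int i = 0; i < N; ++i)
    for (int c = 0; c < 5; ++c) y[1 + 5 * i + c] = st(i, c);

  std::vector<double> atol(n), rtol(n);
  std::vector<int> projIdx;
  atol[0] = tl.atol_c; rtol[0] = tl.rtol_c;
  projIdx.push_back(0);
  for (int i = 0; i < N; ++i) {
    int b = 1 + 5 * i;
    atol[b] = atol[b + 1] = atol[b + 2] = tl.atol_c;
    rtol[b] = rtol[b + 1] = rtol[b + 2] = tl.rtol_c;
    atol[b + 3] = tl.atol_v; rtol[b + 3] = tl.rtol_v;
    atol[b + 4] = tl.atol_h; rtol[b + 4] = tl.rtol_h;
    projIdx.push_back(b); projIdx.push_back(b + 1); projIdx.push_back(b + 2);
  }

  auto glc0At = [&](double t) {
    int j = nsw - 1;
    while (j > 0 && swt[j] > t + 1e-12) --j;
    return swg[j];
  };

  auto deriv = [&](double t, const double* yy, double* dy) {
    double uptake = 0.0, vup;
    for (int i = 0; i < N; ++i) {
      const double gp[4] = {gen(i, 0), gen(i, 1), gen(i, 2), gen(i, 3)};
      cellDeriv(yy + 1 + 5 * i, yy[0], gp, vatpe[i], hmax[i], K, ph,
                dy + 1 + 5 * i, &vup);
      uptake += vup * yy[1 + 5 * i + 3];
    }
    dy[0] = -uptake / Vch + D * (glc0At(t) - yy[0]);
  };

  int nSamp = 0;
  for (int b = 0; b < nb; ++b) if (isSample[b]) ++nSamp;
  const int nTr = trackedIdx.size();
  NumericVector samples(nTr > 0 ? (R_xlen_t)nTr * nSamp * 6 : 0);

  double h = 0.0;
  double tcur = t0;
  bool ok = true;
  double badT = NA_REAL;
  int sCount = 0;
  DPWork work;
  for (int b = 0; b < nb && ok; ++b) {
    if (breaks[b] > tcur + 1e-12) {
      if (!dp45(deriv, y, tcur, breaks[b], atol, rtol, projIdx, h, work)) {
        ok = false; badT = tcur;
        break;
      }
      tcur = breaks[b];
      for (int i = 0; i < N; ++i) {
        double& H = y[1 + 5 * i + 4];
        if (H > hmax[i]) H = hmax[i];
      }
    }
    if (isSample[b]) {
      for (int j = 0; j < nTr; ++j) {
        int i = trackedIdx[j];
        R_xlen_t base = (R_xlen_t)j + (R_xlen_t)sCount * nTr;
        for (int c = 0; c < 5; ++c)
          samples[base + (R_xlen_t)c * nTr * nSamp] = y[1 + 5 * i + c];
        samples[base + (R_xlen_t)5 * nTr * nSamp] = y[0];
      }
      ++sCount;
    }
  }

  NumericMatrix out(N, 5);
  for (int i = 0; i < N; ++i)
    for (int c = 0; c < 5; ++c) out(i, c) = y[1 + 5 * i + c];
  if (nTr > 0) samples.attr("dim") = IntegerVector::create(nTr, nSamp, 6);
  return List::create(_["ok"] = ok, _["states"] = out,
                      _["samples"] = samples, _["glcEnd"] = y[0],
                      _["badCell"] = NA_INTEGER, _["badT"] = badT);
}
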