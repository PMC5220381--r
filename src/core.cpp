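#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

// Reduced three-variable TC relay cell. Two interchangeable function sets:
// closed-form sigmoids (the original model) or piecewise-linear tables (the
// cost-efficient variant). Both are driven through the same derivative code.

namespace {

struct Plf {
  // columns: v_lo, v_hi, K, C ; rows are contiguous segments
  std::vector<double> lo, hi, K, C;
  int n = 0;
  double eval(double x) const {
    // clamp outside the stated domain to the boundary segment
    if (x <= lo[0]) return K[0] * std::max(x, lo[0]) + C[0];
    if (x >= hi[n - 1]) return K[n - 1] * std::min(x, hi[n - 1]) + C[n - 1];
    // ties at a breakpoint resolve to the right-hand segment
    for (int i = n - 1; i >= 0; --i) {
      if (x >= lo[i]) return K[i] * x + C[i];
    }
    return K[0] * x + C[0]; // unreachable
  }
};

struct TcModel {
  // membrane constants
  double cm, g_l, e_l, g_na, e_na, g_k, e_k, g_t, e_t;
  bool plf_mode = false;
  // closed-form gating parameters
  double th_m, sg_m, pw_na, th_p, sg_p, pw_t, c_k, pw_k;
  double th_h, sg_h, th_w, sg_w;
  double ah_a, ah_th, ah_sg, bh_a, bh_th, bh_sg;
  double tw_sc, tw_b, tw_th, tw_sg;
  // piecewise-linear tables f1..f8 (f3 is a function of h, rest of V)
  Plf f[8];

  double f1(double v) const {
    if (plf_mode) return f[0].eval(v);
    return std::pow(1.0 / (1.0 + std::exp(-(v - th_m) / sg_m)), pw_na);
  }
  double f2(double v) const {
    if (plf_mode) return f[1].eval(v);
    return std::pow(1.0 / (1.0 + std::exp(-(v - th_p) / sg_p)), pw_t);
  }
  double f3(double h) const {
    if (plf_mode) return f[2].eval(h);
    return std::pow(c_k * (1.0 - h), pw_k);
  }
  double f4(double v) const { // h_inf
    if (plf_mode) return f[3].eval(v);
    return 1.0 / (1.0 + std::exp((v - th_h) / sg_h));
  }
  double f5(double v) const { // a_h
    if (plf_mode) return f[4].eval(v);
    return ah_a * std::exp(-(v - ah_th) / ah_sg);
  }
  double f6(double v) const { // b_h
    if (plf_mode) return f[5].eval(v);
    return bh_a / (1.0 + std::exp(-(v - bh_th) / bh_sg));
  }
  double f7(double v) const { // w_inf
    if (plf_mode) return f[6].eval(v);
    return 1.0 / (1.0 + std::exp((v - th_w) / sg_w));
  }
  double f8(double v) const { // 1 / tau_w
    if (plf_mode) return f[7].eval(v);
    return 1.0 / (tw_sc * (tw_b + std::exp(-(v - tw_th) / tw_sg)));
  }

  void deriv(double v, double h, double w, double iapp,
             double &dv, double &dh, double &dw) const {
    const double i_l = g_l * (v - e_l);
    const double i_na = g_na * f1(v) * h * (v - e_na);
    const double i_k = g_k * f3(h) * (v - e_k);
    const double i_t = g_t * f2(v) * w * (v - e_t);
    dv = (-i_l - i_na - i_k - i_t + iapp) / cm;
    dh = f5(v) * (1.0 - h) - f6(v) * h;
    dw = (f7(v) - w) * f8(v);
  }

  void euler(double &v, double &h, double &w, double iapp, double dt) const {
    double dv, dh, dw;
    deriv(v, h, w, iapp, dv, dh, dw);
    v += dt * dv;
    h += dt * dh;
    w += dt * dw;
    if (h < 0.0) h = 0.0; else if (h > 1.0) h = 1.0;
    if (w < 0.0) w = 0.0; else if (w > 1.0) w = 1.0;
  }
};

TcModel unpack_model(const List &model) {
  TcModel m;
  NumericVector p = model["membrane"];
  m.cm = p[0]; m.g_l = p[1]; m.e_l = p[2]; m.g_na = p[3]; m.e_na = p[4];
  m.g_k = p[5]; m.e_k = p[6]; m.g_t = p[7]; m.e_t = p[8];
  int kind = as<int>(model["kind"]);
  if (kind == 0) {
    NumericVector g = model["gating"];
    m.th_m = g[0]; m.sg_m = g[1]; m.pw_na = g[2];
    m.th_p = g[3]; m.sg_p = g[4]; m.pw_t = g[5];
    m.c_k = g[6]; m.pw_k = g[7];
    m.th_h = g[8]; m.sg_h = g[9]; m.th_w = g[10]; m.sg_w = g[11];
    m.ah_a = g[12]; m.ah_th = g[13]; m.ah_sg = g[14];
    m.bh_a = g[15]; m.bh_th = g[16]; m.bh_sg = g[17];
    m.tw_sc = g[18]; m.tw_b = g[19]; m.tw_th = g[20]; m.tw_sg = g[21];
  } else {
    m.plf_mode = true;
    List tabs = model["plf"];
    for (int i = 0; i < 8; ++i) {
      NumericMatrix t = tabs[i];
      int n = t.nrow();
      m.f[i].n = n;
      m.f[i].lo.resize(n); m.f[i].hi.resize(n);
      m.f[i].K.resize(n); m.f[i].C.resize(n);
      for (int r = 0; r < n; ++r) {
        m.f[i].lo[r] = t(r, 0); m.f[i].hi[r] = t(r, 1);
        m.f[i].K[r] = t(r, 2); m.f[i].C[r] = t(r, 3);
      }
    }
  }
  return m;
}

// Lower Cholesky of a 4x4 symmetric matrix with escalating diagonal jitter.
// Returns true on success; jitter_used reports the final jitter level.
bool chol4(const double P[16], double L[16], double &jitter_used) {
  const double jit_max = 1e-4;
  double jit = 0.0;
  for (;;) {
    bool ok = true;
    for (int i = 0; i < 16; ++i) L[i] = 0.0;
    for (int j = 0; j < 4 && ok; ++j) {
      double d = P[j * 4 + j] + jit;
      for (int k = 0; k < j; ++k) d -= L[j * 4 + k] * L[j * 4 + k];
      if (d <= 0.0 || !std::isfinite(d)) { ok = false; break; }
      const double ljj = std::sqrt(d);
      L[j * 4 + j] = ljj;
      for (int i = j + 1; i < 4; ++i) {
        double s = P[i * 4 + j];
        for (int k = 0; k < j; ++k) s -= L[i * 4 + k] * L[j * 4 + k];
        L[i * 4 + j] = s / ljj;
      }
    }
    if (ok) { jitter_used = jit; return true; }
    if (jit == 0.0) jit = 1e-10;
    else if (jit >= jit_max) return false;
    else jit *= 10.0;
  }
}

} // namespace

// [[Rcpp::export(name = ".cpp_simulate")]]
NumericMatrix cpp_simulate(List model, NumericVector i_app, NumericVector state0,
                           double dt) {
  TcModel m = unpack_model(model);
  const int nstep = i_app.size() - 1; // i_app sampled at every output instant
  NumericMatrix out(nstep + 1, 3);
  double v = state0[0], h = state0[1], w = state0[2];
  out(0, 0) = v; out(0, 1) = h; out(0, 2) = w;
  for (int k = 0; k < nstep; ++k) {
    m.euler(v, h, w, i_app[k], dt);
    if (!std::isfinite(v) || !std::isfinite(h) || !std::isfinite(w)) {
      stop("integration diverged at step %d (t = %.3f ms): non-finite %s",
           k + 1, (k + 1) * dt,
           !std::isfinite(v) ? "V" : (!std::isfinite(h) ? "h" : "w"));
    }
    out(k + 1, 0) = v; out(k + 1, 1) = h; out(k + 1, 2) = w;
  }
  return out;
}

// [[Rcpp::export(name = ".cpp_derivatives")]]
NumericVector cpp_derivatives(List model, NumericVector state, double i_app) {
  TcModel m = unpack_model(model);
  double dv, dh, dw;
  m.deriv(state[0], state[1], state[2], i_app, dv, dh, dw);
  return NumericVector::create(dv, dh, dw);
}

// [[Rcpp::export(name = ".cpp_gating_eval")]]
NumericVector cpp_gating_eval(List model, int which, NumericVector x) {
  TcModel m = unpack_model(model);
  const int n = x.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    switch (which) {
      case 1: out[i] = m.f1(x[i]); break;
      case 2: out[i] = m.f2(x[i]); break;
      case 3: out[i] = m.f3(x[i]); break;
      case 4: out[i] = m.f4(x[i]); break;
      case 5: out[i] = m.f5(x[i]); break;
      case 6: out[i] = m.f6(x[i]); break;
      case 7: out[i] = m.f7(x[i]); break;
      case 8: out[i] = m.f8(x[i]); break;
      default: stop("which must be 1..8");
    }
  }
  return out;
}

// Joint state/parameter unscented Kalman filter over x = [I_ext, V, h, w].
// 2N symmetric sigma set (N = 4, no central point, weights 1/(2N)); I_ext is a
// random walk, (V, h, w) advance one Euler step with the point's own I_ext.
// Observation row C = [0 1 0 0]; scalar observation variance R.
// [[Rcpp::export(name = ".cpp_ukf")]]
List cpp_ukf(List model, NumericVector obs, double dt, NumericMatrix Q,
             double R, NumericMatrix P0, NumericVector x0,
             bool clamp_gates = true) {
  TcModel m = unpack_model(model);
  const int T = obs.size();
  const int N = 4, NS = 8;
  const double wgt = 1.0 / NS;
  const double sqN = 2.0; // sqrt(N)

  double x[4] = {x0[0], x0[1], x0[2], x0[3]};
  double P[16], L[16], Qm[16];
  for (int i = 0; i < 4; ++i)
    for (int j = 0; j < 4; ++j) {
      P[i * 4 + j] = P0(i, j);
      Qm[i * 4 + j] = Q(i, j);
    }

  NumericMatrix mean_out(T, 4), covd_out(T, 4), gain_out(T, 4);
  NumericVector innov_out(T);
  double sig[NS][4];

  for (int t = 0; t < T; ++t) {
    double jit;
    if (!chol4(P, L, jit)) {
      stop("covariance not factorizable at step %d: filter diverged", t + 1);
    }
    // sigma points: mean +/- sqrt(N) * columns of L
    for (int j = 0; j < N; ++j) {
      for (int i = 0; i < N; ++i) {
        const double off = sqN * L[i * 4 + j];
        sig[j][i] = x[i] + off;
        sig[j + N][i] = x[i] - off;
      }
    }
    // propagate: column of sigma holds [I_ext, V, h, w]
    for (int s = 0; s < NS; ++s) {
      double v = sig[s][1], h = sig[s][2], w = sig[s][3];
      if (clamp_gates) {
        if (h < 0.0) h = 0.0; else if (h > 1.0) h = 1.0;
        if (w < 0.0) w = 0.0; else if (w > 1.0) w = 1.0;
      }
      m.euler(v, h, w, sig[s][0], dt);
      if (!std::isfinite(v)) { // clamp a runaway point, keep the ensemble alive
        v = x[1];
      }
      sig[s][1] = v; sig[s][2] = h; sig[s][3] = w;
    }
    // a priori mean and covariance (+Q); the observation row C = [0 1 0 0]
    // is linear, so the predicted-observation moments come straight from
    // the a priori covariance (second column), Q included
    double xb[4] = {0, 0, 0, 0};
    for (int s = 0; s < NS; ++s)
      for (int i = 0; i < 4; ++i) xb[i] += wgt * sig[s][i];
    double Pb[16];
    for (int i = 0; i < 16; ++i) Pb[i] = Qm[i];
    for (int s = 0; s < NS; ++s) {
      double d[4];
      for (int i = 0; i < 4; ++i) d[i] = sig[s][i] - xb[i];
      for (int i = 0; i < 4; ++i)
        for (int j = 0; j < 4; ++j) Pb[i * 4 + j] += wgt * d[i] * d[j];
    }
    const double yb = xb[1];
    double Pxy[4];
    for (int i = 0; i < 4; ++i) Pxy[i] = Pb[i * 4 + 1];
    const double Pyy = Pb[5];
    // update
    const double S = Pyy + R;
    const double inn = obs[t] - yb;
    double K[4];
    for (int i = 0; i < 4; ++i) K[i] = Pxy[i] / S;
    for (int i = 0; i < 4; ++i) x[i] = xb[i] + K[i] * inn;
    for (int i = 0; i < 4; ++i)
      for (int j = 0; j < 4; ++j) Pb[i * 4 + j] -= K[i] * Pxy[j];
    // re-symmetrize
    for (int i = 0; i < 4; ++i)
      for (int j = i + 1; j < 4; ++j) {
        const double a = 0.5 * (Pb[i * 4 + j] + Pb[j * 4 + i]);
        Pb[i * 4 + j] = a; Pb[j * 4 + i] = a;
      }
    for (int i = 0; i < 16; ++i) P[i] = Pb[i];
    if (clamp_gates) {
      if (x[2] < 0.0) x[2] = 0.0; else if (x[2] > 1.0) x[2] = 1.0;
      if (x[3] < 0.0) x[3] = 0.0; else if (x[3] > 1.0) x[3] = 1.0;
    }
    for (int i = 0; i < 4; ++i) {
      mean_out(t, i) = x[i];
      covd_out(t, i) = P[i * 4 + i];
      gain_out(t, i) = K[i];
    }
    innov_out[t] = inn;
  }

  NumericMatrix Pfin(4, 4);
  for (int i = 0; i < 4; ++i)
    for (int j = 0; j < 4; ++j) Pfin(i, j) = P[i * 4 + j];
  return List::create(_["mean"] = mean_out, _["cov_diag"] = covd_out,
                      _["gain"] = gain_out, _["innovation"] = innov_out,
                      _["P_final"] = Pfin);
}
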