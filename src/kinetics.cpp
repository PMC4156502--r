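// Closed-form evaluation of the first-order decay convolution models and
// derivative-free least-squares fitting (Nelder-Mead with box clamping).
//
// All integrals are exact per segment for a piecewise-linear rate profile
// f(t); increments use only non-positive exponents so large k*t never
// overflows.

#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>

using namespace Rcpp;

static const double PEN_WEIGHT = 1e4;  // quadratic penalty outside the box

// integral over one segment: int_0^dt (f0 + s*u) * exp(k*(u - dt)) du
static inline double seg_conv(double f0, double s, double dt, double k) {
  double em = std::expm1(-k * dt);  // exp(-k dt) - 1, accurate for small k dt
  return f0 * (-em) / k + s * (dt / k + em / (k * k));
}

// cumulative I_j = int_0^{t_j} f_lin(t') exp(k (t' - t_j)) dt' on ascending t
static void conv_cum(const std::vector<double>& t, const std::vector<double>& f,
                     double k, std::vector<double>& I) {
  size_t n = t.size();
  I.assign(n, 0.0);
  for (size_t j = 0; j + 1 < n; ++j) {
    double dt = t[j + 1] - t[j];
    double s = (f[j + 1] - f[j]) / dt;
    I[j + 1] = I[j] * std::exp(-k * dt) + seg_conv(f[j], s, dt, k);
  }
}

static double lin_interp(const std::vector<double>& t,
                         const std::vector<double>& f, double x) {
  if (x <= t.front()) return f.front();
  if (x >= t.back()) return f.back();
  size_t hi = std::upper_bound(t.begin(), t.end(), x) - t.begin();
  size_t lo = hi - 1;
  double w = (x - t[lo]) / (t[hi] - t[lo]);
  return f[lo] + w * (f[hi] - f[lo]);
}

// sorted union of grid and one interior point ts; returns index of ts
static size_t merge_ts(const std::vector<double>& t,
                       const std::vector<double>& f, double ts,
                       std::vector<double>& tm, std::vector<double>& fm) {
  tm.clear();
  fm.clear();
  bool inserted = false;
  size_t pos = 0;
  for (size_t j = 0; j < t.size(); ++j) {
    if (!inserted && ts < t[j]) {
      tm.push_back(ts);
      fm.push_back(lin_interp(t, f, ts));
      pos = tm.size() - 1;
      inserted = true;
    }
    if (!inserted && ts == t[j]) {
      pos = tm.size();
      inserted = true;
    }
    tm.push_back(t[j]);
    fm.push_back(f[j]);
  }
  if (!inserted) pos = tm.size() - 1;  // ts beyond span (prevented by bounds)
  return pos;
}

static void fwd_constant(double A, double B, double C, double k,
                         const std::vector<double>& t,
                         const std::vector<double>& f,
                         std::vector<double>& yhat) {
  std::vector<double> I;
  conv_cum(t, f, k, I);
  yhat.resize(t.size());
  for (size_t j = 0; j < t.size(); ++j)
    yhat[j] = A * I[j] + B + C * std::exp(-k * t[j]);
}

static void fwd_switch(double A, double B, double C, double k1, double k2,
                       double ts, const std::vector<double>& t,
                       const std::vector<double>& f,
                       std::vector<double>& yhat) {
  std::vector<double> tm, fm;
  size_t pos = merge_ts(t, f, ts, tm, fm);
  std::vector<double> I1, I2;
  conv_cum(tm, fm, k1, I1);
  conv_cum(tm, fm, k2, I2);
  double y1s = A * I1[pos] + B + C * std::exp(-k1 * ts);
  // continuity constant G, kept in the overflow-safe form G*exp(-k2*t) =
  // base2 * exp(-k2*(t - ts))
  double base2 = y1s - A * I2[pos] - B * k1 / k2;
  yhat.resize(t.size());
  size_t m = 0;
  for (size_t j = 0; j < t.size(); ++j) {
    while (tm[m] != t[j]) ++m;
    if (t[j] <= ts)
      yhat[j] = A * I1[m] + B + C * std::exp(-k1 * t[j]);
    else
      yhat[j] = A * I2[m] + B * k1 / k2 + base2 * std::exp(-k2 * (t[j] - ts));
    ++m;
  }
}

// [[Rcpp::export]]
NumericVector conv_decay_cpp(NumericVector grid, NumericVector f, double k,
                             NumericVector tq) {
  std::vector<double> t0(grid.begin(), grid.end());
  std::vector<double> f0(f.begin(), f.end());
  std::vector<double> allt(t0);
  for (double q : tq) allt.push_back(q);
  std::sort(allt.begin(), allt.end());
  allt.erase(std::unique(allt.begin(), allt.end()), allt.end());
  std::vector<double> fall(allt.size());
  for (size_t i = 0; i < allt.size(); ++i) fall[i] = lin_interp(t0, f0, allt[i]);
  std::vector<double> I;
  conv_cum(allt, fall, k, I);
  NumericVector out(tq.size());
  for (int i = 0; i < tq.size(); ++i) {
    size_t idx = std::lower_bound(allt.begin(), allt.end(), tq[i]) - allt.begin();
    out[i] = I[idx];
  }
  return out;
}

// [[Rcpp::export]]
NumericVector forward_constant_cpp(NumericVector grid, NumericVector f,
                                   double A, double B, double C, double k) {
  std::vector<double> t(grid.begin(), grid.end());
  std::vector<double> fv(f.begin(), f.end());
  std::vector<double> yhat;
  fwd_constant(A, B, C, k, t, fv, yhat);
  return NumericVector(yhat.begin(), yhat.end());
}

// [[Rcpp::export]]
NumericVector forward_switch_cpp(NumericVector grid, NumericVector f, double A,
                                 double B, double C, double k1, double k2,
                                 double ts) {
  std::vector<double> t(grid.begin(), grid.end());
  std::vector<double> fv(f.begin(), f.end());
  std::vector<double> yhat;
  fwd_switch(A, B, C, k1, k2, ts, t, fv, yhat);
  return NumericVector(yhat.begin(), yhat.end());
}

// ------------------------------------------------------------------ fitting

struct FitCtx {
  std::vector<double> t, f, y;
  bool a_zero;
  bool is_switch;
  double k_min, k_max, ts_lo, ts_hi;
  std::vector<double> yhat;
};

static inline double clampv(double x, double lo, double hi, double& pen) {
  if (x < lo) {
    pen += (lo - x) * (lo - x);
    return lo;
  }
  if (x > hi) {
    pen += (x - hi) * (x - hi);
    return hi;
  }
  return x;
}

static double objective(const std::vector<double>& th, FitCtx* c,
                        bool penalize) {
  double pen = 0.0;
  size_t i = 0;
  double A = c->a_zero ? 0.0 : clampv(th[i++], 0.0, 1e12, pen);
  double B = th[i++];
  double C = th[i++];
  double k1 = clampv(th[i++], c->k_min, c->k_max, pen);
  if (c->is_switch) {
    double k2 = clampv(th[i++], c->k_min, c->k_max, pen);
    double ts = clampv(th[i++], c->ts_lo, c->ts_hi, pen);
    fwd_switch(A, B, C, k1, k2, ts, c->t, c->f, c->yhat);
  } else {
    fwd_constant(A, B, C, k1, c->t, c->f, c->yhat);
  }
  double sse = 0.0;
  for (size_t j = 0; j < c->y.size(); ++j) {
    double r = c->y[j] - c->yhat[j];
    sse += r * r;
  }
  if (!std::isfinite(sse)) return 1e30;
  return penalize ? sse + PEN_WEIGHT * pen : sse;
}

static void clamp_final(std::vector<double>& th, FitCtx* c) {
  double dummy = 0.0;
  size_t i = 0;
  if (!c->a_zero) {
    th[i] = clampv(th[i], 0.0, 1e12, dummy);
    ++i;
  }
  i += 2;  // B, C unbounded
  th[i] = clampv(th[i], c->k_min, c->k_max, dummy);
  ++i;
  if (c->is_switch) {
    th[i] = clampv(th[i], c->k_min, c->k_max, dummy);
    ++i;
    th[i] = clampv(th[i], c->ts_lo, c->ts_hi, dummy);
  }
}

struct NMResult {
  std::vector<double> par;
  double value;
  int feval;
  bool converged;
};

static NMResult nelder_mead(FitCtx* ctx, const std::vector<double>& x0,
                            const std::vector<double>& step, int maxit,
                            double tol) {
  int n = (int)x0.size();
  int nv = n + 1;
  std::vector<std::vector<double>> S(nv, x0);
  std::vector<double> fv(nv);
  for (int i = 0; i < n; ++i) S[i + 1][i] += step[i];
  int feval = 0;
  for (int i = 0; i < nv; ++i) {
    fv[i] = objective(S[i], ctx, true);
    ++feval;
  }
  bool conv = false;
  while (feval < maxit) {
    std::vector<int> ord(nv);
    for (int i = 0; i < nv; ++i) ord[i] = i;
    std::sort(ord.begin(), ord.end(),
              [&](int a, int b) { return fv[a] < fv[b]; });
    int lo = ord[0], hi = ord[nv - 1], nh = ord[nv - 2];
    if (std::fabs(fv[hi] - fv[lo]) <= tol * (std::fabs(fv[lo]) + tol)) {
      conv = true;
      break;
    }
    std::vector<double> cen(n, 0.0);
    for (int i = 0; i < nv; ++i)
      if (i != hi)
        for (int d = 0; d < n; ++d) cen[d] += S[i][d];
    for (int d = 0; d < n; ++d) cen[d] /= n;
    auto mix = [&](double coef) {
      std::vector<double> x(n);
      for (int d = 0; d < n; ++d) x[d] = cen[d] + coef * (cen[d] - S[hi][d]);
      return x;
    };
    std::vector<double> xr = mix(1.0);
    double fr = objective(xr, ctx, true);
    ++feval;
    if (fr < fv[lo]) {
      std::vector<double> xe = mix(2.0);
      double fe = objective(xe, ctx, true);
      ++feval;
      if (fe < fr) {
        S[hi] = xe;
        fv[hi] = fe;
      } else {
        S[hi] = xr;
        fv[hi] = fr;
      }
    } else if (fr < fv[nh]) {
      S[hi] = xr;
      fv[hi] = fr;
    } else {
      bool outside = fr < fv[hi];
      std::vector<double> xc = mix(outside ? 0.5 : -0.5);
      double fc = objective(xc, ctx, true);
      ++feval;
      if (fc < std::min(fr, fv[hi])) {
        S[hi] = xc;
        fv[hi] = fc;
      } else {
        for (int i = 0; i < nv; ++i) {
          if (i == lo) continue;
          for (int d = 0; d < n; ++d)
            S[i][d] = S[lo][d] + 0.5 * (S[i][d] - S[lo][d]);
          fv[i] = objective(S[i], ctx, true);
          ++feval;
        }
      }
    }
  }
  int best = 0;
  for (int i = 1; i < nv; ++i)
    if (fv[i] < fv[best]) best = i;
  NMResult r;
  r.par = S[best];
  r.value = fv[best];
  r.feval = feval;
  r.converged = conv;
  return r;
}

// two-pass local minimization: full run from x0, then a restart with a
// contracted simplex from the found optimum (still within maxit evals total)
static NMResult minimize(FitCtx* ctx, const std::vector<double>& x0,
                         const std::vector<double>& step, int maxit,
                         double tol) {
  NMResult r1 = nelder_mead(ctx, x0, step, maxit, tol);
  std::vector<double> step2(step);
  for (double& s : step2) s *= 0.1;
  int left = maxit - r1.feval;
  if (left < (int)(2 * x0.size() + 2)) left = (int)(2 * x0.size() + 2);
  NMResult r2 = nelder_mead(ctx, r1.par, step2, left, tol);
  NMResult best = (r2.value <= r1.value) ? r2 : r1;
  best.feval = r1.feval + r2.feval;
  best.converged = r1.converged || r2.converged;
  return best;
}

// [[Rcpp::export]]
List fit_constant_cpp(NumericVector grid, NumericVector f, NumericVector y,
                      bool a_zero, NumericVector init, double k_min,
                      double k_max, int maxit, double tol) {
  FitCtx c;
  c.t.assign(grid.begin(), grid.end());
  c.f.assign(f.begin(), f.end());
  c.y.assign(y.begin(), y.end());
  c.a_zero = a_zero;
  c.is_switch = false;
  c.k_min = k_min;
  c.k_max = k_max;
  c.ts_lo = 0;
  c.ts_hi = 0;
  std::vector<double> x0, step;
  if (a_zero) {
    x0 = {init[1], init[2], init[3]};
    step = {0.25, 0.25, 0.01};
  } else {
    x0 = {init[0], init[1], init[2], init[3]};
    step = {0.25, 0.25, 0.25, 0.01};
  }
  NMResult r = minimize(&c, x0, step, maxit, tol);
  clamp_final(r.par, &c);
  double sse = objective(r.par, &c, false);
  NumericVector par(4);
  par.names() = CharacterVector::create("A", "B", "C", "k");
  if (a_zero) {
    par[0] = 0.0;
    par[1] = r.par[0];
    par[2] = r.par[1];
    par[3] = r.par[2];
  } else {
    par[0] = r.par[0];
    par[1] = r.par[1];
    par[2] = r.par[2];
    par[3] = r.par[3];
  }
  return List::create(_["par"] = par, _["sse"] = sse, _["feval"] = r.feval,
                      _["converged"] = r.converged);
}

// [[Rcpp::export]]
List fit_switch_cpp(NumericVector grid, NumericVector f, NumericVector y,
                    bool a_zero, NumericVector init, NumericVector ts_inits,
                    double k_min, double k_max, double ts_lo, double ts_hi,
                    int maxit, double tol) {
  FitCtx c;
  c.t.assign(grid.begin(), grid.end());
  c.f.assign(f.begin(), f.end());
  c.y.assign(y.begin(), y.end());
  c.a_zero = a_zero;
  c.is_switch = true;
  c.k_min = k_min;
  c.k_max = k_max;
  c.ts_lo = ts_lo;
  c.ts_hi = ts_hi;
  bool have = false;
  NMResult best;
  int total_feval = 0;
  double best_ts_init = NA_REAL;
  for (int i = 0; i < ts_inits.size(); ++i) {
    std::vector<double> x0, step;
    if (a_zero) {
      x0 = {init[1], init[2], init[3], init[4], ts_inits[i]};
      step = {0.25, 0.25, 0.01, 0.01, 2.5};
    } else {
      x0 = {init[0], init[1], init[2], init[3], init[4], ts_inits[i]};
      step = {0.25, 0.25, 0.25, 0.01, 0.01, 2.5};
    }
    NMResult r = minimize(&c, x0, step, maxit, tol);
    total_feval += r.feval;
    clamp_final(r.par, &c);
    r.value = objective(r.par, &c, false);
    if (!have || r.value < best.value) {
      best = r;
      have = true;
      best_ts_init = ts_inits[i];
    }
  }
  NumericVector par(6);
  par.names() =
      CharacterVector::create("A", "B", "C", "k1", "k2", "t_switch");
  size_t off = 0;
  if (a_zero) {
    par[0] = 0.0;
  } else {
    par[0] = best.par[0];
    off = 1;
  }
  par[1] = best.par[off + 0];
  par[2] = best.par[off + 1];
  par[3] = best.par[off + 2];
  par[4] = best.par[off + 3];
  par[5] = best.par[off + 4];
  return List::create(_["par"] = par, _["sse"] = best.value,
                      _["feval"] = total_feval,
                      _["converged"] = best.converged,
                      _["ts_init"] = best_ts_init);
}
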