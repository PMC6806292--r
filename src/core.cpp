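#include <Rcpp.h>
using namespace Rcpp;

// Parameter vector layout shared with R/parameters.R (.par_vec):
// 0 SG, 1 SI, 2 Gb, 3 V, 4 Vi, 5 W, 6 tmaxI, 7 tmaxG, 8 ke, 9 p2, 10 Ag
// State layout: 0 G, 1 X, 2 S1, 3 S2, 4 I, 5 Ra1, 6 Ra
// Units: G mg/dL; X 1/min; S1,S2 mU; I uU/mL; Ra1,Ra mg/min;
// uCHO mg/min; uINS mU/min.  I carries the mU/mL -> uU/mL factor:
static const double MU_PER_MILLIU = 1000.0;

static inline void deriv(const double *x, const double *p,
                         double ucho, double uins,
                         double tmaxg, double tmaxi, double *dx) {
  const double SG = p[0], SI = p[1], Gb = p[2], V = p[3], Vi = p[4],
               W = p[5], ke = p[8], p2 = p[9], Ag = p[10];
  dx[0] = -(SG + x[1]) * x[0] + SG * Gb + x[6] / (V * W);
  dx[1] = -p2 * x[1] + p2 * SI * x[4];
  dx[2] = uins - x[2] / tmaxi;
  dx[3] = (x[2] - x[3]) / tmaxi;
  dx[4] = -ke * x[4] + MU_PER_MILLIU * x[3] / (Vi * W * tmaxi);
  dx[5] = -(x[5] - Ag * ucho) / tmaxg;
  dx[6] = -(x[6] - x[5]) / tmaxg;
}

static inline void euler(double *x, const double *p,
                         double ucho, double uins,
                         double tmaxg, double tmaxi, double dt) {
  double dx[7];
  deriv(x, p, ucho, uins, tmaxg, tmaxi, dx);
  for (int j = 0; j < 7; ++j) {
    x[j] += dt * dx[j];
    if (x[j] < 0.0) x[j] = 0.0;  // discretisation guard (ke stiff at dt = 1)
  }
}

// Forward-Euler trajectory at step dt over nstep = length(ucho) steps.
// tmaxg/tmaxi are per-step effective values (meal-class adjustment,
// intra-day insulin-absorption variation).
// [[Rcpp::export(name = ".sim_core")]]
NumericMatrix sim_core(NumericVector x0, NumericVector par,
                       NumericVector ucho, NumericVector uins,
                       NumericVector tmaxg, NumericVector tmaxi,
                       double dt) {
  const int n = ucho.size();
  if (uins.size() != n || tmaxg.size() != n || tmaxi.size() != n)
    stop("input vectors must have equal length");
  if (x0.size() != 7) stop("state must have length 7");
  if (dt <= 0) stop("dt must be positive");
  NumericMatrix out(n + 1, 7);
  double x[7];
  for (int j = 0; j < 7; ++j) { x[j] = x0[j]; out(0, j) = x[j]; }
  const double *p = REAL(par);
  for (int k = 0; k < n; ++k) {
    euler(x, p, ucho[k], uins[k], tmaxg[k], tmaxi[k], dt);
    for (int j = 0; j < 7; ++j) out(k + 1, j) = x[j];
  }
  return out;
}

// OLS slope of y against t for k points (k = 2 -> two-point difference).
static inline double ols_slope(const double *t, const double *y, int k) {
  if (k < 2) return 0.0;
  double tm = 0, ym = 0;
  for (int i = 0; i < k; ++i) { tm += t[i]; ym += y[i]; }
  tm /= k; ym /= k;
  double num = 0, den = 0;
  for (int i = 0; i < k; ++i) {
    num += (t[i] - tm) * (y[i] - ym);
    den += (t[i] - tm) * (t[i] - tm);
  }
  return num / den;
}

// Batch per-sample forecast cycle: advance model M minutes, deconvolve the
// CGM history, fuse gut states and glucose, propagate the fused state over
// the prediction horizon.  Mirrors the R-level step_cycle() exactly; tested
// for agreement with it.
// times: sample times in whole minutes (0-based against the input arrays);
// ucho/uins/tmaxg/tmaxi: per-minute input arrays covering
// [times[0], times[N-1] + ph).
// [[Rcpp::export(name = ".forecaster_core")]]
List forecaster_core(IntegerVector times, NumericVector glucose,
                     NumericVector par,
                     NumericVector ucho, NumericVector uins,
                     NumericVector tmaxg, NumericVector tmaxi,
                     double q1, double q2, int ph,
                     bool announce, int nfilter, int warmup) {
  const int N = times.size();
  if (glucose.size() != N) stop("times and glucose must have equal length");
  const int horizon = ucho.size();
  if (N > 0 && times[N - 1] + ph > horizon)
    stop("input arrays shorter than last sample time + prediction horizon");
  const double *p = REAL(par);
  const double tmaxg_nom = p[7];

  NumericVector rhat(N), rtilde_raw(N), rtilde(N), ra1t(N);
  NumericVector forecast(N, NA_REAL);
  NumericMatrix fused(N, 7);
  double x[7] = {glucose[0], 0, 0, 0, 0, 0, 0};

  for (int i = 0; i < N; ++i) {
    // (1) advance the model to the current sample time
    if (i > 0) {
      for (int k = times[i - 1]; k < times[i]; ++k)
        euler(x, p, ucho[k], uins[k], tmaxg[k], tmaxi[k], 1.0);
    }
    // (2) deconvolution of the CGM history
    double tt[3], yy[3];
    int k0 = i >= 2 ? i - 2 : 0, npt = i - k0 + 1;
    for (int j = 0; j < npt; ++j) {
      tt[j] = times[k0 + j];
      yy[j] = glucose[k0 + j];
    }
    double slope = ols_slope(tt, yy, npt);
    if (slope > 1.0) slope = 1.0;
    if (slope < -1.0) slope = -1.0;
    rhat[i] = (slope + (p[0] + x[1]) * glucose[i] - p[0] * p[2]) * p[3] * p[5];
    double acc = rhat[i];
    for (int j = i - nfilter + 1; j < i; ++j) acc += j >= 0 ? rtilde_raw[j] : 0.0;
    rtilde_raw[i] = acc / nfilter;
    for (int j = 0; j < npt; ++j) yy[j] = rtilde_raw[k0 + j];
    double fslope = ols_slope(tt, yy, npt);
    rtilde[i] = rtilde_raw[i] > 0.0 ? rtilde_raw[i] : 0.0;
    double r1 = fslope * tmaxg_nom + rtilde_raw[i];
    ra1t[i] = r1 > 0.0 ? r1 : 0.0;
    // (3) fusion (gut states and glucose only)
    x[0] = q2 * glucose[i] + (1.0 - q2) * x[0];
    x[6] = q1 * rtilde[i] + (1.0 - q1) * x[6];
    x[5] = q1 * ra1t[i] + (1.0 - q1) * x[5];
    for (int j = 0; j < 7; ++j) fused(i, j) = x[j];
    // (4) open-loop propagation over the horizon
    if (i >= warmup - 1) {
      double xf[7];
      for (int j = 0; j < 7; ++j) xf[j] = x[j];
      for (int k = times[i]; k < times[i] + ph; ++k)
        euler(xf, p, announce ? ucho[k] : 0.0, uins[k],
              tmaxg[k], tmaxi[k], 1.0);
      forecast[i] = xf[0];
    }
  }
  return List::create(_["forecast"] = forecast, _["rhat"] = rhat,
                      _["rtilde_raw"] = rtilde_raw, _["rtilde"] = rtilde,
                      _["ra1"] = ra1t, _["fused"] = fused);
}
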