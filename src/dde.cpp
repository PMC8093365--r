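// Fourth-order method-of-steps integrator for the two-population
// delayed Wilson-Cowan system
//
//   tau u_A' = -u_A + G(a u_B - b s_B(t - D) + i_A(t))
//   tau u_B' = -u_B + G(a u_A - b s_A(t - D) + i_B(t))
//       s_A' = G(u_A) (1 - s_A)/tau - s_A/tau_i
//       s_B' = G(u_B) (1 - s_B)/tau - s_B/tau_i
//
// G is either the Heaviside step at theta or the logistic sigmoid centred
// at theta.  The step h divides the period 2TR exactly (so successive
// periods are grid-aligned); delayed synaptic values are read from the
// stored dense solution by 4-point cubic Lagrange interpolation, which is
// O(h^4) and therefore consistent with the RK4 truncation order.  h <= D/4
// guarantees every interpolation stencil lies in the already-computed past.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

namespace {

struct Pars {
  double a, b, c, d, tau, taui, D, theta, TD, TR, slope;
  int gain;   // 0 = heaviside, 1 = sigmoid
  int input;  // 0 = square, 1 = smooth
};

inline double gainf(const Pars &p, double x) {
  if (p.gain == 0) return x >= p.theta ? 1.0 : 0.0;
  return 1.0 / (1.0 + std::exp(-p.slope * (x - p.theta)));
}

inline double sig0(const Pars &p, double x) {
  return 1.0 / (1.0 + std::exp(-p.slope * x));
}

inline void inputs(const Pars &p, double t, double &iA, double &iB) {
  if (p.input == 0) {
    double per = 2.0 * p.TR;
    double tm = t - per * std::floor(t / per);
    if (per - tm < 1e-12) tm = 0.0;  // guard the floating-point wrap
    bool onA = tm <= p.TD;
    bool onB = tm >= p.TR && tm <= p.TR + p.TD;
    iA = (onA ? p.c : 0.0) + (onB ? p.d : 0.0);
    iB = (onA ? p.d : 0.0) + (onB ? p.c : 0.0);
  } else {
    double w = std::sin(M_PI * t / p.TR);
    double wd = std::sin(M_PI * (p.TD - t) / p.TR);
    double pA = sig0(p, w) * sig0(p, wd);
    double pB = sig0(p, -w) * sig0(p, -wd);
    iA = p.c * pA + p.d * pB;
    iB = p.d * pA + p.c * pB;
  }
}

// cubic Lagrange interpolation of row `row` of the storage at fractional
// column position pos (columns are times -nh0*h, ..., 0, h, ...)
inline double interp(const NumericMatrix &buf, int row, double pos,
                     int maxcol) {
  if (pos <= 0.0) return buf(row, 0);
  int j = (int)std::floor(pos);
  double f = pos - j;
  if (f < 1e-12) return buf(row, j);
  int j0 = j - 1;
  if (j0 < 0) j0 = 0;
  if (j0 + 3 > maxcol) j0 = maxcol - 3;
  double x = pos - j0;  // in [0,3]
  double y0 = buf(row, j0), y1 = buf(row, j0 + 1), y2 = buf(row, j0 + 2),
         y3 = buf(row, j0 + 3);
  double l0 = -(x - 1) * (x - 2) * (x - 3) / 6.0;
  double l1 = x * (x - 2) * (x - 3) / 2.0;
  double l2 = -x * (x - 1) * (x - 3) / 2.0;
  double l3 = x * (x - 1) * (x - 2) / 6.0;
  return l0 * y0 + l1 * y1 + l2 * y2 + l3 * y3;
}

inline void rhs(const Pars &p, double t, const double y[4], double sAd,
                double sBd, double out[4]) {
  double iA, iB;
  inputs(p, t, iA, iB);
  out[0] = (-y[0] + gainf(p, p.a * y[1] - p.b * sBd + iA)) / p.tau;
  out[1] = (-y[1] + gainf(p, p.a * y[0] - p.b * sAd + iB)) / p.tau;
  out[2] = gainf(p, y[0]) * (1.0 - y[2]) / p.tau - y[2] / p.taui;
  out[3] = gainf(p, y[1]) * (1.0 - y[3]) / p.tau - y[3] / p.taui;
}

}  // namespace

// [[Rcpp::export]]
NumericMatrix dde_rk4_cpp(NumericVector par, int gain, int input,
                          NumericMatrix hist, double h, int nsteps) {
  Pars p;
  p.a = par["a"]; p.b = par["b"]; p.c = par["c"]; p.d = par["d"];
  p.tau = par["tau"]; p.taui = par["tau_i"]; p.D = par["D"];
  p.theta = par["theta"]; p.TD = par["TD"]; p.TR = par["TR"];
  p.slope = par["slope"];
  p.gain = gain; p.input = input;
  if (hist.nrow() != 4) stop("history must have 4 rows");
  if (p.D < 4.0 * h) stop("step too large: need h <= D/4");

  int nh = hist.ncol();          // columns at t = -(nh-1)h, ..., 0
  int ncol = nh + nsteps;
  NumericMatrix buf(4, ncol);
  for (int j = 0; j < nh; ++j)
    for (int r = 0; r < 4; ++r) buf(r, j) = hist(r, j);

  int i0 = nh - 1;               // column of t = 0
  double Dh = p.D / h;
  double y[4], yt[4], k1[4], k2[4], k3[4], k4[4];
  for (int r = 0; r < 4; ++r) y[r] = buf(r, i0);

  for (int i = 0; i < nsteps; ++i) {
    double t = i * h;
    int cur = i0 + i;            // last filled column
    double sAd, sBd;

    sAd = interp(buf, 2, cur - Dh, cur);
    sBd = interp(buf, 3, cur - Dh, cur);
    rhs(p, t, y, sAd, sBd, k1);

    sAd = interp(buf, 2, cur + 0.5 - Dh, cur);
    sBd = interp(buf, 3, cur + 0.5 - Dh, cur);
    for (int r = 0; r < 4; ++r) yt[r] = y[r] + 0.5 * h * k1[r];
    rhs(p, t + 0.5 * h, yt, sAd, sBd, k2);

    for (int r = 0; r < 4; ++r) yt[r] = y[r] + 0.5 * h * k2[r];
    rhs(p, t + 0.5 * h, yt, sAd, sBd, k3);

    sAd = interp(buf, 2, cur + 1.0 - Dh, cur);
    sBd = interp(buf, 3, cur + 1.0 - Dh, cur);
    for (int r = 0; r < 4; ++r) yt[r] = y[r] + h * k3[r];
    rhs(p, t + h, yt, sAd, sBd, k4);

    for (int r = 0; r < 4; ++r) {
      y[r] += h / 6.0 * (k1[r] + 2.0 * k2[r] + 2.0 * k3[r] + k4[r]);
      buf(r, cur + 1) = y[r];
    }
    if (!std::isfinite(y[0]) || !std::isfinite(y[2]))
      stop("solution blew up (NaN/Inf) at t = %g", t + h);
  }

  // return t >= 0 only
  NumericMatrix out(4, nsteps + 1);
  for (int j = 0; j <= nsteps; ++j)
    for (int r = 0; r < 4; ++r) out(r, j) = buf(r, i0 + j);
  return out;
}
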