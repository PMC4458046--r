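#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Parameter vector layout (kept in lock-step with .PARAM_NAMES in R/parameters.R)
enum par_idx {
  KD1, KD2, KD3, KD4, KD5, KD6, KD7,
  KP1, KP2, KP3,
  A12, A21, A23, A32,
  C1, C2, C3, C4,
  ALPHA, K1, K2, K3, KC1, KC2, GAMMA, BETA1, R2,
  VOL_B, VOL_LN, S_T, V_I, EPS,
  NPAR
};

static const int NSTATE = 9;

// Continuous-time right-hand side; y = (t_n, t_e1, lv, t_e2, c_pos,
// c_neg, t_e3, ifng, tnfa). Mirrors model_rhs() in R.
static inline void rhs(const double *y, const double *p, double *d) {
  const double t_n = y[0], t_e1 = y[1], lv = y[2], t_e2 = y[3];
  const double c_pos = y[4], c_neg = y[5], t_e3 = y[6];
  const double ifng = y[7], tnfa = y[8];

  const double C = c_pos + c_neg;
  const double eps = p[EPS];
  const double vol_t = eps + p[S_T] * C + p[V_I] * t_e3;
  const double act = lv / (lv + p[GAMMA]);
  const double chk = p[ALPHA] / (p[ALPHA] + t_e1 * t_e1);
  const double conv = p[C3] * ifng / (p[K1] + ifng);

  d[0] = p[C1] - p[KD1] * t_n - p[C2] * t_n * act;
  d[1] = p[C2] * t_n * p[VOL_B] / p[VOL_LN] * act +
         p[KP1] * t_e1 * act * chk +
         p[A21] * t_e2 * p[VOL_B] / p[VOL_LN] - p[A12] * t_e1;
  d[2] = -p[KD2] * lv;
  d[3] = -p[KD3] * t_e2 + p[A12] * t_e1 * p[VOL_LN] / p[VOL_B] -
         p[A21] * t_e2 +
         p[A32] * c_neg / (eps + C) * t_e3 * vol_t / p[VOL_B] -
         p[A23] * t_e2;
  d[4] = conv * c_neg - p[KP2] * c_pos - p[KD4] * c_pos -
         p[C4] * t_e3 * c_pos / (eps + C);
  d[5] = -conv * c_neg - p[KD4] * c_neg + p[KP2] * c_neg -
         p[R2] * c_neg * c_neg + 2.0 * p[KP2] * c_pos;
  d[6] = p[A23] * t_e2 * p[VOL_B] / vol_t -
         p[A32] * t_e3 * c_neg / (eps + C) +
         p[KP3] * c_pos / (eps + C) * t_e3 - p[KD5] * t_e3;
  d[7] = -p[KD6] * ifng + p[KC1] * t_e3;
  d[8] = -p[KD7] * tnfa + p[KC2] * tnfa / (p[K2] + tnfa) * t_e3 +
         p[K3] * t_e3;
}

// [[Rcpp::export]]
NumericVector cpp_model_rhs(NumericVector y, NumericVector p) {
  NumericVector d(NSTATE);
  rhs(REAL(y), REAL(p), REAL(d));
  return d;
}

static inline void rk4_step(double *y, const double *p, double h,
                            double *k1, double *k2, double *k3, double *k4,
                            double *tmp) {
  rhs(y, p, k1);
  for (int i = 0; i < NSTATE; ++i) tmp[i] = y[i] + 0.5 * h * k1[i];
  rhs(tmp, p, k2);
  for (int i = 0; i < NSTATE; ++i) tmp[i] = y[i] + 0.5 * h * k2[i];
  rhs(tmp, p, k3);
  for (int i = 0; i < NSTATE; ++i) tmp[i] = y[i] + h * k3[i];
  rhs(tmp, p, k4);
  for (int i = 0; i < NSTATE; ++i)
    y[i] += h / 6.0 * (k1[i] + 2.0 * k2[i] + 2.0 * k3[i] + k4[i]);
}

// Project negative overshoots (explicit stepping of the stiff kill
// term oscillates the fast tumor state around zero) back to zero,
// recording the worst excursion per state as a diagnostic.
static inline void clip_state(double *y, double *worst) {
  for (int i = 0; i < NSTATE; ++i)
    if (y[i] < 0.0) {
      if (y[i] < worst[i]) worst[i] = y[i];
      y[i] = 0.0;
    }
}

static inline bool finite_state(const double *y) {
  for (int i = 0; i < NSTATE; ++i)
    if (!std::isfinite(y[i])) return false;
  return true;
}

// Fixed-step classical RK4 over [t0, t1] with exact impulse application.
// The grid is segment-wise uniform with step <= dt and lands exactly on
// every event time; at each event the pre-jump and post-jump states are
// both recorded (event flag -1 / +1).
// [[Rcpp::export]]
List cpp_rk4_trajectory(NumericVector y0, NumericVector p,
                        NumericVector ev_time, NumericVector ev_dose,
                        double t0, double t1, double dt,
                        bool clip_negative, double extinct_thr) {
  if (y0.size() != NSTATE) stop("state vector must have length 9");
  if (p.size() != NPAR) stop("parameter vector must have length %d", NPAR);
  if (!(dt > 0.0) || !(t1 > t0)) stop("need dt > 0 and t1 > t0");
  const double *pp = REAL(p);

  // segment breakpoints: t0, events strictly inside (t0, t1), t1
  std::vector<double> brk;
  std::vector<double> brk_dose;  // dose applied on arrival at breakpoint
  brk.push_back(t0);
  brk_dose.push_back(0.0);
  for (int k = 0; k < ev_time.size(); ++k) {
    double tk = ev_time[k];
    if (tk < t0 || tk > t1) continue;  // filtered with warning in R
    if (tk == t0) continue;            // impulse at t0 handled in R wrapper
    brk.push_back(tk);
    brk_dose.push_back(ev_dose[k]);
  }
  if (std::find(brk.begin(), brk.end(), t1) == brk.end()) {
    brk.push_back(t1);
    brk_dose.push_back(0.0);
  }

  // estimate output size
  size_t nout = 1;
  for (size_t s = 1; s < brk.size(); ++s) {
    double len = brk[s] - brk[s - 1];
    size_t n = (size_t)std::ceil(len / dt - 1e-9);
    if (n < 1) n = 1;
    nout += n + (brk_dose[s] != 0.0 ? 2 : 0);
  }
  // events with dose 0 still get pre/post rows
  for (size_t s = 1; s < brk.size(); ++s)
    if (brk_dose[s] == 0.0 && s + 1 < brk.size()) nout += 2;

  std::vector<double> times; times.reserve(nout);
  std::vector<double> states; states.reserve(nout * NSTATE);
  std::vector<int> flags; flags.reserve(nout);

  double y[NSTATE], k1[NSTATE], k2[NSTATE], k3[NSTATE], k4[NSTATE], tmp[NSTATE];
  double worst[NSTATE];
  for (int i = 0; i < NSTATE; ++i) { y[i] = y0[i]; worst[i] = 0.0; }

  times.push_back(t0);
  for (int i = 0; i < NSTATE; ++i) states.push_back(y[i]);
  flags.push_back(0);

  for (size_t s = 1; s < brk.size(); ++s) {
    double a = brk[s - 1], b = brk[s];
    double len = b - a;
    int n = (int)std::ceil(len / dt - 1e-9);
    if (n < 1) n = 1;
    double h = len / n;
    // every interior breakpoint is an impulse event; t1 only if dosed there
    bool event_here = (s + 1 < brk.size()) || (brk_dose[s] != 0.0);
    for (int j = 1; j <= n; ++j) {
      rk4_step(y, pp, h, k1, k2, k3, k4, tmp);
      if (clip_negative) clip_state(y, worst);
      // extinction: below one cell (or the configured floor) the
      // discrete tumor population is gone; absorb at zero so numerical
      // remnants cannot regrow
      if (extinct_thr > 0.0 && y[4] + y[5] < extinct_thr) {
        y[4] = 0.0;
        y[5] = 0.0;
      }
      if (!finite_state(y))
        stop("non-finite state at t = %g (integration blow-up)", a + j * h);
      double tj = (j == n) ? b : a + j * h;
      if (j == n && event_here) {
        // pre-jump record
        times.push_back(tj);
        for (int i = 0; i < NSTATE; ++i) states.push_back(y[i]);
        flags.push_back(-1);
        y[2] += brk_dose[s];
        times.push_back(tj);
        for (int i = 0; i < NSTATE; ++i) states.push_back(y[i]);
        flags.push_back(1);
      } else {
        times.push_back(tj);
        for (int i = 0; i < NSTATE; ++i) states.push_back(y[i]);
        flags.push_back(0);
      }
    }
  }

  int nrow = times.size();
  NumericMatrix out(nrow, NSTATE);
  NumericVector tt(nrow);
  IntegerVector fl(nrow);
  for (int r = 0; r < nrow; ++r) {
    tt[r] = times[r];
    fl[r] = flags[r];
    for (int i = 0; i < NSTATE; ++i) out(r, i) = states[r * NSTATE + i];
  }
  NumericVector wv(NSTATE);
  for (int i = 0; i < NSTATE; ++i) wv[i] = worst[i];
  return List::create(_["time"] = tt, _["state"] = out, _["event"] = fl,
                      _["worst_negative"] = wv);
}

// Integrate and return states only at requested sample times (post-jump
// convention when a sample time coincides with an event). Used by the
// calibration fitness where the dense trajectory is not needed.
// [[Rcpp::export]]
NumericMatrix cpp_rk4_sample(NumericVector y0, NumericVector p,
                             NumericVector ev_time, NumericVector ev_dose,
                             double t0, NumericVector sample_times,
                             double dt, bool clip_negative) {
  if (y0.size() != NSTATE) stop("state vector must have length 9");
  if (p.size() != NPAR) stop("parameter vector must have length %d", NPAR);
  int ns = sample_times.size();
  NumericMatrix out(ns, NSTATE);
  const double *pp = REAL(p);

  // merge breakpoints: events and sample times, ascending
  struct Bp { double t; double dose; bool sample; int sidx; };
  std::vector<Bp> bps;
  for (int k = 0; k < ev_time.size(); ++k)
    if (ev_time[k] > t0) bps.push_back({ev_time[k], ev_dose[k], false, -1});
  for (int j = 0; j < ns; ++j) {
    if (sample_times[j] < t0) stop("sample time before t0");
    bps.push_back({sample_times[j], 0.0, true, j});
  }
  std::stable_sort(bps.begin(), bps.end(),
                   [](const Bp &x, const Bp &y) { return x.t < y.t; });

  double y[NSTATE], k1[NSTATE], k2[NSTATE], k3[NSTATE], k4[NSTATE], tmp[NSTATE];
  double worst[NSTATE];
  for (int i = 0; i < NSTATE; ++i) { y[i] = y0[i]; worst[i] = 0.0; }
  double tcur = t0;

  // events at exactly t0 apply immediately
  for (int k = 0; k < ev_time.size(); ++k)
    if (ev_time[k] == t0) y[2] += ev_dose[k];

  for (size_t b = 0; b < bps.size(); ++b) {
    double target = bps[b].t;
    if (target > tcur) {
      double len = target - tcur;
      int n = (int)std::ceil(len / dt - 1e-9);
      if (n < 1) n = 1;
      double h = len / n;
      for (int j = 0; j < n; ++j) {
        rk4_step(y, pp, h, k1, k2, k3, k4, tmp);
        if (clip_negative) clip_state(y, worst);
        if (!finite_state(y))
          stop("non-finite state at t = %g (integration blow-up)",
               tcur + (j + 1) * h);
      }
      tcur = target;
    }
    if (!bps[b].sample) {
      y[2] += bps[b].dose;  // impulse
    } else {
      // apply any impulse at the same time before sampling (post-jump)
      // (events sorted before samples at equal t by construction below)
      for (int i = 0; i < NSTATE; ++i) out(bps[b].sidx, i) = y[i];
    }
  }
  return out;
}
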