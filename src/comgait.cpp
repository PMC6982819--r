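#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Curvy-foot compliant leg: geometry and force law (mirrors R/slip-forces.R)
// ---------------------------------------------------------------------------

struct Params {
  double m, g, k, l0, R, d;
  double c;    // leg damping (N*s/m); 0 = conservative
  double fpo;  // push-off thrust peak (N); ankle-powered late-stance boost
};

struct Leg {
  double thh;   // theta at touchdown (frozen)
  double chs;   // contact position at touchdown (frozen)
  double th;    // warm start for the Newton solve
  double td_t;  // touchdown time
  bool active;
};

// Invert (x, y) -> (ls, theta) for one leg by Newton iteration.
static inline bool invert_geometry(const Params& P, const Leg& leg,
                                   double x, double y,
                                   double& ls, double& th) {
  th = leg.th;
  for (int i = 0; i < 50; ++i) {
    double st = sin(th), ct = cos(th);
    double l = (y - P.R - P.d * st) / ct;
    double f = leg.chs + P.R * (th - leg.thh) - P.d * ct + l * st - x;
    double dl = (-P.d * ct * ct + (y - P.R - P.d * st) * st) / (ct * ct);
    double df = P.R + P.d * st + l * ct + dl * st;
    double step = f / df;
    th -= step;
    if (fabs(step) < 1e-13) break;
  }
  double st = sin(th), ct = cos(th);
  ls = (y - P.R - P.d * st) / ct;
  return R_finite(ls) && ls > 0 && fabs(th) < 1.3;
}

// GRF components and leg-axis force for one leg at CoM (x, y) with velocity
// (vx, vy); returns false if the leg is unloaded (axial force non-positive)
// or the geometry fails.  The axial force is the spring force plus, in the
// actuated/damped variant used by the walking generator, a parallel damper.
static inline bool leg_force(const Params& P, Leg& leg, double x, double y,
                             double vx, double vy,
                             double& fx, double& fy, double& F,
                             double& Ta, double& fa, double& ls_out, double& th_out) {
  double ls, th;
  if (!invert_geometry(P, leg, x, y, ls, th)) return false;
  leg.th = th;
  ls_out = ls; th_out = th;
  F = P.k * (P.l0 - (ls + P.R));
  if (P.c > 0) {
    double st = sin(th), ct = cos(th);
    double A = P.R + P.d * st + ls * ct, B = P.d * ct - ls * st;
    double det = st * B - A * ct;
    double dls = (B * vx - A * vy) / det;
    F -= P.c * dls;
  }
  if (P.fpo > 0 && th > 0) {
    double u = (th - 0.25) / 0.10;
    F += P.fpo * exp(-u * u);
  }
  if (F <= 0) { fx = fy = Ta = fa = 0; return false; }
  double st = sin(th), ct = cos(th);
  fa = -F * (P.d + P.R * st) / (ls + P.R * ct);
  fx = F * st + fa * ct;
  fy = F * ct - fa * st;
  Ta = P.d * ct * fy + (P.R + P.d * st) * fx;
  return true;
}

// Acceleration of the CoM under the active legs (gravity included).
static inline void accel(const Params& P, std::vector<Leg>& legs,
                         double x, double y, double vx, double vy,
                         double& ax, double& ay) {
  ax = 0; ay = -P.g;
  for (size_t j = 0; j < legs.size(); ++j) {
    if (!legs[j].active) continue;
    double fx, fy, F, Ta, fa, ls, th;
    if (leg_force(P, legs[j], x, y, vx, vy, fx, fy, F, Ta, fa, ls, th)) {
      ax += fx / P.m;
      ay += fy / P.m;
    }
  }
}

static inline void rk4_step(const Params& P, std::vector<Leg>& legs,
                            double* s, double dt) {
  double k1[4], k2[4], k3[4], k4[4], tmp[4], ax, ay;
  accel(P, legs, s[0], s[1], s[2], s[3], ax, ay);
  k1[0] = s[2]; k1[1] = s[3]; k1[2] = ax; k1[3] = ay;
  for (int i = 0; i < 4; ++i) tmp[i] = s[i] + 0.5 * dt * k1[i];
  accel(P, legs, tmp[0], tmp[1], tmp[2], tmp[3], ax, ay);
  k2[0] = tmp[2]; k2[1] = tmp[3]; k2[2] = ax; k2[3] = ay;
  for (int i = 0; i < 4; ++i) tmp[i] = s[i] + 0.5 * dt * k2[i];
  accel(P, legs, tmp[0], tmp[1], tmp[2], tmp[3], ax, ay);
  k3[0] = tmp[2]; k3[1] = tmp[3]; k3[2] = ax; k3[3] = ay;
  for (int i = 0; i < 4; ++i) tmp[i] = s[i] + dt * k3[i];
  accel(P, legs, tmp[0], tmp[1], tmp[2], tmp[3], ax, ay);
  k4[0] = tmp[2]; k4[1] = tmp[3]; k4[2] = ax; k4[3] = ay;
  for (int i = 0; i < 4; ++i)
    s[i] += dt / 6.0 * (k1[i] + 2 * k2[i] + 2 * k3[i] + k4[i]);
}

// touchdown leg angle (negative root) implied by a CoM height with the
// spring at rest length; falls back to th0 when the height is out of range
static inline double theta_td_from_height(const Params& P, double y, double th0) {
  if (y >= P.l0 - 1e-6) return th0;
  double th = th0;
  for (int i = 0; i < 30; ++i) {
    double f = P.R + P.d * sin(th) + (P.l0 - P.R) * cos(th) - y;
    double df = P.d * cos(th) - (P.l0 - P.R) * sin(th);
    double step = f / df;
    th -= step;
    if (fabs(step) < 1e-12) break;
  }
  return (th < -1e-3 && th > -1.2) ? th : th0;
}

static Params unpack(const NumericVector& par) {
  Params P;
  P.m = par["m"]; P.g = par["g"]; P.k = par["k"];
  P.l0 = par["l0"]; P.R = par["R"]; P.d = par["d"];
  P.c = par.containsElementNamed("c") ? (double)par["c"] : 0.0;
  P.fpo = par.containsElementNamed("fpo") ? (double)par["fpo"] : 0.0;
  return P;
}

// ---------------------------------------------------------------------------
// Single-stance simulation: one leg, fixed touchdown references, integrate
// until the vertical GRF unloads (spring back at rest length), with the
// liftoff time located by bisection to dt/100.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_simulate_stance(NumericVector par, double theta_hs, double c_hs,
                         NumericVector init, double dt, double tmax) {
  Params P = unpack(par);
  Leg leg; leg.thh = theta_hs; leg.chs = c_hs; leg.th = theta_hs;
  leg.td_t = 0.0; leg.active = true;
  std::vector<Leg> legs(1, leg);

  int nmax = (int)(tmax / dt) + 2;
  NumericMatrix out(nmax + 1, 11);
  colnames(out) = CharacterVector::create("t", "x", "y", "vx", "vy",
                                          "l", "theta", "fx", "fy", "Ta", "fa");
  double s[4] = { init[0], init[1], init[2], init[3] };
  double t = 0.0;
  bool loaded = false;
  int n = 0;
  std::string err = "";
  double t_lo = NA_REAL;

  for (int i = 0; i <= nmax; ++i) {
    double fx, fy, F, Ta, fa, ls, th;
    bool on = leg_force(P, legs[0], s[0], s[1], s[2], s[3], fx, fy, F, Ta, fa, ls, th);
    if (!R_finite(s[0]) || !R_finite(s[1])) { err = "integration blow-up (NaN state)"; break; }
    out(n, 0) = t; out(n, 1) = s[0]; out(n, 2) = s[1];
    out(n, 3) = s[2]; out(n, 4) = s[3];
    out(n, 5) = ls + P.R; out(n, 6) = th;
    out(n, 7) = fx; out(n, 8) = fy; out(n, 9) = Ta; out(n, 10) = fa;
    ++n;
    if (on && F > 1e-9 * P.k) loaded = true;
    if (loaded && (!on || F <= 0)) {
      // bisect the liftoff time between the previous and current grid point
      double a = t - dt, b = t;
      double sa[4];
      for (int q = 0; q < 4; ++q) sa[q] = out(n - 2, q + 1);
      sa[0] = out(n - 2, 1); sa[1] = out(n - 2, 2); sa[2] = out(n - 2, 3); sa[3] = out(n - 2, 4);
      for (int it = 0; it < 40 && (b - a) > dt / 100.0; ++it) {
        double mid = 0.5 * (a + b);
        double sm[4] = { sa[0], sa[1], sa[2], sa[3] };
        std::vector<Leg> lg = legs;
        rk4_step(P, lg, sm, mid - a);
        double fx2, fy2, F2, Ta2, fa2, ls2, th2;
        bool on2 = leg_force(P, lg[0], sm[0], sm[1], sm[2], sm[3], fx2, fy2, F2, Ta2, fa2, ls2, th2);
        if (on2 && F2 > 0) {
          a = mid; for (int q = 0; q < 4; ++q) sa[q] = sm[q];
          legs = lg;
        } else {
          b = mid;
        }
      }
      t_lo = 0.5 * (a + b);
      // overwrite the last row with the bisected liftoff state (GRF == 0)
      double sm[4] = { sa[0], sa[1], sa[2], sa[3] };
      std::vector<Leg> lg = legs;
      rk4_step(P, lg, sm, t_lo - a);
      double fx2, fy2, F2, Ta2, fa2, ls2, th2;
      leg_force(P, lg[0], sm[0], sm[1], sm[2], sm[3], fx2, fy2, F2, Ta2, fa2, ls2, th2);
      out(n - 1, 0) = t_lo; out(n - 1, 1) = sm[0]; out(n - 1, 2) = sm[1];
      out(n - 1, 3) = sm[2]; out(n - 1, 4) = sm[3];
      out(n - 1, 5) = ls2 + P.R; out(n - 1, 6) = th2;
      out(n - 1, 7) = 0.0; out(n - 1, 8) = 0.0; out(n - 1, 9) = 0.0; out(n - 1, 10) = 0.0;
      break;
    }
    if (i == nmax) { err = "no liftoff before tmax"; break; }
    rk4_step(P, legs, s, dt);
    t += dt;
  }
  NumericMatrix trace = out(Range(0, n - 1), _);
  colnames(trace) = colnames(out);
  return List::create(_["trace"] = trace,
                      _["liftoff"] = t_lo,
                      _["error"] = err);
}

// ---------------------------------------------------------------------------
// Stitched walking: alternating stances with finite double support.  A new
// leg touches down (uncompressed, at the policy angle theta_td) when the CoM
// descends through the touchdown height; the old leg is dropped when its
// spring unloads.  A weak per-touchdown speed regulator emulates steady
// treadmill walking.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_simulate_walk(NumericVector par, double v_target,
                       NumericVector theta_td_seq,
                       int n_steps, double dt, int rec_every, double lambda,
                       int warmup_steps) {
  Params P = unpack(par);
  int n_td = 0;
  double theta_td = theta_td_seq[0];
  double y_td = P.R + P.d * sin(theta_td) + (P.l0 - P.R) * cos(theta_td);

  std::vector<Leg> legs;
  // start mid single support: vertical leg, uncompressed spring (apex-like),
  // forward speed at the target
  double ls0 = P.l0 - P.R;
  Leg first; first.thh = theta_td; first.th = 0.0; first.td_t = 0.0; first.active = true;
  double x0 = 0.0;
  first.chs = x0 + P.R * theta_td + P.d;   // consistent with theta = 0 at x0
  legs.push_back(first);
  double s[4] = { x0, P.R + P.d * 0.0 + ls0, v_target, 0.0 };

  int total_steps = n_steps + warmup_steps;
  std::vector<double> td_t, lo_t, td_thh, td_chs;
  td_t.push_back(0.0); td_thh.push_back(first.thh); td_chs.push_back(first.chs);

  std::vector<double> rec; rec.reserve(200000);
  double t = 0.0, vint = 0.0;
  int rec_i = 0;
  double last_td_t = 0.0, last_td_x = x0;
  std::string err = "";
  long imax = (long)((double)total_steps * 2.5 / v_target / dt) + (long)(8.0 / dt);

  for (long i = 0; i < imax; ++i) {
    // record
    if (rec_i == 0) {
      double ax, ay;
      accel(P, legs, s[0], s[1], s[2], s[3], ax, ay);
      rec.push_back(t); rec.push_back(s[0]); rec.push_back(s[1]);
      rec.push_back(s[2]); rec.push_back(s[3]); rec.push_back(ax); rec.push_back(ay);
    }
    rec_i = (rec_i + 1) % rec_every;

    double y_prev = s[1], t_prev = t;
    // spring force of the oldest active leg before the step
    double F_prev = NA_REAL;
    if (!legs.empty()) {
      double fx, fy, F, Ta, fa, ls, th;
      bool on = leg_force(P, legs[0], s[0], s[1], s[2], s[3], fx, fy, F, Ta, fa, ls, th);
      F_prev = on ? F : 0.0;
    }

    rk4_step(P, legs, s, dt);
    t += dt;

    if (!R_finite(s[0]) || !R_finite(s[1])) { err = "integration blow-up"; break; }
    if (s[1] < 0.5 * P.l0) { err = "fall: CoM height collapsed"; break; }
    if (s[2] < 0.0) { err = "fall: walker moving backward"; break; }

    // liftoff of the oldest leg?
    if (!legs.empty() && R_finite(F_prev) && F_prev > 0) {
      double fx, fy, F, Ta, fa, ls, th;
      bool on = leg_force(P, legs[0], s[0], s[1], s[2], s[3], fx, fy, F, Ta, fa, ls, th);
      double F_now = on ? F : 0.0;
      if (F_now <= 0) {
        double frac = F_prev / (F_prev - F_now);
        lo_t.push_back(t_prev + frac * dt);
        legs.erase(legs.begin());
        if ((int)lo_t.size() >= total_steps) break;
      }
    }

    // touchdown of a new leg?  only during single support (or flight), after
    // the apex (descending CoM): either the CoM descends through the policy
    // touchdown height, or the support leg has swept well past vertical (a
    // flat vault that never re-crosses the trigger height) — then the new
    // leg lands at the angle the current height allows
    if ((int)legs.size() <= 1 && s[3] < 0) {
      bool crossed = (y_prev > y_td && s[1] <= y_td);
      bool swept = !legs.empty() && legs[0].th > 0.95 * fabs(theta_td) &&
                   s[1] < y_td + 1e-9;
      bool flight_low = legs.empty() && s[1] <= y_td;
      bool after_mid = legs.empty() || legs[0].th > 0.02;
      if ((crossed || swept || flight_low) && after_mid) {
        ++n_td;
        double theta_eff = crossed ? theta_td
                                   : theta_td_from_height(P, s[1], theta_td);
        double frac = crossed ? (y_prev - y_td) / (y_prev - s[1]) : 1.0;
        double t_td = t_prev + frac * dt;
        // regulate forward speed once per step (treadmill emulation):
        // proportional + integral action on the per-step mean speed error
        double mean_v = (s[0] - last_td_x) / std::max(1e-6, t - last_td_t);
        double verr = v_target - mean_v;
        vint += 0.4 * verr;
        s[2] += lambda * verr + vint;
        last_td_t = t; last_td_x = s[0];
        Leg nl; nl.thh = theta_eff; nl.th = theta_eff; nl.td_t = t_td; nl.active = true;
        // contact lands ahead of the CoM for theta_eff < 0
        nl.chs = s[0] + P.d * cos(theta_eff) - (P.l0 - P.R) * sin(theta_eff);
        legs.push_back(nl);
        td_t.push_back(t_td); td_thh.push_back(nl.thh); td_chs.push_back(nl.chs);
        // next step's touchdown policy angle
        theta_td = theta_td_seq[std::min(n_td, (int)theta_td_seq.size() - 1)];
        y_td = P.R + P.d * sin(theta_td) + (P.l0 - P.R) * cos(theta_td);
      }
    }
  }
  if (err.empty() && (int)lo_t.size() < total_steps)
    err = "walker did not complete the requested number of steps";

  int nrec = rec.size() / 7;
  NumericMatrix samples(nrec, 7);
  for (int i = 0; i < nrec; ++i)
    for (int j = 0; j < 7; ++j) samples(i, j) = rec[i * 7 + j];
  colnames(samples) = CharacterVector::create("t", "x", "y", "vx", "vy", "ax", "ay");

  return List::create(_["samples"] = samples,
                      _["td_t"] = wrap(td_t), _["lo_t"] = wrap(lo_t),
                      _["td_theta_hs"] = wrap(td_thh), _["td_c_hs"] = wrap(td_chs),
                      _["error"] = err, _["step_at_error"] = (int)lo_t.size() + 1);
}

// ---------------------------------------------------------------------------
// Direct-form II transposed IIR filter with explicit initial conditions
// (building block of the zero-phase Butterworth filter).
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericVector cpp_iir_filter(NumericVector x, NumericVector b, NumericVector a,
                             NumericVector zi) {
  int n = x.size(), nb = b.size();
  NumericVector y(n);
  std::vector<double> z(zi.begin(), zi.end());
  z.resize(nb - 1, 0.0);
  for (int i = 0; i < n; ++i) {
    double xn = x[i];
    double yn = b[0] * xn + (nb > 1 ? z[0] : 0.0);
    for (int j = 1; j < nb - 1; ++j)
      z[j - 1] = b[j] * xn + z[j] - a[j] * yn;
    if (nb > 1) z[nb - 2] = b[nb - 1] * xn - a[nb - 1] * yn;
    y[i] = yn;
  }
  return y;
}
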