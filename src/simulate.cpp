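#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Flattened parameter layout (all times in seconds; pressures mmHg,
// volumes ml, resistances mmHg*s/ml, capacitances ml/mmHg, D in mm).
// Order must match .flatten_params() on the R side.
struct Pars {
  double e_sv, a_sv, b_sv, v0_sv, tes_sv;
  double e_sa, a_sa, b_sa, v0_sa, tes_sa;
  double r_av, r_avv;
  double rc_s, ra_s, rv_s, ca_s, cv_s;
  double rc_p, ra_p, rv_p, ca_p, cv_p;
  double d, tc, dt_shift, eps;
};

static Pars unpack(const NumericVector &p) {
  Pars q;
  double *f = &q.e_sv;
  for (int i = 0; i < 26; ++i) f[i] = p[i];
  return q;
}

// reduce t into [0, tc)
static inline double pmod(double t, double tc) {
  double r = t - tc * std::floor(t / tc);
  if (r >= tc) r -= tc;
  return (r < 0.0) ? r + tc : r;
}

// normalized activation e(t) on [0, tc): half-cosine bump over [0, 2*tes]
static inline double act(double t, double tes) {
  if (t <= 0.0 || t >= 2.0 * tes) return 0.0;
  return 0.5 * (1.0 - std::cos(M_PI * t / tes));
}

// time-varying elastance chamber: e*ESPVR + (1-e)*EDPVR
static inline double chamber_p(double v, double e, double ees, double a,
                               double b, double v0) {
  return e * ees * (v - v0) + (1.0 - e) * a * (std::exp(b * (v - v0)) - 1.0);
}

// Bernoulli orifice, inverted for flow; linear blend below eps to keep
// the derivative bounded at dP = 0
static inline double fen_q(double dp, double d, double eps) {
  if (d <= 0.0) return 0.0;
  double ad = std::fabs(dp);
  double root = (ad < eps) ? ad / std::sqrt(eps) : std::sqrt(ad);
  double q = M_PI * d * d / 8.0 * root;
  return (dp >= 0.0) ? q : -q;
}

// State order: V_SV, V_SA, V_Ca_s, V_Cv_s, V_Ca_p, V_Cv_p
// aux (when non-null): Q_AV Q_as Q_pa Q_ap Q_pv Q_f Q_AVV,
//                      P_SV P_SA P_Ca_s P_Cv_s P_Ca_p P_Cv_p
static void rhs(double t, const double *y, const Pars &p, double *dy,
                double *aux) {
  double tv = pmod(t, p.tc);
  double ta = pmod(t + p.dt_shift, p.tc);
  double p_sv = chamber_p(y[0], act(tv, p.tes_sv), p.e_sv, p.a_sv, p.b_sv, p.v0_sv);
  double p_sa = chamber_p(y[1], act(ta, p.tes_sa), p.e_sa, p.a_sa, p.b_sa, p.v0_sa);
  double p_cas = y[2] / p.ca_s;
  double p_cvs = y[3] / p.cv_s;
  double p_cap = y[4] / p.ca_p;
  double p_cvp = y[5] / p.cv_p;

  double q_av  = (p_sv > p_cas) ? (p_sv - p_cas) / (p.r_av + p.rc_s) : 0.0;
  double q_as  = (p_cas - p_cvs) / p.ra_s;
  double q_pa  = (p_cvs - p_cap) / (p.rv_s + p.rc_p);
  double q_ap  = (p_cap - p_cvp) / p.ra_p;
  double q_pv  = (p_cvp - p_sa) / p.rv_p;
  double q_f   = fen_q(p_cvs - p_sa, p.d, p.eps);
  double q_avv = (p_sa > p_sv) ? (p_sa - p_sv) / p.r_avv : 0.0;

  dy[0] = q_avv - q_av;
  dy[1] = q_pv + q_f - q_avv;
  dy[2] = q_av - q_as;
  dy[3] = q_as - q_pa - q_f;
  dy[4] = q_pa - q_ap;
  dy[5] = q_ap - q_pv;

  if (aux) {
    aux[0] = q_av;  aux[1] = q_as;  aux[2] = q_pa; aux[3] = q_ap;
    aux[4] = q_pv;  aux[5] = q_f;   aux[6] = q_avv;
    aux[7] = p_sv;  aux[8] = p_sa;  aux[9] = p_cas;
    aux[10] = p_cvs; aux[11] = p_cap; aux[12] = p_cvp;
  }
}

static inline void rk4_step(double t, double dt, double *y, const Pars &p) {
  double k1[6], k2[6], k3[6], k4[6], tmp[6];
  rhs(t, y, p, k1, 0);
  for (int j = 0; j < 6; ++j) tmp[j] = y[j] + 0.5 * dt * k1[j];
  rhs(t + 0.5 * dt, tmp, p, k2, 0);
  for (int j = 0; j < 6; ++j) tmp[j] = y[j] + 0.5 * dt * k2[j];
  rhs(t + 0.5 * dt, tmp, p, k3, 0);
  for (int j = 0; j < 6; ++j) tmp[j] = y[j] + dt * k3[j];
  rhs(t + dt, tmp, p, k4, 0);
  for (int j = 0; j < 6; ++j)
    y[j] += dt / 6.0 * (k1[j] + 2.0 * k2[j] + 2.0 * k3[j] + k4[j]);
}

// [[Rcpp::export(name = ".fontan_rhs_cpp")]]
NumericVector fontan_rhs_cpp(NumericVector state, double t, NumericVector pars) {
  Pars p = unpack(pars);
  double dy[6], aux[13];
  rhs(t, REAL(state), p, dy, aux);
  NumericVector out(6);
  for (int j = 0; j < 6; ++j) out[j] = dy[j];
  NumericVector fl(7), pr(6);
  for (int j = 0; j < 7; ++j) fl[j] = aux[j];
  for (int j = 0; j < 6; ++j) pr[j] = aux[7 + j];
  out.attr("flows") = fl;
  out.attr("pressures") = pr;
  return out;
}

// Integrate beat by beat until the end-of-beat state repeats to within
// tol (max abs componentwise), then record one further full beat at
// every step. Returns convergence diagnostics alongside the sampled beat.
// [[Rcpp::export(name = ".fontan_simulate_cpp")]]
List fontan_simulate_cpp(NumericVector y0, NumericVector pars, double dt,
                         int max_beats, double tol) {
  Pars p = unpack(pars);
  int nsteps = (int)std::llround(p.tc / dt);
  if (nsteps < 2) nsteps = 2;
  double h = p.tc / nsteps;  // exact beat alignment

  double y[6];
  for (int j = 0; j < 6; ++j) y[j] = y0[j];
  double v_total0 = 0.0;
  for (int j = 0; j < 6; ++j) v_total0 += y[j];

  bool converged = false;
  double delta = R_PosInf;
  int beats = 0;
  int bad_comp = -1;
  double bad_t = NA_REAL;

  for (int b = 0; b < max_beats; ++b) {
    double yprev[6];
    for (int j = 0; j < 6; ++j) yprev[j] = y[j];
    for (int i = 0; i < nsteps; ++i) rk4_step(i * h, h, y, p);
    beats = b + 1;
    bool bad = false;
    for (int j = 0; j < 6; ++j) {
      if (!std::isfinite(y[j]) || y[j] < -1e-6) { bad = true; bad_comp = j; }
    }
    if (bad) { bad_t = beats * p.tc; break; }
    delta = 0.0;
    for (int j = 0; j < 6; ++j) {
      double d = std::fabs(y[j] - yprev[j]);
      if (d > delta) delta = d;
    }
    if (b >= 1 && delta < tol) { converged = true; break; }
  }

  // record one full beat from the (converged or last) state
  int nrec = nsteps + 1;
  NumericVector times(nrec);
  NumericMatrix V(nrec, 6), P(nrec, 6), Q(nrec, 7);
  if (bad_comp < 0) {
    double dy[6], aux[13];
    for (int i = 0; i < nrec; ++i) {
      double t = i * h;
      times[i] = t;
      rhs(t, y, p, dy, aux);
      for (int j = 0; j < 6; ++j) V(i, j) = y[j];
      for (int j = 0; j < 7; ++j) Q(i, j) = aux[j];
      for (int j = 0; j < 6; ++j) P(i, j) = aux[7 + j];
      if (i < nsteps) rk4_step(t, h, y, p);
    }
  }

  double v_total1 = 0.0;
  for (int j = 0; j < 6; ++j) v_total1 += y[j];

  return List::create(
    _["times"] = times, _["V"] = V, _["P"] = P, _["Q"] = Q,
    _["converged"] = converged, _["beats"] = beats, _["delta"] = delta,
    _["dt"] = h, _["v_total_start"] = v_total0, _["v_total_end"] = v_total1,
    _["bad_component"] = bad_comp + 1, _["bad_time"] = bad_t);
}
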