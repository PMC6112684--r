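#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Exact per-step open time of {c(t) >= theta} for a sum-of-exponentials
// calcium trace, clipped at `cutoff` (pairing-resolution inactivation of the
// piecewise threshold model).  Between impulses the trace decays
// monotonically, so each inter-impulse segment contributes at most one
// downward crossing, located in closed form.
static void gate_occupancy_piecewise(const std::vector<double>& evt,
                                     const std::vector<double>& peaks,
                                     double tau_ca, double theta, double cutoff,
                                     double t_start, double dt, int n_iter,
                                     std::vector<double>& occ) {
  std::fill(occ.begin(), occ.end(), 0.0);
  if (!R_FINITE(theta)) return;
  const int n = (int) evt.size();
  std::vector<std::pair<double, double> > iv;  // disjoint "above" intervals
  for (int i = 0; i < n; i++) {
    if (evt[i] >= cutoff) break;
    if (peaks[i] < theta) continue;
    double a = evt[i];
    double b = (i + 1 < n) ? evt[i + 1] : R_PosInf;
    double cross = a + tau_ca * std::log(peaks[i] / theta);
    double hi = std::min(std::min(b, cross), cutoff);
    if (hi <= a) continue;
    if (!iv.empty() && a <= iv.back().second + 1e-15)
      iv.back().second = std::max(iv.back().second, hi);
    else
      iv.push_back(std::make_pair(a, hi));
  }
  size_t p = 0;
  for (int s = 0; s < n_iter; s++) {
    double lo = t_start + s * dt, hi = lo + dt, tot = 0.0;
    while (p < iv.size() && iv[p].second <= lo) p++;
    for (size_t q = p; q < iv.size() && iv[q].first < hi; q++)
      tot += std::max(0.0, std::min(hi, iv[q].second) - std::max(lo, iv[q].first));
    occ[s] = tot;
  }
}

// c(t) and its running integral at every step midpoint (closed form).
static void midpoint_trace(const std::vector<double>& evt,
                           const std::vector<double>& amp,
                           double tau_ca, double t_start, double dt, int n_iter,
                           std::vector<double>& c_mid, std::vector<double>& i_mid) {
  double c = 0.0, I = 0.0, tprev = R_NegInf;
  size_t e = 0;
  const size_t n = evt.size();
  if (n > 0) { tprev = evt[0]; }
  for (int s = 0; s < n_iter; s++) {
    double t = t_start + (s + 0.5) * dt;
    while (e < n && evt[e] <= t) {
      if (e > 0) {
        double dec = std::exp(-(evt[e] - tprev) / tau_ca);
        I += tau_ca * c * (1.0 - dec);
        c *= dec;
      }
      c += amp[e];
      tprev = evt[e];
      e++;
    }
    if (e == 0) { c_mid[s] = 0.0; i_mid[s] = 0.0; continue; }
    double dec = std::exp(-(t - tprev) / tau_ca);
    c_mid[s] = c * dec;
    i_mid[s] = I + tau_ca * c * (1.0 - dec);
  }
}

// Ensemble Euler-Maruyama integration of the per-pathway bistable efficacy
// SDE.  `gates` has one row per pathway:
//   gamma_p, theta0_p, cutoff_p, mu_p, gamma_d, theta0_d, cutoff_d, mu_d
// cutoffs are absolute times after which the piecewise-model gate is
// inactivated (R_PosInf = never); mu_* are used by the exponential model.
// Snapshot classifications (fraction of the depressed-start ensemble above
// rho_star, fraction of the potentiated-start ensemble below) are recorded
// the first time the integration clock passes each element of `snap_times`.
// [[Rcpp::export]]
List cpp_simulate(NumericVector ev_time, NumericVector ev_amp, double tau_ca,
                  NumericMatrix gates, double tau, double rho_star, double sigma,
                  int threshold_model, double epsilon,
                  double t_start, double dt, int n_iter, int n_syn,
                  NumericVector snap_times, bool linearize, bool return_states) {
  const int n_path = gates.nrow();
  const int n_snap = snap_times.size();
  std::vector<double> evt(ev_time.begin(), ev_time.end());
  std::vector<double> amp(ev_amp.begin(), ev_amp.end());
  const int n_ev = (int) evt.size();

  // concentration immediately after each impulse
  std::vector<double> peaks(n_ev);
  {
    double acc = 0.0, tprev = n_ev ? evt[0] : 0.0;
    for (int i = 0; i < n_ev; i++) {
      acc = acc * std::exp(-(evt[i] - tprev) / tau_ca) + amp[i];
      tprev = evt[i];
      peaks[i] = acc;
    }
  }

  std::vector<double> c_mid, i_mid;
  if (threshold_model == 1) {
    c_mid.resize(n_iter); i_mid.resize(n_iter);
    midpoint_trace(evt, amp, tau_ca, t_start, dt, n_iter, c_mid, i_mid);
  }

  NumericMatrix U(n_snap, n_path), D(n_snap, n_path);
  NumericMatrix states(return_states ? 2 * n_syn : 0, n_path);

  std::vector<double> occ_p(n_iter), occ_d(n_iter), rho(2 * n_syn);

  for (int p = 0; p < n_path; p++) {
    const double gamma_p = gates(p, 0), theta_p = gates(p, 1), cut_p = gates(p, 2), mu_p = gates(p, 3);
    const double gamma_d = gates(p, 4), theta_d = gates(p, 5), cut_d = gates(p, 6), mu_d = gates(p, 7);

    if (threshold_model == 0) {
      gate_occupancy_piecewise(evt, peaks, tau_ca, theta_p, cut_p, t_start, dt, n_iter, occ_p);
      gate_occupancy_piecewise(evt, peaks, tau_ca, theta_d, cut_d, t_start, dt, n_iter, occ_d);
    } else {
      for (int s = 0; s < n_iter; s++) {
        double thp = theta_p, thd = theta_d;
        if (R_FINITE(mu_p)) {
          double z = (i_mid[s] - mu_p) / epsilon;
          thp = (z > 700.0) ? R_PosInf : thp + std::exp(z);
        }
        if (R_FINITE(mu_d)) {
          double z = (i_mid[s] - mu_d) / epsilon;
          thd = (z > 700.0) ? R_PosInf : thd + std::exp(z);
        }
        occ_p[s] = (R_FINITE(thp) && c_mid[s] >= thp) ? dt : 0.0;
        occ_d[s] = (R_FINITE(thd) && c_mid[s] >= thd) ? dt : 0.0;
      }
    }

    for (int j = 0; j < n_syn; j++) rho[j] = 0.0;
    for (int j = n_syn; j < 2 * n_syn; j++) rho[j] = 1.0;

    int b = 0;
    for (int s = 0; s < n_iter; s++) {
      double t = t_start + s * dt;
      while (b < n_snap && snap_times[b] <= t) {
        int cu = 0, cd = 0;
        for (int j = 0; j < n_syn; j++) {
          if (!R_FINITE(rho[j])) stop("non-finite efficacy at step %d (pathway %d)", s, p + 1);
          if (rho[j] > rho_star) cu++;
        }
        for (int j = n_syn; j < 2 * n_syn; j++) if (rho[j] < rho_star) cd++;
        U(b, p) = (double) cu / n_syn;
        D(b, p) = (double) cd / n_syn;
        b++;
      }
      const double op = occ_p[s], od = occ_d[s];
      const double gp = gamma_p * op, gd = gamma_d * od;
      const double ns = (op + od > 0.0 && sigma > 0.0)
                          ? (sigma / tau) * std::sqrt(op + od) : 0.0;
      if (gp == 0.0 && gd == 0.0 && ns == 0.0) {
        if (!linearize) {
          for (int j = 0; j < 2 * n_syn; j++) {
            double r = rho[j];
            rho[j] = r - r * (1.0 - r) * (rho_star - r) * dt / tau;
          }
        }
      } else {
        for (int j = 0; j < 2 * n_syn; j++) {
          double r = rho[j];
          double cubic = linearize ? 0.0 : -r * (1.0 - r) * (rho_star - r) * dt;
          r += (cubic + gp * (1.0 - r) - gd * r) / tau;
          if (ns > 0.0) r += ns * norm_rand();
          rho[j] = r;
        }
      }
    }
    while (b < n_snap) {
      int cu = 0, cd = 0;
      for (int j = 0; j < n_syn; j++) {
        if (!R_FINITE(rho[j])) stop("non-finite efficacy at end of run (pathway %d)", p + 1);
        if (rho[j] > rho_star) cu++;
      }
      for (int j = n_syn; j < 2 * n_syn; j++) if (rho[j] < rho_star) cd++;
      U(b, p) = (double) cu / n_syn;
      D(b, p) = (double) cd / n_syn;
      b++;
    }
    if (return_states)
      for (int j = 0; j < 2 * n_syn; j++) states(j, p) = rho[j];
  }

  List out = List::create(_["U"] = U, _["D"] = D);
  if (return_states) out["states"] = states;
  return out;
}
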