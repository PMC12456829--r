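#include <Rcpp.h>
using namespace Rcpp;

// Sigmoidal-ramp transfer function of the reduced Wong-Wang population model:
// H(x) = (a*x - b) / (1 - exp(-d*(a*x - b))), with the removable singularity
// at a*x = b evaluated as 1/d. expm1 keeps the small-argument branch accurate.
static inline double transfer(double x, double a, double b, double d) {
  double u = a * x - b;
  if (u == 0.0) return 1.0 / d;
  double den = -expm1(-d * u);
  return u / den;
}

// [[Rcpp::export]]
NumericVector transfer_rate_cpp(NumericVector x, double a, double b, double d) {
  int n = x.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = transfer(x[i], a, b, d);
  return out;
}

// Euler-Maruyama integration of the coupled synaptic-gating equations
//   dS_i = [-S_i/tau_s + gamma*(1-S_i)*H(x_i) + theta_i(t)] dt + sigma*sqrt(dt)*xi
//   x_i  = w*J*S_i + G*J*sum_j C_ij S_j + I
// theta is constant on [onset, onset+duration) and zero elsewhere.
// S is clamped to [0,1]; clamp activations are counted. Uses R's RNG
// (seed with set.seed() before calling) so runs are reproducible.
// [[Rcpp::export]]
List sim_mfm_cpp(NumericVector S0, NumericMatrix C,
                 double a, double b, double d, double tau_s, double gamma_kin,
                 double sigma, double w, double J, double G, double I_ext,
                 NumericVector theta, double onset_s, double duration_s,
                 double dt, int n_steps, int record_every) {
  int n = S0.size();
  if (C.nrow() != n || C.ncol() != n) stop("coupling matrix dimension mismatch");
  if (theta.size() != n) stop("theta length mismatch");

  int n_rec = n_steps / record_every + 1;
  NumericVector time_s(n_rec);
  NumericMatrix S_rec(n, n_rec), H_rec(n, n_rec), x_rec(n, n_rec);

  std::vector<double> S(S0.begin(), S0.end());
  std::vector<double> x(n), H(n);
  double sqdt = std::sqrt(dt);
  double clamp_hits = 0;
  bool noisy = sigma > 0.0;

  RNGScope scope;

  auto record = [&](int ridx, double t) {
    time_s[ridx] = t;
    for (int i = 0; i < n; ++i) {
      S_rec(i, ridx) = S[i];
      x_rec(i, ridx) = x[i];
      H_rec(i, ridx) = H[i];
    }
  };

  auto currents = [&]() {
    for (int i = 0; i < n; ++i) {
      double coup = 0.0;
      for (int j = 0; j < n; ++j) coup += C(i, j) * S[j];
      x[i] = w * J * S[i] + G * J * coup + I_ext;
      H[i] = transfer(x[i], a, b, d);
    }
  };

  currents();
  record(0, 0.0);
  int ridx = 1;

  for (int step = 0; step < n_steps; ++step) {
    double t = step * dt;
    bool stim_on = (t >= onset_s) && (t < onset_s + duration_s);
    for (int i = 0; i < n; ++i) {
      double drift = -S[i] / tau_s + gamma_kin * (1.0 - S[i]) * H[i];
      if (stim_on) drift += theta[i];
      double s_new = S[i] + drift * dt;
      if (noisy) s_new += sigma * sqdt * norm_rand();
      if (s_new < 0.0) { s_new = 0.0; ++clamp_hits; }
      else if (s_new > 1.0) { s_new = 1.0; ++clamp_hits; }
      if (!std::isfinite(s_new))
        stop("non-finite gating state at t=%f, region %d", t, i + 1);
      S[i] = s_new;
    }
    currents();
    if ((step + 1) % record_every == 0 && ridx < n_rec)
      record(ridx++, (step + 1) * dt);
  }

  return List::create(_["time_s"] = time_s, _["S"] = S_rec, _["H"] = H_rec,
                      _["x"] = x_rec, _["clamp_hits"] = clamp_hits);
}

// Balloon-Windkessel hemodynamic forward model (Friston 2003 constants by
// default, passed in). Four states per region: vasodilatory signal s, inflow
// f, venous volume v, deoxyhemoglobin q. Euler at the drive sampling rate.
// Returns BOLD in percent signal units.
// [[Rcpp::export]]
NumericMatrix balloon_windkessel_cpp(NumericMatrix drive, double dt,
                                     double kappa, double gamma_f, double tau_h,
                                     double alpha, double rho, double V0) {
  int n = drive.nrow(), T = drive.ncol();
  NumericMatrix bold(n, T);
  double k1 = 7.0 * rho, k2 = 2.0, k3 = 2.0 * rho - 0.2;
  double ialpha = 1.0 / alpha;

  for (int i = 0; i < n; ++i) {
    double s = 0.0, f = 1.0, v = 1.0, q = 1.0;
    for (int t = 0; t < T; ++t) {
      double z = drive(i, t);
      double fv = std::pow(v, ialpha);
      double E = 1.0 - std::pow(1.0 - rho, 1.0 / f);
      double ds = z - kappa * s - gamma_f * (f - 1.0);
      double df = s;
      double dv = (f - fv) / tau_h;
      double dq = (f * E / rho - fv * q / v) / tau_h;
      s += ds * dt; f += df * dt; v += dv * dt; q += dq * dt;
      if (f < 1e-6) f = 1e-6;
      if (v < 1e-6) v = 1e-6;
      if (!std::isfinite(s) || !std::isfinite(f) || !std::isfinite(v) ||
          !std::isfinite(q))
        stop("non-finite hemodynamic state in region %d", i + 1);
      bold(i, t) = 100.0 * V0 *
        (k1 * (1.0 - q) + k2 * (1.0 - q / v) + k3 * (1.0 - v));
    }
  }
  return bold;
}

// LZ76 exhaustive-history phrase count (Lempel & Ziv 1976, Kaspar-Schuster
// scheme) on an integer symbol sequence.
// [[Rcpp::export]]
int lz76_cpp(IntegerVector s) {
  int n = s.size();
  if (n == 0) return 0;
  int c = 1, l = 1, i = 0, k = 1, k_max = 1;
  while (true) {
    if (s[i + k - 1] == s[l + k - 1]) {
      ++k;
      if (l + k > n) { ++c; break; }
    } else {
      if (k > k_max) k_max = k;
      ++i;
      if (i == l) {
        ++c;
        l += k_max;
        if (l + 1 > n) break;
        i = 0; k = 1; k_max = 1;
      } else {
        k = 1;
      }
    }
  }
  return c;
}
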