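#include <Rcpp.h>
using namespace Rcpp;

// Piecewise-linear PRC evaluation on knots (zx, zy). zx must be strictly
// increasing and span [0, 1] with pinned zero endpoints; phases past the
// firing point (phi > 1) contribute nothing.
static inline double z_eval(const double* zx, const double* zy, int nk, double phi) {
  if (phi <= 0.0 || phi >= 1.0) return 0.0;
  // binary search for segment: largest j with zx[j] <= phi
  int lo = 0, hi = nk - 1;
  while (hi - lo > 1) {
    int mid = (lo + hi) / 2;
    if (zx[mid] <= phi) lo = mid; else hi = mid;
  }
  double w = (phi - zx[lo]) / (zx[hi] - zx[lo]);
  return zy[lo] + w * (zy[hi] - zy[lo]);
}

// First-order (Euler) integration of dphi/dt = omega + Z(phi) * I(t), with the
// injected current held constant within each of its own samples.
//
// restart = true : phase resets to 0 at each crossing of phi = 1; every
//                  crossing is recorded (spike-train generation).
// restart = false: only the first crossing is recorded; afterwards the input
//                  is disconnected and phase drifts at omega (the Monte Carlo
//                  convention that maps phases > 1 onto time since the spike).
// refine  = true : crossing time linearly interpolated within the final step;
//                  otherwise the first grid time with phi >= 1 is reported.
//
// Negative excursions of phase are clamped at 0 and counted.
// [[Rcpp::export]]
List cpp_phase_integrate(NumericVector zx, NumericVector zy,
                         double omega, double dt, double t0, double t_end,
                         NumericVector cur, double cur_t0, double cur_dt,
                         bool restart, bool refine, bool record_phase,
                         double phi0) {
  const int nk = zx.size();
  const double* px = zx.begin();
  const double* py = zy.begin();
  const int ncur = cur.size();
  const int n_steps = (int)std::floor((t_end - t0) / dt + 1e-9);

  std::vector<double> spikes;
  NumericVector phases;
  if (record_phase) phases = NumericVector(n_steps + 1);

  double phi = phi0;
  if (record_phase) phases[0] = phi;
  bool noise_on = true;
  int n_clamped = 0;

  for (int k = 0; k < n_steps; ++k) {
    double t = t0 + k * dt;
    double I = 0.0;
    if (noise_on) {
      int j = (int)std::floor((t - cur_t0) / cur_dt + 1e-9);
      if (j >= 0 && j < ncur) I = cur[j];
    }
    double dphi = dt * (omega + (noise_on ? z_eval(px, py, nk, phi) * I : 0.0));
    double phi_new = phi + dphi;
    if (phi_new < 0.0) { phi_new = 0.0; ++n_clamped; }
    if (phi_new >= 1.0 && phi < 1.0) {
      double t_cross;
      if (refine && phi_new > phi) {
        t_cross = t + dt * (1.0 - phi) / (phi_new - phi);
      } else {
        t_cross = t + dt;
      }
      spikes.push_back(t_cross);
      if (restart) {
        phi_new = 0.0;
      } else {
        noise_on = false;  // input disconnected; drift at omega from here on
      }
    }
    phi = phi_new;
    if (record_phase) phases[k + 1] = phi;
  }

  return List::create(_["spikes"] = NumericVector(spikes.begin(), spikes.end()),
                      _["phases"] = record_phase ? (SEXP)phases : R_NilValue,
                      _["n_clamped"] = n_clamped,
                      _["phi_end"] = phi);
}
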