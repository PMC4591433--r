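#include <Rcpp.h>
using namespace Rcpp;

// Morris-Lecar right-hand side. Time in ms, voltages in mV, currents in
// uA/cm^2, conductances in mS/cm^2, capacitance in uF/cm^2.
struct MLPar {
  double C, gCa, gK, gL, VCa, VK, VL, V1, V2, V3, V4, phi, Ibias;
};

static inline void ml_deriv(const MLPar &p, double V, double w, double I,
                            double &dV, double &dw) {
  double minf = 0.5 * (1.0 + tanh((V - p.V1) / p.V2));
  double winf = 0.5 * (1.0 + tanh((V - p.V3) / p.V4));
  double lam  = p.phi * cosh((V - p.V3) / (2.0 * p.V4));
  dV = (I - p.gCa * minf * (V - p.VCa) - p.gK * w * (V - p.VK)
          - p.gL * (V - p.VL)) / p.C;
  dw = lam * (winf - w);
}

// Fixed-step RK4 integration of the Morris-Lecar oscillator with an
// optional rectangular current pulse and optional uniform noise on the bias
// current. The applied current is held constant within each internal
// substep, so a pulse onset aligned to the substep grid is reproduced
// exactly. Returns the membrane potential sampled every `dt` ms.
// [[Rcpp::export]]
NumericVector ml_integrate(NumericVector par, double duration, double dt,
                           int substeps, double stim_on, double stim_dur,
                           double stim_amp, double noise_amp,
                           double V0, double w0) {
  if (par.size() != 13) stop("expected 13 Morris-Lecar parameters");
  MLPar p = {par[0], par[1], par[2], par[3], par[4], par[5], par[6],
             par[7], par[8], par[9], par[10], par[11], par[12]};
  if (substeps < 1) stop("substeps must be >= 1");
  int n_out = (int) std::floor(duration / dt + 1e-9);
  if (n_out < 2) stop("duration too short for this sampling interval");
  double h = dt / substeps;
  NumericVector out(n_out);
  double V = V0, w = w0, t = 0.0;
  RNGScope scope;
  for (int i = 0; i < n_out; ++i) {
    out[i] = V;
    for (int s = 0; s < substeps; ++s) {
      double I = p.Ibias;
      if (noise_amp > 0.0) I += noise_amp * (2.0 * unif_rand() - 1.0);
      if (stim_amp != 0.0 && t >= stim_on - 1e-12 &&
          t < stim_on + stim_dur - 1e-12)
        I += stim_amp;
      double k1V, k1w, k2V, k2w, k3V, k3w, k4V, k4w;
      ml_deriv(p, V, w, I, k1V, k1w);
      ml_deriv(p, V + 0.5 * h * k1V, w + 0.5 * h * k1w, I, k2V, k2w);
      ml_deriv(p, V + 0.5 * h * k2V, w + 0.5 * h * k2w, I, k3V, k3w);
      ml_deriv(p, V + h * k3V, w + h * k3w, I, k4V, k4w);
      V += h / 6.0 * (k1V + 2.0 * k2V + 2.0 * k3V + k4V);
      w += h / 6.0 * (k1w + 2.0 * k2w + 2.0 * k3w + k4w);
      t += h;
    }
  }
  return out;
}

// Fixed-step RK4 integration of the Lorenz-63 system, used as a canonical
// three-dimensional deterministic fixture for embedding diagnostics.
// [[Rcpp::export]]
NumericMatrix lorenz_integrate(int n, double dt, double sigma, double rho,
                               double beta, NumericVector init,
                               int transient_steps, int substeps) {
  if (init.size() != 3) stop("init must have length 3");
  if (n < 2) stop("n must be >= 2");
  if (substeps < 1) stop("substeps must be >= 1");
  double x = init[0], y = init[1], z = init[2];
  double h = dt / substeps;
  NumericMatrix out(n, 3);
  long total = (long) (n + transient_steps);
  long kept = 0;
  for (long i = 0; i < total; ++i) {
    if (i >= transient_steps) {
      out(kept, 0) = x; out(kept, 1) = y; out(kept, 2) = z;
      ++kept;
    }
    for (int s = 0; s < substeps; ++s) {
      double k1x = sigma * (y - x);
      double k1y = x * (rho - z) - y;
      double k1z = x * y - beta * z;
      double x2 = x + 0.5 * h * k1x, y2 = y + 0.5 * h * k1y,
             z2 = z + 0.5 * h * k1z;
      double k2x = sigma * (y2 - x2);
      double k2y = x2 * (rho - z2) - y2;
      double k2z = x2 * y2 - beta * z2;
      double x3 = x + 0.5 * h * k2x, y3 = y + 0.5 * h * k2y,
             z3 = z + 0.5 * h * k2z;
      double k3x = sigma * (y3 - x3);
      double k3y = x3 * (rho - z3) - y3;
      double k3z = x3 * y3 - beta * z3;
      double x4 = x + h * k3x, y4 = y + h * k3y, z4 = z + h * k3z;
      double k4x = sigma * (y4 - x4);
      double k4y = x4 * (rho - z4) - y4;
      double k4z = x4 * y4 - beta * z4;
      x += h / 6.0 * (k1x + 2.0 * k2x + 2.0 * k3x + k4x);
      y += h / 6.0 * (k1y + 2.0 * k2y + 2.0 * k3y + k4y);
      z += h / 6.0 * (k1z + 2.0 * k2z + 2.0 * k3z + k4z);
    }
  }
  return out;
}
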