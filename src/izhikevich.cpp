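#include <Rcpp.h>
using namespace Rcpp;

// Forward-Euler integration of the two-variable spiking neuron
//   dv/dt = 0.04 v^2 + 5 v + 140 - u + I
//   du/dt = a (b v - u)
// with reset v <- c, u <- u + d when v reaches v_peak.
// One element of `I` per Euler step of size dt (ms). Spike time convention:
// the spike is stamped at the end of the step on which v crossed v_peak.

// [[Rcpp::export(name = ".izh_run_cpp")]]
List izh_run_cpp(NumericVector I, double a, double b, double c, double d,
                 double v_peak, double dt, double v0, double u0) {
  const R_xlen_t n = I.size();
  std::vector<int> spike_steps;
  double v = v0, u = u0;
  for (R_xlen_t i = 0; i < n; ++i) {
    double vn = v + dt * (0.04 * v * v + 5.0 * v + 140.0 - u + I[i]);
    double un = u + dt * a * (b * v - u);
    bool spiked = false;
    if (vn >= v_peak) {
      vn = c;
      un += d;
      spiked = true;
    }
    if (!std::isfinite(vn) || !std::isfinite(un))
      stop("izhikevich integration diverged at step %d (dt or input current "
           "outside the admissible range)", (int)(i + 1));
    v = vn;
    u = un;
    if (spiked) spike_steps.push_back((int)(i + 1));
  }
  return List::create(_["spike_steps"] = wrap(spike_steps),
                      _["v"] = v, _["u"] = u);
}
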