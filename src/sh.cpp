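#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Two-compartment algae-zooplankton model: logistic algal growth in both
// compartments, saturating (Monod) grazing in the grazed compartment only,
// linear exchange between compartments. Deterministic fixed-step RK4; the
// state is recorded once per unit time step.

namespace {

struct ShP {
  double r, K, g, h, e, m, d;
};

inline void rates(const ShP& p, const double* s, double* out) {
  double graze = p.g * s[2] * s[0] / (s[0] + p.h);
  out[0] = p.r * s[0] * (1.0 - s[0] / p.K) - graze + p.d * (s[1] - s[0]);
  out[1] = p.r * s[1] * (1.0 - s[1] / p.K) + p.d * (s[0] - s[1]);
  out[2] = p.e * graze - p.m * s[2];
}

} // namespace

// [[Rcpp::export]]
NumericMatrix sh_run_cpp(double A1, double A2, double Z, List params,
                         bool stop_at_extinction) {
  ShP p;
  p.r = params["r"]; p.K = params["K"]; p.g = params["g"];
  p.h = params["h"]; p.e = params["e"]; p.m = params["m"];
  p.d = params["d"];
  const double dt = params["dt"];
  const double z_eps = params["z_eps"];
  const int t_max = params["t_max"];
  const int sub = (int)std::lround(1.0 / dt);  // substeps per unit time

  double s[3] = {A1, A2, Z};
  if (s[2] < z_eps) s[2] = 0.0;
  std::vector<double> rec_t, rec_a1, rec_a2, rec_z;
  rec_t.reserve(t_max + 1);
  rec_t.push_back(0.0); rec_a1.push_back(s[0]);
  rec_a2.push_back(s[1]); rec_z.push_back(s[2]);

  double k1[3], k2[3], k3[3], k4[3], tmp[3];
  bool extinct = s[2] == 0.0;
  for (int step = 1; step <= t_max && !(stop_at_extinction && extinct);
       ++step) {
    for (int q = 0; q < sub; ++q) {
      rates(p, s, k1);
      for (int i = 0; i < 3; ++i) tmp[i] = s[i] + 0.5 * dt * k1[i];
      rates(p, tmp, k2);
      for (int i = 0; i < 3; ++i) tmp[i] = s[i] + 0.5 * dt * k2[i];
      rates(p, tmp, k3);
      for (int i = 0; i < 3; ++i) tmp[i] = s[i] + dt * k3[i];
      rates(p, tmp, k4);
      for (int i = 0; i < 3; ++i) {
        s[i] += dt / 6.0 * (k1[i] + 2 * k2[i] + 2 * k3[i] + k4[i]);
        if (s[i] < 0) s[i] = 0;
        if (!std::isfinite(s[i]))
          stop("non-finite state during integration; reduce dt (dt = %f)",
               dt);
      }
      if (s[2] < z_eps) s[2] = 0.0;  // extinction threshold is absorbing
    }
    extinct = s[2] == 0.0;
    rec_t.push_back((double)step);
    rec_a1.push_back(s[0]); rec_a2.push_back(s[1]); rec_z.push_back(s[2]);
  }

  NumericMatrix out((int)rec_t.size(), 4);
  for (size_t i = 0; i < rec_t.size(); ++i) {
    out(i, 0) = rec_t[i]; out(i, 1) = rec_a1[i];
    out(i, 2) = rec_a2[i]; out(i, 3) = rec_z[i];
  }
  colnames(out) = CharacterVector::create("tick", "A1", "A2", "Z");
  return out;
}
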