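// Fixed-step RK4 integration of the 2n-rotor torsional DNA model with the
// hydrogen-bond break/restore automaton. The right-hand side mirrors the
// R-level equations_rhs(); tests cross-check the two step by step.
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

namespace {

struct Model {
  int n;
  const double *I1, *I2, *K1, *K2, *R1, *R2, *k12, *b1, *b2, *ecr;
  double F0, omega;

  // accelerations for both chains at time t; delta gates pair coupling
  void accel(double t, const std::vector<double>& p1,
             const std::vector<double>& p2, const std::vector<double>& v1,
             const std::vector<double>& v2, const std::vector<int>& delta,
             std::vector<double>& a1, std::vector<double>& a2) const {
    const double f = F0 * std::cos(omega * t);
    for (int i = 0; i < n; ++i) {
      double bb1 = 0.0, bb2 = 0.0;
      if (i > 0) {
        bb1 += K1[i] * (p1[i - 1] - p1[i]);
        bb2 += K2[i] * (p2[i - 1] - p2[i]);
      }
      if (i < n - 1) {
        bb1 += K1[i] * (p1[i + 1] - p1[i]);
        bb2 += K2[i] * (p2[i + 1] - p2[i]);
      }
      double t1 = 0.0, t2 = 0.0;
      if (delta[i]) {
        const double r1 = R1[i], r2 = R2[i], k = k12[i];
        const double s12 = std::sin(p1[i] - p2[i]);
        t1 = k * (-r1 * (r1 + r2) * std::sin(p1[i]) + r1 * r2 * s12);
        t2 = k * (r2 * (r1 + r2) * std::sin(p2[i]) - r1 * r2 * s12);
      }
      a1[i] = (bb1 + t1 + f - b1[i] * v1[i]) / I1[i];
      a2[i] = (bb2 + t2 + f - b2[i] * v2[i]) / I2[i];
    }
  }

  // pair binding potential, full k12 regardless of delta, zero at (0, pi)
  double energy(int i, double p1, double p2) const {
    const double r1 = R1[i], r2 = R2[i];
    return k12[i] * ((r1 + r2) * (r1 + r2) + r1 * r2
                     - r1 * (r1 + r2) * std::cos(p1)
                     + r2 * (r1 + r2) * std::cos(p2)
                     + r1 * r2 * std::cos(p1 - p2));
  }
};

}  // namespace

// [[Rcpp::export(rng = false)]]
List rk4_bond_automaton(NumericVector I1, NumericVector I2,
                        NumericVector K1, NumericVector K2,
                        NumericVector R1, NumericVector R2,
                        NumericVector k12, NumericVector beta1,
                        NumericVector beta2, NumericVector Ecr,
                        NumericVector phi1_0, NumericVector phi2_0,
                        NumericVector v1_0, NumericVector v2_0,
                        IntegerVector delta_0, double F0, double omega,
                        double dt, int m, int steps_per_sample,
                        bool keep_trajectory) {
  const int n = I1.size();
  Model mod{n, I1.begin(), I2.begin(), K1.begin(), K2.begin(), R1.begin(),
            R2.begin(), k12.begin(), beta1.begin(), beta2.begin(),
            Ecr.begin(), F0, omega};

  std::vector<double> p1(phi1_0.begin(), phi1_0.end());
  std::vector<double> p2(phi2_0.begin(), phi2_0.end());
  std::vector<double> v1(v1_0.begin(), v1_0.end());
  std::vector<double> v2(v2_0.begin(), v2_0.end());
  std::vector<int> delta(delta_0.begin(), delta_0.end());

  std::vector<double> a1(n), a2(n), b1v(n), b2v(n), c1(n), c2(n), d1(n), d2(n);
  std::vector<double> pa1(n), pa2(n), va1(n), va2(n);
  std::vector<double> pb1(n), pb2(n), vb1(n), vb2(n);
  std::vector<double> pc1(n), pc2(n), vc1(n), vc2(n);

  NumericVector q(m);
  NumericMatrix tp1, tp2;
  IntegerMatrix td;
  if (keep_trajectory) {
    tp1 = NumericMatrix(m, n);
    tp2 = NumericMatrix(m, n);
    td = IntegerMatrix(m, n);
  }

  const long total_steps = static_cast<long>(m) * steps_per_sample;
  double t = 0.0;
  int sample = 0;
  for (long step = 1; step <= total_steps; ++step) {
    // RK4 stages; bond flags frozen within the step
    mod.accel(t, p1, p2, v1, v2, delta, a1, a2);            // k1
    for (int i = 0; i < n; ++i) {
      pa1[i] = p1[i] + 0.5 * dt * v1[i];
      pa2[i] = p2[i] + 0.5 * dt * v2[i];
      va1[i] = v1[i] + 0.5 * dt * a1[i];
      va2[i] = v2[i] + 0.5 * dt * a2[i];
    }
    mod.accel(t + 0.5 * dt, pa1, pa2, va1, va2, delta, b1v, b2v);  // k2
    for (int i = 0; i < n; ++i) {
      pb1[i] = p1[i] + 0.5 * dt * va1[i];
      pb2[i] = p2[i] + 0.5 * dt * va2[i];
      vb1[i] = v1[i] + 0.5 * dt * b1v[i];
      vb2[i] = v2[i] + 0.5 * dt * b2v[i];
    }
    mod.accel(t + 0.5 * dt, pb1, pb2, vb1, vb2, delta, c1, c2);    // k3
    for (int i = 0; i < n; ++i) {
      pc1[i] = p1[i] + dt * vb1[i];
      pc2[i] = p2[i] + dt * vb2[i];
      vc1[i] = v1[i] + dt * c1[i];
      vc2[i] = v2[i] + dt * c2[i];
    }
    mod.accel(t + dt, pc1, pc2, vc1, vc2, delta, d1, d2);          // k4
    for (int i = 0; i < n; ++i) {
      p1[i] += dt / 6.0 * (v1[i] + 2.0 * va1[i] + 2.0 * vb1[i] + vc1[i]);
      p2[i] += dt / 6.0 * (v2[i] + 2.0 * va2[i] + 2.0 * vb2[i] + vc2[i]);
      v1[i] += dt / 6.0 * (a1[i] + 2.0 * b1v[i] + 2.0 * c1[i] + d1[i]);
      v2[i] += dt / 6.0 * (a2[i] + 2.0 * b2v[i] + 2.0 * c2[i] + d2[i]);
    }
    t += dt;

    // break/restore automaton, once per full step, full k12 in the energy
    for (int i = 0; i < n; ++i) {
      if (!std::isfinite(p1[i]) || !std::isfinite(p2[i]) ||
          !std::isfinite(v1[i]) || !std::isfinite(v2[i]))
        return List::create(_["error_step"] = (double)step,
                            _["error_pair"] = i + 1);
      const double e = mod.energy(i, p1[i], p2[i]);
      if (e > mod.ecr[i]) delta[i] = 0;
      else if (e < mod.ecr[i]) delta[i] = 1;
    }

    if (step % steps_per_sample == 0) {
      int broken = 0;
      for (int i = 0; i < n; ++i) broken += (delta[i] == 0);
      q[sample] = static_cast<double>(broken) / n;
      if (keep_trajectory) {
        for (int i = 0; i < n; ++i) {
          tp1(sample, i) = p1[i];
          tp2(sample, i) = p2[i];
          td(sample, i) = delta[i];
        }
      }
      ++sample;
    }
  }

  List fin = List::create(_["phi1"] = NumericVector(p1.begin(), p1.end()),
                          _["phi2"] = NumericVector(p2.begin(), p2.end()),
                          _["v1"] = NumericVector(v1.begin(), v1.end()),
                          _["v2"] = NumericVector(v2.begin(), v2.end()),
                          _["delta"] = IntegerVector(delta.begin(), delta.end()));
  List out = List::create(_["q"] = q, _["final"] = fin,
                          _["error_step"] = R_NilValue);
  if (keep_trajectory) {
    out["phi1"] = tp1;
    out["phi2"] = tp2;
    out["delta"] = td;
  }
  return out;
}
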