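#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

// Gating-variable rate functions of the squid-axon HH model (1/ms).
// alpha_m and alpha_n have removable singularities at V = -40 and V = -55;
// near them (|x| < 1e-7) we use the analytic limit x/(1 - exp(-x/10)) -> 10.
static inline double alpha_m(double V) {
  double x = V + 40.0;
  if (std::fabs(x) < 1e-7) return 1.0;
  return 0.1 * x / (1.0 - std::exp(-x / 10.0));
}
static inline double beta_m(double V) { return 4.0 * std::exp(-(V + 65.0) / 18.0); }
static inline double alpha_n(double V) {
  double x = V + 55.0;
  if (std::fabs(x) < 1e-7) return 0.1;
  return 0.01 * x / (1.0 - std::exp(-x / 10.0));
}
static inline double beta_n(double V) { return 0.125 * std::exp(-(V + 65.0) / 80.0); }
static inline double alpha_h(double V) { return 0.07 * std::exp(-(V + 65.0) / 20.0); }
static inline double beta_h(double V) { return 1.0 / (1.0 + std::exp(-(V + 35.0) / 10.0)); }

// [[Rcpp::export]]
NumericMatrix gating_rates_cpp(NumericVector V) {
  int nv = V.size();
  NumericMatrix out(nv, 6);
  for (int i = 0; i < nv; ++i) {
    double v = V[i];
    out(i, 0) = alpha_m(v); out(i, 1) = beta_m(v);
    out(i, 2) = alpha_n(v); out(i, 3) = beta_n(v);
    out(i, 4) = alpha_h(v); out(i, 5) = beta_h(v);
  }
  colnames(out) = CharacterVector::create("alpha_m", "beta_m", "alpha_n",
                                          "beta_n", "alpha_h", "beta_h");
  return out;
}

struct HHP {
  double C, gNa, gK, gl, ENa, EK, El;
};

// Derivatives of the full network state. Coupling: neuron j receives
// k * sum_i C_ij (V_i - V_j) over presynaptic i (directed edges i -> j).
static void network_deriv(int n, const HHP &p,
                          const std::vector<std::vector<int> > &pre,
                          const double *I, double k,
                          const double *V, const double *m,
                          const double *nn, const double *h,
                          double *dV, double *dm, double *dn, double *dh) {
  for (int j = 0; j < n; ++j) {
    double v = V[j];
    double iNa = p.gNa * m[j] * m[j] * m[j] * h[j] * (v - p.ENa);
    double iK  = p.gK * nn[j] * nn[j] * nn[j] * nn[j] * (v - p.EK);
    double il  = p.gl * (v - p.El);
    double gap = 0.0;
    const std::vector<int> &pj = pre[j];
    for (size_t e = 0; e < pj.size(); ++e) gap += V[pj[e]] - v;
    dV[j] = (I[j] - iNa - iK - il + k * gap) / p.C;
    dm[j] = alpha_m(v) * (1.0 - m[j]) - beta_m(v) * m[j];
    dn[j] = alpha_n(v) * (1.0 - nn[j]) - beta_n(v) * nn[j];
    dh[j] = alpha_h(v) * (1.0 - h[j]) - beta_h(v) * h[j];
  }
}

// Fixed-step RK4 (or Euler) integration of a gap-junction-coupled HH network.
// edges_from/edges_to are 0-based; an edge i -> j couples V_i into neuron j.
// Noise: one N(mean, sd) draw per neuron per step (optionally scaled by
// 1/sqrt(dt)), held constant across the RK4 stages of that step, added to the
// stimulus current. Uses R's RNG so set.seed() governs reproducibility.
// Recording: every `stride` steps (plus t = 0); gating variables recorded only
// if record_gates. Throws if any gating variable leaves [0,1] by > 1e-6
// (integration instability), naming the offending time.
// [[Rcpp::export]]
List hh_simulate_cpp(int n, IntegerVector edges_from, IntegerVector edges_to,
                     NumericVector I_applied, double k, NumericVector params,
                     NumericVector V0, NumericVector m0, NumericVector n0,
                     NumericVector h0, double dt, int nsteps, int stride,
                     bool euler, bool noise_on, double noise_mean,
                     double noise_sd, bool noise_sqrt_dt, bool record_gates) {
  HHP p;
  p.C = params[0]; p.gNa = params[1]; p.gK = params[2]; p.gl = params[3];
  p.ENa = params[4]; p.EK = params[5]; p.El = params[6];

  std::vector<std::vector<int> > pre(n);
  for (int e = 0; e < edges_from.size(); ++e)
    pre[edges_to[e]].push_back(edges_from[e]);

  int nsamp = nsteps / stride + 1;
  NumericMatrix Vrec(nsamp, n);
  NumericMatrix mrec(record_gates ? nsamp : 1, record_gates ? n : 1);
  NumericMatrix nrec(record_gates ? nsamp : 1, record_gates ? n : 1);
  NumericMatrix hrec(record_gates ? nsamp : 1, record_gates ? n : 1);
  NumericVector times(nsamp);

  std::vector<double> V(V0.begin(), V0.end()), m(m0.begin(), m0.end()),
      nn(n0.begin(), n0.end()), h(h0.begin(), h0.end());
  std::vector<double> Ieff(I_applied.begin(), I_applied.end());
  std::vector<double> k1V(n), k1m(n), k1n(n), k1h(n), k2V(n), k2m(n), k2n(n),
      k2h(n), k3V(n), k3m(n), k3n(n), k3h(n), k4V(n), k4m(n), k4n(n), k4h(n),
      tV(n), tm(n), tn(n), th(n);

  double noise_scale = noise_sqrt_dt ? 1.0 / std::sqrt(dt) : 1.0;
  RNGScope rng;

  int isamp = 0;
  for (int j = 0; j < n; ++j) {
    Vrec(0, j) = V[j];
    if (record_gates) { mrec(0, j) = m[j]; nrec(0, j) = nn[j]; hrec(0, j) = h[j]; }
  }
  times[0] = 0.0;
  isamp = 1;

  for (int step = 0; step < nsteps; ++step) {
    if (noise_on) {
      for (int j = 0; j < n; ++j)
        Ieff[j] = I_applied[j] + noise_mean + noise_sd * noise_scale * R::norm_rand();
    }
    const double *Iptr = Ieff.data();

    network_deriv(n, p, pre, Iptr, k, V.data(), m.data(), nn.data(), h.data(),
                  k1V.data(), k1m.data(), k1n.data(), k1h.data());
    if (euler) {
      for (int j = 0; j < n; ++j) {
        V[j] += dt * k1V[j]; m[j] += dt * k1m[j];
        nn[j] += dt * k1n[j]; h[j] += dt * k1h[j];
      }
    } else {
      for (int j = 0; j < n; ++j) {
        tV[j] = V[j] + 0.5 * dt * k1V[j]; tm[j] = m[j] + 0.5 * dt * k1m[j];
        tn[j] = nn[j] + 0.5 * dt * k1n[j]; th[j] = h[j] + 0.5 * dt * k1h[j];
      }
      network_deriv(n, p, pre, Iptr, k, tV.data(), tm.data(), tn.data(), th.data(),
                    k2V.data(), k2m.data(), k2n.data(), k2h.data());
      for (int j = 0; j < n; ++j) {
        tV[j] = V[j] + 0.5 * dt * k2V[j]; tm[j] = m[j] + 0.5 * dt * k2m[j];
        tn[j] = nn[j] + 0.5 * dt * k2n[j]; th[j] = h[j] + 0.5 * dt * k2h[j];
      }
      network_deriv(n, p, pre, Iptr, k, tV.data(), tm.data(), tn.data(), th.data(),
                    k3V.data(), k3m.data(), k3n.data(), k3h.data());
      for (int j = 0; j < n; ++j) {
        tV[j] = V[j] + dt * k3V[j]; tm[j] = m[j] + dt * k3m[j];
        tn[j] = nn[j] + dt * k3n[j]; th[j] = h[j] + dt * k3h[j];
      }
      network_deriv(n, p, pre, Iptr, k, tV.data(), tm.data(), tn.data(), th.data(),
                    k4V.data(), k4m.data(), k4n.data(), k4h.data());
      double w = dt / 6.0;
      for (int j = 0; j < n; ++j) {
        V[j] += w * (k1V[j] + 2.0 * k2V[j] + 2.0 * k3V[j] + k4V[j]);
        m[j] += w * (k1m[j] + 2.0 * k2m[j] + 2.0 * k3m[j] + k4m[j]);
        nn[j] += w * (k1n[j] + 2.0 * k2n[j] + 2.0 * k3n[j] + k4n[j]);
        h[j] += w * (k1h[j] + 2.0 * k2h[j] + 2.0 * k3h[j] + k4h[j]);
      }
    }

    if ((step + 1) % stride == 0) {
      double tnow = (step + 1) * dt;
      for (int j = 0; j < n; ++j) {
        if (m[j] < -1e-6 || m[j] > 1.0 + 1e-6 || nn[j] < -1e-6 ||
            nn[j] > 1.0 + 1e-6 || h[j] < -1e-6 || h[j] > 1.0 + 1e-6 ||
            !std::isfinite(V[j]))
          stop("integration instability: gating variable outside [0,1] at t = %f ms (neuron %d); reduce dt",
               tnow, j + 1);
        Vrec(isamp, j) = V[j];
        if (record_gates) {
          mrec(isamp, j) = m[j]; nrec(isamp, j) = nn[j]; hrec(isamp, j) = h[j];
        }
      }
      times[isamp] = tnow;
      ++isamp;
    }
  }

  List out = List::create(_["times"] = times, _["V"] = Vrec);
  if (record_gates) {
    out["m"] = mrec; out["n"] = nrec; out["h"] = hrec;
  }
  return out;
}
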