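// Forward-Euler integration loop for Izhikevich point-neuron circuits.
//
// The loop is deliberately self-contained: it carries its own counter-based
// RNG (xoshiro256++ seeded through splitmix64) so that a simulation is a pure
// function of its seed, independent of R's RNG state, and fast enough that a
// full 21x21 input grid stays tractable on one CPU.

#include <Rcpp.h>
#include <cstdint>
#include <cmath>
#include <vector>

using namespace Rcpp;

namespace {

// ---- RNG -------------------------------------------------------------------

struct Xoshiro256pp {
  uint64_t s[4];

  explicit Xoshiro256pp(uint64_t seed) {
    // splitmix64 expansion of the seed into the state
    uint64_t x = seed;
    for (int i = 0; i < 4; ++i) {
      x += 0x9e3779b97f4a7c15ULL;
      uint64_t z = x;
      z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
      z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
      s[i] = z ^ (z >> 31);
    }
  }

  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }

  inline uint64_t next() {
    const uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0];
    s[3] ^= s[1];
    s[1] ^= s[2];
    s[0] ^= s[3];
    s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return result;
  }

  // uniform on (0,1); never exactly 0 (53-bit mantissa + offset)
  inline double unif() {
    return ((next() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }

  bool have_spare = false;
  double spare = 0.0;

  // Marsaglia polar method
  inline double norm() {
    if (have_spare) { have_spare = false; return spare; }
    double u, v, s2;
    do {
      u = 2.0 * unif() - 1.0;
      v = 2.0 * unif() - 1.0;
      s2 = u * u + v * v;
    } while (s2 >= 1.0 || s2 == 0.0);
    double m = std::sqrt(-2.0 * std::log(s2) / s2);
    spare = v * m;
    have_spare = true;
    return u * m;
  }

  // Knuth inversion; fine for the small means used here (rate*dt <= ~1)
  inline int pois(double exp_neg_lambda) {
    if (exp_neg_lambda >= 1.0) return 0;
    int k = 0;
    double p = unif();
    while (p > exp_neg_lambda) {
      ++k;
      p *= unif();
    }
    return k;
  }
};

} // namespace

// [[Rcpp::export(name = ".sim_core_cpp")]]
List sim_core_cpp(NumericVector a, NumericVector b, NumericVector c_,
                  NumericVector d, IntegerVector type, NumericVector v0,
                  NumericVector u0, IntegerVector syn_ptr,
                  IntegerVector syn_post, NumericVector syn_w,
                  NumericVector tau_pre, NumericVector drive_rate,
                  NumericVector noise_offset, double noise_sd,
                  double tau_drive, double dt, int n_steps, int delay_steps,
                  double seed, NumericMatrix schedule, bool lfp_clip) {
  const int n = a.size();
  if (b.size() != n || c_.size() != n || d.size() != n || type.size() != n ||
      v0.size() != n || u0.size() != n || drive_rate.size() != n ||
      noise_offset.size() != n)
    stop("per-neuron argument lengths differ");
  if (syn_ptr.size() != n + 1) stop("syn_ptr must have length n + 1");
  if (dt <= 0) stop("dt must be positive");

  const int n_types = tau_pre.size();
  std::vector<double> decay_syn(n_types);
  for (int t = 0; t < n_types; ++t) decay_syn[t] = std::exp(-dt / tau_pre[t]);
  const double decay_drive = std::exp(-dt / tau_drive);

  std::vector<double> V(v0.begin(), v0.end());
  std::vector<double> U(u0.begin(), u0.end());
  // one decaying trace per presynaptic type per postsynaptic neuron
  std::vector<std::vector<double>> g(n_types, std::vector<double>(n, 0.0));
  std::vector<double> g_drive(n, 0.0);

  // Poisson drive ring buffer: counts drawn at step s arrive at s+delay
  const int ring = delay_steps + 1;
  std::vector<std::vector<int>> drive_ring(ring, std::vector<int>(n, 0));

  // schedule bookkeeping: per-neuron extra rate / extra current, recomputed
  // lazily whenever a segment boundary is crossed
  const int n_seg = schedule.nrow();
  std::vector<double> lambda(n), exp_neg_lambda(n), extra_current(n, 0.0);
  std::vector<int> boundaries;
  for (int i = 0; i < n_seg; ++i) {
    boundaries.push_back((int)schedule(i, 1));
    boundaries.push_back((int)schedule(i, 2));
  }
  boundaries.push_back(0);

  auto refresh_inputs = [&](int step) {
    std::vector<double> rate_add(n_types, 0.0), cur_add(n_types, 0.0);
    for (int i = 0; i < n_seg; ++i) {
      if (step >= (int)schedule(i, 1) && step < (int)schedule(i, 2)) {
        int pop = (int)schedule(i, 0);
        if (pop >= 0 && pop < n_types) {
          rate_add[pop] += schedule(i, 3);
          cur_add[pop] += schedule(i, 4);
        }
      }
    }
    for (int i = 0; i < n; ++i) {
      double r = drive_rate[i] + rate_add[type[i]];
      if (r < 0) r = 0;
      lambda[i] = r * dt / 1000.0;
      exp_neg_lambda[i] = std::exp(-lambda[i]);
      extra_current[i] = cur_add[type[i]];
    }
  };
  refresh_inputs(0);

  Xoshiro256pp rng((uint64_t)seed);

  std::vector<int> spike_id;
  std::vector<int> spike_step;
  spike_id.reserve(n * 64);
  spike_step.reserve(n * 64);
  // per-step offsets into the spike arrays, for the delay line
  std::vector<int> step_ptr(n_steps + 1, 0);

  NumericVector lfp(n_steps);

  for (int s = 0; s < n_steps; ++s) {
    for (int bd : boundaries)
      if (s == bd && n_seg > 0) { refresh_inputs(s); break; }

    // 1. decay synaptic and drive traces
    for (int t = 0; t < n_types; ++t) {
      double dec = decay_syn[t];
      double* gt = g[t].data();
      for (int i = 0; i < n; ++i) gt[i] *= dec;
    }
    for (int i = 0; i < n; ++i) g_drive[i] *= decay_drive;

    // 2. deliver recurrent spikes fired delay_steps ago
    int s_from = s - delay_steps;
    if (s_from >= 0) {
      for (int k = step_ptr[s_from]; k < step_ptr[s_from + 1]; ++k) {
        int j = spike_id[k];
        double* gt = g[type[j]].data();
        for (int e = syn_ptr[j]; e < syn_ptr[j + 1]; ++e)
          gt[syn_post[e]] += syn_w[e];
      }
    }

    // 3. Poisson drive: draw this step's counts, deliver the delayed slot
    int slot_now = s % ring;
    int slot_arrive = (s - delay_steps) >= 0 ? (s - delay_steps) % ring : -1;
    for (int i = 0; i < n; ++i) {
      int cnt = lambda[i] > 0 ? rng.pois(exp_neg_lambda[i]) : 0;
      if (delay_steps == 0) {
        g_drive[i] += cnt;
      } else {
        if (slot_arrive >= 0) g_drive[i] += drive_ring[slot_arrive][i];
        drive_ring[slot_now][i] = cnt;
      }
    }

    // 4. Euler update, spike detection / reset, LFP sample
    double lfp_sum = 0.0;
    for (int i = 0; i < n; ++i) {
      double I = g_drive[i] + noise_offset[i] + extra_current[i];
      for (int t = 0; t < n_types; ++t) I += g[t][i];
      if (noise_sd > 0) I += noise_sd * rng.norm();
      double v = V[i], u = U[i];
      double vn = v + dt * (0.04 * v * v + 5.0 * v + 140.0 - u + I);
      double un = u + dt * (a[i] * (b[i] * v - u));
      if (!std::isfinite(vn) || !std::isfinite(un))
        stop("non-finite state at step %d, neuron %d", s + 1, i + 1);
      if (vn >= 30.0) {
        spike_id.push_back(i);
        spike_step.push_back(s);
        lfp_sum += lfp_clip ? 30.0 : vn;
        vn = c_[i];
        un += d[i];
      } else {
        lfp_sum += vn;
      }
      V[i] = vn;
      U[i] = un;
    }
    lfp[s] = n > 0 ? lfp_sum / n : NA_REAL;
    step_ptr[s + 1] = (int)spike_id.size();
  }

  return List::create(
      _["spike_id"] = IntegerVector(spike_id.begin(), spike_id.end()),
      _["spike_step"] = IntegerVector(spike_step.begin(), spike_step.end()),
      _["lfp"] = lfp, _["v_final"] = NumericVector(V.begin(), V.end()),
      _["u_final"] = NumericVector(U.begin(), U.end()));
}
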