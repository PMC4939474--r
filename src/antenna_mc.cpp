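// Kinetic Monte Carlo core for three-pathway proton exchange on a nanodisc.
//
// Geometry: a reflecting disc of radius R_disc (nm) with the protonatable dye
// at the center inside a capture radius a_f. Surface protons appear as a
// Poisson process (pathway I inward), perform 2D Brownian steps with per-axis
// variance 2 D_s dt, desorb per step with probability k_des*dt, and protonate
// the dye on entering the capture radius while it is deprotonated
// (pathway II). Independently the dye exchanges protons directly with
// bulk/buffer at first-order rates r_on_III / r_off (pathway III and
// deprotonation). Dye transitions are sampled event-driven; surface dynamics
// are time-stepped. When no surface proton is present the clock jumps
// directly to the next scheduled event.

#include <Rcpp.h>
#include <random>
#include <vector>
#include <cmath>
#include <limits>

using namespace Rcpp;

static const double INF = std::numeric_limits<double>::infinity();

// xoshiro256++ with splitmix64 seeding; normals by the cached polar method
struct Rng {
  uint64_t s[4];
  bool have_spare = false;
  double spare = 0.0;
  explicit Rng(uint64_t seed) {
    // splitmix64 expansion of the seed into the state
    uint64_t z = seed;
    for (int i = 0; i < 4; ++i) {
      z += 0x9e3779b97f4a7c15ULL;
      uint64_t t = z;
      t = (t ^ (t >> 30)) * 0xbf58476d1ce4e5b9ULL;
      t = (t ^ (t >> 27)) * 0x94d049bb133111ebULL;
      s[i] = t ^ (t >> 31);
    }
  }
  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  inline uint64_t next() {
    uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return result;
  }
  inline double runif() { // in (0, 1]
    return ((next() >> 11) + 1) * 0x1.0p-53;
  }
  inline double rnorm() {
    if (have_spare) { have_spare = false; return spare; }
    double u, v, q;
    do {
      u = 2.0 * runif() - 1.0;
      v = 2.0 * runif() - 1.0;
      q = u * u + v * v;
    } while (q >= 1.0 || q == 0.0);
    double f = std::sqrt(-2.0 * std::log(q) / q);
    spare = v * f;
    have_spare = true;
    return u * f;
  }
  inline double rexp(double rate) {
    if (rate <= 0.0) return INF;
    return -std::log(runif()) / rate;
  }
  // number of Bernoulli(p) trials up to and including the first success
  inline double rgeom_steps(double p) {
    if (p <= 0.0) return INF;
    return std::floor(std::log(runif()) / std::log1p(-p)) + 1.0;
  }
};

// reflect a radial excursion beyond R back inside
static inline void reflect_edge(double &x, double &y, double R) {
  double r2 = x * x + y * y;
  if (r2 > R * R) {
    double r = std::sqrt(r2);
    double rn = 2.0 * R - r;
    if (rn < 0.0) rn = 0.0;
    double s = rn / r;
    x *= s;
    y *= s;
  }
}

// Capture test for one Brownian step towards an absorbing radius a_f:
// direct hit if the endpoint lies inside; otherwise a Brownian-bridge
// crossing probability exp(-d0 d1 / (D dt)) corrects for passages through
// the trap between sampled positions (removes most of the time-step bias).
static inline bool capture_step(Rng &rng, double r0_2, double r1_2,
                                double a_f, double a2, double Ddt) {
  if (r1_2 <= a2) return true;
  double d0 = std::sqrt(r0_2) - a_f;
  double d1 = std::sqrt(r1_2) - a_f;
  if (d0 <= 0.0) return true;
  if (d0 * d1 < 20.0 * Ddt) {
    return rng.runif() < std::exp(-d0 * d1 / Ddt);
  }
  return false;
}

// [[Rcpp::export]]
List mc_simulate_cpp(double R_disc, double a_f, double D_s, double k_des,
                     double k_ads_rate, double r_on_III, double r_off,
                     double dt, int min_events, double t_max,
                     double seed, int n_boot) {
  Rng rng(static_cast<uint64_t>(seed));

  const double step_sd = std::sqrt(2.0 * D_s * dt);
  const double p_des = k_des * dt;
  const double a2 = a_f * a_f;

  std::vector<double> px, py, plife; // plife: remaining steps to desorption
  px.reserve(64);
  py.reserve(64);
  plife.reserve(64);

  bool dye_prot = false;
  double t = 0.0, dwell_start = 0.0;
  double t_ads = rng.rexp(k_ads_rate);
  double t_dye = rng.rexp(r_on_III);

  std::vector<double> deprot_dwell, prot_dwell;
  deprot_dwell.reserve(min_events + 8);
  prot_dwell.reserve(min_events + 8);
  long n_II = 0, n_III = 0;

  auto add_proton = [&]() {
    double r = R_disc * std::sqrt(rng.runif());
    double th = 2.0 * M_PI * rng.runif();
    px.push_back(r * std::cos(th));
    py.push_back(r * std::sin(th));
    plife.push_back(rng.rgeom_steps(p_des));
  };

  auto protonate = [&](double when, bool via_surface) {
    deprot_dwell.push_back(when - dwell_start);
    dwell_start = when;
    dye_prot = true;
    if (via_surface) ++n_II; else ++n_III;
    t_dye = when + rng.rexp(r_off);
  };
  auto deprotonate = [&](double when) {
    prot_dwell.push_back(when - dwell_start);
    dwell_start = when;
    dye_prot = false; // released proton goes to bulk
    t_dye = when + rng.rexp(r_on_III);
  };

  bool done = false;
  while (!done) {
    if ((long)deprot_dwell.size() >= min_events &&
        (long)prot_dwell.size() >= min_events) break;
    if (t >= t_max) break;

    if (px.empty()) {
      double t_next = std::min(t_ads, t_dye);
      if (t_next == INF || t_next >= t_max) { t = t_max; break; }
      t = t_next;
      if (t_ads <= t_dye) {
        add_proton();
        t_ads = t + rng.rexp(k_ads_rate);
      } else if (dye_prot) {
        deprotonate(t);
      } else {
        protonate(t, false);
      }
    } else {
      double t_end = t + dt;
      // Brownian step + desorption + capture for each surface proton
      for (size_t i = 0; i < px.size();) {
        double r0_2 = px[i] * px[i] + py[i] * py[i];
        px[i] += step_sd * rng.rnorm();
        py[i] += step_sd * rng.rnorm();
        reflect_edge(px[i], py[i], R_disc);
        double r1_2 = px[i] * px[i] + py[i] * py[i];
        bool remove = false;
        if (!dye_prot &&
            capture_step(rng, r0_2, r1_2, a_f, a2, D_s * dt)) {
          protonate(t_end, true);
          remove = true;
        } else if (--plife[i] <= 0.0) { // desorption
          remove = true;
        }
        if (remove) {
          px[i] = px.back(); px.pop_back();
          py[i] = py.back(); py.pop_back();
          plife[i] = plife.back(); plife.pop_back();
        } else {
          ++i;
        }
      }
      if (t_ads <= t_end) {
        add_proton();
        t_ads = t_end + rng.rexp(k_ads_rate);
      }
      if (t_dye <= t_end) {
        if (dye_prot) deprotonate(t_dye); else protonate(t_dye, false);
      }
      t = t_end;
    }
  }

  long n_on = (long)deprot_dwell.size();
  long n_off = (long)prot_dwell.size();
  bool under = (n_on < min_events || n_off < min_events);

  double sum_on = 0.0, sum_off = 0.0;
  for (double d : deprot_dwell) sum_on += d;
  for (double d : prot_dwell) sum_off += d;
  double k_on_eff = (n_on > 0 && sum_on > 0) ? (double)n_on / sum_on : NA_REAL;
  double k_off_eff = (n_off > 0 && sum_off > 0) ? (double)n_off / sum_off : NA_REAL;

  // bootstrap SE of k_prot over the dwell samples
  double se = NA_REAL;
  if (n_on > 1 && n_off > 1) {
    std::vector<double> kp(n_boot);
    for (int b = 0; b < n_boot; ++b) {
      double s_on = 0.0, s_off = 0.0;
      for (long i = 0; i < n_on; ++i)
        s_on += deprot_dwell[(size_t)(rng.runif() * n_on) % n_on];
      for (long i = 0; i < n_off; ++i)
        s_off += prot_dwell[(size_t)(rng.runif() * n_off) % n_off];
      kp[b] = (double)n_on / s_on + (double)n_off / s_off;
    }
    double m = 0.0;
    for (double v : kp) m += v;
    m /= n_boot;
    double ss = 0.0;
    for (double v : kp) ss += (v - m) * (v - m);
    se = std::sqrt(ss / (n_boot - 1));
  }

  return List::create(
    _["k_on_eff"] = k_on_eff, _["k_off_eff"] = k_off_eff,
    _["se_k_prot"] = se,
    _["n_on_events"] = (double)n_on, _["n_off_events"] = (double)n_off,
    _["n_pathway_II"] = (double)n_II, _["n_pathway_III"] = (double)n_III,
    _["sum_deprot_dwell"] = sum_on, _["sum_prot_dwell"] = sum_off,
    _["under_converged"] = under);
}

// [[Rcpp::export]]
List mc_capture_prob_cpp(double R_disc, double a_f, double D_s, double k_des,
                         int n_walkers, double dt, double seed,
                         double max_steps) {
  Rng rng(static_cast<uint64_t>(seed));
  const double step_sd = std::sqrt(2.0 * D_s * dt);
  const double p_des = k_des * dt;
  const double a2 = a_f * a_f;
  long captured = 0;
  for (int w = 0; w < n_walkers; ++w) {
    double r = R_disc * std::sqrt(rng.runif());
    double th = 2.0 * M_PI * rng.runif();
    double x = r * std::cos(th), y = r * std::sin(th);
    double life = rng.rgeom_steps(p_des);
    if (life > max_steps) life = max_steps;
    if (x * x + y * y <= a2) { ++captured; continue; }
    for (double s = 0; s < life; ++s) {
      double r0_2 = x * x + y * y;
      x += step_sd * rng.rnorm();
      y += step_sd * rng.rnorm();
      reflect_edge(x, y, R_disc);
      if (capture_step(rng, r0_2, x * x + y * y, a_f, a2, D_s * dt)) {
        ++captured;
        break;
      }
    }
  }
  double p = (double)captured / n_walkers;
  double sep = std::sqrt(std::max(p * (1.0 - p) / n_walkers, 1e-300));
  return List::create(_["p"] = p, _["se"] = sep,
                      _["n_walkers"] = (double)n_walkers);
}
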