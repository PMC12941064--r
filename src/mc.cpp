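// Multilayer Monte Carlo photon transport for infinitely wide layered slabs.
// Weighted (implicit-capture) walk with Russian roulette, MCML-style:
// pencil beam at normal incidence, Henyey-Greenstein scattering, unpolarized
// Fresnel boundaries. Only the depth coordinate matters (layers are laterally
// infinite), so no radial tracking is done.

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <vector>

using namespace Rcpp;

// --- counter-based RNG -------------------------------------------------------
// Each photon owns an independent splitmix64 stream keyed by (seed, stream,
// photon index), so results do not depend on batching or evaluation order.

static inline uint64_t splitmix64_next(uint64_t &state) {
  uint64_t z = (state += 0x9E3779B97F4A7C15ULL);
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

static inline uint64_t mix_key(uint64_t a, uint64_t b) {
  uint64_t s = a * 0x9E3779B97F4A7C15ULL + b;
  // run a few scramble rounds so nearby keys decorrelate
  splitmix64_next(s);
  splitmix64_next(s);
  return s;
}

struct Rng {
  uint64_t state;
  explicit Rng(uint64_t key) : state(key) {}
  // uniform on [0, 1)
  double u01() {
    return (splitmix64_next(state) >> 11) * (1.0 / 9007199254740992.0);
  }
  // uniform on (0, 1]: safe for log()
  double u01_open0() { return 1.0 - u01(); }
};

// --- physics helpers ---------------------------------------------------------

// Unpolarized Fresnel reflectance for incidence cosine cos_i (>= 0).
static double fresnel(double ni, double nt, double cos_i) {
  if (ni == nt) return 0.0;
  if (cos_i > 1.0) cos_i = 1.0;
  if (cos_i < 0.0) cos_i = 0.0;
  double sin_i = std::sqrt(std::max(0.0, 1.0 - cos_i * cos_i));
  double sin_t = ni / nt * sin_i;
  if (sin_t >= 1.0) return 1.0;  // total internal reflection
  double cos_t = std::sqrt(std::max(0.0, 1.0 - sin_t * sin_t));
  double rs = (ni * cos_i - nt * cos_t) / (ni * cos_i + nt * cos_t);
  double rp = (ni * cos_t - nt * cos_i) / (ni * cos_t + nt * cos_i);
  return 0.5 * (rs * rs + rp * rp);
}

// Henyey-Greenstein deflection cosine via the analytic inverse CDF.
static inline double hg_cosine(double g, double u) {
  if (g == 0.0) return 2.0 * u - 1.0;
  double f = (1.0 - g * g) / (1.0 - g + 2.0 * g * u);
  double c = (1.0 + g * g - f * f) / (2.0 * g);
  if (c > 1.0) c = 1.0;
  if (c < -1.0) c = -1.0;
  return c;
}

// [[Rcpp::export]]
double fresnel_cpp(double n1, double n2, double cos_theta_i) {
  return fresnel(n1, n2, cos_theta_i);
}

// [[Rcpp::export]]
NumericVector hg_cosine_cpp(double g, NumericVector u) {
  int n = u.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = hg_cosine(g, u[i]);
  return out;
}

// --- transport ---------------------------------------------------------------

struct Tally {
  double diffuse = 0.0;
  double transmitted = 0.0;
  double absorbed = 0.0;
};

// [[Rcpp::export]]
List mc_simulate_cpp(NumericVector mua, NumericVector mus, NumericVector g,
                     NumericVector n, NumericVector d,
                     double ambient_n_top, double ambient_n_bottom,
                     double n_photons, int seed, int stream,
                     double roulette_threshold, int roulette_m) {
  const int L = mua.size();
  std::vector<double> z0(L), z1(L);
  double z = 0.0;
  for (int i = 0; i < L; ++i) {
    z0[i] = z;
    z += d[i];
    z1[i] = z;
  }

  // specular reflection of the normally incident pencil beam at the top surface
  double rsp = fresnel(ambient_n_top, n[0], 1.0);
  const double w_launch = 1.0 - rsp;
  const double inv_m = 1.0 / static_cast<double>(roulette_m);
  const long long ntot = static_cast<long long>(n_photons);

  // hot-loop constants per layer
  std::vector<double> inv_mut(L), p_abs(L);
  for (int i = 0; i < L; ++i) {
    double mut = mua[i] + mus[i];
    inv_mut[i] = (mut > 0.0) ? 1.0 / mut : R_PosInf;
    p_abs[i] = (mut > 0.0) ? mua[i] / mut : 0.0;
  }

  Tally tally;
  const uint64_t base =
      mix_key(static_cast<uint64_t>(static_cast<uint32_t>(seed)),
              static_cast<uint64_t>(static_cast<uint32_t>(stream)) << 32);

  for (long long p = 0; p < ntot; ++p) {
    Rng rng(mix_key(base, static_cast<uint64_t>(p)));
    double w = w_launch;
    double pz = 0.0, ux = 0.0, uy = 0.0, uz = 1.0;
    int layer = 0;
    bool alive = true;
    long max_iter = 100000000L;  // safety net against degenerate configs

    while (alive && max_iter-- > 0) {
      double db;  // distance to boundary along the flight direction
      double zb;  // boundary depth hit
      int dir;    // -1 going up, +1 going down, 0 parallel
      if (uz > 0.0) {
        db = (z1[layer] - pz) / uz;
        zb = z1[layer];
        dir = 1;
      } else if (uz < 0.0) {
        db = (z0[layer] - pz) / uz;
        zb = z0[layer];
        dir = -1;
      } else {
        db = R_PosInf;
        zb = pz;
        dir = 0;
      }

      double s = -std::log(rng.u01_open0()) * inv_mut[layer];

      if (s < db) {
        // interaction inside the layer
        pz += s * uz;
        double dw = w * p_abs[layer];
        tally.absorbed += dw;
        w -= dw;

        // scatter: HG deflection + uniform azimuth.
        // Azimuth via rejection in the unit disk with the angle-doubling
        // identity (cos 2t, sin 2t) -- no trig calls.
        double ct = hg_cosine(g[layer], rng.u01());
        double st = std::sqrt(std::max(0.0, 1.0 - ct * ct));
        double cp, sp;
        for (;;) {
          double a = 2.0 * rng.u01() - 1.0;
          double bb = 2.0 * rng.u01() - 1.0;
          double r2 = a * a + bb * bb;
          if (r2 > 0.0 && r2 < 1.0) {
            cp = (a * a - bb * bb) / r2;
            sp = 2.0 * a * bb / r2;
            break;
          }
        }
        if (std::fabs(uz) > 0.99999) {
          ux = st * cp;
          uy = st * sp;
          uz = (uz >= 0.0) ? ct : -ct;
        } else {
          double den = std::sqrt(1.0 - uz * uz);
          double nux = st * (ux * uz * cp - uy * sp) / den + ux * ct;
          double nuy = st * (uy * uz * cp + ux * sp) / den + uy * ct;
          double nuz = -st * cp * den + uz * ct;
          double norm = std::sqrt(nux * nux + nuy * nuy + nuz * nuz);
          ux = nux / norm;
          uy = nuy / norm;
          uz = nuz / norm;
        }

        // Russian roulette on low weight
        if (w < roulette_threshold) {
          if (rng.u01() < inv_m) {
            w *= roulette_m;
          } else {
            tally.absorbed += w;
            alive = false;
          }
        }
      } else {
        // boundary hit
        if (dir == 0) {  // glass-layer corner case: flight parallel to slabs
          tally.absorbed += w;
          break;
        }
        pz = zb;
        double ni = n[layer];
        double nt = (dir < 0)
                        ? (layer == 0 ? ambient_n_top : n[layer - 1])
                        : (layer == L - 1 ? ambient_n_bottom : n[layer + 1]);
        double cos_i = std::fabs(uz);
        double R = fresnel(ni, nt, cos_i);
        if (rng.u01() < R) {
          uz = -uz;  // internal reflection
        } else {
          // refract across the interface
          if (ni != nt) {
            double ratio = ni / nt;
            double sin_i = std::sqrt(std::max(0.0, 1.0 - cos_i * cos_i));
            double sin_t = ratio * sin_i;
            double cos_t = std::sqrt(std::max(0.0, 1.0 - sin_t * sin_t));
            ux *= ratio;
            uy *= ratio;
            uz = (uz >= 0.0) ? cos_t : -cos_t;
            double norm = std::sqrt(ux * ux + uy * uy + uz * uz);
            ux /= norm;
            uy /= norm;
            uz /= norm;
          }
          if (dir < 0 && layer == 0) {
            tally.diffuse += w;  // escaped through the top surface
            alive = false;
          } else if (dir > 0 && layer == L - 1) {
            tally.transmitted += w;  // crossed the bottom boundary
            alive = false;
          } else {
            layer += dir;
          }
        }
      }
    }
  }

  double nn = static_cast<double>(ntot);
  return List::create(
      _["r_hat"] = tally.diffuse / nn, _["r_specular"] = rsp,
      _["transmitted_weight"] = tally.transmitted / nn,
      _["absorbed_weight"] = tally.absorbed / nn,
      _["n_total"] = nn);
}
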