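// Monte Carlo photon transport in a homogeneous turbid slab with a
// probe-emulated finite LED source and aperture/acceptance-cone limited
// detection at the top surface. Analytic slab boundaries (no voxel grid),
// continuous absorption weighting, Henyey-Greenstein scattering and Russian
// roulette, in the style of MCML-class codes.
//
// Units: lengths cm, attenuation coefficients cm^-1. z is depth into the
// medium (z = 0 top surface, z = slab_z bottom). The detector/aperture axis
// is at the lateral origin; the source centre sits at (+rho, 0, 0).

#include <Rcpp.h>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

namespace {

// xoshiro256** with splitmix64 seeding: fast, counter-free, and
// bit-reproducible across platforms for a given (seed, stream) pair.
struct Xoshiro {
  uint64_t s[4];
  static uint64_t splitmix(uint64_t& x) {
    x += 0x9E3779B97F4A7C15ULL;
    uint64_t z = x;
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }
  Xoshiro(uint64_t seed, uint64_t stream) {
    uint64_t x = seed ^ (0x632BE59BD9B4E019ULL + stream * 0x9E3779B97F4A7C15ULL);
    for (int i = 0; i < 4; ++i) s[i] = splitmix(x);
  }
  static uint64_t rotl(uint64_t x, int k) { return (x << k) | (x >> (64 - k)); }
  uint64_t next() {
    const uint64_t result = rotl(s[1] * 5ULL, 7) * 9ULL;
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0];
    s[3] ^= s[1];
    s[1] ^= s[2];
    s[0] ^= s[3];
    s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return result;
  }
  // strictly inside (0, 1): safe for log()
  double unif() { return ((next() >> 11) + 0.5) * (1.0 / 9007199254740992.0); }
  // uniform azimuth as (cos, sin) via rejection sampling: avoids trig calls
  void unit2d(double& c, double& s) {
    double a, b, r2;
    do {
      a = 2.0 * unif() - 1.0;
      b = 2.0 * unif() - 1.0;
      r2 = a * a + b * b;
    } while (r2 > 1.0 || r2 < 1e-300);
    c = (a * a - b * b) / r2;
    s = 2.0 * a * b / r2;
  }
};

inline double hg_cos(double g, double u) {
  if (std::fabs(g) < 1e-12) return 1.0 - 2.0 * u;
  double t = (1.0 - g * g) / (1.0 - g + 2.0 * g * u);
  return (1.0 + g * g - t * t) / (2.0 * g);
}

inline double fresnel_unpol(double n1, double n2, double cosi) {
  if (cosi < 0.0) cosi = 0.0;
  if (cosi > 1.0) cosi = 1.0;
  double sini = std::sqrt(std::max(0.0, 1.0 - cosi * cosi));
  double sint = n1 / n2 * sini;
  if (sint >= 1.0) return 1.0;  // total internal reflection
  double cost = std::sqrt(std::max(0.0, 1.0 - sint * sint));
  double rs = (n1 * cosi - n2 * cost) / (n1 * cosi + n2 * cost);
  double rp = (n1 * cost - n2 * cosi) / (n1 * cost + n2 * cosi);
  return 0.5 * (rs * rs + rp * rp);
}

// Outcome of a photon reaching the top surface travelling upward.
// 0 = internally reflected, 1 = detected, 2 = terminated on mask,
// 3 = transmitted through aperture but outside acceptance cone.
inline int surface_event(double x, double y, double cosi, double u,
                         double n_med, double n_out,
                         double aperture_radius, double accept_cos_min) {
  double R = fresnel_unpol(n_med, n_out, cosi);
  if (u < R) return 0;
  double r_exit = std::sqrt(x * x + y * y);
  if (r_exit > aperture_radius) return 2;
  double sini = std::sqrt(std::max(0.0, 1.0 - cosi * cosi));
  double sint = n_med / n_out * sini;
  double cost = std::sqrt(std::max(0.0, 1.0 - sint * sint));
  return (cost >= accept_cos_min) ? 1 : 3;
}

inline void spin(double& ux, double& uy, double& uz, double cost,
                 double cosp, double sinp) {
  double sint = std::sqrt(std::max(0.0, 1.0 - cost * cost));
  if (std::fabs(uz) > 0.99999) {
    ux = sint * cosp;
    uy = sint * sinp;
    uz = (uz >= 0.0) ? cost : -cost;
  } else {
    double den = std::sqrt(1.0 - uz * uz);
    double nux = sint * (ux * uz * cosp - uy * sinp) / den + ux * cost;
    double nuy = sint * (uy * uz * cosp + ux * sinp) / den + uy * cost;
    double nuz = -sint * cosp * den + uz * cost;
    double nrm = std::sqrt(nux * nux + nuy * nuy + nuz * nuz);
    ux = nux / nrm;
    uy = nuy / nrm;
    uz = nuz / nrm;
  }
}

inline void launch_one(Xoshiro& rng, double rho, double side, double div_m,
                       double& x, double& y, double& z,
                       double& ux, double& uy, double& uz) {
  x = rho + side * (rng.unif() - 0.5);
  y = side * (rng.unif() - 0.5);
  z = 0.0;
  // generalized Lambertian: pdf(theta) proportional to cos^m(theta) sin(theta)
  double cost = std::pow(rng.unif(), 1.0 / (div_m + 1.0));
  double cosp, sinp;
  rng.unit2d(cosp, sinp);
  double sint = std::sqrt(std::max(0.0, 1.0 - cost * cost));
  ux = sint * cosp;
  uy = sint * sinp;
  uz = cost;  // into the medium
}

}  // namespace

// [[Rcpp::export]]
List mc_run(double mu_a, double mu_s, double g, double n_med, double n_out,
            double rho, double emitter_side, double divergence_m,
            double aperture_radius, double accept_cos_min,
            double slab_x, double slab_y, double slab_z,
            double n_photons, double seed, double stream,
            double rr_threshold, double rr_survive, double max_steps) {
  if (n_photons < 1) stop("n_photons must be >= 1");
  if (mu_a < 0 || mu_s < 0) stop("mu_a and mu_s must be non-negative");
  if (g <= -1 || g >= 1) stop("g must lie in (-1, 1)");

  Xoshiro rng(static_cast<uint64_t>(seed), static_cast<uint64_t>(stream));
  const double mu_t = mu_a + mu_s;
  const double albedo = (mu_t > 0.0) ? mu_s / mu_t : 0.0;
  const double xmax = slab_x / 2.0, ymax = slab_y / 2.0;
  const long n = static_cast<long>(n_photons);
  const long max_st = static_cast<long>(max_steps);

  double det_w = 0.0, det_w2 = 0.0, mask_w = 0.0, cone_w = 0.0, esc_w = 0.0;
  double abs_w = 0.0, rr_kill = 0.0, rr_gain = 0.0, lost_w = 0.0;
  long det_n = 0;

  for (long i = 0; i < n; ++i) {
    double x, y, z, ux, uy, uz;
    launch_one(rng, rho, emitter_side, divergence_m, x, y, z, ux, uy, uz);
    double w = 1.0;
    bool alive = true;
    long steps = 0;

    while (alive) {
      if (++steps > max_st) {
        lost_w += w;
        break;
      }
      double s = (mu_t > 0.0) ? -std::log(rng.unif()) / mu_t : 1e30;
      bool collided = false;
      while (true) {
        // distance to the nearest slab boundary along the current direction
        double d = 1e30;
        int hit = 0;  // 1 = top, 2 = other (absorbing) boundary
        if (uz < 0.0) {
          double t = -z / uz;
          if (t < d) { d = t; hit = 1; }
        } else if (uz > 0.0) {
          double t = (slab_z - z) / uz;
          if (t < d) { d = t; hit = 2; }
        }
        if (ux > 0.0) {
          double t = (xmax - x) / ux;
          if (t < d) { d = t; hit = 2; }
        } else if (ux < 0.0) {
          double t = (-xmax - x) / ux;
          if (t < d) { d = t; hit = 2; }
        }
        if (uy > 0.0) {
          double t = (ymax - y) / uy;
          if (t < d) { d = t; hit = 2; }
        } else if (uy < 0.0) {
          double t = (-ymax - y) / uy;
          if (t < d) { d = t; hit = 2; }
        }
        if (s < d) {
          x += s * ux; y += s * uy; z += s * uz;
          collided = true;
          break;
        }
        x += d * ux; y += d * uy; z += d * uz;
        s -= d;
        if (hit == 1) {
          z = 0.0;
          int ev = surface_event(x, y, -uz, rng.unif(), n_med, n_out,
                                 aperture_radius, accept_cos_min);
          if (ev == 0) { uz = -uz; continue; }
          if (ev == 1) { det_w += w; det_w2 += w * w; ++det_n; }
          else if (ev == 2) mask_w += w;
          else cone_w += w;
          alive = false;
          break;
        }
        // side or bottom boundary: absorbing (photon lost)
        esc_w += w;
        alive = false;
        break;
      }
      if (!alive || !collided) break;

      // interaction site: continuous absorption weighting, then scatter
      double dw = w * (mu_t > 0.0 ? mu_a / mu_t : 0.0);
      abs_w += dw;
      w -= dw;
      if (w <= 0.0) break;
      double cost = hg_cos(g, rng.unif());
      double cosp, sinp;
      rng.unit2d(cosp, sinp);
      spin(ux, uy, uz, cost, cosp, sinp);

      if (w < rr_threshold) {
        if (rng.unif() < rr_survive) {
          rr_gain += w * (1.0 / rr_survive - 1.0);
          w /= rr_survive;
        } else {
          rr_kill += w;
          break;
        }
      }
    }
  }

  return List::create(
      _["detected_weight"] = det_w, _["detected_weight_sq"] = det_w2,
      _["detected_count"] = (double)det_n,
      _["launched"] = (double)n, _["p_det"] = det_w / (double)n,
      _["absorbed_weight"] = abs_w, _["escaped_weight"] = esc_w,
      _["mask_weight"] = mask_w, _["cone_weight"] = cone_w,
      _["roulette_killed"] = rr_kill, _["roulette_gain"] = rr_gain,
      _["lost_weight"] = lost_w);
}

// [[Rcpp::export]]
NumericVector mc_sample_hg(double n, double g, double seed) {
  Xoshiro rng(static_cast<uint64_t>(seed), 101ULL);
  long m = static_cast<long>(n);
  NumericVector out(m);
  for (long i = 0; i < m; ++i) out[i] = hg_cos(g, rng.unif());
  return out;
}

// [[Rcpp::export]]
NumericMatrix mc_sample_launch(double n, double rho, double emitter_side,
                               double divergence_m, double seed) {
  Xoshiro rng(static_cast<uint64_t>(seed), 102ULL);
  long m = static_cast<long>(n);
  NumericMatrix out(m, 6);
  double x, y, z, ux, uy, uz;
  for (long i = 0; i < m; ++i) {
    launch_one(rng, rho, emitter_side, divergence_m, x, y, z, ux, uy, uz);
    out(i, 0) = x; out(i, 1) = y; out(i, 2) = z;
    out(i, 3) = ux; out(i, 4) = uy; out(i, 5) = uz;
  }
  colnames(out) = CharacterVector::create("x", "y", "z", "ux", "uy", "uz");
  return out;
}

// [[Rcpp::export]]
NumericVector mc_fresnel(double n1, double n2, NumericVector cos_incidence) {
  int m = cos_incidence.size();
  NumericVector out(m);
  for (int i = 0; i < m; ++i) out[i] = fresnel_unpol(n1, n2, cos_incidence[i]);
  return out;
}

// [[Rcpp::export]]
IntegerVector mc_surface_classify(NumericVector x, NumericVector y,
                                  NumericVector cos_incidence,
                                  NumericVector xi, double n_med, double n_out,
                                  double aperture_radius,
                                  double accept_cos_min) {
  int m = x.size();
  IntegerVector out(m);
  for (int i = 0; i < m; ++i)
    out[i] = surface_event(x[i], y[i], cos_incidence[i], xi[i], n_med, n_out,
                           aperture_radius, accept_cos_min);
  return out;
}

// [[Rcpp::export]]
NumericVector mc_sample_free_paths(double n, double mu_t, double seed) {
  Xoshiro rng(static_cast<uint64_t>(seed), 103ULL);
  long m = static_cast<long>(n);
  NumericVector out(m);
  for (long i = 0; i < m; ++i) out[i] = -std::log(rng.unif()) / mu_t;
  return out;
}
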