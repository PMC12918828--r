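// Weighted-packet Monte Carlo photon transport kernels.
//
// cpp_propagate: genuinely two-dimensional transport (directions on the unit
// circle, 2D Henyey-Greenstein scattering) through a stack of horizontal
// layers with air above, used to model fluorescence escaping frog skin/lymph.
// cpp_mc_slab_1d: plane-parallel slab transport with 3D HG sampling, the
// independent oracle for the adding-doubling forward model.
//
// Both kernels use a self-contained PCG32 generator so results are
// bit-reproducible across platforms and independent of R's RNG state.

#include <Rcpp.h>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

namespace {

struct Pcg32 {
  uint64_t state, inc;
  explicit Pcg32(uint64_t seed) {
    // splitmix64 scramble of the seed for state and stream
    uint64_t z = seed + 0x9e3779b97f4a7c15ULL;
    z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
    z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
    state = z ^ (z >> 31);
    z = seed + 0x3c6ef372fe94f82aULL;
    z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
    z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
    inc = (z ^ (z >> 31)) | 1ULL;
    next(); next();
  }
  uint32_t next() {
    uint64_t old = state;
    state = old * 6364136223846793005ULL + inc;
    uint32_t xorshifted = static_cast<uint32_t>(((old >> 18u) ^ old) >> 27u);
    uint32_t rot = static_cast<uint32_t>(old >> 59u);
    return (xorshifted >> rot) | (xorshifted << ((-rot) & 31));
  }
  // uniform double in (0, 1)
  double uniform() {
    return (static_cast<double>(next()) + 0.5) * 2.3283064365386963e-10;
  }
};

// Unpolarized Fresnel reflectance, incidence cosine mu_i, from n1 into n2.
double fresnel(double mu_i, double n1, double n2) {
  double sin_i2 = 1.0 - mu_i * mu_i;
  double sin_t2 = (n1 / n2) * (n1 / n2) * sin_i2;
  if (sin_t2 >= 1.0) return 1.0;  // total internal reflection
  double mu_t = std::sqrt(1.0 - sin_t2);
  double rs = (n1 * mu_i - n2 * mu_t) / (n1 * mu_i + n2 * mu_t);
  double rp = (n1 * mu_t - n2 * mu_i) / (n1 * mu_t + n2 * mu_i);
  return 0.5 * (rs * rs + rp * rp);
}

}  // namespace

// 2D layered transport. Geometry: x in [0, width] mm, y increases downward
// from the air interface at y = 0. layer_y0/layer_y1 bound each transport
// layer; the bottom of the last layer is either absorbing or an ideal
// specular mirror. Side walls absorb or mirror. The absorbed-weight map bins
// the full domain [0, width] x [0, ny * pixel].
// [[Rcpp::export]]
List cpp_propagate(NumericVector layer_y0, NumericVector layer_y1,
                   NumericVector mua, NumericVector mus,
                   double g, double n_medium, double width,
                   int bottom_mirror, int side_mirror,
                   int nx, int ny, double pixel,
                   double src_x, double src_y, int src_downward,
                   double det_x0, double det_x1,
                   int n_photons, double seed,
                   double roulette_thresh, double roulette_surv,
                   double max_path) {
  const int n_layers = layer_y0.size();
  
  const double hg_fac = (1.0 - g) / (1.0 + g);
  const bool has_gate = max_path > 0;

  Pcg32 rng(static_cast<uint64_t>(seed));
  NumericMatrix absorbed(ny, nx);
  double detected = 0, lost_side = 0, lost_bottom = 0, lost_outside = 0,
         lost_roulette = 0, lost_maxpath = 0;
  const double inv_n = 1.0 / n_photons;
  const long max_events = 100000;  // hard cap against pathological loops

  for (int ip = 0; ip < n_photons; ++ip) {
    double x = src_x, y = src_y;
    double ux, uy;
    if (src_downward) {
      ux = 0.0; uy = 1.0;
    } else {
      double th = 2.0 * M_PI * rng.uniform();
      ux = std::sin(th); uy = std::cos(th);
    }
    // locate the starting layer
    int lay = 0;
    while (lay < n_layers - 1 && y >= layer_y1[lay]) ++lay;
    double w = 1.0, path = 0.0;
    bool alive = true;
    long events = 0;

    while (alive) {
      double s_tau = -std::log(rng.uniform());
      while (s_tau > 0 && alive) {
        if (++events > max_events) {
          // pathological non-terminating trajectory (e.g. lossless and
          // perfectly horizontal): retire the packet into the path-gate bucket
          lost_maxpath += w * inv_n;
          alive = false;
          break;
        }
        double mut = mua[lay] + mus[lay];
        // distance to the nearest boundary along the ray
        double d_y = R_PosInf, d_x = R_PosInf;
        int y_hit = 0;  // -1 top of layer, +1 bottom of layer
        if (uy > 0)      { d_y = (layer_y1[lay] - y) / uy; y_hit = 1; }
        else if (uy < 0) { d_y = (y - layer_y0[lay]) / (-uy); y_hit = -1; }
        int x_hit = 0;
        if (ux > 0)      { d_x = (width - x) / ux; x_hit = 1; }
        else if (ux < 0) { d_x = x / (-ux); x_hit = -1; }
        double d_b = std::min(d_y, d_x);
        if (d_b < 0) d_b = 0;

        double d_free = (mut > 0) ? s_tau / mut : R_PosInf;
        double d_move = std::min(d_free, d_b);
        if (has_gate && path + d_move > max_path) {
          lost_maxpath += w * inv_n;
          alive = false;
          break;
        }

        if (d_free < d_b) {
          // interaction inside the layer
          x += ux * d_move; y += uy * d_move; path += d_move;
          s_tau = 0;
          double dep = w * mua[lay] / mut;
          if (dep > 0) {
            int ix = static_cast<int>(x / pixel);
            int iy = static_cast<int>(y / pixel);
            if (ix < 0) ix = 0;
            if (ix >= nx) ix = nx - 1;
            if (iy < 0) iy = 0;
            if (iy >= ny) iy = ny - 1;
            absorbed(iy, ix) += dep * inv_n;
          }
          w -= dep;
          if (mus[lay] <= 0 || w <= 0) { alive = false; break; }
          // 2D Henyey-Greenstein deflection by inverse CDF
          double u = rng.uniform();
          double th = 2.0 * std::atan(hg_fac * std::tan(M_PI * (u - 0.5)));
          double c = std::cos(th), s = std::sin(th);
          double ux2 = c * ux - s * uy, uy2 = s * ux + c * uy;
          ux = ux2; uy = uy2;
          // Russian roulette with explicit weight bookkeeping
          if (w < roulette_thresh) {
            if (rng.uniform() < roulette_surv) {
              double w_new = w / roulette_surv;
              lost_roulette += (w - w_new) * inv_n;
              w = w_new;
            } else {
              lost_roulette += w * inv_n;
              alive = false;
            }
          }
        } else {
          // move to the boundary
          x += ux * d_b; y += uy * d_b; path += d_b;
          s_tau -= mut * d_b;
          if (s_tau < 1e-14) s_tau = 0;
          if (d_x <= d_y) {
            // side wall
            x = (x_hit > 0) ? width : 0.0;
            if (side_mirror) { ux = -ux; }
            else { lost_side += w * inv_n; alive = false; }
          } else if (y_hit > 0) {
            y = layer_y1[lay];
            if (lay < n_layers - 1) { ++lay; }
            else if (bottom_mirror) { uy = -uy; }
            else { lost_bottom += w * inv_n; alive = false; }
          } else {
            y = layer_y0[lay];
            if (lay > 0) { --lay; }
            else {
              // air interface: Fresnel split, transmitted part to detector
              double mu_i = -uy;  // cosine of incidence on the interface
              double rho = (n_medium == 1.0) ? 0.0
                                             : fresnel(mu_i, n_medium, 1.0);
              double w_out = w * (1.0 - rho);
              if (w_out > 0) {
                if (x >= det_x0 && x <= det_x1) detected += w_out * inv_n;
                else lost_outside += w_out * inv_n;
              }
              w *= rho;
              if (w <= 0) { alive = false; }
              else {
                uy = -uy;
                if (w < roulette_thresh) {
                  if (rng.uniform() < roulette_surv) {
                    double w_new = w / roulette_surv;
                    lost_roulette += (w - w_new) * inv_n;
                    w = w_new;
                  } else {
                    lost_roulette += w * inv_n;
                    alive = false;
                  }
                }
              }
            }
          }
        }
      }
    }
  }

  return List::create(_["detected"] = detected,
                      _["absorbed"] = absorbed,
                      _["lost_side"] = lost_side,
                      _["lost_bottom"] = lost_bottom,
                      _["lost_outside_detector"] = lost_outside,
                      _["lost_roulette"] = lost_roulette,
                      _["lost_maxpath"] = lost_maxpath);
}

// Plane-parallel homogeneous slab, index matched, collimated normal
// incidence; 3D Henyey-Greenstein sampling. Returns total R and T with
// per-photon variance accumulators for Monte Carlo standard errors.
// [[Rcpp::export]]
List cpp_mc_slab_1d(double mua, double mus, double g, double thickness,
                    int n_photons, double seed,
                    double roulette_thresh, double roulette_surv) {
  Pcg32 rng(static_cast<uint64_t>(seed));
  const double mut = mua + mus;
  double sum_r = 0, sum_r2 = 0, sum_t = 0, sum_t2 = 0;

  for (int ip = 0; ip < n_photons; ++ip) {
    double z = 0.0, ux = 0.0, uy = 0.0, uz = 1.0, w = 1.0;
    double r_i = 0.0, t_i = 0.0;
    bool alive = mut > 0;
    if (!alive) t_i = 1.0;  // transparent slab
    while (alive) {
      double s = -std::log(rng.uniform()) / mut;
      z += uz * s;
      if (z < 0)          { r_i += w; break; }
      if (z > thickness)  { t_i += w; break; }
      w *= mus / mut;
      if (w <= 0) break;
      double ct;
      if (g == 0) {
        ct = 2.0 * rng.uniform() - 1.0;
      } else {
        double tmp = (1.0 - g * g) / (1.0 - g + 2.0 * g * rng.uniform());
        ct = (1.0 + g * g - tmp * tmp) / (2.0 * g);
      }
      double st = std::sqrt(std::max(0.0, 1.0 - ct * ct));
      double phi = 2.0 * M_PI * rng.uniform();
      double cp = std::cos(phi), sp = std::sin(phi);
      if (std::fabs(uz) > 0.99999) {
        ux = st * cp; uy = st * sp; uz = ct * (uz >= 0 ? 1.0 : -1.0);
      } else {
        double den = std::sqrt(1.0 - uz * uz);
        double ux2 = st * (ux * uz * cp - uy * sp) / den + ux * ct;
        double uy2 = st * (uy * uz * cp + ux * sp) / den + uy * ct;
        double uz2 = -st * cp * den + uz * ct;
        ux = ux2; uy = uy2; uz = uz2;
      }
      if (w < roulette_thresh) {
        if (rng.uniform() < roulette_surv) w /= roulette_surv;
        else break;
      }
    }
    sum_r += r_i; sum_r2 += r_i * r_i;
    sum_t += t_i; sum_t2 += t_i * t_i;
  }
  double n = static_cast<double>(n_photons);
  double mr = sum_r / n, mt = sum_t / n;
  double se_r = std::sqrt(std::max(0.0, sum_r2 / n - mr * mr) / n);
  double se_t = std::sqrt(std::max(0.0, sum_t2 / n - mt * mt) / n);
  return List::create(_["reflectance"] = mr, _["transmittance"] = mt,
                      _["se_reflectance"] = se_r, _["se_transmittance"] = se_t);
}
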