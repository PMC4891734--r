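// Monte Carlo photon random walk in a slab / semi-infinite medium.
//
// Scattering-only transport (absorption is applied afterwards as the
// time-bin weight exp(-mu_a v t_j)): a pencil beam enters at the origin
// moving along +z, free paths are exponential with rate mu_s, deflections
// follow Henyey-Greenstein, and boundary hits undergo unpolarized Fresnel
// reflection / transmission (total internal reflection included).  Per
// detected trajectory the kernel records the exit time t = path/v, the
// maximum depth z_max and the mean depth zbar of its scattering events,
// accumulated into time-binned tallies and the (time x z_max) count
// matrix.  Uses R's RNG stream so runs are reproducible from set.seed();
// the draw order per scattering cycle is: step u, boundary u's (only when
// n_rel != 1), deflection u, azimuth u -- mirrored verbatim by the pure-R
// reference implementation in the test suite.

#include <Rcpp.h>
using namespace Rcpp;

static inline double runif_open() {
  double u;
  do { u = unif_rand(); } while (u <= 0.0 || u >= 1.0);
  return u;
}

static double fresnel_unpol(double ci, double n_rel) {
  if (n_rel == 1.0) return 0.0;
  double st2 = 1.0 - ci * ci;
  double sin_t2 = n_rel * n_rel * st2;
  if (sin_t2 >= 1.0) return 1.0;  // total internal reflection
  double ctt = std::sqrt(1.0 - sin_t2);
  double Rs = (n_rel * ci - ctt) / (n_rel * ci + ctt);
  double Rp = (n_rel * ctt - ci) / (n_rel * ctt + ci);
  return 0.5 * (Rs * Rs + Rp * Rp);
}

// [[Rcpp::export(name = ".mc_kernel")]]
List mc_kernel(int n_photons, double mu_s, double g, double n_rel,
               double s0, double v, double dt, int n_time_bins,
               int n_z_bins, double z_cap, double max_path,
               NumericVector ring_centers, double ring_halfwidth) {
  const bool finite_slab = R_finite(s0);
  const int n_rings = ring_centers.size();
  const double dz = z_cap / n_z_bins;
  const int KZ = n_z_bins + 1;            // last column: overflow bin

  IntegerVector N(n_time_bins);
  NumericVector sum_zmax(n_time_bins), sum_zbar(n_time_bins);
  NumericVector sum_zmax2(n_time_bins), sum_zbar2(n_time_bins);
  IntegerMatrix M(n_time_bins, KZ);
  IntegerMatrix ringN(n_time_bins, std::max(n_rings, 1));
  NumericMatrix ring_sum_zmax(n_time_bins, std::max(n_rings, 1));
  NumericMatrix ring_sum_zbar(n_time_bins, std::max(n_rings, 1));
  IntegerVector ringM(n_time_bins * KZ * std::max(n_rings, 1));

  int detected = 0, detected_late = 0, transmitted = 0, discarded = 0;

  for (int i = 0; i < n_photons; ++i) {
    double x = 0.0, y = 0.0, z = 0.0;
    double ux = 0.0, uy = 0.0, uz = 1.0;
    double path = 0.0, zmax = 0.0, zsum = 0.0;
    long nscat = 0;
    bool alive = true;

    while (alive) {
      double step = -std::log(runif_open()) / mu_s;

      // propagate, handling boundary crossings within this step
      for (;;) {
        if (uz < 0.0) {
          double t_hit = -z / uz;
          if (t_hit <= step) {
            x += ux * t_hit; y += uy * t_hit; z = 0.0;
            path += t_hit; step -= t_hit;
            bool exit_now = true;
            if (n_rel != 1.0) {
              double RF = fresnel_unpol(-uz, n_rel);
              if (unif_rand() < RF) exit_now = false;
            }
            if (exit_now) {
              double t = path / v;
              int j = (int)(t / dt);
              ++detected;
              if (j >= n_time_bins) { ++detected_late; }
              else {
                double zbar = zsum / (double)nscat;
                int k = (int)(zmax / dz); if (k >= n_z_bins) k = n_z_bins;
                ++N[j]; sum_zmax[j] += zmax; sum_zbar[j] += zbar;
                sum_zmax2[j] += zmax * zmax; sum_zbar2[j] += zbar * zbar;
                ++M(j, k);
                if (n_rings > 0) {
                  double rho = std::sqrt(x * x + y * y);
                  for (int r = 0; r < n_rings; ++r) {
                    if (std::fabs(rho - ring_centers[r]) <= ring_halfwidth) {
                      ++ringN(j, r);
                      ring_sum_zmax(j, r) += zmax;
                      ring_sum_zbar(j, r) += zbar;
                      ++ringM[j + n_time_bins * (k + KZ * r)];
                      break;
                    }
                  }
                }
              }
              alive = false;
              break;
            }
            uz = -uz;       // internal reflection at the top face
            continue;
          }
        } else if (finite_slab && uz > 0.0) {
          double t_hit = (s0 - z) / uz;
          if (t_hit <= step) {
            x += ux * t_hit; y += uy * t_hit; z = s0;
            if (z > zmax) zmax = z;
            path += t_hit; step -= t_hit;
            bool exit_now = true;
            if (n_rel != 1.0) {
              double RF = fresnel_unpol(uz, n_rel);
              if (unif_rand() < RF) exit_now = false;
            }
            if (exit_now) { ++transmitted; alive = false; break; }
            uz = -uz;       // internal reflection at the deep face
            continue;
          }
        }
        x += ux * step; y += uy * step; z += uz * step;
        path += step;
        break;
      }
      if (!alive) break;

      // scattering event
      ++nscat; zsum += z;
      if (z > zmax) zmax = z;
      if (path > max_path) { ++discarded; break; }

      // new direction: Henyey-Greenstein deflection + uniform azimuth
      double cost;
      double u1 = unif_rand();
      if (g == 0.0) {
        cost = 2.0 * u1 - 1.0;
      } else {
        double tmp = (1.0 - g * g) / (1.0 - g + 2.0 * g * u1);
        cost = (1.0 + g * g - tmp * tmp) / (2.0 * g);
        if (cost > 1.0) cost = 1.0; else if (cost < -1.0) cost = -1.0;
      }
      double phi = 2.0 * M_PI * unif_rand();
      double sint = std::sqrt(1.0 - cost * cost);
      double cosp = std::cos(phi), sinp = std::sin(phi);
      if (std::fabs(uz) > 0.99999) {
        ux = sint * cosp; uy = sint * sinp;
        uz = (uz >= 0.0 ? cost : -cost);
      } else {
        double den = std::sqrt(1.0 - uz * uz);
        double nux = sint * (ux * uz * cosp - uy * sinp) / den + ux * cost;
        double nuy = sint * (uy * uz * cosp + ux * sinp) / den + uy * cost;
        double nuz = -den * sint * cosp + uz * cost;
        ux = nux; uy = nuy; uz = nuz;
      }
    }
  }

  ringM.attr("dim") = IntegerVector::create(n_time_bins, KZ,
                                            std::max(n_rings, 1));
  return List::create(
    _["N"] = N, _["sum_zmax"] = sum_zmax, _["sum_zbar"] = sum_zbar,
    _["sum_zmax2"] = sum_zmax2, _["sum_zbar2"] = sum_zbar2,
    _["M"] = M,
    _["ringN"] = ringN, _["ring_sum_zmax"] = ring_sum_zmax,
    _["ring_sum_zbar"] = ring_sum_zbar, _["ringM"] = ringM,
    _["detected"] = detected, _["detected_late"] = detected_late,
    _["transmitted"] = transmitted, _["discarded"] = discarded);
}
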