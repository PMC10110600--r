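// Monte-Carlo photon transport through a plane-parallel slab with
// Henyey-Greenstein scattering and Fresnel cuvette-wall boundaries.
// Validation-only reference for the adding-doubling forward model:
// collimated normal incidence, weight-based absorption with Russian
// roulette, tallies of total (diffuse + specular) reflectance and total
// transmittance with per-photon variance estimates.
//
// Uses R's RNG (unif_rand) so results are reproducible under set.seed().

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static double fresnel_unpol(double ni, double nt, double mu) {
  if (mu > 1.0) mu = 1.0;
  if (mu < 0.0) mu = 0.0;
  double sin_t2 = (ni / nt) * (ni / nt) * (1.0 - mu * mu);
  if (sin_t2 >= 1.0) return 1.0;
  double mu_t = std::sqrt(1.0 - sin_t2);
  double rs = (ni * mu - nt * mu_t) / (ni * mu + nt * mu_t);
  double rp = (ni * mu_t - nt * mu) / (ni * mu_t + nt * mu);
  return 0.5 * (rs * rs + rp * rp);
}

// medium | wall | outside composite boundary, incoherent wall reflections
static double wall_reflectance(double mu, double n_slab, double n_wall,
                               double n_out) {
  if (std::fabs(n_wall - n_slab) < 1e-12)
    return fresnel_unpol(n_slab, n_out, mu);
  double r1 = fresnel_unpol(n_slab, n_wall, mu);
  double sin_w2 = (n_slab / n_wall) * (n_slab / n_wall) * (1.0 - mu * mu);
  if (sin_w2 >= 1.0) return 1.0;
  double mu_w = std::sqrt(1.0 - sin_w2);
  double r2 = fresnel_unpol(n_wall, n_out, mu_w);
  return r1 + (1.0 - r1) * (1.0 - r1) * r2 / (1.0 - r1 * r2);
}

// [[Rcpp::export]]
List mc_slab_cpp(double mu_a, double mu_s, double g, double d,
                 double n_slab, double n_wall, double n_out,
                 int n_photons) {
  const double mu_t = mu_a + mu_s;
  const double albedo = (mu_t > 0.0) ? mu_s / mu_t : 0.0;
  const double w_min = 1e-4;
  double sumR = 0.0, sumR2 = 0.0, sumT = 0.0, sumT2 = 0.0;

  const double r_spec = wall_reflectance(1.0, n_slab, n_wall, n_out);

  for (int ip = 0; ip < n_photons; ip++) {
    double wR = r_spec;            // deterministic first-surface specular
    double wT = 0.0;
    double w = 1.0 - r_spec;
    double z = 0.0, uz = 1.0, ux = 0.0, uy = 0.0;
    bool alive = w > 0.0 && mu_t * d > 0.0;
    if (mu_t * d <= 0.0 && w > 0.0) { wT += w; alive = false; }
    while (alive) {
      double step = -std::log(unif_rand()) / mu_t;  // mm
      // propagate, handling boundary crossings
      for (;;) {
        double zb = (uz > 0.0) ? d : 0.0;
        double dist = (uz != 0.0) ? (zb - z) / uz : R_PosInf;
        if (step < dist) { z += step * uz; break; }
        // reach the boundary, spend dist of the step
        step -= dist;
        z = zb;
        double mu_inc = std::fabs(uz);
        double r = wall_reflectance(mu_inc, n_slab, n_wall, n_out);
        if (unif_rand() < r) {
          uz = -uz;                 // specular internal reflection
        } else {
          if (zb == 0.0) wR += w; else wT += w;
          alive = false;
          break;
        }
      }
      if (!alive) break;
      // interaction: absorb a (1 - albedo) fraction, then scatter
      w *= albedo;
      if (w < w_min) {              // Russian roulette
        if (unif_rand() < 0.1) w *= 10.0; else { alive = false; break; }
      }
      double ct;
      if (std::fabs(g) < 1e-8) {
        ct = 2.0 * unif_rand() - 1.0;
      } else {
        double t = (1.0 - g * g) / (1.0 - g + 2.0 * g * unif_rand());
        ct = (1.0 + g * g - t * t) / (2.0 * g);
        if (ct > 1.0) ct = 1.0;
        if (ct < -1.0) ct = -1.0;
      }
      double st = std::sqrt(1.0 - ct * ct);
      double phi = 2.0 * M_PI * unif_rand();
      double cp = std::cos(phi), sp = std::sin(phi);
      if (std::fabs(uz) > 0.99999) {
        ux = st * cp; uy = st * sp; uz = ct * ((uz >= 0.0) ? 1.0 : -1.0);
      } else {
        double den = std::sqrt(1.0 - uz * uz);
        double nx = st * (ux * uz * cp - uy * sp) / den + ux * ct;
        double ny = st * (uy * uz * cp + ux * sp) / den + uy * ct;
        double nz = -den * st * cp + uz * ct;
        ux = nx; uy = ny; uz = nz;
        double norm = std::sqrt(ux * ux + uy * uy + uz * uz);
        ux /= norm; uy /= norm; uz /= norm;
      }
    }
    sumR += wR; sumR2 += wR * wR;
    sumT += wT; sumT2 += wT * wT;
  }
  double n = (double)n_photons;
  double Rm = sumR / n, Tm = sumT / n;
  double Rse = std::sqrt(std::max(0.0, sumR2 / n - Rm * Rm) / n);
  double Tse = std::sqrt(std::max(0.0, sumT2 / n - Tm * Tm) / n);
  return List::create(_["R_d"] = Rm, _["T_t"] = Tm,
                      _["R_se"] = Rse, _["T_se"] = Tse);
}
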