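// Monte Carlo photon transport in a stack of plane-parallel turbid layers.
// MCML conventions: exponential step sampling in dimensionless optical depth,
// weight deposition mu_a/mu_t at each interaction, Henyey-Greenstein
// scattering, unpolarized Fresnel boundaries with Snell refraction, and
// Russian-roulette termination.  All lengths are in mm, coefficients in 1/mm.
// Uses R's RNG so runs are reproducible through set.seed().

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

namespace {

// uniform variate strictly inside (0, 1); guards log(0)
inline double ru_pos() {
  double u = unif_rand();
  while (u <= 0.0 || u >= 1.0) u = unif_rand();
  return u;
}

// Unpolarized Fresnel reflectance for incidence cosine ci going from index
// n1 into n2; writes the transmitted cosine into ct (0 under total internal
// reflection).
inline double fresnel_R(double n1, double n2, double ci, double& ct) {
  if (n1 == n2) {
    ct = ci;
    return 0.0;
  }
  double s2 = (n1 / n2) * (n1 / n2) * (1.0 - ci * ci);
  if (s2 >= 1.0) {  // beyond the critical angle
    ct = 0.0;
    return 1.0;
  }
  ct = std::sqrt(1.0 - s2);
  double rs = (n1 * ci - n2 * ct) / (n1 * ci + n2 * ct);
  double rp = (n1 * ct - n2 * ci) / (n1 * ct + n2 * ci);
  return 0.5 * (rs * rs + rp * rp);
}

// Henyey-Greenstein deflection cosine with mean cosine g.
inline double hg_cos(double g) {
  double u = unif_rand();
  if (std::fabs(g) < 1e-6) return 2.0 * u - 1.0;
  double tmp = (1.0 - g * g) / (1.0 - g + 2.0 * g * u);
  double ct = (1.0 + g * g - tmp * tmp) / (2.0 * g);
  if (ct > 1.0) ct = 1.0;
  if (ct < -1.0) ct = -1.0;
  return ct;
}

// Rotate the direction cosines by an HG deflection and a uniform azimuth.
inline void spin(double& ux, double& uy, double& uz, double g) {
  double ct = hg_cos(g);
  double st = std::sqrt(1.0 - ct * ct);
  double phi = 2.0 * M_PI * unif_rand();
  double cp = std::cos(phi), sp = std::sin(phi);
  double x = ux, y = uy, z = uz;
  if (std::fabs(z) > 0.99999) {
    ux = st * cp;
    uy = st * sp;
    uz = (z >= 0.0) ? ct : -ct;
  } else {
    double den = std::sqrt(1.0 - z * z);
    ux = st * (x * z * cp - y * sp) / den + x * ct;
    uy = st * (y * z * cp + x * sp) / den + y * ct;
    uz = -den * st * cp + z * ct;
  }
  double nrm = std::sqrt(ux * ux + uy * uy + uz * uz);
  ux /= nrm;
  uy /= nrm;
  uz /= nrm;
}

}  // namespace

//' Unpolarized Fresnel reflectance at a refractive-index step
//'
//' @param n1,n2 refractive indices of the incident and transmitting media.
//' @param cos_incidence cosine of the incidence angle (1 = normal incidence).
//' @return Reflection probability in \code{[0, 1]}; 1 beyond the critical
//'   angle when \code{n1 > n2}.
//' @export
// [[Rcpp::export]]
double fresnel_unpolarized(double n1, double n2, double cos_incidence) {
  if (n1 < 1.0 || n2 < 1.0) stop("refractive indices must be >= 1");
  if (cos_incidence < 0.0 || cos_incidence > 1.0)
    stop("cos_incidence must lie in [0, 1]");
  double ct;
  return fresnel_R(n1, n2, cos_incidence, ct);
}

//' Sample Henyey-Greenstein deflection cosines
//'
//' Draws from the single-parameter Henyey-Greenstein phase function whose
//' mean deflection cosine equals the anisotropy factor \code{g}.  Uses R's
//' RNG, so results are reproducible under \code{set.seed()}.
//'
//' @param n number of draws.
//' @param g anisotropy factor in \code{[-1, 1]}; 0 gives isotropic scattering.
//' @return Numeric vector of \code{n} deflection cosines in \code{[-1, 1]}.
//' @export
// [[Rcpp::export]]
NumericVector hg_sample_cos(int n, double g) {
  if (g < -1.0 || g > 1.0) stop("g must lie in [-1, 1]");
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = hg_cos(g);
  return out;
}

//' Sample post-scattering photon directions
//'
//' Applies \code{n} independent Henyey-Greenstein scattering events to the
//' incoming unit direction and returns the resulting direction cosines.
//'
//' @param n number of scattering events to sample.
//' @param g anisotropy factor.
//' @param ux,uy,uz incoming direction cosines (unit norm).
//' @return \code{n x 3} matrix of unit direction cosines.
//' @export
// [[Rcpp::export]]
NumericMatrix scatter_directions(int n, double g, double ux, double uy,
                                 double uz) {
  double nrm = std::sqrt(ux * ux + uy * uy + uz * uz);
  if (std::fabs(nrm - 1.0) > 1e-6) stop("(ux, uy, uz) must be a unit vector");
  NumericMatrix out(n, 3);
  for (int i = 0; i < n; ++i) {
    double a = ux, b = uy, c = uz;
    spin(a, b, c, g);
    out(i, 0) = a;
    out(i, 1) = b;
    out(i, 2) = c;
  }
  return out;
}

// Core transport kernel.  Layer k occupies [boundaries[k], boundaries[k+1]).
// Tally grids carry one overflow row/column (index nr / nz) for events beyond
// the grid.  crossing(ir, k) records the weight making its FIRST downward
// crossing of the plane z = k * dz at radial bin ir, k = 0..nz; plane 0 is
// credited at launch.  roulette_net is the net weight created (+) or removed
// (-) by Russian roulette, so that
//   specular + sum(refl) + sum(trans) + sum(per_layer) - roulette_net
// equals n_photons to floating-point accuracy.
// [[Rcpp::export]]
List mc_transport(NumericVector mua, NumericVector mus, NumericVector g,
                  NumericVector n_idx, NumericVector boundaries,
                  double n_above, double n_below, int n_photons,
                  double beam_radius, bool pencil, double dr, int nr,
                  double dz, int nz, double roulette_threshold,
                  double roulette_survival) {
  const int nl = mua.size();
  if (mus.size() != nl || g.size() != nl || n_idx.size() != nl)
    stop("layer property vectors must have equal length");
  if (boundaries.size() != nl + 1) stop("boundaries must have length nlayer + 1");
  if (n_photons <= 0) stop("n_photons must be positive");
  if (dr <= 0 || dz <= 0 || nr <= 0 || nz <= 0) stop("invalid tally grid");
  if (roulette_survival <= 0.0 || roulette_survival >= 1.0)
    stop("roulette_survival must lie in (0, 1)");

  std::vector<double> mut(nl);
  for (int i = 0; i < nl; ++i) {
    if (mua[i] < 0 || mus[i] < 0) stop("mu_a and mu_s must be non-negative");
    mut[i] = mua[i] + mus[i];
    if (mut[i] <= 0.0) stop("vacuum layers (mu_a + mu_s == 0) are unsupported");
  }

  NumericMatrix A(nr + 1, nz + 1);
  NumericMatrix crossing(nr + 1, nz + 1);
  NumericVector refl_r(nr + 1), trans_r(nr + 1), per_layer(nl);
  double specular_total = 0.0, roulette_net = 0.0;

  // per-photon accumulators for Monte Carlo standard errors
  std::vector<double> dep_sum(nl, 0.0), dep_ss(nl, 0.0);
  double refl_sum = 0, refl_ss = 0, trans_sum = 0, trans_ss = 0;
  double rou_sum = 0, rou_ss = 0;
  double xd_sum = 0, xd_ss = 0, yd_sum = 0, yd_ss = 0;

  const double n0 = n_idx[0];
  double rsp = 0.0;
  if (n_above != n0) {
    double t = (n_above - n0) / (n_above + n0);
    rsp = t * t;
  }

  std::vector<double> dep(nl);
  long long capped = 0;

  for (int ip = 0; ip < n_photons; ++ip) {
    double x = 0.0, y = 0.0;
    if (!pencil) {
      double r0 = beam_radius * std::sqrt(unif_rand());
      double ph = 2.0 * M_PI * unif_rand();
      x = r0 * std::cos(ph);
      y = r0 * std::sin(ph);
    }
    double z = 0.0, ux = 0.0, uy = 0.0, uz = 1.0;
    int layer = 0;
    double w = 1.0 - rsp;
    specular_total += rsp;
    std::fill(dep.begin(), dep.end(), 0.0);
    double refl_w = 0, trans_w = 0, rou_p = 0, xd = 0, yd = 0;

    {
      double r = std::sqrt(x * x + y * y);
      int ir = (int)(r / dr);
      if (ir > nr) ir = nr;
      crossing(ir, 0) += w;
    }
    int max_plane = 0;
    double s = 0.0;  // remaining dimensionless step
    bool alive = true;
    long long events = 0;

    while (alive) {
      if (++events > 20000000LL) {  // defensive cap; never reached in practice
        ++capped;
        roulette_net -= w;
        rou_p -= w;
        break;
      }
      if (s <= 0.0) s = -std::log(ru_pos());
      double mt = mut[layer];
      double step = s / mt;
      double db = R_PosInf;
      if (uz > 0.0)
        db = (boundaries[layer + 1] - z) / uz;
      else if (uz < 0.0)
        db = (boundaries[layer] - z) / uz;
      if (db < 0.0) db = 0.0;

      double move = (db <= step) ? db : step;
      double x2 = x + ux * move, y2 = y + uy * move;
      double z2;
      if (db <= step)
        z2 = (uz > 0.0) ? boundaries[layer + 1] : boundaries[layer];
      else
        z2 = z + uz * move;

      if (uz > 0.0 && max_plane < nz && z2 > z) {
        int kmax = (int)std::floor(z2 / dz + 1e-12);
        if (kmax > nz) kmax = nz;
        for (int k = max_plane + 1; k <= kmax; ++k) {
          double t = (k * dz - z) / (z2 - z);
          double xc = x + (x2 - x) * t, yc = y + (y2 - y) * t;
          double r = std::sqrt(xc * xc + yc * yc);
          int ir = (int)(r / dr);
          if (ir > nr) ir = nr;
          crossing(ir, k) += w;
        }
        if (kmax > max_plane) max_plane = kmax;
      }

      if (db <= step) {
        // hit a layer boundary: Fresnel / Snell interaction
        s -= db * mt;
        x = x2;
        y = y2;
        z = z2;
        int next = (uz > 0.0) ? layer + 1 : layer - 1;
        double n1 = n_idx[layer], n2, ct;
        if (next < 0)
          n2 = n_above;
        else if (next >= nl)
          n2 = n_below;
        else
          n2 = n_idx[next];
        double ci = std::fabs(uz);
        double R = fresnel_R(n1, n2, ci, ct);
        if (unif_rand() < R) {
          uz = -uz;  // internal reflection
        } else {
          if (n1 != n2) {  // Snell refraction
            double ratio = n1 / n2;
            ux *= ratio;
            uy *= ratio;
            uz = (uz >= 0.0) ? ct : -ct;
            double nrm = std::sqrt(ux * ux + uy * uy + uz * uz);
            ux /= nrm;
            uy /= nrm;
            uz /= nrm;
          }
          if (next < 0) {  // escaped the top surface: diffuse reflectance
            double r = std::sqrt(x * x + y * y);
            int ir = (int)(r / dr);
            if (ir > nr) ir = nr;
            refl_r[ir] += w;
            refl_w += w;
            alive = false;
          } else if (next >= nl) {  // escaped the bottom: transmittance
            double r = std::sqrt(x * x + y * y);
            int ir = (int)(r / dr);
            if (ir > nr) ir = nr;
            trans_r[ir] += w;
            trans_w += w;
            alive = false;
          } else {
            layer = next;
          }
        }
      } else {
        // interaction site: deposit, scatter, roulette
        x = x2;
        y = y2;
        z = z2;
        s = 0.0;
        double dwgt = w * mua[layer] / mt;
        if (dwgt > 0.0) {
          double r = std::sqrt(x * x + y * y);
          int ir = (int)(r / dr);
          if (ir > nr) ir = nr;
          int iz = (int)(z / dz);
          if (iz > nz) iz = nz;
          A(ir, iz) += dwgt;
          per_layer[layer] += dwgt;
          dep[layer] += dwgt;
          xd += dwgt * x;
          yd += dwgt * y;
          w -= dwgt;
        }
        if (mus[layer] > 0.0) spin(ux, uy, uz, g[layer]);
        if (w < roulette_threshold) {
          if (unif_rand() < roulette_survival) {
            double gain = w / roulette_survival - w;
            roulette_net += gain;
            rou_p += gain;
            w /= roulette_survival;
          } else {
            roulette_net -= w;
            rou_p -= w;
            alive = false;
          }
        }
      }
    }

    for (int l = 0; l < nl; ++l) {
      dep_sum[l] += dep[l];
      dep_ss[l] += dep[l] * dep[l];
    }
    refl_sum += refl_w;
    refl_ss += refl_w * refl_w;
    trans_sum += trans_w;
    trans_ss += trans_w * trans_w;
    rou_sum += rou_p;
    rou_ss += rou_p * rou_p;
    xd_sum += xd;
    xd_ss += xd * xd;
    yd_sum += yd;
    yd_ss += yd * yd;
  }

  return List::create(
      _["absorption"] = A, _["crossing"] = crossing,
      _["reflectance_r"] = refl_r, _["transmittance_r"] = trans_r,
      _["per_layer"] = per_layer, _["specular"] = specular_total,
      _["roulette_net"] = roulette_net,
      _["stats"] = List::create(
          _["dep_sum"] = wrap(dep_sum), _["dep_ss"] = wrap(dep_ss),
          _["refl_sum"] = refl_sum, _["refl_ss"] = refl_ss,
          _["trans_sum"] = trans_sum, _["trans_ss"] = trans_ss,
          _["rou_sum"] = rou_sum, _["rou_ss"] = rou_ss,
          _["xdep_sum"] = xd_sum, _["xdep_ss"] = xd_ss,
          _["ydep_sum"] = yd_sum, _["ydep_ss"] = yd_ss),
      _["capped"] = (double)capped);
}
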