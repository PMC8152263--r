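// Monte Carlo photon transport in a plane-parallel, layered ocean under a
// wind-roughened (Cox-Munk) surface. Semi-analog weighted transport: at each
// collision the absorbed fraction a/c is deposited and the photon always
// scatters with weight multiplied by the single-scattering albedo. Photons
// below the weight cutoff deposit their residual weight as water-column
// absorption, so the four budget tallies sum to the launched weight exactly.
//
// Geometry: z is depth, positive downward, 0 at the mean surface. Direction
// cosines (ux, uy, uz) with uz > 0 meaning downward travel. Facet normals
// are stored pointing up into the air (negative z component).

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static inline double unif() { return R::unif_rand(); }

// unpolarized Fresnel reflectance; cos_i >= 0, n_rel = n_trans / n_inc
// [[Rcpp::export(name = "fresnel_cpp")]]
double fresnel_cpp(double cos_i, double n_rel) {
  if (cos_i < 0) cos_i = 0;
  if (cos_i > 1) cos_i = 1;
  double sin2_t = (1.0 - cos_i * cos_i) / (n_rel * n_rel);
  if (sin2_t >= 1.0) return 1.0; // total internal reflection
  double cos_t = std::sqrt(1.0 - sin2_t);
  double rs = (cos_i - n_rel * cos_t) / (cos_i + n_rel * cos_t);
  double rp = (cos_t - n_rel * cos_i) / (cos_t + n_rel * cos_i);
  return 0.5 * (rs * rs + rp * rp);
}

struct Vec3 { double x, y, z; };

static inline double dot(const Vec3& a, const Vec3& b) {
  return a.x * b.x + a.y * b.y + a.z * b.z;
}

// rotate direction u by scattering angle (cos_s) and azimuth phi
static inline Vec3 rotate_dir(const Vec3& u, double cos_s, double phi) {
  double sin_s = std::sqrt(std::max(0.0, 1.0 - cos_s * cos_s));
  double cp = std::cos(phi), sp = std::sin(phi);
  Vec3 v;
  if (std::fabs(u.z) > 0.999999) {
    double sgn = u.z >= 0 ? 1.0 : -1.0;
    v.x = sin_s * cp;
    v.y = sin_s * sp;
    v.z = sgn * cos_s;
  } else {
    double den = std::sqrt(1.0 - u.z * u.z);
    v.x = sin_s * (u.x * u.z * cp - u.y * sp) / den + u.x * cos_s;
    v.y = sin_s * (u.y * u.z * cp + u.x * sp) / den + u.y * cos_s;
    v.z = -sin_s * cp * den + u.z * cos_s;
  }
  double nn = std::sqrt(dot(v, v));
  v.x /= nn; v.y /= nn; v.z /= nn;
  return v;
}

// sample cos(theta) from an inverse-CDF table at equispaced quantiles
static inline double sample_cdf(const double* tab, int n, double u) {
  double p = u * (n - 1);
  int i = (int)p;
  if (i > n - 2) i = n - 2;
  double f = p - i;
  return tab[i] * (1.0 - f) + tab[i + 1] * f;
}

// Cox-Munk facet normal (upward, z component negative in depth coords)
static inline Vec3 sample_facet(double slope_sd) {
  double sx = R::norm_rand() * slope_sd;
  double sy = R::norm_rand() * slope_sd;
  double nn = std::sqrt(1.0 + sx * sx + sy * sy);
  Vec3 N; N.x = -sx / nn; N.y = -sy / nn; N.z = -1.0 / nn;
  return N;
}

// reflect u about unit normal N
static inline Vec3 reflect_dir(const Vec3& u, const Vec3& N) {
  double d = dot(u, N);
  Vec3 v; v.x = u.x - 2 * d * N.x; v.y = u.y - 2 * d * N.y; v.z = u.z - 2 * d * N.z;
  return v;
}

// refract u through unit normal M oriented against u (dot(u, M) < 0);
// eta = n_inc / n_trans. Returns false on total internal reflection.
static inline bool refract_dir(const Vec3& u, const Vec3& M, double eta, Vec3& out) {
  double c1 = -dot(u, M);
  double s2 = eta * eta * (1.0 - c1 * c1);
  if (s2 >= 1.0) return false;
  double c2 = std::sqrt(1.0 - s2);
  out.x = eta * u.x + (eta * c1 - c2) * M.x;
  out.y = eta * u.y + (eta * c1 - c2) * M.y;
  out.z = eta * u.z + (eta * c1 - c2) * M.z;
  double nn = std::sqrt(dot(out, out));
  out.x /= nn; out.y /= nn; out.z /= nn;
  return true;
}

// [[Rcpp::export(name = "mc_simulate_cpp")]]
List mc_simulate_cpp(int n_photons, int n_batches,
                     NumericVector layer_bottom,     // cumulative bottoms, last = ocean depth
                     NumericVector layer_a, NumericVector layer_b,
                     List layer_comp_cumfrac,        // per layer: cumulative component b fractions
                     List layer_comp_cdf,            // per layer: list of cos-theta quantile tables
                     double sun_zenith_deg, double sky_diffuse_fraction,
                     double slope_variance, double receiver_half_angle_deg,
                     double n_water,
                     double bottom_mirror, double bottom_diffuse,
                     double weight_cutoff) {
  RNGScope scope;
  const int n_layers = layer_bottom.size();
  const double depth = layer_bottom[n_layers - 1];
  const double slope_sd = std::sqrt(slope_variance / 2.0);
  const double cos_cone = std::cos(receiver_half_angle_deg * M_PI / 180.0);
  const double mu_sun = std::cos(sun_zenith_deg * M_PI / 180.0);
  const double sin_sun = std::sin(sun_zenith_deg * M_PI / 180.0);
  const long max_events = 1000000;

  // unpack component tables
  std::vector<std::vector<double>> cumfrac(n_layers);
  std::vector<std::vector<const double*>> cdfs(n_layers);
  std::vector<std::vector<int>> cdf_len(n_layers);
  std::vector<NumericVector> keep; // guard SEXPs from gc
  for (int l = 0; l < n_layers; ++l) {
    NumericVector cf = layer_comp_cumfrac[l];
    cumfrac[l] = std::vector<double>(cf.begin(), cf.end());
    List tabs = layer_comp_cdf[l];
    for (int k = 0; k < tabs.size(); ++k) {
      NumericVector t = tabs[k];
      keep.push_back(t);
      cdfs[l].push_back(REAL(t));
      cdf_len[l].push_back(t.size());
    }
  }

  double absorbed_col = 0, absorbed_bottom = 0, water_leaving = 0, surface_lost = 0;
  double cone_sum = 0, eu0m = 0, ed0m = 0;
  NumericVector cone_batch(n_batches);

  for (int ip = 0; ip < n_photons; ++ip) {
    int batch = (int)((double)ip * n_batches / n_photons);
    double w = 1.0;
    Vec3 u;

    // launch: direct beam or cardioid-distributed diffuse sky radiance
    if (unif() < sky_diffuse_fraction) {
      double mu;
      do {
        mu = unif();
      } while (unif() * 3.0 >= (1.0 + 2.0 * mu) * mu);
      double phi = 2.0 * M_PI * unif();
      double sn = std::sqrt(1.0 - mu * mu);
      u.x = sn * std::cos(phi); u.y = sn * std::sin(phi); u.z = mu;
    } else {
      u.x = sin_sun; u.y = 0.0; u.z = mu_sun;
    }

    // surface interaction from above (photon tagged: reflected light is not
    // water-leaving and is tallied as surface loss)
    bool entered = false;
    for (int attempt = 0; attempt < 200; ++attempt) {
      Vec3 N = sample_facet(slope_sd);
      double ci = -dot(u, N); // N points up, u points down: ci > 0 normally
      if (ci <= 0) continue;  // facet not visible to this direction; resample
      double R = fresnel_cpp(ci, n_water);
      if (unif() < R) {
        Vec3 v = reflect_dir(u, N);
        if (v.z < 0) { entered = false; break; } // back to the sky: lost
        u = v; // reflected toward the water: test the surface again
      } else {
        Vec3 t;
        if (!refract_dir(u, N, 1.0 / n_water, t)) continue;
        if (t.z <= 0) continue; // pathological facet; resample
        u = t;
        entered = true;
        break;
      }
    }
    if (!entered) { surface_lost += w; continue; }
    ed0m += w;

    double z = 0.0;
    int layer = 0;
    bool alive = true;
    long events = 0;

    while (alive) {
      if (++events > max_events) { absorbed_col += w; break; }
      double c = layer_a[layer] + layer_b[layer];
      double s = (c > 0) ? -std::log(unif()) / c : 1e30;
      double z_new = z + u.z * s;
      double z_top = (layer == 0) ? 0.0 : layer_bottom[layer - 1];
      double z_bot = layer_bottom[layer];

      if (u.z > 0 && z_new > z_bot) {
        // crossing the layer bottom
        if (z_bot >= depth) {
          double r = unif();
          if (r < bottom_mirror) {
            z = depth; u.z = -u.z;
          } else if (r < bottom_mirror + bottom_diffuse) {
            double mu = std::sqrt(unif()); // Lambertian re-emission upward
            double phi = 2.0 * M_PI * unif();
            double sn = std::sqrt(1.0 - mu * mu);
            u.x = sn * std::cos(phi); u.y = sn * std::sin(phi); u.z = -mu;
            z = depth;
          } else {
            absorbed_bottom += w;
            alive = false;
          }
        } else {
          z = z_bot; layer += 1;
        }
        continue;
      }
      if (u.z < 0 && z_new < z_top) {
        if (z_top <= 0.0) {
          // surface from below
          eu0m += w;
          bool done = false;
          for (int attempt = 0; attempt < 200; ++attempt) {
            Vec3 N = sample_facet(slope_sd);
            Vec3 M; M.x = -N.x; M.y = -N.y; M.z = -N.z; // oppose upward photon
            double ci = -dot(u, M);
            if (ci <= 0) continue;
            double sin2t = n_water * n_water * (1.0 - ci * ci);
            double R = (sin2t >= 1.0) ? 1.0 : fresnel_cpp(ci, 1.0 / n_water);
            if (unif() < R) {
              Vec3 v = reflect_dir(u, M);
              if (v.z > 0) { // reflected back into the water column
                u = v; z = 0.0; done = true; break;
              }
              u = v; // still upward: interacts with the surface again
            } else {
              Vec3 t;
              if (!refract_dir(u, M, n_water, t)) continue;
              if (t.z >= 0) continue;
              water_leaving += w;
              if (-t.z >= cos_cone) { cone_sum += w; cone_batch[batch] += w; }
              alive = false; done = true;
              break;
            }
          }
          if (!done) { // exhausted attempts: treat as internally reflected
            u.z = -u.z; z = 0.0;
          }
          if (!alive) break;
          ed0m += w; // re-entering downward through 0-
          continue;
        } else {
          z = z_top; layer -= 1;
          continue;
        }
      }

      // collision inside the layer
      z = z_new;
      double albedo = (c > 0) ? layer_b[layer] / c : 0.0;
      absorbed_col += w * (1.0 - albedo);
      w *= albedo;
      if (w < weight_cutoff) { absorbed_col += w; break; }
      // choose scattering component, then the deflection angle from its table
      double r = unif();
      int comp = 0;
      const std::vector<double>& cf = cumfrac[layer];
      while (comp < (int)cf.size() - 1 && r >= cf[comp]) ++comp;
      double cos_s = sample_cdf(cdfs[layer][comp], cdf_len[layer][comp], unif());
      double phi = 2.0 * M_PI * unif();
      u = rotate_dir(u, cos_s, phi);
    }
  }

  return List::create(
    _["cone_sum"] = cone_sum,
    _["cone_batch"] = cone_batch,
    _["absorbed_column"] = absorbed_col,
    _["absorbed_bottom"] = absorbed_bottom,
    _["water_leaving"] = water_leaving,
    _["surface_lost"] = surface_lost,
    _["eu0m"] = eu0m,
    _["ed0m"] = ed0m
  );
}
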