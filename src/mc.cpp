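// Voxel/layer Monte Carlo photon-packet transport for a layered slab.
//
// Geometry: z increases downward from the air-tissue surface at z = 0;
// layer i occupies the half-open slab [z_bounds[i], z_bounds[i+1]).
// Lateral extent is a square of side `lateral` centred on the origin.
// Uses R's RNG stream, so set.seed() on the R side fixes a run bitwise.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static inline double safe_clamp(double x, double lo, double hi) {
  return x < lo ? lo : (x > hi ? hi : x);
}

// Henyey-Greenstein inverse-transform sample of the deflection cosine.
static inline double hg_cosine(double g, double xi) {
  if (std::fabs(g) < 1e-12) return 1.0 - 2.0 * xi;
  double t = (1.0 - g * g) / (1.0 - g + 2.0 * g * xi);
  double c = (1.0 + g * g - t * t) / (2.0 * g);
  return safe_clamp(c, -1.0, 1.0);
}

// Unpolarized Fresnel reflectance for incidence cosine ci (>0), n1 -> n2.
// Returns 1.0 beyond the critical angle; fills ct with the refraction cosine.
static inline double fresnel_R(double n1, double n2, double ci, double *ct) {
  ci = safe_clamp(ci, 0.0, 1.0);
  if (n1 == n2) { *ct = ci; return 0.0; }
  double si = std::sqrt(std::max(0.0, 1.0 - ci * ci));
  double st = n1 / n2 * si;
  if (st >= 1.0) { *ct = 0.0; return 1.0; }  // total internal reflection
  double c2 = std::sqrt(std::max(0.0, 1.0 - st * st));
  *ct = c2;
  double rs = (n1 * ci - n2 * c2) / (n1 * ci + n2 * c2);
  double rp = (n1 * c2 - n2 * ci) / (n1 * c2 + n2 * ci);
  return 0.5 * (rs * rs + rp * rp);
}

// Rotate unit vector u by deflection cosine ct and azimuth psi (radians).
static inline void rotate_dir(double *ux, double *uy, double *uz,
                              double ct, double psi) {
  double st = std::sqrt(std::max(0.0, 1.0 - ct * ct));
  double cp = std::cos(psi), sp = std::sin(psi);
  double x = *ux, y = *uy, z = *uz;
  double nx, ny, nz;
  if (std::fabs(z) > 0.99999) {
    nx = st * cp;
    ny = st * sp;
    nz = (z >= 0 ? 1.0 : -1.0) * ct;
  } else {
    double den = std::sqrt(1.0 - z * z);
    nx = st * (x * z * cp - y * sp) / den + x * ct;
    ny = st * (y * z * cp + x * sp) / den + y * ct;
    nz = -st * cp * den + z * ct;
  }
  double norm = std::sqrt(nx * nx + ny * ny + nz * nz);
  *ux = nx / norm; *uy = ny / norm; *uz = nz / norm;
}

// ---- exported primitives (same code paths the engine uses) ----

// [[Rcpp::export(name = ".hg_cosine_cpp")]]
NumericVector hg_cosine_cpp(double g, NumericVector xi) {
  int n = xi.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = hg_cosine(g, xi[i]);
  return out;
}

// [[Rcpp::export(name = ".fresnel_reflectance_cpp")]]
List fresnel_reflectance_cpp(double n1, double n2, double cos_incidence) {
  double ct;
  double R = fresnel_R(n1, n2, cos_incidence, &ct);
  return List::create(_["reflectance"] = R, _["cos_transmit"] = ct);
}

// [[Rcpp::export(name = ".rotate_direction_cpp")]]
NumericVector rotate_direction_cpp(NumericVector dir, double cos_theta,
                                   double psi) {
  double ux = dir[0], uy = dir[1], uz = dir[2];
  rotate_dir(&ux, &uy, &uz, cos_theta, psi);
  return NumericVector::create(ux, uy, uz);
}

// ---- full simulation ----

// [[Rcpp::export(name = ".mc_run_cpp")]]
List mc_run_cpp(NumericVector z_bounds,      // length L+1, ascending from 0
                NumericMatrix optics,        // L x 4: mua, mus, g, n
                double n_ambient,
                double lateral,
                double src_x, double src_y,
                double det_x, double det_y, double det_radius,
                int n_launch_max, int n_detect_target,
                double roulette_threshold, double roulette_survival,
                double max_path,
                bool record_fluence, double voxel_edge,
                IntegerVector flu_dim) {
  const int L = optics.nrow();
  const double hx = lateral / 2.0;
  const double zmax = z_bounds[L];
  const double INF = R_PosInf;

  // hoist medium properties out of the transport loop
  std::vector<double> v_mua(L), v_mus(L), v_g(L), v_n(L), v_zb(L + 1);
  for (int i = 0; i < L; ++i) {
    v_mua[i] = optics(i, 0); v_mus[i] = optics(i, 1);
    v_g[i] = optics(i, 2);   v_n[i] = optics(i, 3);
  }
  for (int i = 0; i <= L; ++i) v_zb[i] = z_bounds[i];

  NumericVector fluence;
  int fnx = 0, fny = 0, fnz = 0;
  if (record_fluence) {
    fnx = flu_dim[0]; fny = flu_dim[1]; fnz = flu_dim[2];
    fluence = NumericVector((R_xlen_t)fnx * fny * fnz, 0.0);
  }

  double specular = 0.0, detected_w = 0.0, reflected_w = 0.0;
  double transmitted_w = 0.0, escaped_w = 0.0, absorbed_w = 0.0;
  double terminated_w = 0.0, roulette_net = 0.0;
  double path_sum_detected = 0.0;
  int n_detected = 0, n_launched = 0;

  const double n0 = v_n[0];
  const double rsp = ((n_ambient - n0) / (n_ambient + n0)) *
                     ((n_ambient - n0) / (n_ambient + n0));

  for (int ph = 0; ph < n_launch_max; ++ph) {
    if (n_detect_target > 0 && n_detected >= n_detect_target) break;
    ++n_launched;
    specular += rsp;
    double w = 1.0 - rsp;
    double x = src_x, y = src_y, z = 0.0;
    double ux = 0.0, uy = 0.0, uz = 1.0;
    int layer = 0;
    double path = 0.0;
    double s = -std::log(unif_rand());   // dimensionless step

    bool alive = true;
    while (alive) {
      double mua = v_mua[layer], mus = v_mus[layer];
      double mut = mua + mus;
      double d_geom = (mut > 0.0) ? s / mut : INF;

      // distance to the bounding z-plane of the current layer
      double d_bound = INF;
      bool going_down = uz > 0.0;
      if (uz > 1e-15)       d_bound = (v_zb[layer + 1] - z) / uz;
      else if (uz < -1e-15) d_bound = (v_zb[layer] - z) / uz;
      if (d_bound < 0.0) d_bound = 0.0;

      // distance to a lateral wall
      double d_lat = INF;
      if (ux > 1e-15)       d_lat = (hx - x) / ux;
      else if (ux < -1e-15) d_lat = (-hx - x) / ux;
      if (uy > 1e-15)       d_lat = std::min(d_lat, (hx - y) / uy);
      else if (uy < -1e-15) d_lat = std::min(d_lat, (-hx - y) / uy);

      double d = std::min(d_geom, std::min(d_bound, d_lat));
      x += ux * d; y += uy * d; z += uz * d;
      path += d;
      if (mut > 0.0) s -= mut * d;

      if (path > max_path) { terminated_w += w; break; }

      if (d == d_lat && d < d_geom) {           // left through a side wall
        escaped_w += w;
        break;
      }

      if (d == d_bound && d < d_geom) {         // layer interface / surface
        int next = going_down ? layer + 1 : layer - 1;
        double n1 = v_n[layer];
        double n2 = (next < 0 || next >= L) ? n_ambient : v_n[next];
        double ci = std::fabs(uz);
        double ct;
        double R = fresnel_R(n1, n2, ci, &ct);
        if (unif_rand() < R) {                  // reflect back
          uz = -uz;
          z = going_down ? v_zb[layer + 1] : v_zb[layer];
        } else {                                 // transmit / refract
          if (n1 != n2) {
            double ratio = n1 / n2;
            ux *= ratio; uy *= ratio;
            uz = (uz >= 0 ? 1.0 : -1.0) * ct;
            double norm = std::sqrt(ux * ux + uy * uy + uz * uz);
            ux /= norm; uy /= norm; uz /= norm;
          }
          if (next < 0) {                        // exits the top surface
            double dx = x - det_x, dy = y - det_y;
            if (dx * dx + dy * dy <= det_radius * det_radius) {
              detected_w += w;
              path_sum_detected += path;
              ++n_detected;
            } else {
              reflected_w += w;
            }
            break;
          }
          if (next >= L) {                       // exits the bottom
            transmitted_w += w;
            break;
          }
          layer = next;
          z = going_down ? v_zb[layer] : v_zb[layer + 1];
        }
        continue;
      }

      // interaction site: deposit, maybe roulette, scatter
      if (mut <= 0.0) break;                     // cannot happen: d finite
      double dep = w * mua / mut;
      absorbed_w += dep;
      if (record_fluence && dep > 0.0) {
        int ix = (int)std::floor((x + hx) / voxel_edge);
        int iy = (int)std::floor((y + hx) / voxel_edge);
        int iz = (int)std::floor(z / voxel_edge);
        if (ix < 0) ix = 0; if (ix >= fnx) ix = fnx - 1;
        if (iy < 0) iy = 0; if (iy >= fny) iy = fny - 1;
        if (iz < 0) iz = 0; if (iz >= fnz) iz = fnz - 1;
        fluence[(R_xlen_t)ix + (R_xlen_t)fnx * (iy + (R_xlen_t)fny * iz)] += dep;
      }
      w -= dep;

      if (w < roulette_threshold) {
        if (unif_rand() < roulette_survival) {
          double w_new = w / roulette_survival;
          roulette_net -= (w_new - w);           // injected weight
          w = w_new;
        } else {
          roulette_net += w;                     // killed weight
          break;
        }
      }

      double ct = hg_cosine(v_g[layer], unif_rand());
      double psi = 2.0 * M_PI * unif_rand();
      rotate_dir(&ux, &uy, &uz, ct, psi);
      s = -std::log(unif_rand());

      (void)zmax;
    }
  }

  List out = List::create(
    _["n_launched"] = n_launched,
    _["n_detected"] = n_detected,
    _["detected_weight_total"] = detected_w,
    _["intensity"] = n_launched > 0 ? detected_w / n_launched : NA_REAL,
    _["mean_optical_path"] =
        n_detected > 0 ? path_sum_detected / n_detected : NA_REAL,
    _["specular_weight"] = specular,
    _["reflected_weight"] = reflected_w,
    _["transmitted_weight"] = transmitted_w,
    _["escaped_side_weight"] = escaped_w,
    _["absorbed_weight"] = absorbed_w,
    _["terminated_weight"] = terminated_w,
    _["roulette_net"] = roulette_net);
  if (record_fluence) {
    fluence.attr("dim") = IntegerVector::create(fnx, fny, fnz);
    out["fluence_deposited"] = fluence;
  }
  return out;
}
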