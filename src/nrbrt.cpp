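#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static const double EPS = 1e-12;

// ---------------------------------------------------------------------------
// 2D voxel-walk line integral on a slice map.
//
// The map g has nrow = nz, ncol = ny; voxel (iz, iy) (0-based) covers
// z in [iz*h, (iz+1)*h), y in [iy*h, (iy+1)*h).  The ray starts at (y0, z0)
// (inside or on the boundary of the grid), travels along the unit vector
// (uy, uz) and is truncated at tmax or at the grid boundary, whichever comes
// first.  Chords are attributed to voxels by their midpoints, which is exact
// for piecewise-constant maps and robust when the ray runs along gridlines.
// ---------------------------------------------------------------------------
static double ray_integral_1(const NumericMatrix& g, double h,
                             double y0, double z0, double uy, double uz,
                             double tmax) {
  const int nz = g.nrow(), ny = g.ncol();
  const double Ly = ny * h, Lz = nz * h;

  // distance to grid exit
  double tExit = tmax;
  if (uy > EPS)       tExit = std::min(tExit, (Ly - y0) / uy);
  else if (uy < -EPS) tExit = std::min(tExit, (0.0 - y0) / uy);
  if (uz > EPS)       tExit = std::min(tExit, (Lz - z0) / uz);
  else if (uz < -EPS) tExit = std::min(tExit, (0.0 - z0) / uz);
  if (tExit <= 0) return 0.0;

  double t0 = 0.0, acc = 0.0;
  const double tiny = 1e-9 * h;
  int guard = 4 * (ny + nz) + 16;
  while (t0 < tExit - tiny && guard-- > 0) {
    double py = y0 + t0 * uy, pz = z0 + t0 * uz;
    double t1 = tExit;
    if (uy > EPS) {
      double nxt = (std::floor(py / h + 1e-9) + 1.0) * h;
      t1 = std::min(t1, t0 + (nxt - py) / uy);
    } else if (uy < -EPS) {
      double nxt = (std::ceil(py / h - 1e-9) - 1.0) * h;
      t1 = std::min(t1, t0 + (nxt - py) / uy);
    }
    if (uz > EPS) {
      double nxt = (std::floor(pz / h + 1e-9) + 1.0) * h;
      t1 = std::min(t1, t0 + (nxt - pz) / uz);
    } else if (uz < -EPS) {
      double nxt = (std::ceil(pz / h - 1e-9) - 1.0) * h;
      t1 = std::min(t1, t0 + (nxt - pz) / uz);
    }
    if (t1 <= t0 + tiny) t1 = std::min(t0 + tiny, tExit);
    double my = y0 + 0.5 * (t0 + t1) * uy, mz = z0 + 0.5 * (t0 + t1) * uz;
    int iy = (int)std::floor(my / h); if (iy < 0) iy = 0; if (iy >= ny) iy = ny - 1;
    int iz = (int)std::floor(mz / h); if (iz < 0) iz = 0; if (iz >= nz) iz = nz - 1;
    acc += g(iz, iy) * (t1 - t0);
    t0 = t1;
  }
  return acc;
}

// [[Rcpp::export]]
double cpp_ray_integral(NumericMatrix g, double h,
                        double y0, double z0, double uy, double uz,
                        double tmax) {
  return ray_integral_1(g, h, y0, z0, uy, uz, tmax);
}

// Vectorized form: starts is n x 2 (y, z), dirs is n x 2 (uy, uz) unit,
// tmax length n (use R_PosInf to integrate to the boundary).
// [[Rcpp::export]]
NumericVector cpp_ray_integrals(NumericMatrix g, double h,
                                NumericMatrix starts, NumericMatrix dirs,
                                NumericVector tmax) {
  const int n = starts.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; ++i)
    out[i] = ray_integral_1(g, h, starts(i, 0), starts(i, 1),
                            dirs(i, 0), dirs(i, 1), tmax[i]);
  return out;
}

// ---------------------------------------------------------------------------
// Analog Monte Carlo photon transport in a voxelized cuboid.
//
// Grids are 3D arrays in R layout (dim = c(nx, ny, nz), column-major), voxel
// (ix, iy, iz) covering [i*h, (i+1)*h) on each axis.  At the excitation
// wavelength the local interaction channels are intrinsic absorption (mu_a),
// isotropic elastic scattering (mu_s) and absorption by the fluorophore
// (n*sigma) followed by isotropic re-emission at the fluorescence wavelength
// with unit quantum yield.  At the fluorescence wavelength only mu_a_f and
// mu_s_f act (no reabsorption by the fluorophore).  Boundaries are
// index-matched: photons leaving the cuboid exit and are recorded.
//
// Free paths are sampled exactly for the piecewise-constant grids by
// accumulating optical depth voxel by voxel against an Exp(1) deviate.
// ---------------------------------------------------------------------------

struct Grid3 {
  const double* mu_a; const double* mu_s; const double* nsig;
  const double* mu_a_f; const double* mu_s_f;
  int nx, ny, nz; double h;
  inline int idx(int ix, int iy, int iz) const {
    return ix + nx * (iy + ny * iz);
  }
};

static inline void iso_dir(double& dx, double& dy, double& dz) {
  double ct = 2.0 * unif_rand() - 1.0;
  double st = std::sqrt(std::max(0.0, 1.0 - ct * ct));
  double ph = 2.0 * M_PI * unif_rand();
  dx = st * std::cos(ph); dy = st * std::sin(ph); dz = ct;
}

// [[Rcpp::export]]
List cpp_mc_propagate(NumericVector mu_a, NumericVector mu_s, NumericVector nsig,
                      NumericVector mu_a_f, NumericVector mu_s_f,
                      IntegerVector dims, double h,
                      NumericVector src_pos, NumericVector src_dir,
                      double n_photons,
                      bool record_excitation,
                      NumericMatrix record_axes, double record_cos_min,
                      double max_hits) {
  Grid3 G;
  G.mu_a = mu_a.begin(); G.mu_s = mu_s.begin(); G.nsig = nsig.begin();
  G.mu_a_f = mu_a_f.begin(); G.mu_s_f = mu_s_f.begin();
  G.nx = dims[0]; G.ny = dims[1]; G.nz = dims[2]; G.h = h;
  const double Lx = G.nx * h, Ly = G.ny * h, Lz = G.nz * h;
  const int n_axes = record_axes.ncol();

  std::vector<double> hits; // x,y,z,dx,dy,dz,tag per hit
  hits.reserve(1024);
  double absorbed = 0, exited_exc = 0, exited_flr = 0, converted = 0;
  bool overflow = false;
  const double tiny = 1e-9 * h;
  const long long N = (long long)n_photons;

  for (long long ip = 0; ip < N; ++ip) {
    double px = src_pos[0], py = src_pos[1], pz = src_pos[2];
    double dx = src_dir[0], dy = src_dir[1], dz = src_dir[2];
    int tag = 0; // 0 = excitation, 1 = fluorescence
    bool alive = true;
    int events = 0;

    while (alive && ++events < 100000) {
      double tau = -std::log(std::max(unif_rand(), 1e-300));
      // walk voxels until tau consumed or boundary reached
      bool exited = false;
      while (true) {
        // distance to next voxel boundary along each axis
        double t1 = R_PosInf;
        if (dx > EPS)       t1 = std::min(t1, ((std::floor(px / h + 1e-9) + 1.0) * h - px) / dx);
        else if (dx < -EPS) t1 = std::min(t1, ((std::ceil (px / h - 1e-9) - 1.0) * h - px) / dx);
        if (dy > EPS)       t1 = std::min(t1, ((std::floor(py / h + 1e-9) + 1.0) * h - py) / dy);
        else if (dy < -EPS) t1 = std::min(t1, ((std::ceil (py / h - 1e-9) - 1.0) * h - py) / dy);
        if (dz > EPS)       t1 = std::min(t1, ((std::floor(pz / h + 1e-9) + 1.0) * h - pz) / dz);
        else if (dz < -EPS) t1 = std::min(t1, ((std::ceil (pz / h - 1e-9) - 1.0) * h - pz) / dz);
        if (!R_FINITE(t1) || t1 < tiny) t1 = tiny;

        // voxel at the chord midpoint
        double mx = px + 0.5 * t1 * dx, my = py + 0.5 * t1 * dy, mz = pz + 0.5 * t1 * dz;
        if (mx < 0 || mx >= Lx || my < 0 || my >= Ly || mz < 0 || mz >= Lz) {
          exited = true;
          break;
        }
        int ix = (int)std::floor(mx / h), iy = (int)std::floor(my / h), iz = (int)std::floor(mz / h);
        int id = G.idx(ix, iy, iz);
        double mt = (tag == 0) ? (G.mu_a[id] + G.mu_s[id] + G.nsig[id])
                               : (G.mu_a_f[id] + G.mu_s_f[id]);
        double depth = mt * t1;
        if (depth >= tau && mt > 0) {
          // interaction inside this voxel
          double step = tau / mt;
          px += step * dx; py += step * dy; pz += step * dz;
          double u = unif_rand() * mt;
          if (tag == 0) {
            if (u < G.mu_a[id]) { absorbed += 1; alive = false; }
            else if (u < G.mu_a[id] + G.mu_s[id]) { iso_dir(dx, dy, dz); }
            else { tag = 1; converted += 1; iso_dir(dx, dy, dz); }
          } else {
            if (u < G.mu_a_f[id]) { absorbed += 1; alive = false; }
            else { iso_dir(dx, dy, dz); }
          }
          break;
        }
        tau -= depth;
        px += t1 * dx; py += t1 * dy; pz += t1 * dz;
      }
      if (exited) {
        if (tag == 0) exited_exc += 1; else exited_flr += 1;
        bool rec = record_excitation || tag == 1;
        if (rec && n_axes > 0 && tag == 1) {
          bool in_cone = false;
          for (int a = 0; a < n_axes && !in_cone; ++a) {
            double c = dx * record_axes(0, a) + dy * record_axes(1, a) + dz * record_axes(2, a);
            if (c >= record_cos_min) in_cone = true;
          }
          rec = in_cone;
        }
        if (rec) {
          if ((double)hits.size() / 7.0 < max_hits) {
            hits.push_back(px); hits.push_back(py); hits.push_back(pz);
            hits.push_back(dx); hits.push_back(dy); hits.push_back(dz);
            hits.push_back((double)tag);
          } else overflow = true;
        }
        alive = false;
      }
    }
    if (alive) { absorbed += 1; } // guard tripped: count as terminated
  }

  int nh = (int)(hits.size() / 7);
  NumericMatrix H(nh, 7);
  for (int i = 0; i < nh; ++i)
    for (int j = 0; j < 7; ++j) H(i, j) = hits[7 * i + j];
  colnames(H) = CharacterVector::create("x", "y", "z", "dx", "dy", "dz", "tag");
  return List::create(_["hits"] = H,
                      _["absorbed"] = absorbed,
                      _["exited_excitation"] = exited_exc,
                      _["exited_fluorescence"] = exited_flr,
                      _["converted"] = converted,
                      _["overflow"] = overflow);
}
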