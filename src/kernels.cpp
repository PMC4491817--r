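#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Trilinear sample of a column-major volume at continuous 0-based (x,y,z).
// Out-of-field coordinates return `fill`.
static inline double tri_sample(const double* v, int nx, int ny, int nz,
                                double x, double y, double z, double fill) {
  if (x < 0.0 || y < 0.0 || z < 0.0 ||
      x > nx - 1.0 || y > ny - 1.0 || z > nz - 1.0)
    return fill;
  int x0 = (int)std::floor(x), y0 = (int)std::floor(y), z0 = (int)std::floor(z);
  if (x0 == nx - 1) x0--;
  if (y0 == ny - 1) y0--;
  if (z0 == nz - 1) z0--;
  double fx = x - x0, fy = y - y0, fz = z - z0;
  const double* p = v + (size_t)x0 + (size_t)nx * ((size_t)y0 + (size_t)ny * z0);
  size_t sx = 1, sy = nx, sz = (size_t)nx * ny;
  double c00 = p[0] * (1 - fx) + p[sx] * fx;
  double c10 = p[sy] * (1 - fx) + p[sy + sx] * fx;
  double c01 = p[sz] * (1 - fx) + p[sz + sx] * fx;
  double c11 = p[sz + sy] * (1 - fx) + p[sz + sy + sx] * fx;
  double c0 = c00 * (1 - fy) + c10 * fy;
  double c1 = c01 * (1 - fy) + c11 * fy;
  return c0 * (1 - fz) + c1 * fz;
}

// Affine resampling: out(i,j,k) = vol(M %*% (i,j,k) + b), trilinear, 0-based.
// [[Rcpp::export]]
NumericVector cpp_affine_sample(NumericVector vol, IntegerVector dim,
                                NumericMatrix M, NumericVector b,
                                IntegerVector odim, double fill) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  int ox = odim[0], oy = odim[1], oz = odim[2];
  NumericVector out((size_t)ox * oy * oz);
  const double* v = vol.begin();
  double m00 = M(0, 0), m01 = M(0, 1), m02 = M(0, 2);
  double m10 = M(1, 0), m11 = M(1, 1), m12 = M(1, 2);
  double m20 = M(2, 0), m21 = M(2, 1), m22 = M(2, 2);
  double b0 = b[0], b1 = b[1], b2 = b[2];
  size_t idx = 0;
  for (int k = 0; k < oz; k++) {
    for (int j = 0; j < oy; j++) {
      double xj = m01 * j + m02 * k + b0;
      double yj = m11 * j + m12 * k + b1;
      double zj = m21 * j + m22 * k + b2;
      for (int i = 0; i < ox; i++, idx++) {
        out[idx] = tri_sample(v, nx, ny, nz,
                              m00 * i + xj, m10 * i + yj, m20 * i + zj, fill);
      }
    }
  }
  return out;
}

// Single-axis (y) backprojection of ramp-weighted projections.
// projs: nx x ny x ntilt, angles in radians, output nx x ny x nz.
// Rotation convention matches projecting a volume rotated by Ry(angle):
// image coordinate of voxel (x,z) is xr = (x-cx)*cos(a) + (z-cz)*sin(a) + cx.
// [[Rcpp::export]]
NumericVector cpp_backproject(NumericVector projs, IntegerVector pdim,
                              NumericVector angles, IntegerVector odim) {
  int nx = pdim[0], ny = pdim[1], nt = pdim[2];
  int ox = odim[0], oy = odim[1], oz = odim[2];
  NumericVector out((size_t)ox * oy * oz);
  double cx = std::floor(nx / 2.0), cox = std::floor(ox / 2.0),
         coz = std::floor(oz / 2.0);
  for (int t = 0; t < nt; t++) {
    double ca = std::cos(angles[t]), sa = std::sin(angles[t]);
    const double* P = projs.begin() + (size_t)t * nx * ny;
    for (int k = 0; k < oz; k++) {
      for (int i = 0; i < ox; i++) {
        double xr = (i - cox) * ca + (k - coz) * sa + cx;
        if (xr < 0.0 || xr > nx - 1.0) continue;
        int x0 = (int)std::floor(xr);
        if (x0 == nx - 1) x0--;
        double fx = xr - x0;
        const double* p0 = P + x0;
        double* o = out.begin() + (size_t)i + (size_t)ox * oy * k;
        for (int j = 0; j < oy; j++) {
          double val = p0[(size_t)nx * j] * (1 - fx) +
                       p0[(size_t)nx * j + 1] * fx;
          o[(size_t)ox * j] += val;
        }
      }
    }
  }
  return out;
}

static inline void euler_zxz(double phi, double theta, double psi, double R[9]) {
  double d = M_PI / 180.0;
  double cf = std::cos(phi * d), sf = std::sin(phi * d);
  double ct = std::cos(theta * d), st = std::sin(theta * d);
  double cp = std::cos(psi * d), sp = std::sin(psi * d);
  // R = Rz(phi) Rx(theta) Rz(psi), column-major storage R[col*3+row]
  R[0] = cf * cp - sf * ct * sp;  R[1] = sf * cp + cf * ct * sp;  R[2] = st * sp;
  R[3] = -cf * sp - sf * ct * cp; R[4] = -sf * sp + cf * ct * cp; R[5] = st * cp;
  R[6] = sf * st;                 R[7] = -cf * st;                R[8] = ct;
}

// Weighted local normalized CC of a body placed into a map.
// Body voxel p (0-based) maps to R*(p - cb) + pos in the map.
static double dock_cc(const double* map, int mx, int my, int mz,
                      const double* body, const double* mask,
                      int bx, int by, int bz,
                      const double R[9], const double* pos, double fill) {
  double cbx = std::floor(bx / 2.0), cby = std::floor(by / 2.0),
         cbz = std::floor(bz / 2.0);
  double Sm = 0, Sa = 0, Sb = 0, Saa = 0, Sbb = 0, Sab = 0;
  size_t idx = 0;
  for (int k = 0; k < bz; k++) {
    for (int j = 0; j < by; j++) {
      for (int i = 0; i < bx; i++, idx++) {
        double m = mask[idx];
        if (m <= 1e-8) continue;
        double px = i - cbx, py = j - cby, pz = k - cbz;
        double wx = R[0] * px + R[3] * py + R[6] * pz + pos[0];
        double wy = R[1] * px + R[4] * py + R[7] * pz + pos[1];
        double wz = R[2] * px + R[5] * py + R[8] * pz + pos[2];
        double a = tri_sample(map, mx, my, mz, wx, wy, wz, fill);
        double b = body[idx];
        Sm += m; Sa += m * a; Sb += m * b;
        Saa += m * a * a; Sbb += m * b * b; Sab += m * a * b;
      }
    }
  }
  if (Sm <= 0) return -2.0;
  double va = Saa - Sa * Sa / Sm, vb = Sbb - Sb * Sb / Sm;
  double cab = Sab - Sa * Sb / Sm;
  if (va <= 1e-12 || vb <= 1e-12) return -2.0;
  return cab / std::sqrt(va * vb);
}

// [[Rcpp::export]]
double cpp_dock_score(NumericVector map, IntegerVector mdim,
                      NumericVector body, NumericVector mask,
                      IntegerVector bdim, NumericVector euler,
                      NumericVector pos, double fill) {
  double R[9];
  euler_zxz(euler[0], euler[1], euler[2], R);
  double p[3] = {pos[0], pos[1], pos[2]};
  return dock_cc(map.begin(), mdim[0], mdim[1], mdim[2], body.begin(),
                 mask.begin(), bdim[0], bdim[1], bdim[2], R, p, fill);
}

// Coordinate-descent rigid-body refinement of a docking pose.
// Angle steps in degrees, shift steps in voxels; each schedule level runs
// until no single-parameter move improves the CC by more than tol,
// or max_steps sweeps are exhausted.
// [[Rcpp::export]]
List cpp_dock_refine(NumericVector map, IntegerVector mdim,
                     NumericVector body, NumericVector mask,
                     IntegerVector bdim, NumericVector euler0,
                     NumericVector pos0, NumericVector ang_steps,
                     NumericVector shift_steps, int max_steps,
                     double tol, double fill) {
  double par[6] = {euler0[0], euler0[1], euler0[2], pos0[0], pos0[1], pos0[2]};
  const double* mp = map.begin();
  const double* bp = body.begin();
  const double* mk = mask.begin();
  int mx = mdim[0], my = mdim[1], mz = mdim[2];
  int bx = bdim[0], by = bdim[1], bz = bdim[2];
  double R[9];
  euler_zxz(par[0], par[1], par[2], R);
  double best = dock_cc(mp, mx, my, mz, bp, mk, bx, by, bz, R, par + 3, fill);
  int neval = 1;
  int nlev = ang_steps.size();
  for (int lev = 0; lev < nlev; lev++) {
    double steps[6] = {ang_steps[lev], ang_steps[lev], ang_steps[lev],
                       shift_steps[lev], shift_steps[lev], shift_steps[lev]};
    for (int sweep = 0; sweep < max_steps; sweep++) {
      double gain = 0.0;
      for (int p = 0; p < 6; p++) {
        for (int sgn = -1; sgn <= 1; sgn += 2) {
          double trial[6];
          for (int q = 0; q < 6; q++) trial[q] = par[q];
          trial[p] += sgn * steps[p];
          euler_zxz(trial[0], trial[1], trial[2], R);
          double cc = dock_cc(mp, mx, my, mz, bp, mk, bx, by, bz, R,
                              trial + 3, fill);
          neval++;
          if (cc > best) {
            gain += cc - best;
            best = cc;
            for (int q = 0; q < 6; q++) par[q] = trial[q];
          }
        }
      }
      if (gain < tol) break;
    }
  }
  return List::create(_["phi"] = par[0], _["theta"] = par[1],
                      _["psi"] = par[2],
                      _["pos"] = NumericVector::create(par[3], par[4], par[5]),
                      _["cc"] = best, _["neval"] = neval);
}
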