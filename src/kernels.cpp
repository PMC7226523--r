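#include <Rcpp.h>
using namespace Rcpp;

// Separable 3-D filtering with circular (periodic) boundary handling.
// Filters are applied as centered correlations: out[i] = sum_k f[k] * v[i + k - c]
// with c = (len - 1) / 2 (integer division), independently along each axis.

static void filter_axis(const std::vector<double> &in, std::vector<double> &out,
                        int nx, int ny, int nz, const NumericVector &f, int axis) {
  const int len = f.size();
  const int c = (len - 1) / 2;
  const int n[3] = {nx, ny, nz};
  const int stride[3] = {1, nx, nx * ny};
  const int na = n[axis], sa = stride[axis];

  for (int z = 0; z < nz; ++z) {
    for (int y = 0; y < ny; ++y) {
      for (int x = 0; x < nx; ++x) {
        int idx[3] = {x, y, z};
        if (idx[axis] != 0) continue;  // process each line once, from its head
        int base = x + y * nx + z * nx * ny;
        for (int i = 0; i < na; ++i) {
          double acc = 0.0;
          for (int k = 0; k < len; ++k) {
            int j = i + k - c;
            j %= na; if (j < 0) j += na;  // wrap
            acc += f[k] * in[base + j * sa];
          }
          out[base + i * sa] = acc;
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_sep_filter3d(NumericVector vol, IntegerVector dim,
                               NumericVector fx, NumericVector fy, NumericVector fz) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  if ((int)vol.size() != nx * ny * nz) stop("volume length does not match dim");
  std::vector<double> a(vol.begin(), vol.end()), b(vol.size());
  filter_axis(a, b, nx, ny, nz, fx, 0);
  filter_axis(b, a, nx, ny, nz, fy, 1);
  filter_axis(a, b, nx, ny, nz, fz, 2);
  NumericVector out(b.begin(), b.end());
  out.attr("dim") = dim;
  return out;
}

// Trilinear resampling between grids that share a physical frame.
// Voxel centers sit at origin + (i - 1 + 0.5) * spacing (1-based indices).

// [[Rcpp::export]]
NumericVector cpp_resample3d(NumericVector vol, IntegerVector dim,
                             NumericVector spacing, NumericVector origin,
                             IntegerVector out_dim, NumericVector out_spacing,
                             NumericVector out_origin, bool nearest) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  int ox = out_dim[0], oy = out_dim[1], oz = out_dim[2];
  NumericVector out((R_xlen_t)ox * oy * oz);

  for (int k = 0; k < oz; ++k) {
    double pz = out_origin[2] + (k + 0.5) * out_spacing[2];
    double gz = (pz - origin[2]) / spacing[2] - 0.5;  // 0-based continuous index
    for (int j = 0; j < oy; ++j) {
      double py = out_origin[1] + (j + 0.5) * out_spacing[1];
      double gy = (py - origin[1]) / spacing[1] - 0.5;
      for (int i = 0; i < ox; ++i) {
        double px = out_origin[0] + (i + 0.5) * out_spacing[0];
        double gx = (px - origin[0]) / spacing[0] - 0.5;
        double val;
        if (nearest) {
          int xi = (int)std::lround(gx), yi = (int)std::lround(gy), zi = (int)std::lround(gz);
          xi = std::min(std::max(xi, 0), nx - 1);
          yi = std::min(std::max(yi, 0), ny - 1);
          zi = std::min(std::max(zi, 0), nz - 1);
          val = vol[xi + (R_xlen_t)yi * nx + (R_xlen_t)zi * nx * ny];
        } else {
          double cx = std::min(std::max(gx, 0.0), nx - 1.0);
          double cy = std::min(std::max(gy, 0.0), ny - 1.0);
          double cz = std::min(std::max(gz, 0.0), nz - 1.0);
          int x0 = (int)std::floor(cx), y0 = (int)std::floor(cy), z0 = (int)std::floor(cz);
          int x1 = std::min(x0 + 1, nx - 1), y1 = std::min(y0 + 1, ny - 1), z1 = std::min(z0 + 1, nz - 1);
          double tx = cx - x0, ty = cy - y0, tz = cz - z0;
          #define V(a,b,c) vol[(a) + (R_xlen_t)(b) * nx + (R_xlen_t)(c) * nx * ny]
          double c00 = V(x0,y0,z0) * (1-tx) + V(x1,y0,z0) * tx;
          double c10 = V(x0,y1,z0) * (1-tx) + V(x1,y1,z0) * tx;
          double c01 = V(x0,y0,z1) * (1-tx) + V(x1,y0,z1) * tx;
          double c11 = V(x0,y1,z1) * (1-tx) + V(x1,y1,z1) * tx;
          #undef V
          double c0 = c00 * (1-ty) + c10 * ty;
          double c1 = c01 * (1-ty) + c11 * ty;
          val = c0 * (1-tz) + c1 * tz;
        }
        out[i + (R_xlen_t)j * ox + (R_xlen_t)k * ox * oy] = val;
      }
    }
  }
  out.attr("dim") = out_dim;
  return out;
}
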