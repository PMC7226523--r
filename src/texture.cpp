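#include <Rcpp.h>
using namespace Rcpp;

// Texture-matrix builders on a discretized ROI: an integer volume where 0 marks
// voxels outside the mask and masked voxels carry gray levels 1..ng.
// Conventions: distance-1 neighborhoods; the 13 unique 3-D directions (offsets
// modulo sign) for co-occurrence and runs; 26-connectivity for zones,
// dependence counts and gray-tone neighborhoods.

static const int DIR13[13][3] = {
  {1,0,0},{0,1,0},{0,0,1},
  {1,1,0},{1,-1,0},{1,0,1},{1,0,-1},{0,1,1},{0,1,-1},
  {1,1,1},{1,1,-1},{1,-1,1},{1,-1,-1}
};

static inline int idx3(int x, int y, int z, int nx, int ny) {
  return x + y * nx + z * nx * ny;
}

// Symmetric co-occurrence counts, one ng x ng slab per direction -> ng x ng x 13.
// [[Rcpp::export]]
NumericVector cpp_glcm(IntegerVector lev, IntegerVector dim, int ng) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  NumericVector out((R_xlen_t)ng * ng * 13);
  for (int d = 0; d < 13; ++d) {
    int dx = DIR13[d][0], dy = DIR13[d][1], dz = DIR13[d][2];
    double *M = &out[(R_xlen_t)d * ng * ng];
    for (int z = 0; z < nz; ++z)
      for (int y = 0; y < ny; ++y)
        for (int x = 0; x < nx; ++x) {
          int a = lev[idx3(x, y, z, nx, ny)];
          if (a == 0) continue;
          int x2 = x + dx, y2 = y + dy, z2 = z + dz;
          if (x2 < 0 || x2 >= nx || y2 < 0 || y2 >= ny || z2 < 0 || z2 >= nz) continue;
          int b = lev[idx3(x2, y2, z2, nx, ny)];
          if (b == 0) continue;
          M[(a - 1) + (R_xlen_t)(b - 1) * ng] += 1.0;  // both orders: symmetric
          M[(b - 1) + (R_xlen_t)(a - 1) * ng] += 1.0;
        }
  }
  out.attr("dim") = IntegerVector::create(ng, ng, 13);
  return out;
}

// Run-length counts, ng x maxrun slab per direction -> ng x maxrun x 13.
// A run is a maximal straight segment of same-level masked voxels.
// [[Rcpp::export]]
NumericVector cpp_glrlm(IntegerVector lev, IntegerVector dim, int ng) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  int maxrun = std::max(std::max(nx, ny), nz);
  NumericVector out((R_xlen_t)ng * maxrun * 13);
  for (int d = 0; d < 13; ++d) {
    int dx = DIR13[d][0], dy = DIR13[d][1], dz = DIR13[d][2];
    double *M = &out[(R_xlen_t)d * ng * maxrun];
    for (int z = 0; z < nz; ++z)
      for (int y = 0; y < ny; ++y)
        for (int x = 0; x < nx; ++x) {
          int a = lev[idx3(x, y, z, nx, ny)];
          if (a == 0) continue;
          // start of a run: predecessor outside grid/mask or different level
          int xp = x - dx, yp = y - dy, zp = z - dz;
          bool head = xp < 0 || xp >= nx || yp < 0 || yp >= ny || zp < 0 || zp >= nz;
          if (!head && lev[idx3(xp, yp, zp, nx, ny)] != a) head = true;
          if (!head) continue;
          int len = 1;
          int xn = x + dx, yn = y + dy, zn = z + dz;
          while (xn >= 0 && xn < nx && yn >= 0 && yn < ny && zn >= 0 && zn < nz &&
                 lev[idx3(xn, yn, zn, nx, ny)] == a) {
            ++len; xn += dx; yn += dy; zn += dz;
          }
          M[(a - 1) + (R_xlen_t)(len - 1) * ng] += 1.0;
        }
  }
  out.attr("dim") = IntegerVector::create(ng, maxrun, 13);
  return out;
}

// Size-zone counts: 26-connected components of constant level -> ng x maxsize.
// [[Rcpp::export]]
NumericVector cpp_glszm(IntegerVector lev, IntegerVector dim, int ng) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  int n = nx * ny * nz;
  std::vector<char> seen(n, 0);
  std::vector<int> stack;
  std::vector<std::pair<int,int>> zones;  // (level, size)
  int maxsize = 1;
  for (int v = 0; v < n; ++v) {
    if (seen[v] || lev[v] == 0) continue;
    int a = lev[v], size = 0;
    stack.clear(); stack.push_back(v); seen[v] = 1;
    while (!stack.empty()) {
      int u = stack.back(); stack.pop_back(); ++size;
      int ux = u % nx, uy = (u / nx) % ny, uz = u / (nx * ny);
      for (int dz = -1; dz <= 1; ++dz)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dx = -1; dx <= 1; ++dx) {
            if (!dx && !dy && !dz) continue;
            int x2 = ux + dx, y2 = uy + dy, z2 = uz + dz;
            if (x2 < 0 || x2 >= nx || y2 < 0 || y2 >= ny || z2 < 0 || z2 >= nz) continue;
            int w = idx3(x2, y2, z2, nx, ny);
            if (!seen[w] && lev[w] == a) { seen[w] = 1; stack.push_back(w); }
          }
    }
    zones.push_back(std::make_pair(a, size));
    if (size > maxsize) maxsize = size;
  }
  NumericMatrix out(ng, maxsize);
  for (size_t i = 0; i < zones.size(); ++i)
    out(zones[i].first - 1, zones[i].second - 1) += 1.0;
  return out;
}

// Dependence counts: for each masked voxel, the number of 26-neighbors in the
// mask whose level differs by at most alpha (default 0) -> ng x (27) counts,
// column j = dependence j-1 (a voxel with no qualifying neighbor sits in col 1).
// [[Rcpp::export]]
NumericMatrix cpp_gldm(IntegerVector lev, IntegerVector dim, int ng, int alpha) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  NumericMatrix out(ng, 27);
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        int a = lev[idx3(x, y, z, nx, ny)];
        if (a == 0) continue;
        int dep = 0;
        for (int dz = -1; dz <= 1; ++dz)
          for (int dy = -1; dy <= 1; ++dy)
            for (int dx = -1; dx <= 1; ++dx) {
              if (!dx && !dy && !dz) continue;
              int x2 = x + dx, y2 = y + dy, z2 = z + dz;
              if (x2 < 0 || x2 >= nx || y2 < 0 || y2 >= ny || z2 < 0 || z2 >= nz) continue;
              int b = lev[idx3(x2, y2, z2, nx, ny)];
              if (b != 0 && std::abs(b - a) <= alpha) ++dep;
            }
        out(a - 1, dep) += 1.0;
      }
  return out;
}

// Neighboring gray-tone difference: per level i, n_i (voxel count) and
// s_i = sum over those voxels of |i - mean(masked 26-neighborhood)|.
// Voxels with no masked neighbor are skipped entirely.
// [[Rcpp::export]]
NumericMatrix cpp_ngtdm(IntegerVector lev, IntegerVector dim, int ng) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  NumericMatrix out(ng, 2);  // col 1: n_i, col 2: s_i
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        int a = lev[idx3(x, y, z, nx, ny)];
        if (a == 0) continue;
        double sum = 0.0; int cnt = 0;
        for (int dz = -1; dz <= 1; ++dz)
          for (int dy = -1; dy <= 1; ++dy)
            for (int dx = -1; dx <= 1; ++dx) {
              if (!dx && !dy && !dz) continue;
              int x2 = x + dx, y2 = y + dy, z2 = z + dz;
              if (x2 < 0 || x2 >= nx || y2 < 0 || y2 >= ny || z2 < 0 || z2 >= nz) continue;
              int b = lev[idx3(x2, y2, z2, nx, ny)];
              if (b != 0) { sum += b; ++cnt; }
            }
        if (cnt == 0) continue;
        out(a - 1, 0) += 1.0;
        out(a - 1, 1) += std::fabs(a - sum / cnt);
      }
  return out;
}
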