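#include <Rcpp.h>
using namespace Rcpp;

// Mesh-based shape measurements of a (possibly smoothed) mask field.
//
// The iso-surface of the scalar field sampled at voxel centers is
// triangulated by marching tetrahedra: each grid cube (spanning 8 voxel
// centers, grid padded with background) is split into the six Kuhn
// tetrahedra around the main diagonal; within a tetrahedron the surface
// crosses in-out edges at the linearly interpolated iso level. Triangles
// are oriented outward by construction checks, so the divergence theorem
// gives the enclosed volume.

struct V3 { double x, y, z; };
static inline V3 mid(const V3 &a, const V3 &b) {
  V3 m = {(a.x + b.x) / 2, (a.y + b.y) / 2, (a.z + b.z) / 2}; return m;
}
static inline V3 sub(const V3 &a, const V3 &b) { V3 r = {a.x-b.x, a.y-b.y, a.z-b.z}; return r; }
static inline V3 cross(const V3 &a, const V3 &b) {
  V3 r = {a.y*b.z - a.z*b.y, a.z*b.x - a.x*b.z, a.x*b.y - a.y*b.x}; return r;
}
static inline double dot(const V3 &a, const V3 &b) { return a.x*b.x + a.y*b.y + a.z*b.z; }

// Kuhn tetrahedra of the unit cube; corner ids use bits x=1, y=2, z=4.
static const int TETS[6][4] = {
  {0,1,3,7},{0,1,5,7},{0,2,3,7},{0,2,6,7},{0,4,5,7},{0,4,6,7}
};

// accumulate one outward-oriented triangle
static void add_tri(V3 a, V3 b, V3 c, const V3 &inside_ref,
                    double &area, double &vol6) {
  V3 n = cross(sub(b, a), sub(c, a));
  V3 centroid = {(a.x+b.x+c.x)/3, (a.y+b.y+c.y)/3, (a.z+b.z+c.z)/3};
  V3 outwards = sub(centroid, inside_ref);
  if (dot(n, outwards) < 0) { V3 t = b; b = c; c = t; n = cross(sub(b,a), sub(c,a)); }
  area += 0.5 * std::sqrt(dot(n, n));
  vol6 += dot(a, cross(b, c));
}

// [[Rcpp::export]]
List cpp_mesh_shape(NumericVector field, IntegerVector dim, NumericVector spacing,
                    double iso) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  double sx = spacing[0], sy = spacing[1], sz = spacing[2];
  double area = 0.0, vol6 = 0.0;

  // padded grid-point lookup: voxel centers, background outside
  auto val = [&](int x, int y, int z) -> double {
    if (x < 0 || x >= nx || y < 0 || y >= ny || z < 0 || z >= nz) return 0.0;
    return field[x + (R_xlen_t)y * nx + (R_xlen_t)z * nx * ny];
  };

  for (int z = -1; z < nz; ++z)
    for (int y = -1; y < ny; ++y)
      for (int x = -1; x < nx; ++x) {
        double corner_val[8];
        V3 corner_pos[8];
        int total = 0;
        for (int c = 0; c < 8; ++c) {
          int cx = x + (c & 1), cy = y + ((c >> 1) & 1), cz = z + ((c >> 2) & 1);
          corner_val[c] = val(cx, cy, cz);
          total += corner_val[c] > iso;
          corner_pos[c].x = (cx + 0.5) * sx;
          corner_pos[c].y = (cy + 0.5) * sy;
          corner_pos[c].z = (cz + 0.5) * sz;
        }
        if (total == 0 || total == 8) continue;
        for (int t = 0; t < 6; ++t) {
          int vin[4], nin = 0, nout = 0, vout[4];
          for (int c = 0; c < 4; ++c) {
            int id = TETS[t][c];
            if (corner_val[id] > iso) vin[nin++] = id; else vout[nout++] = id;
          }
          if (nin == 0 || nin == 4) continue;
          // linear interpolation of the iso crossing along an in-out edge
          auto xing = [&](int vi, int vo) -> V3 {
            double a = corner_val[vi], b = corner_val[vo];
            double tt = (a == b) ? 0.5 : (iso - a) / (b - a);
            if (tt < 0) tt = 0; if (tt > 1) tt = 1;
            V3 p = {corner_pos[vi].x + tt * (corner_pos[vo].x - corner_pos[vi].x),
                    corner_pos[vi].y + tt * (corner_pos[vo].y - corner_pos[vi].y),
                    corner_pos[vi].z + tt * (corner_pos[vo].z - corner_pos[vi].z)};
            return p;
          };
          // reference point on the inside of the local surface patch
          V3 iref = {0, 0, 0};
          for (int c = 0; c < nin; ++c) {
            iref.x += corner_pos[vin[c]].x; iref.y += corner_pos[vin[c]].y;
            iref.z += corner_pos[vin[c]].z;
          }
          iref.x /= nin; iref.y /= nin; iref.z /= nin;
          if (nin == 1) {
            add_tri(xing(vin[0], vout[0]), xing(vin[0], vout[1]),
                    xing(vin[0], vout[2]), iref, area, vol6);
          } else if (nin == 3) {
            add_tri(xing(vin[0], vout[0]), xing(vin[1], vout[0]),
                    xing(vin[2], vout[0]), iref, area, vol6);
          } else {  // 2 in, 2 out: quad over the four crossed edges
            V3 a = xing(vin[0], vout[0]);
            V3 b = xing(vin[0], vout[1]);
            V3 c = xing(vin[1], vout[1]);
            V3 d = xing(vin[1], vout[0]);
            add_tri(a, b, c, iref, area, vol6);
            add_tri(a, c, d, iref, area, vol6);
          }
        }
      }

  return List::create(_["surface_area"] = area,
                      _["mesh_volume"] = std::fabs(vol6) / 6.0);
}

// Maximum pairwise extents from surface voxel centers (voxels with a
// face-neighbor outside the mask). "slice" pairs share the 3rd index,
// "column" the 2nd, "row" the 1st; distances are taken in the remaining plane.
// [[Rcpp::export]]
List cpp_diameters(IntegerVector mask, IntegerVector dim, NumericVector spacing) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  std::vector<double> px, py, pz;
  auto inm = [&](int x, int y, int z) -> bool {
    if (x < 0 || x >= nx || y < 0 || y >= ny || z < 0 || z >= nz) return false;
    return mask[x + (R_xlen_t)y * nx + (R_xlen_t)z * nx * ny] != 0;
  };
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        if (!inm(x, y, z)) continue;
        bool surf = !inm(x-1,y,z) || !inm(x+1,y,z) || !inm(x,y-1,z) ||
                    !inm(x,y+1,z) || !inm(x,y,z-1) || !inm(x,y,z+1);
        if (!surf) continue;
        px.push_back((x + 0.5) * spacing[0]);
        py.push_back((y + 0.5) * spacing[1]);
        pz.push_back((z + 0.5) * spacing[2]);
      }
  size_t m = px.size();
  double d3 = 0, dsl = 0, dcol = 0, drow = 0;
  for (size_t i = 0; i < m; ++i)
    for (size_t j = i + 1; j < m; ++j) {
      double dx = px[i]-px[j], dy = py[i]-py[j], dz = pz[i]-pz[j];
      double dd = dx*dx + dy*dy + dz*dz;
      if (dd > d3) d3 = dd;
      if (pz[i] == pz[j] && dx*dx + dy*dy > dsl) dsl = dx*dx + dy*dy;
      if (py[i] == py[j] && dx*dx + dz*dz > dcol) dcol = dx*dx + dz*dz;
      if (px[i] == px[j] && dy*dy + dz*dz > drow) drow = dy*dy + dz*dz;
    }
  return List::create(_["max3d"] = std::sqrt(d3),
                      _["slice"] = std::sqrt(dsl),
                      _["column"] = std::sqrt(dcol),
                      _["row"] = std::sqrt(drow));
}
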