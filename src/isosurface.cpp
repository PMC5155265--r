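// Isosurface extraction from a scalar grid by tetrahedral decomposition of
// each cell (Kuhn 6-tet split with a fixed main diagonal). The split is
// face-consistent across neighbouring cells, and every tetrahedral case is
// unambiguous, so the extracted surface is watertight by construction.
#include <Rcpp.h>
#include <vector>
#include <cstdint>
#include <unordered_map>
#include "vec3.h"

using namespace Rcpp;

// values: grid of nx*ny*nz scalars at voxel centres (x fastest), world
// position of point (i,j,k) = origin + (i,j,k)*spacing
// [[Rcpp::export]]
List cpp_marching_tets(NumericVector values, int nx, int ny, int nz,
                       NumericVector origin, double spacing, double iso) {
  // the six tetrahedra of the Kuhn subdivision, as cube-corner ids
  // (bit 1 = +x, bit 2 = +y, bit 4 = +z); all share diagonal 0-7
  static const int tets[6][4] = {
    {0, 1, 3, 7}, {0, 1, 5, 7}, {0, 2, 3, 7},
    {0, 2, 6, 7}, {0, 4, 5, 7}, {0, 4, 6, 7}
  };

  auto gid = [&](int i, int j, int k) {
    return (int64_t)i + (int64_t)nx * ((int64_t)j + (int64_t)ny * k);
  };
  auto gpos = [&](int64_t g) {
    int i = (int)(g % nx);
    int j = (int)((g / nx) % ny);
    int k = (int)(g / ((int64_t)nx * ny));
    return Vec3(origin[0] + i * spacing, origin[1] + j * spacing,
                origin[2] + k * spacing);
  };

  std::vector<double> vert;
  std::vector<int> face;
  std::unordered_map<int64_t, int> edgemap;
  int64_t NG = (int64_t)nx * ny * nz;

  auto crossing = [&](int64_t ga, int64_t gb) {
    int64_t lo = std::min(ga, gb), hi = std::max(ga, gb);
    int64_t key = lo * NG + hi;
    auto it = edgemap.find(key);
    if (it != edgemap.end()) return it->second;
    double va = values[lo], vb = values[hi];
    double t = (va == vb) ? 0.5 : (iso - va) / (vb - va);
    if (t < 0) t = 0;
    if (t > 1) t = 1;
    Vec3 pa = gpos(lo), pb = gpos(hi);
    Vec3 p = pa + (pb - pa) * t;
    int id = (int)(vert.size() / 3);
    vert.insert(vert.end(), {p.x, p.y, p.z});
    edgemap[key] = id;
    return id;
  };

  auto emit = [&](int a, int b, int c, const Vec3& inref, const Vec3& outref) {
    Vec3 pa(vert[3 * a], vert[3 * a + 1], vert[3 * a + 2]);
    Vec3 pb(vert[3 * b], vert[3 * b + 1], vert[3 * b + 2]);
    Vec3 pc(vert[3 * c], vert[3 * c + 1], vert[3 * c + 2]);
    Vec3 n = (pb - pa).cross(pc - pa);
    if (n.dot(outref - inref) < 0) std::swap(b, c);
    face.insert(face.end(), {a, b, c});
  };

  for (int k = 0; k + 1 < nz; ++k)
    for (int j = 0; j + 1 < ny; ++j)
      for (int i = 0; i + 1 < nx; ++i) {
        int64_t corners[8];
        double cv[8];
        bool anyin = false, anyout = false;
        for (int c = 0; c < 8; ++c) {
          corners[c] = gid(i + (c & 1), j + ((c >> 1) & 1), k + ((c >> 2) & 1));
          cv[c] = values[corners[c]];
          if (cv[c] >= iso) anyin = true; else anyout = true;
        }
        if (!anyin || !anyout) continue;
        for (int t = 0; t < 6; ++t) {
          int64_t tg[4];
          bool tin[4];
          int nin = 0;
          for (int v = 0; v < 4; ++v) {
            tg[v] = corners[tets[t][v]];
            tin[v] = cv[tets[t][v]] >= iso;
            if (tin[v]) ++nin;
          }
          if (nin == 0 || nin == 4) continue;
          int ins[4], outs[4];
          int ni = 0, no = 0;
          for (int v = 0; v < 4; ++v) {
            if (tin[v]) ins[ni++] = v; else outs[no++] = v;
          }
          Vec3 cin(0, 0, 0), cout(0, 0, 0);
          for (int v = 0; v < ni; ++v) cin = cin + gpos(tg[ins[v]]);
          for (int v = 0; v < no; ++v) cout = cout + gpos(tg[outs[v]]);
          cin = cin * (1.0 / ni);
          cout = cout * (1.0 / no);
          if (nin == 1) {
            int a = crossing(tg[ins[0]], tg[outs[0]]);
            int b = crossing(tg[ins[0]], tg[outs[1]]);
            int c = crossing(tg[ins[0]], tg[outs[2]]);
            emit(a, b, c, cin, cout);
          } else if (nin == 3) {
            int a = crossing(tg[outs[0]], tg[ins[0]]);
            int b = crossing(tg[outs[0]], tg[ins[1]]);
            int c = crossing(tg[outs[0]], tg[ins[2]]);
            emit(a, b, c, cin, cout);
          } else {
            int a = crossing(tg[ins[0]], tg[outs[0]]);
            int b = crossing(tg[ins[0]], tg[outs[1]]);
            int c = crossing(tg[ins[1]], tg[outs[1]]);
            int d = crossing(tg[ins[1]], tg[outs[0]]);
            emit(a, b, c, cin, cout);
            emit(a, c, d, cin, cout);
          }
        }
      }

  int nv = (int)(vert.size() / 3), nf = (int)(face.size() / 3);
  NumericMatrix V(nv, 3);
  for (int i = 0; i < nv; ++i)
    for (int c = 0; c < 3; ++c) V(i, c) = vert[3 * i + c];
  IntegerMatrix F(nf, 3);
  for (int i = 0; i < nf; ++i)
    for (int c = 0; c < 3; ++c) F(i, c) = face[3 * i + c] + 1;
  return List::create(_["vertices"] = V, _["faces"] = F);
}
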