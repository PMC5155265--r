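// Point-to-mesh distance queries (median-split AABB tree) and generalized
// winding numbers, shared by the signed-distance field, cell classification
// and surface-distance metrics.
#include <Rcpp.h>
#include <vector>
#include <stack>
#include <limits>
#include <cstdint>
#include <unordered_map>
#include <functional>
#include "vec3.h"

using namespace Rcpp;

namespace {

struct Tri { Vec3 a, b, c; };

struct BVHNode {
  Vec3 lo, hi;
  int left, right;   // -1 for leaf
  int start, count;  // leaf range into order[]
};

struct BVH {
  std::vector<Tri> tris;
  std::vector<int> order;
  std::vector<BVHNode> nodes;

  void build(const NumericMatrix& V, const IntegerMatrix& F) {
    int m = F.nrow();
    tris.resize(m);
    order.resize(m);
    for (int i = 0; i < m; ++i) {
      int ia = F(i, 0) - 1, ib = F(i, 1) - 1, ic = F(i, 2) - 1;
      tris[i].a = Vec3(V(ia, 0), V(ia, 1), V(ia, 2));
      tris[i].b = Vec3(V(ib, 0), V(ib, 1), V(ib, 2));
      tris[i].c = Vec3(V(ic, 0), V(ic, 1), V(ic, 2));
      order[i] = i;
    }
    nodes.reserve(2 * m);
    if (m > 0) build_node(0, m);
  }

  int build_node(int start, int count) {
    BVHNode nd;
    nd.lo = Vec3(1e300, 1e300, 1e300);
    nd.hi = Vec3(-1e300, -1e300, -1e300);
    for (int i = start; i < start + count; ++i) {
      const Tri& t = tris[order[i]];
      const Vec3* ps[3] = { &t.a, &t.b, &t.c };
      for (int k = 0; k < 3; ++k) {
        nd.lo.x = std::min(nd.lo.x, ps[k]->x); nd.hi.x = std::max(nd.hi.x, ps[k]->x);
        nd.lo.y = std::min(nd.lo.y, ps[k]->y); nd.hi.y = std::max(nd.hi.y, ps[k]->y);
        nd.lo.z = std::min(nd.lo.z, ps[k]->z); nd.hi.z = std::max(nd.hi.z, ps[k]->z);
      }
    }
    int idx = (int)nodes.size();
    nodes.push_back(nd);
    if (count <= 8) {
      nodes[idx].left = nodes[idx].right = -1;
      nodes[idx].start = start; nodes[idx].count = count;
      return idx;
    }
    Vec3 ext = nd.hi - nd.lo;
    int axis = 0;
    if (ext.y > ext.x && ext.y >= ext.z) axis = 1;
    else if (ext.z > ext.x && ext.z >= ext.y) axis = 2;
    int mid = start + count / 2;
    std::nth_element(order.begin() + start, order.begin() + mid,
                     order.begin() + start + count,
                     [&](int u, int v) { return centroid(u, axis) < centroid(v, axis); });
    int l = build_node(start, mid - start);
    int r = build_node(mid, start + count - mid);
    nodes[idx].left = l; nodes[idx].right = r;
    nodes[idx].start = -1; nodes[idx].count = 0;
    return idx;
  }

  double centroid(int t, int axis) const {
    const Tri& tr = tris[t];
    double s = 0;
    switch (axis) {
      case 0: s = tr.a.x + tr.b.x + tr.c.x; break;
      case 1: s = tr.a.y + tr.b.y + tr.c.y; break;
      default: s = tr.a.z + tr.b.z + tr.c.z; break;
    }
    return s / 3.0;
  }

  static double box_dist2(const Vec3& p, const Vec3& lo, const Vec3& hi) {
    double dx = std::max({lo.x - p.x, 0.0, p.x - hi.x});
    double dy = std::max({lo.y - p.y, 0.0, p.y - hi.y});
    double dz = std::max({lo.z - p.z, 0.0, p.z - hi.z});
    return dx * dx + dy * dy + dz * dz;
  }

  double nearest(const Vec3& p, Vec3* cp = nullptr) const {
    if (nodes.empty()) return std::numeric_limits<double>::infinity();
    double best = std::numeric_limits<double>::infinity();
    Vec3 bestp;
    std::stack<int> st;
    st.push(0);
    while (!st.empty()) {
      int ni = st.top(); st.pop();
      const BVHNode& nd = nodes[ni];
      if (box_dist2(p, nd.lo, nd.hi) >= best) continue;
      if (nd.left < 0) {
        for (int i = nd.start; i < nd.start + nd.count; ++i) {
          const Tri& t = tris[order[i]];
          Vec3 q = closest_point_triangle(p, t.a, t.b, t.c);
          double d2 = (q - p).norm2();
          if (d2 < best) { best = d2; bestp = q; }
        }
      } else {
        double dl = box_dist2(p, nodes[nd.left].lo, nodes[nd.left].hi);
        double dr = box_dist2(p, nodes[nd.right].lo, nodes[nd.right].hi);
        if (dl < dr) { st.push(nd.right); st.push(nd.left); }
        else { st.push(nd.left); st.push(nd.right); }
      }
    }
    if (cp) *cp = bestp;
    return std::sqrt(best);
  }
};

}  // namespace

// [[Rcpp::export]]
NumericVector cpp_nearest_distance(NumericMatrix V, IntegerMatrix F,
                                   NumericMatrix P) {
  BVH bvh;
  bvh.build(V, F);
  int n = P.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    Vec3 p(P(i, 0), P(i, 1), P(i, 2));
    out[i] = bvh.nearest(p);
  }
  return out;
}

// Generalized winding number of each query point with respect to the surface
// (sum of signed solid angles / 4*pi); ~0 outside, ~1 inside a closed
// outward-oriented surface.
// [[Rcpp::export]]
NumericVector cpp_winding_number(NumericMatrix V, IntegerMatrix F,
                                 NumericMatrix P) {
  int m = F.nrow(), n = P.nrow();
  std::vector<Vec3> verts(V.nrow());
  for (int i = 0; i < V.nrow(); ++i) verts[i] = Vec3(V(i, 0), V(i, 1), V(i, 2));
  NumericVector out(n);
  const double fourpi = 4.0 * M_PI;
  for (int i = 0; i < n; ++i) {
    Vec3 p(P(i, 0), P(i, 1), P(i, 2));
    double w = 0.0;
    for (int f = 0; f < m; ++f) {
      Vec3 a = verts[F(f, 0) - 1] - p;
      Vec3 b = verts[F(f, 1) - 1] - p;
      Vec3 c = verts[F(f, 2) - 1] - p;
      double la = a.norm(), lb = b.norm(), lc = c.norm();
      double det = a.dot(b.cross(c));
      double den = la * lb * lc + a.dot(b) * lc + b.dot(c) * la + c.dot(a) * lb;
      w += 2.0 * std::atan2(det, den);
    }
    out[i] = w / fourpi;
  }
  return out;
}

// Tolerance-based vertex welding: grid hashing plus union-find over the 27
// neighbouring cells, so pairs straddling a cell boundary still merge.
// [[Rcpp::export]]
List cpp_merge_vertices(NumericMatrix V, IntegerMatrix F, double tol) {
  int n = V.nrow();
  std::vector<int> parent(n);
  for (int i = 0; i < n; ++i) parent[i] = i;
  std::function<int(int)> find = [&](int x) {
    while (parent[x] != x) { parent[x] = parent[parent[x]]; x = parent[x]; }
    return x;
  };
  auto unite = [&](int a, int b) {
    a = find(a); b = find(b);
    if (a != b) parent[std::max(a, b)] = std::min(a, b);
  };

  if (tol > 0 && n > 0) {
    double cell = tol * 2.0;
    std::unordered_map<uint64_t, std::vector<int>> grid;
    grid.reserve(n * 2);
    auto key = [&](long long ix, long long iy, long long iz) {
      uint64_t h = (uint64_t)(ix * 73856093LL) ^ (uint64_t)(iy * 19349663LL) ^
                   (uint64_t)(iz * 83492791LL);
      return h;
    };
    std::vector<long long> cix(n), ciy(n), ciz(n);
    for (int i = 0; i < n; ++i) {
      cix[i] = (long long)std::floor(V(i, 0) / cell);
      ciy[i] = (long long)std::floor(V(i, 1) / cell);
      ciz[i] = (long long)std::floor(V(i, 2) / cell);
      grid[key(cix[i], ciy[i], ciz[i])].push_back(i);
    }
    double tol2 = tol * tol;
    for (int i = 0; i < n; ++i) {
      for (long long dx = -1; dx <= 1; ++dx)
        for (long long dy = -1; dy <= 1; ++dy)
          for (long long dz = -1; dz <= 1; ++dz) {
            auto it = grid.find(key(cix[i] + dx, ciy[i] + dy, ciz[i] + dz));
            if (it == grid.end()) continue;
            for (int j : it->second) {
              if (j <= i) continue;
              double ddx = V(i, 0) - V(j, 0), ddy = V(i, 1) - V(j, 1),
                     ddz = V(i, 2) - V(j, 2);
              if (ddx * ddx + ddy * ddy + ddz * ddz <= tol2) unite(i, j);
            }
          }
    }
  }

  // compact representative vertices (first occurrence keeps its coordinates)
  std::vector<int> newid(n, -1);
  int nv = 0;
  for (int i = 0; i < n; ++i) {
    int r = find(i);
    if (newid[r] < 0) newid[r] = nv++;
    newid[i] = newid[r];
  }
  NumericMatrix V2(nv, 3);
  std::vector<bool> seen(nv, false);
  for (int i = 0; i < n; ++i) {
    int id = newid[i];
    if (!seen[id]) {
      V2(id, 0) = V(i, 0); V2(id, 1) = V(i, 1); V2(id, 2) = V(i, 2);
      seen[id] = true;
    }
  }
  IntegerMatrix F2(F.nrow(), 3);
  for (int f = 0; f < F.nrow(); ++f)
    for (int k = 0; k < 3; ++k) F2(f, k) = newid[F(f, k) - 1] + 1;
  IntegerVector map(n);
  for (int i = 0; i < n; ++i) map[i] = newid[i] + 1;
  return List::create(_["vertices"] = V2, _["faces"] = F2, _["map"] = map);
}
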