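// Core of the mesh Boolean engine: AABB-grid candidate pair culling,
// triangle-triangle intersection segments, constrained retriangulation of
// intersected faces (so intersection curves become mesh edges), a
// self-intersection scan, and T-junction repair.
#include <Rcpp.h>
#include <vector>
#include <array>
#include <cstdint>
#include <unordered_map>
#include <algorithm>
#include "vec3.h"

using namespace Rcpp;

namespace {

struct P2 { double x, y; };

inline double orient2(const P2& a, const P2& b, const P2& c) {
  return (b.x - a.x) * (c.y - a.y) - (b.y - a.y) * (c.x - a.x);
}

inline double d2(const P2& a, const P2& b) {
  double dx = a.x - b.x, dy = a.y - b.y;
  return dx * dx + dy * dy;
}

// signed: > 0 iff d strictly inside circumcircle of CCW triangle (a,b,c)
inline double incircle(const P2& a, const P2& b, const P2& c, const P2& d) {
  double adx = a.x - d.x, ady = a.y - d.y;
  double bdx = b.x - d.x, bdy = b.y - d.y;
  double cdx = c.x - d.x, cdy = c.y - d.y;
  double ad2 = adx * adx + ady * ady;
  double bd2 = bdx * bdx + bdy * bdy;
  double cd2 = cdx * cdx + cdy * cdy;
  return adx * (bdy * cd2 - cdy * bd2) - ady * (bdx * cd2 - cdx * bd2) +
         ad2 * (bdx * cdy - cdx * bdy);
}

// ---------------------------------------------------------------------------
// Local constrained triangulation of one face
// ---------------------------------------------------------------------------

struct LocalCDT {
  std::vector<P2> pts;
  std::vector<std::array<int, 3>> tris;  // [0] == -1 marks a dead triangle
  double tol;                            // world-unit snapping tolerance

  void init(const P2& a, const P2& b, const P2& c) {
    pts = {a, b, c};
    tris.clear();
    tris.push_back({0, 1, 2});
  }

  bool alive(int t) const { return tris[t][0] >= 0; }
  void kill(int t) { tris[t][0] = -1; }

  int find_vertex(const P2& p) const {
    double t2 = tol * tol;
    for (size_t i = 0; i < pts.size(); ++i)
      if (d2(pts[i], p) <= t2) return (int)i;
    return -1;
  }

  // index of the alive triangle with directed edge (a,b), else -1
  int tri_with_edge(int a, int b) const {
    for (size_t t = 0; t < tris.size(); ++t) {
      if (!alive((int)t)) continue;
      for (int k = 0; k < 3; ++k)
        if (tris[t][k] == a && tris[t][(k + 1) % 3] == b) return (int)t;
    }
    return -1;
  }

  // Lawson legalization of the edge opposite `pid` in triangle t
  void legalize(int t, int pid) {
    if (!alive(t)) return;
    int a = -1, b = -1;
    for (int k = 0; k < 3; ++k)
      if (tris[t][k] == pid) {
        a = tris[t][(k + 1) % 3];
        b = tris[t][(k + 2) % 3];
        break;
      }
    if (a < 0) return;
    int t2 = tri_with_edge(b, a);
    if (t2 < 0) return;
    int c = -1;
    for (int k = 0; k < 3; ++k)
      if (tris[t2][k] == b && tris[t2][(k + 1) % 3] == a) {
        c = tris[t2][(k + 2) % 3];
        break;
      }
    if (c < 0) return;
    if (incircle(pts[pid], pts[a], pts[b], pts[c]) <= 0) return;
    // flip only when the replacement triangles are valid (convex quad)
    if (orient2(pts[pid], pts[a], pts[c]) <= 0 ||
        orient2(pts[pid], pts[c], pts[b]) <= 0)
      return;
    kill(t);
    kill(t2);
    tris.push_back({pid, a, c});
    tris.push_back({pid, c, b});
    int n1 = (int)tris.size() - 2, n2 = (int)tris.size() - 1;
    legalize(n1, pid);
    legalize(n2, pid);
  }

  // insert p; returns its point index (existing if snapped)
  int add_point(const P2& p) {
    int ex = find_vertex(p);
    if (ex >= 0) return ex;
    int pid = (int)pts.size();
    pts.push_back(p);

    int best = -1;
    double bestmin = -1e300;
    for (size_t t = 0; t < tris.size(); ++t) {
      if (!alive((int)t)) continue;
      const P2& a = pts[tris[t][0]];
      const P2& b = pts[tris[t][1]];
      const P2& c = pts[tris[t][2]];
      double s0 = orient2(b, c, p), s1 = orient2(c, a, p), s2 = orient2(a, b, p);
      double m = std::min({s0, s1, s2});
      if (m > bestmin) { bestmin = m; best = (int)t; }
    }
    if (best < 0) { pts.pop_back(); return -1; }

    std::array<int, 3> T = tris[best];
    // edge distances: |orient2| / |edge|
    int onedge = -1;
    double bestd = tol;
    for (int k = 0; k < 3; ++k) {
      int u = T[(k + 1) % 3], v = T[(k + 2) % 3];  // edge opposite vertex k
      double s = orient2(pts[u], pts[v], p);
      double len = std::sqrt(d2(pts[u], pts[v]));
      if (len <= 0) continue;
      double dd = std::fabs(s) / len;
      if (dd < bestd) { bestd = dd; onedge = k; }
    }
    std::vector<int> fresh;
    if (onedge >= 0) {
      int u = T[(onedge + 1) % 3], v = T[(onedge + 2) % 3], w = T[onedge];
      int nb = tri_with_edge(v, u);
      kill(best);
      tris.push_back({u, pid, w});
      tris.push_back({pid, v, w});
      fresh.push_back((int)tris.size() - 2);
      fresh.push_back((int)tris.size() - 1);
      if (nb >= 0) {
        int z = -1;
        for (int k = 0; k < 3; ++k)
          if (tris[nb][k] == v && tris[nb][(k + 1) % 3] == u) {
            z = tris[nb][(k + 2) % 3];
            break;
          }
        kill(nb);
        tris.push_back({v, pid, z});
        tris.push_back({pid, u, z});
        fresh.push_back((int)tris.size() - 2);
        fresh.push_back((int)tris.size() - 1);
      }
    } else {
      kill(best);
      tris.push_back({T[0], T[1], pid});
      tris.push_back({T[1], T[2], pid});
      tris.push_back({T[2], T[0], pid});
      fresh.push_back((int)tris.size() - 3);
      fresh.push_back((int)tris.size() - 2);
      fresh.push_back((int)tris.size() - 1);
    }
    for (int t : fresh) legalize(t, pid);
    return pid;
  }

  bool edge_exists(int u, int v) const {
    for (size_t t = 0; t < tris.size(); ++t) {
      if (!alive((int)t)) continue;
      for (int k = 0; k < 3; ++k) {
        int a = tris[t][k], b = tris[t][(k + 1) % 3];
        if ((a == u && b == v) || (a == v && b == u)) return true;
      }
    }
    return false;
  }

  // length of the part of segment (p,q) lying inside triangle t, and the
  // clipped midpoint's minimum signed area (interior test)
  double clip_len(const P2& p, const P2& q, int t, double* midmin) const {
    const P2& a = pts[tris[t][0]];
    const P2& b = pts[tris[t][1]];
    const P2& c = pts[tris[t][2]];
    double t0 = 0.0, t1 = 1.0;
    const P2* e0[3] = { &a, &b, &c };
    const P2* e1[3] = { &b, &c, &a };
    for (int k = 0; k < 3; ++k) {
      double sp = orient2(*e0[k], *e1[k], p);
      double sq = orient2(*e0[k], *e1[k], q);
      // keep side >= 0 (interior of CCW triangle)
      if (sp < 0 && sq < 0) return 0.0;
      if (sp < 0) t0 = std::max(t0, sp / (sp - sq));
      else if (sq < 0) t1 = std::min(t1, sp / (sp - sq));
    }
    if (t1 <= t0) return 0.0;
    double tm = 0.5 * (t0 + t1);
    P2 m { p.x + (q.x - p.x) * tm, p.y + (q.y - p.y) * tm };
    double s0 = orient2(b, c, m), s1 = orient2(c, a, m), s2 = orient2(a, b, m);
    *midmin = std::min({s0, s1, s2});
    return (t1 - t0) * std::sqrt(d2(p, q));
  }

  void emit(int a, int b, int c) {
    if (orient2(pts[a], pts[b], pts[c]) < 0) std::swap(b, c);
    tris.push_back({a, b, c});
  }

  void tri_pseudo(int a, int b, const std::vector<int>& chain) {
    if (chain.empty()) return;
    size_t ci = 0;
    if (chain.size() > 1) {
      P2 A = pts[a], B = pts[b], C = pts[chain[0]];
      bool ccw = orient2(A, C, B) > 0;
      for (size_t i = 1; i < chain.size(); ++i) {
        const P2& D = pts[chain[i]];
        double ic = ccw ? incircle(A, pts[chain[ci]], B, D)
                        : incircle(A, B, pts[chain[ci]], D);
        if (ic > 0) { ci = i; C = pts[chain[ci]]; ccw = orient2(A, C, B) > 0; }
      }
    }
    emit(a, chain[ci], b);
    std::vector<int> left(chain.begin(), chain.begin() + ci);
    std::vector<int> right(chain.begin() + ci + 1, chain.end());
    tri_pseudo(a, chain[ci], left);
    tri_pseudo(chain[ci], b, right);
  }

  void insert_constraint(int u, int v) {
    if (u == v || edge_exists(u, v)) return;
    const P2& pu = pts[u];
    const P2& pv = pts[v];
    double seglen = std::sqrt(d2(pu, pv));
    if (seglen <= tol) return;

    std::vector<int> S;
    for (size_t t = 0; t < tris.size(); ++t) {
      if (!alive((int)t)) continue;
      double midmin = -1;
      double cl = clip_len(pu, pv, (int)t, &midmin);
      if (cl > tol && midmin > 0) S.push_back((int)t);
    }
    if (S.empty()) return;

    // directed boundary edges of the cavity
    std::unordered_map<int64_t, int> inS;
    for (int t : S)
      for (int k = 0; k < 3; ++k) {
        int a = tris[t][k], b = tris[t][(k + 1) % 3];
        inS[(int64_t)a * 1000000 + b] = 1;
      }
    std::unordered_map<int, int> nxt;
    for (int t : S)
      for (int k = 0; k < 3; ++k) {
        int a = tris[t][k], b = tris[t][(k + 1) % 3];
        if (inS.find((int64_t)b * 1000000 + a) == inS.end()) nxt[a] = b;
      }
    if (nxt.find(u) == nxt.end() || nxt.find(v) == nxt.end()) return;

    // walk the cycle from u
    std::vector<int> cyc;
    int cur = u;
    for (size_t guard = 0; guard <= nxt.size() + 1; ++guard) {
      cyc.push_back(cur);
      auto it = nxt.find(cur);
      if (it == nxt.end()) return;
      cur = it->second;
      if (cur == u) break;
    }
    size_t vi = 0; bool found = false;
    for (size_t i = 0; i < cyc.size(); ++i)
      if (cyc[i] == v) { vi = i; found = true; break; }
    if (!found || vi == 0) return;

    std::vector<int> chain1(cyc.begin() + 1, cyc.begin() + vi);
    std::vector<int> chain2(cyc.begin() + vi + 1, cyc.end());
    for (int t : S) kill(t);
    tri_pseudo(u, v, chain1);
    tri_pseudo(v, u, chain2);
  }
};

inline int64_t ekey(int a, int b) {
  int lo = std::min(a, b), hi = std::max(a, b);
  return (int64_t)lo * 2000000000LL + hi;
}

// uniform grid over triangle boxes
struct TriGrid {
  double cell;
  Vec3 org;
  std::unordered_map<int64_t, std::vector<int>> cells;

  static int64_t ckey(long long i, long long j, long long k) {
    return (i * 73856093LL) ^ (j * 19349663LL) ^ (k * 83492791LL);
  }

  void build(const NumericMatrix& V, const IntegerMatrix& F, double cellsize) {
    cell = cellsize;
    org = Vec3(0, 0, 0);
    for (int f = 0; f < F.nrow(); ++f) insert_box(V, F, f);
  }

  void insert_box(const NumericMatrix& V, const IntegerMatrix& F, int f) {
    double lo[3] = {1e300, 1e300, 1e300}, hi[3] = {-1e300, -1e300, -1e300};
    for (int k = 0; k < 3; ++k) {
      int vi = F(f, k) - 1;
      for (int d = 0; d < 3; ++d) {
        lo[d] = std::min(lo[d], V(vi, d));
        hi[d] = std::max(hi[d], V(vi, d));
      }
    }
    long long i0 = (long long)std::floor(lo[0] / cell), i1 = (long long)std::floor(hi[0] / cell);
    long long j0 = (long long)std::floor(lo[1] / cell), j1 = (long long)std::floor(hi[1] / cell);
    long long k0 = (long long)std::floor(lo[2] / cell), k1 = (long long)std::floor(hi[2] / cell);
    for (long long i = i0; i <= i1; ++i)
      for (long long j = j0; j <= j1; ++j)
        for (long long k = k0; k <= k1; ++k)
          cells[ckey(i, j, k)].push_back(f);
  }

  void query_box(const double lo[3], const double hi[3], std::vector<int>& out) const {
    long long i0 = (long long)std::floor(lo[0] / cell), i1 = (long long)std::floor(hi[0] / cell);
    long long j0 = (long long)std::floor(lo[1] / cell), j1 = (long long)std::floor(hi[1] / cell);
    long long k0 = (long long)std::floor(lo[2] / cell), k1 = (long long)std::floor(hi[2] / cell);
    for (long long i = i0; i <= i1; ++i)
      for (long long j = j0; j <= j1; ++j)
        for (long long k = k0; k <= k1; ++k) {
          auto it = cells.find(ckey(i, j, k));
          if (it == cells.end()) continue;
          out.insert(out.end(), it->second.begin(), it->second.end());
        }
  }
};

inline void tri_box(const NumericMatrix& V, const IntegerMatrix& F, int f,
                    double lo[3], double hi[3]) {
  lo[0] = lo[1] = lo[2] = 1e300;
  hi[0] = hi[1] = hi[2] = -1e300;
  for (int k = 0; k < 3; ++k) {
    int vi = F(f, k) - 1;
    for (int d = 0; d < 3; ++d) {
      lo[d] = std::min(lo[d], V(vi, d));
      hi[d] = std::max(hi[d], V(vi, d));
    }
  }
}

inline double mean_tri_diag(const NumericMatrix& V, const IntegerMatrix& F) {
  double s = 0;
  int m = F.nrow();
  for (int f = 0; f < m; ++f) {
    double lo[3], hi[3];
    tri_box(V, F, f, lo, hi);
    double dx = hi[0] - lo[0], dy = hi[1] - lo[1], dz = hi[2] - lo[2];
    s += std::sqrt(dx * dx + dy * dy + dz * dz);
  }
  return m > 0 ? s / m : 1.0;
}

// project onto the dominant plane of normal n
inline P2 dom_proj(const Vec3& n, const Vec3& v) {
  double an[3] = {std::fabs(n.x), std::fabs(n.y), std::fabs(n.z)};
  if (an[1] >= an[0] && an[1] >= an[2]) return P2{v.x, v.z};
  if (an[2] >= an[0] && an[2] >= an[1]) return P2{v.x, v.y};
  return P2{v.y, v.z};
}

// 2D overlap of two coplanar triangles (positive-area interior overlap)
bool coplanar_overlap(const Vec3 T1[3], const Vec3 T2[3], const Vec3& n2) {
  P2 A[3] = {dom_proj(n2, T1[0]), dom_proj(n2, T1[1]), dom_proj(n2, T1[2])};
  P2 B[3] = {dom_proj(n2, T2[0]), dom_proj(n2, T2[1]), dom_proj(n2, T2[2])};
  double oa = orient2(A[0], A[1], A[2]);
  double ob = orient2(B[0], B[1], B[2]);
  if (oa == 0 || ob == 0) return false;
  auto inside = [&](const P2 T[3], double o, const P2& pt) {
    double sgn = o > 0 ? 1.0 : -1.0;
    double e = 1e-12 * std::fabs(o);
    return sgn * orient2(T[0], T[1], pt) > e &&
           sgn * orient2(T[1], T[2], pt) > e &&
           sgn * orient2(T[2], T[0], pt) > e;
  };
  P2 ca{(A[0].x + A[1].x + A[2].x) / 3, (A[0].y + A[1].y + A[2].y) / 3};
  P2 cb{(B[0].x + B[1].x + B[2].x) / 3, (B[0].y + B[1].y + B[2].y) / 3};
  if (inside(B, ob, ca) || inside(A, oa, cb)) return true;
  for (int i = 0; i < 3; ++i) {
    if (inside(B, ob, A[i])) return true;
    if (inside(A, oa, B[i])) return true;
  }
  auto segx = [&](const P2& a, const P2& b, const P2& c, const P2& d) {
    double o1 = orient2(a, b, c), o2 = orient2(a, b, d);
    double o3 = orient2(c, d, a), o4 = orient2(c, d, b);
    return ((o1 > 0) != (o2 > 0)) && ((o3 > 0) != (o4 > 0)) &&
           o1 != 0 && o2 != 0 && o3 != 0 && o4 != 0;
  };
  for (int i = 0; i < 3; ++i)
    for (int j = 0; j < 3; ++j)
      if (segx(A[i], A[(i + 1) % 3], B[j], B[(j + 1) % 3])) return true;
  return false;
}

// clip each edge of Tb against triangle Ta (in Ta's dominant plane) and
// append the clipped 3D segments (constraints for splitting Ta)
void coplanar_clip(const Vec3 Ta[3], const Vec3 Tb[3], const Vec3& na,
                   double minlen, std::vector<double>& segs) {
  P2 A[3] = {dom_proj(na, Ta[0]), dom_proj(na, Ta[1]), dom_proj(na, Ta[2])};
  double oa = orient2(A[0], A[1], A[2]);
  if (oa == 0) return;
  double sgn = oa > 0 ? 1.0 : -1.0;
  for (int e = 0; e < 3; ++e) {
    Vec3 P = Tb[e], Q = Tb[(e + 1) % 3];
    P2 p = dom_proj(na, P), q = dom_proj(na, Q);
    double t0 = 0.0, t1 = 1.0;
    bool gone = false;
    for (int k = 0; k < 3 && !gone; ++k) {
      double sp = sgn * orient2(A[k], A[(k + 1) % 3], p);
      double sq = sgn * orient2(A[k], A[(k + 1) % 3], q);
      if (sp < 0 && sq < 0) gone = true;
      else if (sp < 0) t0 = std::max(t0, sp / (sp - sq));
      else if (sq < 0) t1 = std::min(t1, sp / (sp - sq));
    }
    if (gone || t1 <= t0) continue;
    Vec3 p3 = P + (Q - P) * t0;
    Vec3 q3 = P + (Q - P) * t1;
    if ((q3 - p3).norm() > minlen)
      segs.insert(segs.end(), {p3.x, p3.y, p3.z, q3.x, q3.y, q3.z});
  }
}

// triangle-triangle intersection: returns 0 none, 1 segment (in p,q),
// 2 coplanar-overlap
int tritri(const Vec3 T1[3], const Vec3 T2[3], double epsd, Vec3* p, Vec3* q) {
  Vec3 n2 = (T2[1] - T2[0]).cross(T2[2] - T2[0]);
  double dv[3];
  for (int i = 0; i < 3; ++i) dv[i] = n2.dot(T1[i] - T2[0]);
  double s2 = n2.norm();
  int sv[3];
  for (int i = 0; i < 3; ++i)
    sv[i] = dv[i] > epsd * s2 ? 1 : (dv[i] < -epsd * s2 ? -1 : 0);
  if (sv[0] == 0 && sv[1] == 0 && sv[2] == 0)
    return coplanar_overlap(T1, T2, n2) ? 2 : 0;

  // an edge of one triangle lying exactly in the other's plane: emit the
  // clipped edge once (from the positive-side triangle)
  auto edge_in_plane = [&](const Vec3 T[3], const int s[3], const Vec3 To[3],
                           const Vec3& no) -> int {
    int z0 = -1, z1 = -1, pos = -1;
    for (int i = 0; i < 3; ++i) {
      if (s[i] == 0) { if (z0 < 0) z0 = i; else z1 = i; }
      else pos = i;
    }
    if (z1 < 0 || pos < 0 || s[pos] < 0) return 0;
    P2 O[3] = {dom_proj(no, To[0]), dom_proj(no, To[1]), dom_proj(no, To[2])};
    double oo = orient2(O[0], O[1], O[2]);
    if (oo == 0) return 0;
    double sgn = oo > 0 ? 1.0 : -1.0;
    P2 a = dom_proj(no, T[z0]), b = dom_proj(no, T[z1]);
    double t0 = 0.0, t1 = 1.0;
    for (int k = 0; k < 3; ++k) {
      double sp = sgn * orient2(O[k], O[(k + 1) % 3], a);
      double sq = sgn * orient2(O[k], O[(k + 1) % 3], b);
      if (sp < 0 && sq < 0) return 0;
      if (sp < 0) t0 = std::max(t0, sp / (sp - sq));
      else if (sq < 0) t1 = std::min(t1, sp / (sp - sq));
    }
    if (t1 <= t0) return 0;
    *p = T[z0] + (T[z1] - T[z0]) * t0;
    *q = T[z0] + (T[z1] - T[z0]) * t1;
    return 1;
  };
  {
    int nz = (sv[0] == 0) + (sv[1] == 0) + (sv[2] == 0);
    if (nz == 2) return edge_in_plane(T1, sv, T2, n2);
  }
  if ((sv[0] >= 0 && sv[1] >= 0 && sv[2] >= 0) ||
      (sv[0] <= 0 && sv[1] <= 0 && sv[2] <= 0))
    return 0;

  Vec3 n1 = (T1[1] - T1[0]).cross(T1[2] - T1[0]);
  double du[3];
  for (int i = 0; i < 3; ++i) du[i] = n1.dot(T2[i] - T1[0]);
  double s1 = n1.norm();
  int su[3];
  for (int i = 0; i < 3; ++i)
    su[i] = du[i] > epsd * s1 ? 1 : (du[i] < -epsd * s1 ? -1 : 0);
  {
    int nz = (su[0] == 0) + (su[1] == 0) + (su[2] == 0);
    if (nz == 2) return edge_in_plane(T2, su, T1, n1);
  }
  if ((su[0] >= 0 && su[1] >= 0 && su[2] >= 0) ||
      (su[0] <= 0 && su[1] <= 0 && su[2] <= 0))
    return 0;

  auto crossings = [&](const Vec3 T[3], const double d[3], const int s[3],
                       std::vector<Vec3>& out) {
    for (int i = 0; i < 3; ++i) {
      if (s[i] == 0) out.push_back(T[i]);
      int j = (i + 1) % 3;
      if (s[i] * s[j] < 0) {
        double t = d[i] / (d[i] - d[j]);
        out.push_back(T[i] + (T[j] - T[i]) * t);
      }
    }
  };
  std::vector<Vec3> X, Y;
  crossings(T1, dv, sv, X);
  crossings(T2, du, su, Y);
  if (X.size() < 2 || Y.size() < 2) return 0;

  Vec3 D = n1.cross(n2);
  auto spar = [&](const Vec3& v) { return D.dot(v); };
  auto minmax = [&](std::vector<Vec3>& pts, Vec3& pmin, Vec3& pmax) {
    pmin = pmax = pts[0];
    for (auto& v : pts) {
      if (spar(v) < spar(pmin)) pmin = v;
      if (spar(v) > spar(pmax)) pmax = v;
    }
  };
  Vec3 x0, x1, y0, y1;
  minmax(X, x0, x1);
  minmax(Y, y0, y1);
  Vec3 lo = spar(x0) > spar(y0) ? x0 : y0;
  Vec3 hi = spar(x1) < spar(y1) ? x1 : y1;
  if (spar(hi) <= spar(lo)) return 0;
  *p = lo;
  *q = hi;
  return 1;
}

}  // namespace

// candidate face pairs between two meshes whose AABBs (expanded by margin)
// overlap; returns a 2-column 1-based index matrix
// [[Rcpp::export]]
IntegerMatrix cpp_box_pairs(NumericMatrix VA, IntegerMatrix FA,
                            NumericMatrix VB, IntegerMatrix FB, double margin) {
  double cs = std::max(mean_tri_diag(VA, FA), 1e-9);
  TriGrid grid;
  grid.build(VA, FA, cs);
  std::vector<std::pair<int, int>> pairs;
  std::vector<int> cand;
  for (int f = 0; f < FB.nrow(); ++f) {
    double lo[3], hi[3];
    tri_box(VB, FB, f, lo, hi);
    for (int d = 0; d < 3; ++d) { lo[d] -= margin; hi[d] += margin; }
    cand.clear();
    grid.query_box(lo, hi, cand);
    std::sort(cand.begin(), cand.end());
    cand.erase(std::unique(cand.begin(), cand.end()), cand.end());
    for (int a : cand) {
      double la[3], ha[3];
      tri_box(VA, FA, a, la, ha);
      bool ov = true;
      for (int d = 0; d < 3; ++d)
        if (la[d] > hi[d] || ha[d] < lo[d]) { ov = false; break; }
      if (ov) pairs.push_back({a + 1, f + 1});
    }
  }
  IntegerMatrix out((int)pairs.size(), 2);
  for (size_t i = 0; i < pairs.size(); ++i) {
    out(i, 0) = pairs[i].first;
    out(i, 1) = pairs[i].second;
  }
  return out;
}

// intersection segments for candidate pairs; eps is the seam snapping
// tolerance in world units (segments shorter than eps are dropped)
// [[Rcpp::export]]
List cpp_tritri_segments(NumericMatrix VA, IntegerMatrix FA,
                         NumericMatrix VB, IntegerMatrix FB,
                         IntegerMatrix pairs, double eps) {
  std::vector<double> seg;
  std::vector<int> fa, fb;
  std::vector<double> segcopA, segcopB;
  std::vector<int> facopA, facopB;
  std::vector<int> coppairs;
  double epsd = eps * 1e-3;
  for (int i = 0; i < pairs.nrow(); ++i) {
    int a = pairs(i, 0) - 1, b = pairs(i, 1) - 1;
    Vec3 T1[3], T2[3];
    for (int k = 0; k < 3; ++k) {
      int va = FA(a, k) - 1, vb = FB(b, k) - 1;
      T1[k] = Vec3(VA(va, 0), VA(va, 1), VA(va, 2));
      T2[k] = Vec3(VB(vb, 0), VB(vb, 1), VB(vb, 2));
    }
    Vec3 p, q;
    int r = tritri(T1, T2, epsd, &p, &q);
    if (r == 2) {
      // coplanar overlap: split each face along the other's clipped edges
      Vec3 na = (T1[1] - T1[0]).cross(T1[2] - T1[0]);
      Vec3 nb = (T2[1] - T2[0]).cross(T2[2] - T2[0]);
      size_t beforeA = segcopA.size(), beforeB = segcopB.size();
      coplanar_clip(T1, T2, na, eps, segcopA);
      coplanar_clip(T2, T1, nb, eps, segcopB);
      while (facopA.size() < segcopA.size() / 6) facopA.push_back(a + 1);
      while (facopB.size() < segcopB.size() / 6) facopB.push_back(b + 1);
      (void)beforeA; (void)beforeB;
      coppairs.push_back(a + 1);
      coppairs.push_back(b + 1);
    }
    if (r == 1 && (q - p).norm() > eps) {
      fa.push_back(a + 1);
      fb.push_back(b + 1);
      seg.insert(seg.end(), {p.x, p.y, p.z, q.x, q.y, q.z});
    }
  }
  int n = (int)fa.size();
  NumericMatrix S(n, 6);
  IntegerVector FAo(n), FBo(n);
  for (int i = 0; i < n; ++i) {
    FAo[i] = fa[i];
    FBo[i] = fb[i];
    for (int k = 0; k < 6; ++k) S(i, k) = seg[6 * i + k];
  }
  auto segmat = [](const std::vector<double>& v) {
    int m = (int)(v.size() / 6);
    NumericMatrix M(m, 6);
    for (int i = 0; i < m; ++i)
      for (int k = 0; k < 6; ++k) M(i, k) = v[6 * i + k];
    return M;
  };
  IntegerMatrix CP((int)(coppairs.size() / 2), 2);
  for (int i = 0; i < CP.nrow(); ++i) {
    CP(i, 0) = coppairs[2 * i];
    CP(i, 1) = coppairs[2 * i + 1];
  }
  return List::create(
    _["faceA"] = FAo, _["faceB"] = FBo, _["segments"] = S,
    _["n_coplanar"] = (int)CP.nrow(),
    _["cop_pairs"] = CP,
    _["copA_face"] = wrap(facopA), _["copA_segs"] = segmat(segcopA),
    _["copB_face"] = wrap(facopB), _["copB_segs"] = segmat(segcopB));
}

// retriangulate faces so each listed segment is covered by mesh edges;
// returns augmented vertices, new faces and per-face provenance
// [[Rcpp::export]]
List cpp_split_faces(NumericMatrix V, IntegerMatrix F, IntegerVector segFace,
                     NumericMatrix segs, double eps) {
  int nf = F.nrow();
  std::vector<std::vector<int>> byface(nf);
  for (int i = 0; i < segFace.size(); ++i) byface[segFace[i] - 1].push_back(i);

  std::vector<double> newV;  // appended vertex coords
  std::vector<int> outF;
  std::vector<int> prov;
  int nV = V.nrow();
  auto addV = [&](const Vec3& p) {
    newV.insert(newV.end(), {p.x, p.y, p.z});
    return nV + (int)(newV.size() / 3) - 1;  // 0-based global
  };

  for (int f = 0; f < nf; ++f) {
    if (byface[f].empty()) {
      outF.insert(outF.end(), {F(f, 0) - 1, F(f, 1) - 1, F(f, 2) - 1});
      prov.push_back(f + 1);
      continue;
    }
    int ia = F(f, 0) - 1, ib = F(f, 1) - 1, ic = F(f, 2) - 1;
    Vec3 A(V(ia, 0), V(ia, 1), V(ia, 2));
    Vec3 B(V(ib, 0), V(ib, 1), V(ib, 2));
    Vec3 C(V(ic, 0), V(ic, 1), V(ic, 2));
    Vec3 n = (B - A).cross(C - A);
    Vec3 e1 = (B - A) * (1.0 / (B - A).norm());
    Vec3 e2 = n.cross(e1);
    e2 = e2 * (1.0 / e2.norm());
    auto to2d = [&](const Vec3& p) {
      Vec3 d = p - A;
      return P2{d.dot(e1), d.dot(e2)};
    };
    auto lift = [&](const P2& p) { return A + e1 * p.x + e2 * p.y; };

    LocalCDT cdt;
    cdt.tol = eps;
    P2 a2 = to2d(A), b2 = to2d(B), c2 = to2d(C);
    cdt.init(a2, b2, c2);
    std::vector<int> gid = {ia, ib, ic};  // global id per local point
    std::vector<Vec3> p3 = {A, B, C};

    // endpoint candidates, clamped into the face triangle
    struct Cand { P2 p; Vec3 w; };
    std::vector<Cand> cands;
    std::vector<std::pair<int, int>> segloc;  // candidate index pairs
    double oABC = orient2(a2, b2, c2);
    auto clamp_in = [&](P2 p, Vec3 w) {
      // clamp tiny negative barycentric coordinates
      double w0 = orient2(b2, c2, p) / oABC;
      double w1 = orient2(c2, a2, p) / oABC;
      double w2 = orient2(a2, b2, p) / oABC;
      if (w0 < 0 || w1 < 0 || w2 < 0) {
        w0 = std::max(w0, 0.0); w1 = std::max(w1, 0.0); w2 = std::max(w2, 0.0);
        double s = w0 + w1 + w2;
        if (s <= 0) return Cand{p, w};
        w0 /= s; w1 /= s; w2 /= s;
        P2 q{w0 * a2.x + w1 * b2.x + w2 * c2.x,
             w0 * a2.y + w1 * b2.y + w2 * c2.y};
        return Cand{q, lift(q)};
      }
      return Cand{p, w};
    };
    for (int si : byface[f]) {
      Vec3 p(segs(si, 0), segs(si, 1), segs(si, 2));
      Vec3 q(segs(si, 3), segs(si, 4), segs(si, 5));
      cands.push_back(clamp_in(to2d(p), p));
      cands.push_back(clamp_in(to2d(q), q));
      segloc.push_back({(int)cands.size() - 2, (int)cands.size() - 1});
    }
    // proper pairwise segment crossings become extra points
    std::vector<Cand> extra;
    for (size_t i = 0; i < segloc.size(); ++i)
      for (size_t j = i + 1; j < segloc.size(); ++j) {
        const P2& p1 = cands[segloc[i].first].p;
        const P2& q1 = cands[segloc[i].second].p;
        const P2& p2 = cands[segloc[j].first].p;
        const P2& q2 = cands[segloc[j].second].p;
        double o1 = orient2(p1, q1, p2), o2 = orient2(p1, q1, q2);
        double o3 = orient2(p2, q2, p1), o4 = orient2(p2, q2, q1);
        if (((o1 > 0) != (o2 > 0)) && ((o3 > 0) != (o4 > 0)) &&
            o1 != o2 && o3 != o4) {
          double t = o3 / (o3 - o4);
          P2 x{p1.x + (q1.x - p1.x) * t, p1.y + (q1.y - p1.y) * t};
          extra.push_back({x, lift(x)});
        }
      }
    for (auto& e : extra) cands.push_back(e);

    // insert all points
    std::vector<int> loc(cands.size());
    for (size_t i = 0; i < cands.size(); ++i) {
      int li = cdt.add_point(cands[i].p);
      loc[i] = li;
      if (li >= (int)gid.size()) {
        gid.push_back(addV(cands[i].w));
        p3.push_back(cands[i].w);
      }
    }
    // constraints: for each segment, all points within eps of it, ordered
    for (auto& sl : segloc) {
      int lu = loc[sl.first], lv = loc[sl.second];
      if (lu < 0 || lv < 0 || lu == lv) continue;
      P2 pu = cdt.pts[lu], pv = cdt.pts[lv];
      double len = std::sqrt(d2(pu, pv));
      if (len <= eps) continue;
      std::vector<std::pair<double, int>> on;
      for (size_t k = 0; k < cdt.pts.size(); ++k) {
        const P2& p = cdt.pts[k];
        double t = ((p.x - pu.x) * (pv.x - pu.x) + (p.y - pu.y) * (pv.y - pu.y)) /
                   (len * len);
        if (t < -eps / len || t > 1 + eps / len) continue;
        double dd = std::fabs(orient2(pu, pv, p)) / len;
        if (dd <= eps) on.push_back({t, (int)k});
      }
      std::sort(on.begin(), on.end());
      for (size_t k = 0; k + 1 < on.size(); ++k)
        cdt.insert_constraint(on[k].second, on[k + 1].second);
    }

    for (size_t t = 0; t < cdt.tris.size(); ++t) {
      if (!cdt.alive((int)t)) continue;
      int l0 = cdt.tris[t][0], l1 = cdt.tris[t][1], l2 = cdt.tris[t][2];
      outF.insert(outF.end(), {gid[l0], gid[l1], gid[l2]});
      prov.push_back(f + 1);
    }
  }

  int nNew = (int)(newV.size() / 3);
  NumericMatrix V2(nV + nNew, 3);
  for (int i = 0; i < nV; ++i)
    for (int k = 0; k < 3; ++k) V2(i, k) = V(i, k);
  for (int i = 0; i < nNew; ++i)
    for (int k = 0; k < 3; ++k) V2(nV + i, k) = newV[3 * i + k];
  int m = (int)(outF.size() / 3);
  IntegerMatrix F2(m, 3);
  IntegerVector pr(m);
  for (int i = 0; i < m; ++i) {
    for (int k = 0; k < 3; ++k) F2(i, k) = outF[3 * i + k] + 1;
    pr[i] = prov[i];
  }
  return List::create(_["vertices"] = V2, _["faces"] = F2, _["orig_face"] = pr);
}

// TRUE if any two faces sharing no vertex intersect in a segment longer
// than eps (or overlap coplanarly)
// [[Rcpp::export]]
bool cpp_self_intersects(NumericMatrix V, IntegerMatrix F, double eps) {
  double cs = std::max(mean_tri_diag(V, F), 1e-9);
  TriGrid grid;
  grid.build(V, F, cs);
  std::vector<int> cand;
  double epsd = eps * 1e-3;
  for (int f = 0; f < F.nrow(); ++f) {
    double lo[3], hi[3];
    tri_box(V, F, f, lo, hi);
    cand.clear();
    grid.query_box(lo, hi, cand);
    for (int g : cand) {
      if (g <= f) continue;
      bool share = false;
      for (int k = 0; k < 3 && !share; ++k)
        for (int l = 0; l < 3; ++l)
          if (F(f, k) == F(g, l)) { share = true; break; }
      if (share) continue;
      Vec3 T1[3], T2[3];
      for (int k = 0; k < 3; ++k) {
        int va = F(f, k) - 1, vb = F(g, k) - 1;
        T1[k] = Vec3(V(va, 0), V(va, 1), V(va, 2));
        T2[k] = Vec3(V(vb, 0), V(vb, 1), V(vb, 2));
      }
      Vec3 p, q;
      int r = tritri(T1, T2, epsd, &p, &q);
      if (r == 2) return true;
      if (r == 1 && (q - p).norm() > eps) return true;
    }
  }
  return false;
}

// split edges that have other vertices lying on them (T-junctions); faces
// acquiring edge points are re-fanned around their centroid
// [[Rcpp::export]]
List cpp_fix_tjunctions(NumericMatrix V, IntegerMatrix F, double tol) {
  int nV = V.nrow(), nF = F.nrow();
  // grid the face edges at a geometry-scaled cell; query one cell (plus
  // neighbours) per vertex
  double meanlen = 0;
  for (int f = 0; f < nF; ++f) {
    for (int k = 0; k < 3; ++k) {
      int a = F(f, k) - 1, b = F(f, (k + 1) % 3) - 1;
      Vec3 d(V(a, 0) - V(b, 0), V(a, 1) - V(b, 1), V(a, 2) - V(b, 2));
      meanlen += d.norm();
    }
  }
  meanlen = nF > 0 ? meanlen / (3.0 * nF) : 1.0;
  double cell = std::max(meanlen, tol * 8);
  std::unordered_map<int64_t, std::vector<int>> grid;  // edge id = f*3+slot
  auto ck = [&](long long i, long long j, long long k) {
    return (int64_t)((i * 73856093LL) ^ (j * 19349663LL) ^ (k * 83492791LL));
  };
  for (int f = 0; f < nF; ++f)
    for (int s = 0; s < 3; ++s) {
      int a = F(f, s) - 1, b = F(f, (s + 1) % 3) - 1;
      double lo[3], hi[3];
      for (int d = 0; d < 3; ++d) {
        lo[d] = std::min(V(a, d), V(b, d)) - tol;
        hi[d] = std::max(V(a, d), V(b, d)) + tol;
      }
      long long i0 = (long long)std::floor(lo[0] / cell), i1 = (long long)std::floor(hi[0] / cell);
      long long j0 = (long long)std::floor(lo[1] / cell), j1 = (long long)std::floor(hi[1] / cell);
      long long k0 = (long long)std::floor(lo[2] / cell), k1 = (long long)std::floor(hi[2] / cell);
      for (long long ii = i0; ii <= i1; ++ii)
        for (long long jj = j0; jj <= j1; ++jj)
          for (long long kk = k0; kk <= k1; ++kk)
            grid[ck(ii, jj, kk)].push_back(f * 3 + s);
    }

  // per edge (face*3+slot): interior vertices on it
  std::unordered_map<int, std::vector<std::pair<double, int>>> onedge;
  for (int w = 0; w < nV; ++w) {
    Vec3 p(V(w, 0), V(w, 1), V(w, 2));
    auto it = grid.find(ck((long long)std::floor(p.x / cell),
                           (long long)std::floor(p.y / cell),
                           (long long)std::floor(p.z / cell)));
    if (it == grid.end()) continue;
    for (int eid : it->second) {
      int f = eid / 3, s = eid % 3;
      int a = F(f, s) - 1, b = F(f, (s + 1) % 3) - 1;
      if (w == F(f, 0) - 1 || w == F(f, 1) - 1 || w == F(f, 2) - 1) continue;
      Vec3 pa(V(a, 0), V(a, 1), V(a, 2)), pb(V(b, 0), V(b, 1), V(b, 2));
      double len2 = (pb - pa).norm2();
      if (len2 <= 0) continue;
      double len = std::sqrt(len2);
      double t = (p - pa).dot(pb - pa) / len2;
      if (t < tol / len || t > 1 - tol / len) continue;
      Vec3 proj = pa + (pb - pa) * t;
      if ((p - proj).norm() <= tol) onedge[eid].push_back({t, w});
    }
  }

  std::vector<double> newV;
  std::vector<int> outF;
  auto addV = [&](const Vec3& p) {
    newV.insert(newV.end(), {p.x, p.y, p.z});
    return nV + (int)(newV.size() / 3) - 1;
  };

  for (int f = 0; f < nF; ++f) {
    int vi[3] = {F(f, 0) - 1, F(f, 1) - 1, F(f, 2) - 1};
    Vec3 P[3];
    for (int k = 0; k < 3; ++k) P[k] = Vec3(V(vi[k], 0), V(vi[k], 1), V(vi[k], 2));
    std::vector<std::pair<double, int>> onE[3];
    for (int k = 0; k < 3; ++k) {
      auto it = onedge.find(f * 3 + k);
      if (it == onedge.end()) continue;
      onE[k] = it->second;
      std::sort(onE[k].begin(), onE[k].end());
      onE[k].erase(std::unique(onE[k].begin(), onE[k].end(),
                               [](const std::pair<double, int>& x,
                                  const std::pair<double, int>& y) {
                                 return x.second == y.second;
                               }),
                   onE[k].end());
    }
    if (onE[0].empty() && onE[1].empty() && onE[2].empty()) {
      outF.insert(outF.end(), {vi[0], vi[1], vi[2]});
      continue;
    }
    // boundary polygon and centroid fan
    std::vector<int> poly;
    for (int k = 0; k < 3; ++k) {
      poly.push_back(vi[k]);
      for (auto& pr : onE[k]) poly.push_back(pr.second);
    }
    Vec3 g = (P[0] + P[1] + P[2]) * (1.0 / 3.0);
    int gi = addV(g);
    int np = (int)poly.size();
    for (int k = 0; k < np; ++k)
      outF.insert(outF.end(), {gi, poly[k], poly[(k + 1) % np]});
  }

  int nNew = (int)(newV.size() / 3);
  NumericMatrix V2(nV + nNew, 3);
  for (int i = 0; i < nV; ++i)
    for (int k = 0; k < 3; ++k) V2(i, k) = V(i, k);
  for (int i = 0; i < nNew; ++i)
    for (int k = 0; k < 3; ++k) V2(nV + i, k) = newV[3 * i + k];
  int m = (int)(outF.size() / 3);
  IntegerMatrix F2(m, 3);
  for (int i = 0; i < m; ++i)
    for (int k = 0; k < 3; ++k) F2(i, k) = outF[3 * i + k] + 1;
  return List::create(_["vertices"] = V2, _["faces"] = F2);
}
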