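// Planar cross-sections of a triangle mesh (segments chained into closed
// loops) and nonzero-winding scanline rasterization of stacked polygons.
#include <Rcpp.h>
#include <vector>
#include <map>
#include <cstdint>
#include <cmath>
#include <algorithm>

using namespace Rcpp;

namespace {
typedef std::pair<long long, long long> QKey;
}

// Cross-sections at heights zs of a mesh already rotated so the slicing
// direction is +z. qtol is the endpoint-welding tolerance for chaining.
// Returns, per height, a list of closed loops (k x 2 matrices, first row not
// repeated) plus a count of open (unclosable) chains.
// [[Rcpp::export]]
List cpp_slice_mesh(NumericMatrix V, IntegerMatrix F, NumericVector zs,
                    double qtol) {
  int nz = zs.size(), nF = F.nrow();
  List out(nz);
  IntegerVector nopen(nz);

  for (int zi = 0; zi < nz; ++zi) {
    double z = zs[zi];
    std::vector<double> segs;  // x1 y1 x2 y2
    for (int f = 0; f < nF; ++f) {
      int vi[3] = {F(f, 0) - 1, F(f, 1) - 1, F(f, 2) - 1};
      double d[3];
      for (int k = 0; k < 3; ++k) {
        d[k] = V(vi[k], 2) - z;
        if (d[k] == 0) d[k] = qtol * 1e-3;  // nudge exact hits
      }
      double px[2], py[2];
      int nc = 0;
      for (int k = 0; k < 3 && nc < 2; ++k) {
        int a = vi[k], b = vi[(k + 1) % 3];
        double da = d[k], db = d[(k + 1) % 3];
        if ((da > 0) != (db > 0)) {
          double t = da / (da - db);
          px[nc] = V(a, 0) + (V(b, 0) - V(a, 0)) * t;
          py[nc] = V(a, 1) + (V(b, 1) - V(a, 1)) * t;
          ++nc;
        }
      }
      if (nc == 2) segs.insert(segs.end(), {px[0], py[0], px[1], py[1]});
    }
    int ns = (int)(segs.size() / 4);

    // endpoint welding by quantized key
    std::map<QKey, std::vector<int>> ends;  // endpoint id = 2*seg + side
    auto key = [&](double x, double y) {
      return QKey((long long)std::llround(x / qtol),
                  (long long)std::llround(y / qtol));
    };
    for (int s = 0; s < ns; ++s) {
      ends[key(segs[4 * s], segs[4 * s + 1])].push_back(2 * s);
      ends[key(segs[4 * s + 2], segs[4 * s + 3])].push_back(2 * s + 1);
    }
    std::vector<bool> used(ns, false);
    List loops;
    int nop = 0;
    for (int s0 = 0; s0 < ns; ++s0) {
      if (used[s0]) continue;
      std::vector<double> loop;
      int seg = s0, side = 0;
      bool closed = false;
      while (true) {
        used[seg] = true;
        double x0 = segs[4 * seg + 2 * side], y0 = segs[4 * seg + 2 * side + 1];
        int oside = 1 - side;
        double x1 = segs[4 * seg + 2 * oside], y1 = segs[4 * seg + 2 * oside + 1];
        loop.insert(loop.end(), {x0, y0});
        // find partner at the far endpoint
        auto it = ends.find(key(x1, y1));
        int nseg = -1, nside = 0;
        if (it != ends.end()) {
          for (int eid : it->second) {
            int cs = eid / 2;
            if (cs == seg || used[cs]) continue;
            nseg = cs;
            nside = eid % 2;
            break;
          }
        }
        if (nseg < 0) {
          // back at start?
          if (key(x1, y1) == key(segs[4 * s0], segs[4 * s0 + 1])) closed = true;
          break;
        }
        seg = nseg;
        side = nside;
      }
      if (closed && loop.size() >= 6) {
        int k = (int)(loop.size() / 2);
        NumericMatrix L(k, 2);
        for (int i = 0; i < k; ++i) {
          L(i, 0) = loop[2 * i];
          L(i, 1) = loop[2 * i + 1];
        }
        loops.push_back(L);
      } else if (!closed) {
        ++nop;
      }
    }
    out[zi] = loops;
    nopen[zi] = nop;
  }
  return List::create(_["loops"] = out, _["n_open"] = nopen);
}

// Nonzero-winding scanline fill of a set of closed loops evaluated at grid
// centres xs x ys; boundary-inclusive within eps.
// [[Rcpp::export]]
LogicalMatrix cpp_fill_polygons(List loops, NumericVector xs, NumericVector ys,
                                double eps) {
  int nx = xs.size(), ny = ys.size();
  LogicalMatrix out(nx, ny);
  int nl = loops.size();
  std::vector<NumericMatrix> L(nl);
  for (int i = 0; i < nl; ++i) L[i] = as<NumericMatrix>(loops[i]);

  std::vector<std::pair<double, int>> cross;
  for (int j = 0; j < ny; ++j) {
    for (int pass = 0; pass < 2; ++pass) {
      double yp = ys[j] + (pass == 0 ? -eps : eps);
      cross.clear();
      for (int li = 0; li < nl; ++li) {
        const NumericMatrix& P = L[li];
        int k = P.nrow();
        for (int e = 0; e < k; ++e) {
          double x0 = P(e, 0), y0 = P(e, 1);
          double x1 = P((e + 1) % k, 0), y1 = P((e + 1) % k, 1);
          int dir = 0;
          if (y0 <= yp && yp < y1) dir = 1;
          else if (y1 <= yp && yp < y0) dir = -1;
          if (dir != 0) {
            double t = (yp - y0) / (y1 - y0);
            cross.push_back({x0 + (x1 - x0) * t, dir});
          }
        }
      }
      if (cross.empty()) continue;
      std::sort(cross.begin(), cross.end());
      int w = 0;
      double xstart = 0;
      for (size_t c = 0; c < cross.size(); ++c) {
        int wprev = w;
        w += cross[c].second;
        if (wprev == 0 && w != 0) {
          xstart = cross[c].first;
        } else if (wprev != 0 && w == 0) {
          double a = xstart - eps, b = cross[c].first + eps;
          int i0 = (int)(std::lower_bound(xs.begin(), xs.end(), a) - xs.begin());
          for (int i = i0; i < nx && xs[i] <= b; ++i) out(i, j) = true;
        }
      }
    }
  }
  return out;
}
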