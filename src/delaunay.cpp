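// 2D Delaunay triangulation (Bowyer-Watson, incremental with walk-based
// point location) and a grid-hashed nearest-neighbour spacing helper.
// Both back the projected-area and voxel-size defaults; coordinates are
// expected pre-normalized to O(1) scale by the R wrappers.
#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cmath>
#include <cstdint>
#include <algorithm>
using namespace Rcpp;

static inline double orient2d(double ax, double ay, double bx, double by,
                              double cx, double cy) {
  return (bx - ax) * (cy - ay) - (by - ay) * (cx - ax);
}

// > 0 iff d strictly inside circumcircle of ccw triangle (a, b, c)
static inline double incircle(double ax, double ay, double bx, double by,
                              double cx, double cy, double dx, double dy) {
  const double adx = ax - dx, ady = ay - dy;
  const double bdx = bx - dx, bdy = by - dy;
  const double cdx = cx - dx, cdy = cy - dy;
  const double ad = adx * adx + ady * ady;
  const double bd = bdx * bdx + bdy * bdy;
  const double cd = cdx * cdx + cdy * cdy;
  return adx * (bdy * cd - bd * cdy) - ady * (bdx * cd - bd * cdx) +
         ad * (bdx * cdy - bdy * cdx);
}

struct Tri {
  int v[3];    // vertex indices, ccw
  int adj[3];  // adj[i] = triangle sharing the edge opposite v[i]; -1 none
  bool alive;
};

class Delaunay {
public:
  std::vector<double> px, py;
  std::vector<Tri> tris;
  int last_tri = 0;

  explicit Delaunay(const NumericMatrix& pts) {
    const int n = pts.nrow();
    px.reserve(n + 3);
    py.reserve(n + 3);
    for (int i = 0; i < n; ++i) {
      px.push_back(pts(i, 0));
      py.push_back(pts(i, 1));
    }
    double xmin = px[0], xmax = px[0], ymin = py[0], ymax = py[0];
    for (int i = 1; i < n; ++i) {
      xmin = std::min(xmin, px[i]); xmax = std::max(xmax, px[i]);
      ymin = std::min(ymin, py[i]); ymax = std::max(ymax, py[i]);
    }
    const double cx = 0.5 * (xmin + xmax), cy = 0.5 * (ymin + ymax);
    double m = std::max(xmax - xmin, ymax - ymin);
    if (m <= 0) m = 1.0;
    const double R = 60.0 * m;
    // super-triangle vertices appended after the real points
    px.push_back(cx - 1.8 * R); py.push_back(cy - R);
    px.push_back(cx + 1.8 * R); py.push_back(cy - R);
    px.push_back(cx);           py.push_back(cy + 2.0 * R);
    Tri t;
    t.v[0] = n; t.v[1] = n + 1; t.v[2] = n + 2;
    t.adj[0] = t.adj[1] = t.adj[2] = -1;
    t.alive = true;
    tris.push_back(t);
  }

  bool in_tri(int t, double x, double y) const {
    const Tri& T = tris[t];
    for (int e = 0; e < 3; ++e) {
      const int a = T.v[e], b = T.v[(e + 1) % 3];
      if (orient2d(px[a], py[a], px[b], py[b], x, y) < 0) return false;
    }
    return true;
  }

  // walk toward (x, y) from last_tri; returns containing triangle or -1
  int locate(double x, double y) const {
    int t = last_tri;
    if (t < 0 || t >= (int)tris.size() || !tris[t].alive) {
      t = -1;
      for (int i = (int)tris.size() - 1; i >= 0; --i)
        if (tris[i].alive) { t = i; break; }
      if (t < 0) return -1;
    }
    const int max_steps = 8 * (int)tris.size() + 64;
    for (int step = 0; step < max_steps; ++step) {
      const Tri& T = tris[t];
      int next = -1;
      for (int e = 0; e < 3; ++e) {
        const int a = T.v[e], b = T.v[(e + 1) % 3];
        if (orient2d(px[a], py[a], px[b], py[b], x, y) < 0) {
          next = T.adj[(e + 2) % 3];
          break;
        }
      }
      if (next < 0) return t;  // inside t (or stuck on hull: accept)
      t = next;
    }
    // walk failed (degenerate geometry): exhaustive fallback
    for (int i = 0; i < (int)tris.size(); ++i)
      if (tris[i].alive && in_tri(i, x, y)) return i;
    return -1;
  }

  bool insert(int ip) {
    const double x = px[ip], y = py[ip];
    const int t0 = locate(x, y);
    if (t0 < 0) return false;
    // cavity = BFS over triangles whose circumcircle contains p
    std::vector<int> cavity;
    std::vector<char> in_cav(tris.size(), 0);
    std::vector<int> stack;
    stack.push_back(t0);
    in_cav[t0] = 1;
    while (!stack.empty()) {
      const int t = stack.back();
      stack.pop_back();
      cavity.push_back(t);
      for (int e = 0; e < 3; ++e) {
        const int nb = tris[t].adj[e];
        if (nb < 0 || in_cav[nb]) continue;
        const Tri& N = tris[nb];
        if (incircle(px[N.v[0]], py[N.v[0]], px[N.v[1]], py[N.v[1]],
                     px[N.v[2]], py[N.v[2]], x, y) > 0) {
          in_cav[nb] = 1;
          stack.push_back(nb);
        }
      }
    }
    // boundary edges of the cavity, directed ccw in their triangle
    struct BEdge { int a, b, ext; };
    std::vector<BEdge> bed;
    for (size_t k = 0; k < cavity.size(); ++k) {
      const int t = cavity[k];
      const Tri& T = tris[t];
      for (int e = 0; e < 3; ++e) {
        const int nb = T.adj[(e + 2) % 3];  // neighbour across edge (v[e], v[e+1])
        if (nb >= 0 && in_cav[nb]) continue;
        BEdge be;
        be.a = T.v[e];
        be.b = T.v[(e + 1) % 3];
        be.ext = nb;
        bed.push_back(be);
      }
    }
    if (bed.empty()) return false;
    for (size_t k = 0; k < cavity.size(); ++k) tris[cavity[k]].alive = false;
    // one new triangle (a, b, p) per boundary edge
    std::unordered_map<int, int> by_a, by_b;
    const int base = (int)tris.size();
    for (size_t k = 0; k < bed.size(); ++k) {
      Tri t;
      t.v[0] = bed[k].a; t.v[1] = bed[k].b; t.v[2] = ip;
      t.adj[0] = -1; t.adj[1] = -1; t.adj[2] = bed[k].ext;
      t.alive = true;
      const int id = base + (int)k;
      tris.push_back(t);
      by_a[bed[k].a] = id;
      by_b[bed[k].b] = id;
      if (bed[k].ext >= 0) {
        // ext's former neighbour was some cavity triangle; find the slot
        // whose adjacent triangle is dead and matches the shared edge
        int slot = -1;
        for (int e = 0; e < 3; ++e) {
          const int nb = tris[bed[k].ext].adj[e];
          if (nb >= 0 && nb < base && !tris[nb].alive) {
            // shared edge of ext opposite e is (v[e+1], v[e+2])
            const int ea = tris[bed[k].ext].v[(e + 1) % 3];
            const int eb = tris[bed[k].ext].v[(e + 2) % 3];
            if ((ea == bed[k].a && eb == bed[k].b) ||
                (ea == bed[k].b && eb == bed[k].a)) { slot = e; break; }
          }
        }
        if (slot >= 0) tris[bed[k].ext].adj[slot] = id;
      }
    }
    // stitch new triangles around p: edge (b, p) of tri(a,b) meets edge
    // (p, a') of the tri whose a' == b
    for (size_t k = 0; k < bed.size(); ++k) {
      const int id = base + (int)k;
      tris[id].adj[0] = by_a[bed[k].b];  // across edge (b, p), opposite v[0]=a
      tris[id].adj[1] = by_b[bed[k].a];  // across edge (p, a), opposite v[1]=b
    }
    last_tri = base;
    return true;
  }

};

// [[Rcpp::export(name = ".delaunay_cpp")]]
IntegerMatrix delaunay_cpp(NumericMatrix pts) {
  const int n = pts.nrow();
  if (n < 3) return IntegerMatrix(0, 3);
  Delaunay D(pts);
  // boustrophedon grid order for walk locality
  std::vector<int> ord(n);
  for (int i = 0; i < n; ++i) ord[i] = i;
  double xmin = pts(0, 0), xmax = pts(0, 0), ymin = pts(0, 1), ymax = pts(0, 1);
  for (int i = 1; i < n; ++i) {
    xmin = std::min(xmin, pts(i, 0)); xmax = std::max(xmax, pts(i, 0));
    ymin = std::min(ymin, pts(i, 1)); ymax = std::max(ymax, pts(i, 1));
  }
  const int nb = std::max(1, (int)std::floor(std::sqrt((double)n / 2.0)));
  const double sx = (xmax > xmin) ? nb / (xmax - xmin) : 1.0;
  const double sy = (ymax > ymin) ? nb / (ymax - ymin) : 1.0;
  std::sort(ord.begin(), ord.end(), [&](int i, int j) {
    int ri = std::min(nb - 1, (int)((pts(i, 1) - ymin) * sy));
    int rj = std::min(nb - 1, (int)((pts(j, 1) - ymin) * sy));
    if (ri != rj) return ri < rj;
    int ci = std::min(nb - 1, (int)((pts(i, 0) - xmin) * sx));
    int cj = std::min(nb - 1, (int)((pts(j, 0) - xmin) * sx));
    if (ri % 2 == 1) std::swap(ci, cj);
    if (ci != cj) return ci < cj;
    return i < j;
  });
  for (int k = 0; k < n; ++k) {
    if (!D.insert(ord[k]))
      stop("Delaunay insertion failed (degenerate point configuration)");
  }
  // keep alive triangles not touching super-triangle vertices
  std::vector<int> keep;
  for (int i = 0; i < (int)D.tris.size(); ++i) {
    if (!D.tris[i].alive) continue;
    const Tri& T = D.tris[i];
    if (T.v[0] >= n || T.v[1] >= n || T.v[2] >= n) continue;
    keep.push_back(i);
  }
  IntegerMatrix out((int)keep.size(), 3);
  for (size_t k = 0; k < keep.size(); ++k)
    for (int e = 0; e < 3; ++e)
      out((int)k, e) = D.tris[keep[k]].v[e] + 1;
  return out;
}

static inline int64_t cell_key(int ix, int iy, int iz) {
  return ((int64_t)(ix + 1048576)) |
         (((int64_t)(iy + 1048576)) << 21) |
         (((int64_t)(iz + 1048576)) << 42);
}

// nearest-neighbour distance for each of at most `sample_n` points
// (deterministic evenly-spaced subsample), searched against the full set
// via an expanding-ring grid hash; works for 2- or 3-column matrices.
// [[Rcpp::export(name = ".nn_spacing_cpp")]]
NumericVector nn_spacing_cpp(NumericMatrix pts, int sample_n) {
  const int n = pts.nrow();
  const int d = pts.ncol();
  if (n < 2) return NumericVector(0);
  std::vector<double> lo(3, 0.0), hi(3, 0.0);
  for (int j = 0; j < d; ++j) {
    lo[j] = hi[j] = pts(0, j);
    for (int i = 1; i < n; ++i) {
      lo[j] = std::min(lo[j], pts(i, j));
      hi[j] = std::max(hi[j], pts(i, j));
    }
  }
  double vol = 1.0, span = 0.0;
  for (int j = 0; j < d; ++j) {
    vol *= std::max(hi[j] - lo[j], 1e-300);
    span = std::max(span, hi[j] - lo[j]);
  }
  double cell = std::pow(vol / n, 1.0 / d);
  if (!(cell > 0) || !R_finite(cell)) cell = (span > 0) ? span / 64.0 : 1.0;
  std::unordered_map<int64_t, std::vector<int>> grid;
  grid.reserve(2 * n);
  auto cix = [&](int i, int j) {
    return (int)std::floor((pts(i, j) - lo[j]) / cell);
  };
  for (int i = 0; i < n; ++i) {
    const int ix = cix(i, 0), iy = cix(i, 1), iz = (d == 3) ? cix(i, 2) : 0;
    grid[cell_key(ix, iy, iz)].push_back(i);
  }
  const int m = std::min(sample_n, n);
  const double step = (double)n / m;
  NumericVector out(m);
  for (int s = 0; s < m; ++s) {
    const int i = std::min(n - 1, (int)std::floor(s * step));
    const int ix = cix(i, 0), iy = cix(i, 1), iz = (d == 3) ? cix(i, 2) : 0;
    double best = R_PosInf;
    const int max_ring = 1 + (int)std::ceil(span / cell);
    for (int ring = 1; ring <= max_ring; ++ring) {
      const int zlo = (d == 3) ? -ring : 0, zhi = (d == 3) ? ring : 0;
      for (int dx = -ring; dx <= ring; ++dx)
        for (int dy = -ring; dy <= ring; ++dy)
          for (int dz = zlo; dz <= zhi; ++dz) {
            if (ring > 1 && std::abs(dx) < ring && std::abs(dy) < ring &&
                std::abs(dz) < ring)
              continue;  // only the new shell (ring 1 scans the full block)
            auto it = grid.find(cell_key(ix + dx, iy + dy, iz + dz));
            if (it == grid.end()) continue;
            for (size_t q = 0; q < it->second.size(); ++q) {
              const int j = it->second[q];
              if (j == i) continue;
              double dd = 0.0;
              for (int c = 0; c < d; ++c) {
                const double t = pts(i, c) - pts(j, c);
                dd += t * t;
              }
              best = std::min(best, dd);
            }
          }
      // neighbour in ring r guarantees true NN within distance (r+1)*cell
      if (R_finite(best) && std::sqrt(best) <= ring * cell) break;
    }
    out[s] = std::sqrt(best);
  }
  return out;
}
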