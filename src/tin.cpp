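// Incremental (Bowyer-Watson) Delaunay triangulation with walk-based point
// location. Powers progressive-TIN ground densification and linear TIN
// interpolation for the DTM. Incremental insertion matters here: the ground
// filter grows the triangulation across iterations without rebuilding it.
#include <Rcpp.h>
#include <algorithm>
#include <array>
#include <cmath>
#include <map>
#include <unordered_map>
#include <utility>
#include <vector>

using namespace Rcpp;

namespace {

struct Tri {
  std::array<int, 3> v;  // vertex indices, counter-clockwise
  std::array<int, 3> n;  // neighbour across edge opposite v[i]; -1 = none
  bool alive;
};

class Delaunay {
 public:
  std::vector<double> px, py, pz;
  std::vector<Tri> tris;
  int last_alive = 0;

  // super-triangle spans [xmin,xmax]x[ymin,ymax] with a wide margin
  void init(double xmin, double xmax, double ymin, double ymax) {
    double cx = 0.5 * (xmin + xmax), cy = 0.5 * (ymin + ymax);
    double span = std::max(xmax - xmin, ymax - ymin) + 1.0;
    double m = 50.0 * span;
    px = {cx - m, cx + m, cx};
    py = {cy - m, cy - m, cy + m};
    pz = {0.0, 0.0, 0.0};
    tris.clear();
    tris.push_back({{0, 1, 2}, {-1, -1, -1}, true});
    last_alive = 0;
  }

  static double orient(double ax, double ay, double bx, double by, double qx,
                       double qy) {
    return (bx - ax) * (qy - ay) - (by - ay) * (qx - ax);
  }

  double orient_v(int a, int b, double qx, double qy) const {
    return orient(px[a], py[a], px[b], py[b], qx, qy);
  }

  // > 0 when q lies strictly inside the circumcircle of CCW triangle (a,b,c)
  double incircle(int a, int b, int c, double qx, double qy) const {
    double adx = px[a] - qx, ady = py[a] - qy;
    double bdx = px[b] - qx, bdy = py[b] - qy;
    double cdx = px[c] - qx, cdy = py[c] - qy;
    double ad2 = adx * adx + ady * ady;
    double bd2 = bdx * bdx + bdy * bdy;
    double cd2 = cdx * cdx + cdy * cdy;
    return adx * (bdy * cd2 - cdy * bd2) - ady * (bdx * cd2 - cdx * bd2) +
           ad2 * (bdx * cdy - cdx * bdy);
  }

  // walk from a recently used triangle towards (qx, qy); returns triangle
  // index or -1 when the walk fails (then caller falls back to a scan)
  int locate(double qx, double qy) const {
    int t = last_alive;
    if (t < 0 || t >= (int)tris.size() || !tris[t].alive) t = first_alive();
    int guard = 8 * (int)tris.size() + 64;
    while (guard-- > 0) {
      const Tri& tr = tris[t];
      int next = -1;
      for (int i = 0; i < 3; ++i) {
        int a = tr.v[(i + 1) % 3], b = tr.v[(i + 2) % 3];
        if (orient_v(a, b, qx, qy) < 0) {
          next = tr.n[i];
          break;
        }
      }
      if (next == -1) return t;  // inside or on boundary of t
      t = next;
    }
    return scan(qx, qy);
  }

  int first_alive() const {
    for (int i = (int)tris.size() - 1; i >= 0; --i)
      if (tris[i].alive) return i;
    return -1;
  }

  int scan(double qx, double qy) const {
    for (int t = 0; t < (int)tris.size(); ++t) {
      if (!tris[t].alive) continue;
      const Tri& tr = tris[t];
      bool in = true;
      for (int i = 0; i < 3 && in; ++i)
        if (orient_v(tr.v[(i + 1) % 3], tr.v[(i + 2) % 3], qx, qy) < -1e-9)
          in = false;
      if (in) return t;
    }
    return -1;
  }

  // insert point (x, y, z); returns false for a (near-)duplicate vertex
  bool insert(double x, double y, double z) {
    int t0 = locate(x, y);
    if (t0 < 0) return false;
    for (int i = 0; i < 3; ++i) {
      int v = tris[t0].v[i];
      double dx = px[v] - x, dy = py[v] - y;
      if (dx * dx + dy * dy < 1e-16) return false;  // duplicate xy
    }
    int pi = (int)px.size();
    px.push_back(x);
    py.push_back(y);
    pz.push_back(z);

    // grow cavity of triangles whose circumcircle contains the new point
    std::vector<int> bad;
    std::vector<char> inbad(tris.size(), 0);
    std::vector<int> stack = {t0};
    inbad[t0] = 1;
    while (!stack.empty()) {
      int t = stack.back();
      stack.pop_back();
      bad.push_back(t);
      for (int i = 0; i < 3; ++i) {
        int nb = tris[t].n[i];
        if (nb < 0 || inbad[nb] || !tris[nb].alive) continue;
        const Tri& tn = tris[nb];
        if (incircle(tn.v[0], tn.v[1], tn.v[2], x, y) > 0) {
          inbad[nb] = 1;
          stack.push_back(nb);
        }
      }
    }

    // boundary edges of the cavity, with their outside neighbour
    struct Edge {
      int a, b, outer;
    };
    std::vector<Edge> boundary;
    for (int t : bad) {
      for (int i = 0; i < 3; ++i) {
        int nb = tris[t].n[i];
        if (nb >= 0 && inbad[nb]) continue;
        boundary.push_back({tris[t].v[(i + 1) % 3], tris[t].v[(i + 2) % 3], nb});
      }
      tris[t].alive = false;
    }

    // retriangulate: fan of (a, b, pi); stitch adjacency through an edge map
    std::vector<int> fresh(boundary.size());
    for (size_t k = 0; k < boundary.size(); ++k) {
      fresh[k] = (int)tris.size();
      tris.push_back({{boundary[k].a, boundary[k].b, pi}, {-1, -1, -1}, true});
    }
    // adjacency: edge (a,b) faces the outer neighbour (opposite vertex pi,
    // slot 2); edges (b,pi) slot 0 (opposite a) and (pi,a) slot 1 (opposite b)
    // pair up between fan members sharing a boundary endpoint
    std::map<std::pair<int, int>, std::pair<int, int>> open;  // edge -> (tri, slot)
    for (size_t k = 0; k < boundary.size(); ++k) {
      int t = fresh[k];
      int outer = boundary[k].outer;
      tris[t].n[2] = outer;
      if (outer >= 0) {
        for (int i = 0; i < 3; ++i) {
          int oa = tris[outer].v[(i + 1) % 3], ob = tris[outer].v[(i + 2) % 3];
          if ((oa == boundary[k].b && ob == boundary[k].a) ||
              (oa == boundary[k].a && ob == boundary[k].b))
            tris[outer].n[i] = t;
        }
      }
      for (int slot = 0; slot < 2; ++slot) {
        int va = (slot == 0) ? boundary[k].b : pi;
        int vb = (slot == 0) ? pi : boundary[k].a;
        auto key = std::minmax(va, vb);
        auto it = open.find({key.first, key.second});
        if (it == open.end()) {
          open[{key.first, key.second}] = {t, slot};
        } else {
          tris[t].n[slot] = it->second.first;
          tris[it->second.first].n[it->second.second] = t;
          open.erase(it);
        }
      }
    }
    last_alive = fresh.empty() ? first_alive() : fresh[0];
    return true;
  }

  bool has_super(int t) const {
    return tris[t].v[0] < 3 || tris[t].v[1] < 3 || tris[t].v[2] < 3;
  }

  // linear interpolation on the facet under (qx,qy); NAN outside the hull
  double facet_z(double qx, double qy) const {
    int t = locate(qx, qy);
    if (t < 0 || has_super(t)) return NA_REAL;
    return plane_z(t, qx, qy);
  }

  double plane_z(int t, double qx, double qy) const {
    const Tri& tr = tris[t];
    double x1 = px[tr.v[0]], y1 = py[tr.v[0]], z1 = pz[tr.v[0]];
    double x2 = px[tr.v[1]], y2 = py[tr.v[1]], z2 = pz[tr.v[1]];
    double x3 = px[tr.v[2]], y3 = py[tr.v[2]], z3 = pz[tr.v[2]];
    double det = (y2 - y3) * (x1 - x3) + (x3 - x2) * (y1 - y3);
    if (std::abs(det) < 1e-300) return NA_REAL;
    double l1 = ((y2 - y3) * (qx - x3) + (x3 - x2) * (qy - y3)) / det;
    double l2 = ((y3 - y1) * (qx - x3) + (x1 - x3) * (qy - y3)) / det;
    double l3 = 1.0 - l1 - l2;
    return l1 * z1 + l2 * z2 + l3 * z3;
  }
};

}  // namespace

// Linear TIN interpolation of scattered (x, y, z) at query points.
// Returns NA outside the convex hull.
// [[Rcpp::export(name = ".tin_interpolate")]]
NumericVector tin_interpolate_cpp(NumericVector x, NumericVector y,
                                  NumericVector z, NumericVector qx,
                                  NumericVector qy) {
  int n = x.size();
  if (n < 3) stop("TIN interpolation needs at least 3 points");
  Delaunay dt;
  dt.init(*std::min_element(x.begin(), x.end()),
          *std::max_element(x.begin(), x.end()),
          *std::min_element(y.begin(), y.end()),
          *std::max_element(y.begin(), y.end()));
  for (int i = 0; i < n; ++i) dt.insert(x[i], y[i], z[i]);
  int m = qx.size();
  NumericVector out(m);
  for (int j = 0; j < m; ++j) out[j] = dt.facet_z(qx[j], qy[j]);
  return out;
}

// Exact neighbour counts within a point-centred Chebyshev cube of
// half-side `half` (a cube of side 2*half centred on each point, boundary
// inclusive), excluding the point itself. Voxel hashing keeps it O(n).
// [[Rcpp::export(name = ".cube_neighbor_counts")]]
IntegerVector cube_neighbor_counts_cpp(NumericVector x, NumericVector y,
                                       NumericVector z, double half) {
  int n = x.size();
  IntegerVector out(n);
  if (n == 0) return out;
  double h = half;  // bin size = half-side, so candidates span <= 3 bins/axis
  std::unordered_map<long long, std::vector<int>> bins;
  bins.reserve(2 * n);
  auto key = [&](double cx, double cy, double cz) -> long long {
    long long ix = (long long)std::floor(cx / h) + 1048576LL;
    long long iy = (long long)std::floor(cy / h) + 1048576LL;
    long long iz = (long long)std::floor(cz / h) + 1048576LL;
    return (ix << 42) ^ (iy << 21) ^ iz;
  };
  for (int i = 0; i < n; ++i) bins[key(x[i], y[i], z[i])].push_back(i);
  for (int i = 0; i < n; ++i) {
    int cnt = 0;
    for (int dx = -1; dx <= 1; ++dx)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dz = -1; dz <= 1; ++dz) {
          auto it = bins.find(key(x[i] + dx * h, y[i] + dy * h, z[i] + dz * h));
          if (it == bins.end()) continue;
          for (int j : it->second) {
            if (j == i) continue;
            if (std::abs(x[j] - x[i]) <= half &&
                std::abs(y[j] - y[i]) <= half && std::abs(z[j] - z[i]) <= half)
              ++cnt;
          }
        }
    out[i] = cnt;
  }
  return out;
}

// Progressive TIN densification ground filter.
// seed: logical, the per-cell minima used to start the TIN.
// A candidate is accepted when |dz to facet| <= max_dist and either
// |dz| <= noise_floor or atan(|dz| / d_nearest_facet_vertex) <= max_angle.
// Returns an integer per point: 0 seed, k >= 1 the densification iteration
// that accepted it, -1 never accepted.
// [[Rcpp::export(name = ".tin_densify")]]
IntegerVector tin_densify_cpp(NumericVector x, NumericVector y, NumericVector z,
                              LogicalVector seed, double max_dist,
                              double max_angle_deg, double noise_floor,
                              int max_iter) {
  int n = x.size();
  IntegerVector status(n, -1);
  Delaunay dt;
  dt.init(*std::min_element(x.begin(), x.end()),
          *std::max_element(x.begin(), x.end()),
          *std::min_element(y.begin(), y.end()),
          *std::max_element(y.begin(), y.end()));
  std::vector<int> cand;
  cand.reserve(n);
  for (int i = 0; i < n; ++i) {
    if (seed[i]) {
      dt.insert(x[i], y[i], z[i]);
      status[i] = 0;
    } else {
      cand.push_back(i);
    }
  }
  double tan_max = std::tan(max_angle_deg * M_PI / 180.0);
  for (int iter = 1; iter <= max_iter && !cand.empty(); ++iter) {
    // phase 1: evaluate every remaining candidate against the current TIN
    std::vector<int> accepted, remaining;
    for (int i : cand) {
      int tri = dt.locate(x[i], y[i]);
      if (tri < 0) {
        remaining.push_back(i);
        continue;
      }
      double dz, dmin;
      if (dt.has_super(tri)) {
        // outside the current hull (transect edge strip): test against the
        // nearest real vertex of the hull triangle so the hull can grow
        dz = R_PosInf;
        dmin = R_PosInf;
        const Tri& tr = dt.tris[tri];
        for (int k = 0; k < 3; ++k) {
          if (tr.v[k] < 3) continue;  // super vertex
          double dx = dt.px[tr.v[k]] - x[i], dy = dt.py[tr.v[k]] - y[i];
          double d = std::sqrt(dx * dx + dy * dy);
          if (d < dmin) {
            dmin = d;
            dz = std::abs(z[i] - dt.pz[tr.v[k]]);
          }
        }
        if (!std::isfinite(dz)) {
          remaining.push_back(i);
          continue;
        }
      } else {
        double zt = dt.plane_z(tri, x[i], y[i]);
        dz = std::abs(z[i] - zt);
        dmin = R_PosInf;
        const Tri& tr = dt.tris[tri];
        for (int k = 0; k < 3; ++k) {
          double dx = dt.px[tr.v[k]] - x[i], dy = dt.py[tr.v[k]] - y[i];
          double d = std::sqrt(dx * dx + dy * dy);
          if (d < dmin) dmin = d;
        }
      }
      bool ok = dz <= max_dist &&
                (dz <= noise_floor || dz <= tan_max * dmin);
      if (ok)
        accepted.push_back(i);
      else
        remaining.push_back(i);
    }
    if (accepted.empty()) break;
    // phase 2: densify the TIN with this iteration's acceptances
    for (int i : accepted) {
      dt.insert(x[i], y[i], z[i]);
      status[i] = iter;
    }
    cand.swap(remaining);
  }
  return status;
}
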