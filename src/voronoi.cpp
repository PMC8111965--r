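#include <Rcpp.h>
#include <vector>
#include <array>
#include <map>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

// Voronoi tessellation computed cell by cell: each cell starts as the
// bounding box and is clipped by the bisector planes of nearby points, in
// order of increasing distance, until no farther point can cut the cell
// (a bisector at distance d/2 beyond the farthest cell vertex is inactive).
// This bounds every cell by the box exactly and yields, as a by-product,
// the Delaunay tetrahedra of the point set: every cell vertex defined by
// three bisector planes is the circumcenter of the tetrahedron formed by
// the generator and those three neighbors, with an empty circumsphere.

struct Plane {
  double nx, ny, nz, d;  // inside: n.x <= d
  int neighbor;          // generating point index, -1 for box planes
};

struct Vertex {
  double x, y, z;
  int p1, p2, p3;  // defining plane indices (local)
};

static inline double dist3(double ax, double ay, double az, double bx,
                           double by, double bz) {
  double dx = ax - bx, dy = ay - by, dz = az - bz;
  return std::sqrt(dx * dx + dy * dy + dz * dz);
}

// intersection of three planes; returns false if nearly parallel
static bool intersect3(const Plane &a, const Plane &b, const Plane &c,
                       double &x, double &y, double &z) {
  double det = a.nx * (b.ny * c.nz - b.nz * c.ny) -
               a.ny * (b.nx * c.nz - b.nz * c.nx) +
               a.nz * (b.nx * c.ny - b.ny * c.nx);
  if (std::fabs(det) < 1e-14) return false;
  x = (a.d * (b.ny * c.nz - b.nz * c.ny) -
       a.ny * (b.d * c.nz - b.nz * c.d) +
       a.nz * (b.d * c.ny - b.ny * c.d)) / det;
  y = (a.nx * (b.d * c.nz - b.nz * c.d) -
       a.d * (b.nx * c.nz - b.nz * c.nx) +
       a.nz * (b.nx * c.d - b.d * c.nx)) / det;
  z = (a.nx * (b.ny * c.d - b.d * c.ny) -
       a.ny * (b.nx * c.d - b.d * c.nx) +
       a.d * (b.nx * c.ny - b.ny * c.nx)) / det;
  return true;
}

// uniform grid for neighbor search
struct Grid {
  double lo[3], cell;
  int n[3];
  std::vector<std::vector<int>> bins;
  Grid(const NumericMatrix &pts, const double blo[3], const double bhi[3]) {
    double vol = 1.0;
    for (int k = 0; k < 3; ++k) vol *= (bhi[k] - blo[k]);
    double target = std::cbrt(vol / std::max(1, (int)pts.nrow())) * 1.5;
    for (int k = 0; k < 3; ++k) {
      lo[k] = blo[k];
      n[k] = std::max(1, (int)std::floor((bhi[k] - blo[k]) / target));
      n[k] = std::min(n[k], 128);
    }
    cell = 0.0;
    for (int k = 0; k < 3; ++k)
      cell = std::max(cell, (bhi[k] - blo[k]) / n[k]);
    bins.assign((size_t)n[0] * n[1] * n[2], {});
    for (int i = 0; i < pts.nrow(); ++i) bins[index_of(pts, i)].push_back(i);
  }
  int clampi(double v, int k) const {
    int c = (int)std::floor((v - lo[k]) / cell);
    return std::min(std::max(c, 0), n[k] - 1);
  }
  size_t index_of(const NumericMatrix &pts, int i) const {
    return ((size_t)clampi(pts(i, 0), 0) * n[1] + clampi(pts(i, 1), 1)) * n[2] +
           clampi(pts(i, 2), 2);
  }
  // all points within `shells` grid shells of point i's bin
  void collect(const NumericMatrix &pts, int i, int shells,
               std::vector<int> &out) const {
    out.clear();
    int c0 = clampi(pts(i, 0), 0), c1 = clampi(pts(i, 1), 1),
        c2 = clampi(pts(i, 2), 2);
    for (int a = std::max(0, c0 - shells); a <= std::min(n[0] - 1, c0 + shells); ++a)
      for (int b = std::max(0, c1 - shells); b <= std::min(n[1] - 1, c1 + shells); ++b)
        for (int c = std::max(0, c2 - shells); c <= std::min(n[2] - 1, c2 + shells); ++c)
          for (int j : bins[((size_t)a * n[1] + b) * n[2] + c])
            if (j != i) out.push_back(j);
  }
  bool full(int shells, int c0, int c1, int c2) const {
    return c0 - shells <= 0 && c0 + shells >= n[0] - 1 && c1 - shells <= 0 &&
           c1 + shells >= n[1] - 1 && c2 - shells <= 0 && c2 + shells >= n[2] - 1;
  }
};

// clip the cell by plane q (index into planes); returns false if plane inactive
static bool clip_cell(std::vector<Vertex> &verts,
                      const std::vector<Plane> &planes, int q, double eps) {
  const Plane &P = planes[q];
  int nv = verts.size();
  std::vector<double> s(nv);
  bool any_out = false;
  for (int v = 0; v < nv; ++v) {
    s[v] = P.nx * verts[v].x + P.ny * verts[v].y + P.nz * verts[v].z - P.d;
    if (s[v] > eps) any_out = true;
  }
  if (!any_out) return false;
  // edges = vertex pairs sharing two planes, one inside one outside
  std::map<std::pair<int, int>, bool> made;
  std::vector<Vertex> nv_list;
  for (int a = 0; a < nv; ++a) {
    if (s[a] > eps) continue;
    nv_list.push_back(verts[a]);
  }
  for (int a = 0; a < nv; ++a) {
    if (s[a] > eps) continue;
    for (int b = 0; b < nv; ++b) {
      if (s[b] <= eps) continue;
      int pa[3] = {verts[a].p1, verts[a].p2, verts[a].p3};
      int pb[3] = {verts[b].p1, verts[b].p2, verts[b].p3};
      int shared[3], ns = 0;
      for (int u = 0; u < 3; ++u)
        for (int w = 0; w < 3; ++w)
          if (pa[u] == pb[w] && ns < 3) shared[ns++] = pa[u];
      if (ns != 2) continue;
      std::pair<int, int> key(std::min(shared[0], shared[1]),
                              std::max(shared[0], shared[1]));
      if (made.count(key)) continue;
      double x, y, z;
      if (!intersect3(planes[shared[0]], planes[shared[1]], P, x, y, z))
        continue;
      made[key] = true;
      nv_list.push_back({x, y, z, shared[0], shared[1], q});
    }
  }
  verts.swap(nv_list);
  return true;
}

static double max_vertex_dist(const std::vector<Vertex> &verts, double px,
                              double py, double pz) {
  double m = 0.0;
  for (const auto &v : verts)
    m = std::max(m, dist3(v.x, v.y, v.z, px, py, pz));
  return m;
}

// polyhedron volume: group vertices by plane (face), fan-triangulate each
// face, sum pyramid volumes from the generator (inside the convex cell)
static double cell_volume(const std::vector<Vertex> &verts, double px,
                          double py, double pz) {
  std::map<int, std::vector<int>> faces;
  for (size_t v = 0; v < verts.size(); ++v) {
    faces[verts[v].p1].push_back(v);
    faces[verts[v].p2].push_back(v);
    faces[verts[v].p3].push_back(v);
  }
  double vol = 0.0;
  for (auto &f : faces) {
    std::vector<int> &vi = f.second;
    if (vi.size() < 3) continue;
    // face centroid
    double cx = 0, cy = 0, cz = 0;
    for (int v : vi) { cx += verts[v].x; cy += verts[v].y; cz += verts[v].z; }
    cx /= vi.size(); cy /= vi.size(); cz /= vi.size();
    // order around centroid: build local frame from face normal
    double ax = verts[vi[0]].x - cx, ay = verts[vi[0]].y - cy,
           az = verts[vi[0]].z - cz;
    double qx = cx - px, qy = cy - py, qz = cz - pz;  // approx normal dir
    // orthogonalize a against q
    double qn = std::sqrt(qx * qx + qy * qy + qz * qz);
    if (qn < 1e-300) continue;
    qx /= qn; qy /= qn; qz /= qn;
    double ad = ax * qx + ay * qy + az * qz;
    ax -= ad * qx; ay -= ad * qy; az -= ad * qz;
    double an = std::sqrt(ax * ax + ay * ay + az * az);
    if (an < 1e-300) continue;
    ax /= an; ay /= an; az /= an;
    double bx = qy * az - qz * ay, by = qz * ax - qx * az,
           bz = qx * ay - qy * ax;
    std::vector<std::pair<double, int>> ang;
    for (int v : vi) {
      double ux = verts[v].x - cx, uy = verts[v].y - cy, uz = verts[v].z - cz;
      ang.push_back({std::atan2(ux * bx + uy * by + uz * bz,
                                ux * ax + uy * ay + uz * az), v});
    }
    std::sort(ang.begin(), ang.end());
    for (size_t t = 0; t < ang.size(); ++t) {
      const Vertex &A = verts[ang[t].second];
      const Vertex &B = verts[ang[(t + 1) % ang.size()].second];
      double v1x = A.x - px, v1y = A.y - py, v1z = A.z - pz;
      double v2x = B.x - px, v2y = B.y - py, v2z = B.z - pz;
      double v3x = cx - px, v3y = cy - py, v3z = cz - pz;
      vol += std::fabs(v1x * (v2y * v3z - v2z * v3y) -
                       v1y * (v2x * v3z - v2z * v3x) +
                       v1z * (v2x * v3y - v2y * v3x)) / 6.0;
    }
  }
  return vol;
}

// [[Rcpp::export]]
List voronoi_cells_cpp(NumericMatrix pts, NumericVector box_lo,
                       NumericVector box_hi, bool collect_tets) {
  int N = pts.nrow();
  double blo[3], bhi[3], diag = 0.0;
  for (int k = 0; k < 3; ++k) {
    blo[k] = box_lo[k];
    bhi[k] = box_hi[k];
    diag += (bhi[k] - blo[k]) * (bhi[k] - blo[k]);
  }
  diag = std::sqrt(diag);
  double eps = diag * 1e-12;
  Grid grid(pts, blo, bhi);

  NumericVector volumes(N);
  List adjacency(N);
  // Delaunay tetrahedra keyed by sorted indices
  std::map<std::array<int, 4>, std::pair<double, double>> tets;  // -> (circumradius, volume)

  std::vector<int> cand;
  for (int i = 0; i < N; ++i) {
    double px = pts(i, 0), py = pts(i, 1), pz = pts(i, 2);
    std::vector<Plane> planes;
    // box planes
    for (int k = 0; k < 3; ++k) {
      Plane lo{0, 0, 0, -blo[k], -1};
      Plane hi{0, 0, 0, bhi[k], -1};
      (&lo.nx)[k] = -1.0;
      (&hi.nx)[k] = 1.0;
      planes.push_back(lo);
      planes.push_back(hi);
    }
    std::vector<Vertex> verts;
    int corner_planes[8][3] = {{0, 2, 4}, {0, 2, 5}, {0, 3, 4}, {0, 3, 5},
                               {1, 2, 4}, {1, 2, 5}, {1, 3, 4}, {1, 3, 5}};
    for (auto &cp : corner_planes) {
      double x, y, z;
      intersect3(planes[cp[0]], planes[cp[1]], planes[cp[2]], x, y, z);
      verts.push_back({x, y, z, cp[0], cp[1], cp[2]});
    }

    int shells = 1;
    int c0 = grid.clampi(px, 0), c1 = grid.clampi(py, 1), c2 = grid.clampi(pz, 2);
    size_t processed = 0;
    std::vector<std::pair<double, int>> queue;  // (distance, j)
    bool done = false;
    while (!done) {
      grid.collect(pts, i, shells, cand);
      queue.clear();
      for (int j : cand)
        queue.push_back({dist3(px, py, pz, pts(j, 0), pts(j, 1), pts(j, 2)), j});
      std::sort(queue.begin(), queue.end());
      double search_radius = shells * grid.cell;  // guaranteed-complete radius
      bool grid_full = grid.full(shells, c0, c1, c2);
      processed = 0;
      // rebuild the cell from scratch at this shell level (cheap, and keeps
      // the plane ordering by distance which minimizes clipping work)
      planes.resize(6);
      verts.clear();
      for (auto &cp : corner_planes) {
        double x, y, z;
        intersect3(planes[cp[0]], planes[cp[1]], planes[cp[2]], x, y, z);
        verts.push_back({x, y, z, cp[0], cp[1], cp[2]});
      }
      double rmax = max_vertex_dist(verts, px, py, pz);
      done = true;
      for (auto &dj : queue) {
        if (dj.first * 0.5 > rmax) break;  // no farther point can cut
        if (dj.first < eps) stop("duplicate points in Voronoi input");
        double mx = 0.5 * (px + pts(dj.second, 0)),
               my = 0.5 * (py + pts(dj.second, 1)),
               mz = 0.5 * (pz + pts(dj.second, 2));
        double nx = (pts(dj.second, 0) - px) / dj.first,
               ny = (pts(dj.second, 1) - py) / dj.first,
               nz = (pts(dj.second, 2) - pz) / dj.first;
        planes.push_back({nx, ny, nz, nx * mx + ny * my + nz * mz, dj.second});
        if (clip_cell(verts, planes, planes.size() - 1, eps))
          rmax = max_vertex_dist(verts, px, py, pz);
        ++processed;
      }
      // the cell is certain only if all points within 2*rmax were examined
      if (!grid_full && search_radius < 2.0 * rmax) {
        shells *= 2;
        done = false;
      }
    }

    volumes[i] = cell_volume(verts, px, py, pz);
    // adjacency: bisector planes contributing >= 3 vertices (a face)
    std::map<int, int> plane_count;
    for (auto &v : verts) {
      plane_count[v.p1]++;
      plane_count[v.p2]++;
      plane_count[v.p3]++;
    }
    std::vector<int> adj;
    for (auto &pc : plane_count)
      if (pc.second >= 3 && planes[pc.first].neighbor >= 0)
        adj.push_back(planes[pc.first].neighbor);
    std::sort(adj.begin(), adj.end());
    adjacency[i] = IntegerVector(adj.begin(), adj.end()) + 1;  // 1-based

    if (collect_tets) {
      for (auto &v : verts) {
        int a = planes[v.p1].neighbor, b = planes[v.p2].neighbor,
            c = planes[v.p3].neighbor;
        if (a < 0 || b < 0 || c < 0) continue;  // touches the box
        std::array<int, 4> key{i, a, b, c};
        std::sort(key.begin(), key.end());
        if (tets.count(key)) continue;
        double r = dist3(v.x, v.y, v.z, px, py, pz);
        // tetrahedron volume
        double x0 = pts(key[0], 0), y0 = pts(key[0], 1), z0 = pts(key[0], 2);
        double ax = pts(key[1], 0) - x0, ay = pts(key[1], 1) - y0,
               az = pts(key[1], 2) - z0;
        double bx2 = pts(key[2], 0) - x0, by2 = pts(key[2], 1) - y0,
               bz2 = pts(key[2], 2) - z0;
        double cx = pts(key[3], 0) - x0, cy = pts(key[3], 1) - y0,
               cz = pts(key[3], 2) - z0;
        double tv = std::fabs(ax * (by2 * cz - bz2 * cy) -
                              ay * (bx2 * cz - bz2 * cx) +
                              az * (bx2 * cy - by2 * cx)) / 6.0;
        tets[key] = {r, tv};
      }
    }
  }

  List out = List::create(_["volumes"] = volumes, _["adjacency"] = adjacency);
  if (collect_tets) {
    int T = tets.size();
    IntegerMatrix tm(T, 4);
    NumericVector tr(T), tv(T);
    int t = 0;
    for (auto &kv : tets) {
      for (int k = 0; k < 4; ++k) tm(t, k) = kv.first[k] + 1;
      tr[t] = kv.second.first;
      tv[t] = kv.second.second;
      ++t;
    }
    out["tets"] = tm;
    out["circumradius"] = tr;
    out["tet_volume"] = tv;
  }
  return out;
}

// graph-distance-k neighborhood density: for each point, BFS to depth k on
// the cell-adjacency graph; density = count / total volume of the
// neighborhood (self included; k = 0 gives 1 / own volume)
// [[Rcpp::export]]
NumericVector kring_density_cpp(List adjacency, NumericVector volumes, int k) {
  int N = adjacency.size();
  NumericVector dens(N);
  std::vector<int> mark(N, -1);
  std::vector<int> frontier, next;
  for (int i = 0; i < N; ++i) {
    double vol = volumes[i];
    int count = 1;
    mark[i] = i;
    frontier.assign(1, i);
    for (int depth = 0; depth < k; ++depth) {
      next.clear();
      for (int u : frontier) {
        IntegerVector nb = adjacency[u];
        for (int w : nb) {
          int j = w - 1;
          if (mark[j] != i) {
            mark[j] = i;
            next.push_back(j);
            vol += volumes[j];
            ++count;
          }
        }
      }
      frontier.swap(next);
    }
    dens[i] = count / vol;
  }
  return dens;
}
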