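// Voxel-grid core for probe-constrained tunnel search.
//
// Grid convention: voxel (ix, iy, iz) has linear index ix + nx*(iy + ny*iz)
// and center origin + spacing * (ix, iy, iz). All lengths in Angstrom.

#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
#include <limits>

using namespace Rcpp;

namespace {

const double INF = std::numeric_limits<double>::infinity();

struct Grid {
  int nx, ny, nz;
  double ox, oy, oz, h;
  int n() const { return nx * ny * nz; }
  int idx(int ix, int iy, int iz) const { return ix + nx * (iy + ny * iz); }
  void decode(int i, int &ix, int &iy, int &iz) const {
    ix = i % nx; i /= nx; iy = i % ny; iz = i / ny;
  }
  double x(int ix) const { return ox + h * ix; }
  double y(int iy) const { return oy + h * iy; }
  double z(int iz) const { return oz + h * iz; }
};

// 26-connected neighbourhood offsets and step lengths (units of spacing).
struct Neigh {
  int dx[26], dy[26], dz[26];
  double len[26];
  Neigh() {
    int k = 0;
    for (int a = -1; a <= 1; ++a)
      for (int b = -1; b <= 1; ++b)
        for (int c = -1; c <= 1; ++c) {
          if (a == 0 && b == 0 && c == 0) continue;
          dx[k] = a; dy[k] = b; dz[k] = c;
          len[k] = std::sqrt(double(a * a + b * b + c * c));
          ++k;
        }
  }
};
const Neigh NB;

// Cell list over atoms for exact nearest-surface queries.
struct CellList {
  double cs, ox, oy, oz;
  int ncx, ncy, ncz;
  std::vector<int> start;   // CSR offsets, size ncells+1
  std::vector<int> items;   // atom indices
  double max_vdw;

  CellList(const NumericMatrix &coords, const NumericVector &vdw, double cell_size)
      : cs(cell_size) {
    int na = coords.nrow();
    double xmin = INF, ymin = INF, zmin = INF, xmax = -INF, ymax = -INF, zmax = -INF;
    max_vdw = 0.0;
    for (int a = 0; a < na; ++a) {
      xmin = std::min(xmin, coords(a, 0)); xmax = std::max(xmax, coords(a, 0));
      ymin = std::min(ymin, coords(a, 1)); ymax = std::max(ymax, coords(a, 1));
      zmin = std::min(zmin, coords(a, 2)); zmax = std::max(zmax, coords(a, 2));
      max_vdw = std::max(max_vdw, vdw[a]);
    }
    ox = xmin; oy = ymin; oz = zmin;
    ncx = std::max(1, (int)std::floor((xmax - xmin) / cs) + 1);
    ncy = std::max(1, (int)std::floor((ymax - ymin) / cs) + 1);
    ncz = std::max(1, (int)std::floor((zmax - zmin) / cs) + 1);
    int nc = ncx * ncy * ncz;
    std::vector<int> cell_of(na), count(nc, 0);
    for (int a = 0; a < na; ++a) {
      int cx = std::min(ncx - 1, std::max(0, (int)std::floor((coords(a, 0) - ox) / cs)));
      int cy = std::min(ncy - 1, std::max(0, (int)std::floor((coords(a, 1) - oy) / cs)));
      int cz = std::min(ncz - 1, std::max(0, (int)std::floor((coords(a, 2) - oz) / cs)));
      cell_of[a] = cx + ncx * (cy + ncy * cz);
      count[cell_of[a]]++;
    }
    start.assign(nc + 1, 0);
    for (int c = 0; c < nc; ++c) start[c + 1] = start[c] + count[c];
    items.resize(na);
    std::vector<int> fill(start.begin(), start.end() - 1);
    for (int a = 0; a < na; ++a) items[fill[cell_of[a]]++] = a;
  }

  // squared distance from point p to the box of cell (cx, cy, cz)
  double box_dist2(double px, double py, double pz, int cx, int cy, int cz) const {
    double d = 0.0, lo, hi, t;
    lo = ox + cs * cx; hi = lo + cs;
    t = (px < lo) ? lo - px : (px > hi ? px - hi : 0.0); d += t * t;
    lo = oy + cs * cy; hi = lo + cs;
    t = (py < lo) ? lo - py : (py > hi ? py - hi : 0.0); d += t * t;
    lo = oz + cs * cz; hi = lo + cs;
    t = (pz < lo) ? lo - pz : (pz > hi ? pz - hi : 0.0); d += t * t;
    return d;
  }

  // exact min over atoms of (|p - atom| - vdw), via expanding ring search
  double free_radius(double px, double py, double pz,
                     const NumericMatrix &coords, const NumericVector &vdw) const {
    int vcx = (int)std::floor((px - ox) / cs);
    int vcy = (int)std::floor((py - oy) / cs);
    int vcz = (int)std::floor((pz - oz) / cs);
    int kmax = 0;
    kmax = std::max(kmax, std::max(vcx, ncx - 1 - vcx));
    kmax = std::max(kmax, std::max(vcy, ncy - 1 - vcy));
    kmax = std::max(kmax, std::max(vcz, ncz - 1 - vcz));
    double best = INF;
    for (int k = 0; k <= kmax; ++k) {
      if (best < INF && (k - 1) * cs - max_vdw > best) break;
      for (int cz = vcz - k; cz <= vcz + k; ++cz) {
        if (cz < 0 || cz >= ncz) continue;
        for (int cy = vcy - k; cy <= vcy + k; ++cy) {
          if (cy < 0 || cy >= ncy) continue;
          for (int cx = vcx - k; cx <= vcx + k; ++cx) {
            if (cx < 0 || cx >= ncx) continue;
            // only the ring surface (cells at Chebyshev distance exactly k)
            if (std::max(std::abs(cx - vcx), std::max(std::abs(cy - vcy), std::abs(cz - vcz))) != k)
              continue;
            double bd2 = box_dist2(px, py, pz, cx, cy, cz);
            double bd = std::sqrt(bd2);
            if (best < INF && bd - max_vdw > best) continue;
            int c = cx + ncx * (cy + ncy * cz);
            for (int s = start[c]; s < start[c + 1]; ++s) {
              int a = items[s];
              double dx = px - coords(a, 0), dy = py - coords(a, 1), dz = pz - coords(a, 2);
              double d = std::sqrt(dx * dx + dy * dy + dz * dz) - vdw[a];
              if (d < best) best = d;
            }
          }
        }
      }
    }
    return best;
  }
};

void field_impl(const NumericMatrix &coords, const NumericVector &vdw,
                const Grid &g, std::vector<double> &field) {
  CellList cl(coords, vdw, 2.5);
  field.assign(g.n(), 0.0);
  for (int iz = 0; iz < g.nz; ++iz)
    for (int iy = 0; iy < g.ny; ++iy)
      for (int ix = 0; ix < g.nx; ++ix)
        field[g.idx(ix, iy, iz)] = cl.free_radius(g.x(ix), g.y(iy), g.z(iz), coords, vdw);
}

// flood fill of {field >= shell_radius} from the grid boundary, 26-connected
void bulk_impl(const std::vector<double> &field, const Grid &g,
               double shell_radius, std::vector<char> &bulk) {
  bulk.assign(g.n(), 0);
  std::queue<int> q;
  auto seed = [&](int ix, int iy, int iz) {
    int i = g.idx(ix, iy, iz);
    if (!bulk[i] && field[i] >= shell_radius) { bulk[i] = 1; q.push(i); }
  };
  for (int iy = 0; iy < g.ny; ++iy)
    for (int ix = 0; ix < g.nx; ++ix) { seed(ix, iy, 0); seed(ix, iy, g.nz - 1); }
  for (int iz = 0; iz < g.nz; ++iz)
    for (int ix = 0; ix < g.nx; ++ix) { seed(ix, 0, iz); seed(ix, g.ny - 1, iz); }
  for (int iz = 0; iz < g.nz; ++iz)
    for (int iy = 0; iy < g.ny; ++iy) { seed(0, iy, iz); seed(g.nx - 1, iy, iz); }
  while (!q.empty()) {
    int u = q.front(); q.pop();
    int ux, uy, uz; g.decode(u, ux, uy, uz);
    for (int k = 0; k < 26; ++k) {
      int vx = ux + NB.dx[k], vy = uy + NB.dy[k], vz = uz + NB.dz[k];
      if (vx < 0 || vx >= g.nx || vy < 0 || vy >= g.ny || vz < 0 || vz >= g.nz) continue;
      int v = g.idx(vx, vy, vz);
      if (!bulk[v] && field[v] >= shell_radius) { bulk[v] = 1; q.push(v); }
    }
  }
}

// Dijkstra over allowed voxels; edge weight = step_length * r(target)^(-cost_exponent).
// Ties in distance are broken toward the smaller linear index, so the search
// is fully deterministic for a given field.
void dijkstra_impl(const std::vector<double> &field, const Grid &g,
                   const std::vector<char> &allowed, int start,
                   double cost_exponent,
                   std::vector<double> &dist, std::vector<int> &pred) {
  int n = g.n();
  dist.assign(n, INF);
  pred.assign(n, -1);
  typedef std::pair<double, int> Node;
  std::priority_queue<Node, std::vector<Node>, std::greater<Node> > pq;
  dist[start] = 0.0;
  pq.push(Node(0.0, start));
  std::vector<char> done(n, 0);
  while (!pq.empty()) {
    Node top = pq.top(); pq.pop();
    int u = top.second;
    if (done[u]) continue;
    done[u] = 1;
    int ux, uy, uz; g.decode(u, ux, uy, uz);
    for (int k = 0; k < 26; ++k) {
      int vx = ux + NB.dx[k], vy = uy + NB.dy[k], vz = uz + NB.dz[k];
      if (vx < 0 || vx >= g.nx || vy < 0 || vy >= g.ny || vz < 0 || vz >= g.nz) continue;
      int v = g.idx(vx, vy, vz);
      if (!allowed[v] || done[v]) continue;
      double w = g.h * NB.len[k] * std::pow(field[v], -cost_exponent);
      double nd = dist[u] + w;
      if (nd < dist[v]) {
        dist[v] = nd;
        pred[v] = u;
        pq.push(Node(nd, v));
      }
    }
  }
}

Grid make_grid(const NumericVector &origin, const IntegerVector &dims, double spacing) {
  Grid g;
  g.ox = origin[0]; g.oy = origin[1]; g.oz = origin[2];
  g.nx = dims[0]; g.ny = dims[1]; g.nz = dims[2];
  g.h = spacing;
  return g;
}

} // namespace

// [[Rcpp::export]]
NumericVector cpp_free_radius_field(NumericMatrix coords, NumericVector vdw,
                                    NumericVector origin, IntegerVector dims,
                                    double spacing) {
  Grid g = make_grid(origin, dims, spacing);
  std::vector<double> field;
  field_impl(coords, vdw, g, field);
  NumericVector out(field.begin(), field.end());
  out.attr("dim") = dims;
  return out;
}

// [[Rcpp::export]]
LogicalVector cpp_flood_bulk(NumericVector field, IntegerVector dims,
                             double shell_radius) {
  Grid g; g.nx = dims[0]; g.ny = dims[1]; g.nz = dims[2];
  g.ox = g.oy = g.oz = 0.0; g.h = 1.0;
  std::vector<double> f(field.begin(), field.end());
  std::vector<char> bulk;
  bulk_impl(f, g, shell_radius, bulk);
  LogicalVector out(bulk.size());
  for (size_t i = 0; i < bulk.size(); ++i) out[i] = bulk[i] != 0;
  out.attr("dim") = dims;
  return out;
}

// [[Rcpp::export]]
List cpp_grid_dijkstra(NumericVector field, IntegerVector dims, double spacing,
                       int start0, double probe_radius, double cost_exponent,
                       LogicalVector allowed) {
  Grid g; g.nx = dims[0]; g.ny = dims[1]; g.nz = dims[2];
  g.ox = g.oy = g.oz = 0.0; g.h = spacing;
  std::vector<double> f(field.begin(), field.end());
  std::vector<char> ok(g.n(), 0);
  for (int i = 0; i < g.n(); ++i)
    ok[i] = (allowed[i] && f[i] >= probe_radius) ? 1 : 0;
  if (start0 < 0 || start0 >= g.n() || !ok[start0])
    stop("start voxel is not traversable");
  std::vector<double> dist; std::vector<int> pred;
  dijkstra_impl(f, g, ok, start0, cost_exponent, dist, pred);
  NumericVector d(dist.begin(), dist.end());
  IntegerVector p(pred.begin(), pred.end());
  d.attr("dim") = dims;
  return List::create(_["dist"] = d, _["pred"] = p + 1); // 1-based, 0 = none
}

List detect_core(const std::vector<double> &field, const Grid &g,
                 NumericVector start, double probe_radius,
                 double shell_radius, double shell_depth,
                 double cost_exponent, double duplicate_threshold,
                 double snap_radius);

// [[Rcpp::export]]
List cpp_detect_frame(NumericMatrix coords, NumericVector vdw,
                      NumericVector origin, IntegerVector dims, double spacing,
                      NumericVector start, double probe_radius,
                      double shell_radius, double shell_depth,
                      double cost_exponent, double duplicate_threshold,
                      double snap_radius) {
  Grid g = make_grid(origin, dims, spacing);
  std::vector<double> field;
  field_impl(coords, vdw, g, field);
  return detect_core(field, g, start, probe_radius, shell_radius, shell_depth,
                     cost_exponent, duplicate_threshold, snap_radius);
}

// Fast path for gated ensembles: only the gate atoms move between frames, so
// the static-wall field is computed once and the per-frame field is its
// pointwise minimum with the exact brute-force field of the few gate atoms.
// [[Rcpp::export]]
List cpp_detect_frame_cached(NumericVector static_field,
                             NumericMatrix gate_coords, NumericVector gate_vdw,
                             NumericVector origin, IntegerVector dims,
                             double spacing, NumericVector start,
                             double probe_radius, double shell_radius,
                             double shell_depth, double cost_exponent,
                             double duplicate_threshold, double snap_radius) {
  Grid g = make_grid(origin, dims, spacing);
  std::vector<double> field(static_field.begin(), static_field.end());
  int ng = gate_coords.nrow();
  std::vector<double> gx(ng), gy(ng), gz(ng), gr(ng);
  for (int a = 0; a < ng; ++a) {
    gx[a] = gate_coords(a, 0); gy[a] = gate_coords(a, 1);
    gz[a] = gate_coords(a, 2); gr[a] = gate_vdw[a];
  }
  int i = 0;
  for (int iz = 0; iz < g.nz; ++iz) {
    double pz = g.z(iz);
    for (int iy = 0; iy < g.ny; ++iy) {
      double py = g.y(iy);
      for (int ix = 0; ix < g.nx; ++ix, ++i) {
        double px = g.x(ix);
        double best = field[i];
        for (int a = 0; a < ng; ++a) {
          double dx = px - gx[a], dy = py - gy[a], dz = pz - gz[a];
          double d = std::sqrt(dx * dx + dy * dy + dz * dz) - gr[a];
          if (d < best) best = d;
        }
        field[i] = best;
      }
    }
  }
  return detect_core(field, g, start, probe_radius, shell_radius, shell_depth,
                     cost_exponent, duplicate_threshold, snap_radius);
}

List detect_core(const std::vector<double> &field, const Grid &g,
                 NumericVector start, double probe_radius,
                 double shell_radius, double shell_depth,
                 double cost_exponent, double duplicate_threshold,
                 double snap_radius) {
  std::vector<char> bulk;
  bulk_impl(field, g, shell_radius, bulk);

  int n = g.n();
  std::vector<char> allowed(n, 0);
  for (int i = 0; i < n; ++i)
    allowed[i] = (!bulk[i] && field[i] >= probe_radius) ? 1 : 0;

  // start voxel: nearest voxel center, snapped if below probe radius
  int sx = std::min(g.nx - 1, std::max(0, (int)std::lround((start[0] - g.ox) / g.h)));
  int sy = std::min(g.ny - 1, std::max(0, (int)std::lround((start[1] - g.oy) / g.h)));
  int sz = std::min(g.nz - 1, std::max(0, (int)std::lround((start[2] - g.oz) / g.h)));
  int sv = g.idx(sx, sy, sz);
  if (bulk[sv]) stop("start point not buried");
  bool snapped = false;
  if (!allowed[sv]) {
    int r = (int)std::ceil(snap_radius / g.h);
    double best = INF; int bestv = -1;
    for (int iz = std::max(0, sz - r); iz <= std::min(g.nz - 1, sz + r); ++iz)
      for (int iy = std::max(0, sy - r); iy <= std::min(g.ny - 1, sy + r); ++iy)
        for (int ix = std::max(0, sx - r); ix <= std::min(g.nx - 1, sx + r); ++ix) {
          int v = g.idx(ix, iy, iz);
          if (!allowed[v]) continue;
          double dx = g.x(ix) - start[0], dy = g.y(iy) - start[1], dz = g.z(iz) - start[2];
          double d = std::sqrt(dx * dx + dy * dy + dz * dz);
          if (d <= snap_radius && (d < best || (d == best && v < bestv))) {
            best = d; bestv = v;
          }
        }
    if (bestv < 0)
      stop("no traversable voxel with free radius >= probe radius within %.1f A of the start point",
           snap_radius);
    sv = bestv;
    snapped = true;
  }

  std::vector<double> dist; std::vector<int> pred;
  dijkstra_impl(field, g, allowed, sv, cost_exponent, dist, pred);

  // candidate exits: reached interior voxels with a bulk 26-neighbour
  std::vector<int> cand;
  for (int i = 0; i < n; ++i) {
    if (!allowed[i] || dist[i] == INF) continue;
    int ix, iy, iz; g.decode(i, ix, iy, iz);
    bool contact = false;
    for (int k = 0; k < 26 && !contact; ++k) {
      int vx = ix + NB.dx[k], vy = iy + NB.dy[k], vz = iz + NB.dz[k];
      if (vx < 0 || vx >= g.nx || vy < 0 || vy >= g.ny || vz < 0 || vz >= g.nz) continue;
      if (bulk[g.idx(vx, vy, vz)]) contact = true;
    }
    if (contact) cand.push_back(i);
  }
  std::sort(cand.begin(), cand.end(), [&](int a, int b) {
    if (dist[a] != dist[b]) return dist[a] < dist[b];
    return a < b;
  });

  // greedy redundancy suppression in ascending cost order: reject a candidate
  // whose exit, or whose path, comes within duplicate_threshold of a kept exit
  std::vector<std::vector<int> > kept_paths;
  std::vector<int> kept_exit;
  double thr2 = duplicate_threshold * duplicate_threshold;
  auto vox_dist2 = [&](int a, int b) {
    int ax, ay, az, bx, by, bz;
    g.decode(a, ax, ay, az); g.decode(b, bx, by, bz);
    double dx = g.h * (ax - bx), dy = g.h * (ay - by), dz = g.h * (az - bz);
    return dx * dx + dy * dy + dz * dz;
  };
  for (size_t c = 0; c < cand.size(); ++c) {
    int e = cand[c];
    bool drop = false;
    for (size_t j = 0; j < kept_exit.size() && !drop; ++j)
      if (vox_dist2(e, kept_exit[j]) < thr2) drop = true;
    if (drop) continue;
    std::vector<int> path;
    for (int v = e; v != -1; v = pred[v]) path.push_back(v);
    std::reverse(path.begin(), path.end()); // start -> exit
    for (size_t p = 0; p < path.size() && !drop; ++p)
      for (size_t j = 0; j < kept_exit.size() && !drop; ++j)
        if (vox_dist2(path[p], kept_exit[j]) < thr2) drop = true;
    if (drop) continue;
    kept_exit.push_back(e);
    kept_paths.push_back(path);
  }

  // build spines, trimming shell_depth of arc length from the bulk end
  List tunnels;
  NumericVector costs;
  for (size_t t = 0; t < kept_paths.size(); ++t) {
    const std::vector<int> &path = kept_paths[t];
    int m = (int)path.size();
    std::vector<double> px(m), py(m), pz(m);
    for (int i = 0; i < m; ++i) {
      int ix, iy, iz; g.decode(path[i], ix, iy, iz);
      px[i] = g.x(ix); py[i] = g.y(iy); pz[i] = g.z(iz);
    }
    double acc = 0.0;
    int j = m - 1;
    while (j > 0) {
      double dx = px[j] - px[j - 1], dy = py[j] - py[j - 1], dz = pz[j] - pz[j - 1];
      double seg = std::sqrt(dx * dx + dy * dy + dz * dz);
      if (acc + seg > shell_depth) break;
      acc += seg;
      --j;
    }
    int keep = j + 1;
    if (keep < 2) continue; // shallower than the shell depth: a surface dimple
    NumericMatrix spine(keep, 4);
    for (int i = 0; i < keep; ++i) {
      spine(i, 0) = px[i]; spine(i, 1) = py[i]; spine(i, 2) = pz[i];
      spine(i, 3) = field[path[i]];
    }
    tunnels.push_back(spine);
    costs.push_back(dist[kept_paths[t].back()]);
  }

  return List::create(_["tunnels"] = tunnels, _["cost"] = costs,
                      _["snapped"] = snapped);
}
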