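// 3-D morphology primitives for calibrated confocal stacks.
// All physical arguments are in micrometres; arrays are x-fastest
// (R array order) with dims = (nx, ny, nz).

#include <Rcpp.h>
#include <queue>
#include <vector>
#include <limits>
#include <cmath>

using namespace Rcpp;

static inline int idx3(int x, int y, int z, int nx, int ny) {
  return x + nx * (y + ny * z);
}

// [[Rcpp::export]]
IntegerVector cpp_label3d(LogicalVector mask, IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int n = nx * ny * nz;
  IntegerVector lab(n, 0);
  int next = 0;
  std::vector<int> stack;
  for (int i = 0; i < n; ++i) {
    if (!mask[i] || lab[i]) continue;
    ++next;
    stack.push_back(i);
    lab[i] = next;
    while (!stack.empty()) {
      int v = stack.back(); stack.pop_back();
      int z = v / (nx * ny), r = v % (nx * ny), y = r / nx, x = r % nx;
      for (int dz = -1; dz <= 1; ++dz)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dx = -1; dx <= 1; ++dx) {
            if (!dx && !dy && !dz) continue;
            int xx = x + dx, yy = y + dy, zz = z + dz;
            if (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny || zz >= nz)
              continue;
            int w = idx3(xx, yy, zz, nx, ny);
            if (mask[w] && !lab[w]) { lab[w] = next; stack.push_back(w); }
          }
    }
  }
  return lab;
}

// 1-D squared distance transform (Felzenszwalb & Huttenlocher) with
// physical sample spacing `h`.
static void dt1d(std::vector<double> &f, std::vector<double> &d,
                 std::vector<int> &v, std::vector<double> &zb, double h) {
  const int n = (int) f.size();
  const double INF = std::numeric_limits<double>::infinity();
  int k = 0;
  v[0] = 0; zb[0] = -INF; zb[1] = INF;
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      double qq = (double) q * h, vv = (double) v[k] * h;
      s = ((f[q] + qq * qq) - (f[v[k]] + vv * vv)) / (2.0 * qq - 2.0 * vv);
      if (s > zb[k]) break;
      --k;
    }
    ++k;
    v[k] = q; zb[k] = s; zb[k + 1] = INF;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    double qq = (double) q * h;
    while (zb[k + 1] < qq) ++k;
    double vv = (double) v[k] * h;
    d[q] = (qq - vv) * (qq - vv) + f[v[k]];
  }
}

// Euclidean distance (um) from every foreground voxel to the nearest
// background voxel centre; 0 on background. Anisotropy respected.
// [[Rcpp::export]]
NumericVector cpp_edt3d(LogicalVector mask, IntegerVector dim,
                        NumericVector voxel_size) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int n = nx * ny * nz;
  const double INF = std::numeric_limits<double>::infinity();
  // large finite sentinel instead of INF: a fully-foreground scan line
  // would otherwise produce NaN parabola intersections in dt1d
  const double BIG = 1e9;
  std::vector<double> g(n);
  for (int i = 0; i < n; ++i) g[i] = mask[i] ? BIG : 0.0;

  int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), d(nmax), zb(nmax + 1);
  std::vector<int> v(nmax);

  // pass along x
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y) {
      for (int x = 0; x < nx; ++x) f[x] = g[idx3(x, y, z, nx, ny)];
      f.resize(nx); d.resize(nx);
      dt1d(f, d, v, zb, voxel_size[0]);
      for (int x = 0; x < nx; ++x) g[idx3(x, y, z, nx, ny)] = d[x];
      f.resize(nmax); d.resize(nmax);
    }
  // pass along y
  for (int z = 0; z < nz; ++z)
    for (int x = 0; x < nx; ++x) {
      for (int y = 0; y < ny; ++y) f[y] = g[idx3(x, y, z, nx, ny)];
      f.resize(ny); d.resize(ny);
      dt1d(f, d, v, zb, voxel_size[1]);
      for (int y = 0; y < ny; ++y) g[idx3(x, y, z, nx, ny)] = d[y];
      f.resize(nmax); d.resize(nmax);
    }
  // pass along z
  for (int y = 0; y < ny; ++y)
    for (int x = 0; x < nx; ++x) {
      for (int z = 0; z < nz; ++z) f[z] = g[idx3(x, y, z, nx, ny)];
      f.resize(nz); d.resize(nz);
      dt1d(f, d, v, zb, voxel_size[2]);
      for (int z = 0; z < nz; ++z) g[idx3(x, y, z, nx, ny)] = d[z];
      f.resize(nmax); d.resize(nmax);
    }
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = std::sqrt(g[i]);
  return out;
}

// Dijkstra over the 26-neighbourhood restricted to `mask`, from the
// given 0-based linear seeds. Edge cost = physical step length times
// the mean of the two node weights (weight 1 everywhere = plain
// geodesic distance). Returns dist (um-weighted) and 0-based
// predecessor (-1 at seeds/unreached).
// [[Rcpp::export]]
List cpp_geodesic(LogicalVector mask, IntegerVector dim,
                  NumericVector voxel_size, IntegerVector seeds,
                  NumericVector node_weight) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int n = nx * ny * nz;
  const double INF = std::numeric_limits<double>::infinity();
  const bool wtd = node_weight.size() == n;
  NumericVector dist(n, INF);
  IntegerVector pred(n, -1);
  typedef std::pair<double, int> P;
  std::priority_queue<P, std::vector<P>, std::greater<P> > pq;
  for (int s = 0; s < seeds.size(); ++s) {
    int v = seeds[s];
    if (v < 0 || v >= n || !mask[v]) continue;
    dist[v] = 0.0;
    pq.push(P(0.0, v));
  }
  double step[3][3][3];
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx)
        step[dx + 1][dy + 1][dz + 1] = std::sqrt(
          dx * dx * voxel_size[0] * voxel_size[0] +
          dy * dy * voxel_size[1] * voxel_size[1] +
          dz * dz * voxel_size[2] * voxel_size[2]);
  while (!pq.empty()) {
    P top = pq.top(); pq.pop();
    int u = top.second;
    if (top.first > dist[u]) continue;
    int z = u / (nx * ny), r = u % (nx * ny), y = r / nx, x = r % nx;
    for (int dz = -1; dz <= 1; ++dz)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dx = -1; dx <= 1; ++dx) {
          if (!dx && !dy && !dz) continue;
          int xx = x + dx, yy = y + dy, zz = z + dz;
          if (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny || zz >= nz)
            continue;
          int w = idx3(xx, yy, zz, nx, ny);
          if (!mask[w]) continue;
          double cost = step[dx + 1][dy + 1][dz + 1];
          if (wtd) cost *= 0.5 * (node_weight[u] + node_weight[w]);
          double nd = dist[u] + cost;
          if (nd < dist[w]) {
            dist[w] = nd;
            pred[w] = u;
            pq.push(P(nd, w));
          }
        }
  }
  return List::create(_["dist"] = dist, _["pred"] = pred);
}

// Separable Gaussian blur, sigma given in voxels per axis.
// [[Rcpp::export]]
NumericVector cpp_gauss3d(NumericVector img, IntegerVector dim,
                          NumericVector sigma_vox) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int n = nx * ny * nz;
  std::vector<double> a(img.begin(), img.end()), b(n);
  const int dims[3] = {nx, ny, nz};
  for (int ax = 0; ax < 3; ++ax) {
    double s = sigma_vox[ax];
    if (s <= 0) continue;
    int radius = (int) std::ceil(3.0 * s);
    std::vector<double> k(2 * radius + 1);
    double ksum = 0.0;
    for (int i = -radius; i <= radius; ++i) {
      k[i + radius] = std::exp(-0.5 * i * i / (s * s));
      ksum += k[i + radius];
    }
    for (size_t i = 0; i < k.size(); ++i) k[i] /= ksum;
    int strides[3] = {1, nx, nx * ny};
    int stride = strides[ax], len = dims[ax];
    for (int i = 0; i < n; ++i) {
      int z = i / (nx * ny), r = i % (nx * ny), y = r / nx, x = r % nx;
      int pos3[3] = {x, y, z};
      int pos = pos3[ax];
      double acc = 0.0;
      for (int j = -radius; j <= radius; ++j) {
        int p = pos + j;
        if (p < 0) p = 0;            // replicate edges
        if (p >= len) p = len - 1;
        acc += k[j + radius] * a[i + (p - pos) * stride];
      }
      b[i] = acc;
    }
    std::swap(a, b);
  }
  return NumericVector(a.begin(), a.end());
}

static inline double clampd(double v, double lo, double hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

// Render a union of capsules (cylinders with spherical caps) into an
// intensity image: voxel value = max over covering capsules of the
// capsule's value. seg has one row per capsule:
// x1 y1 z1 x2 y2 z2 radius value (physical um; sphere when p1 == p2).
// [[Rcpp::export]]
NumericVector cpp_render_capsules(IntegerVector dim, NumericVector voxel_size,
                                  NumericVector origin, NumericMatrix seg) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  NumericVector img(nx * ny * nz, 0.0);
  for (int s = 0; s < seg.nrow(); ++s) {
    double p1[3] = {seg(s, 0), seg(s, 1), seg(s, 2)};
    double p2[3] = {seg(s, 3), seg(s, 4), seg(s, 5)};
    double rad = seg(s, 6), val = seg(s, 7);
    double lo[3], hi[3];
    int ilo[3], ihi[3];
    for (int a = 0; a < 3; ++a) {
      lo[a] = std::min(p1[a], p2[a]) - rad;
      hi[a] = std::max(p1[a], p2[a]) + rad;
      // voxel centre a-coordinate = origin + (i + 0.5) * voxel_size
      ilo[a] = (int) std::floor((lo[a] - origin[a]) / voxel_size[a] - 0.5);
      ihi[a] = (int) std::ceil((hi[a] - origin[a]) / voxel_size[a] - 0.5);
    }
    int dims[3] = {nx, ny, nz};
    for (int a = 0; a < 3; ++a) {
      if (ilo[a] < 0) ilo[a] = 0;
      if (ihi[a] > dims[a] - 1) ihi[a] = dims[a] - 1;
    }
    double d[3] = {p2[0] - p1[0], p2[1] - p1[1], p2[2] - p1[2]};
    double len2 = d[0] * d[0] + d[1] * d[1] + d[2] * d[2];
    for (int z = ilo[2]; z <= ihi[2]; ++z) {
      double cz = origin[2] + (z + 0.5) * voxel_size[2];
      for (int y = ilo[1]; y <= ihi[1]; ++y) {
        double cy = origin[1] + (y + 0.5) * voxel_size[1];
        for (int x = ilo[0]; x <= ihi[0]; ++x) {
          double cx = origin[0] + (x + 0.5) * voxel_size[0];
          double t = 0.0;
          if (len2 > 0) {
            t = ((cx - p1[0]) * d[0] + (cy - p1[1]) * d[1] +
                 (cz - p1[2]) * d[2]) / len2;
            t = clampd(t, 0.0, 1.0);
          }
          double qx = p1[0] + t * d[0] - cx;
          double qy = p1[1] + t * d[1] - cy;
          double qz = p1[2] + t * d[2] - cz;
          double dd = qx * qx + qy * qy + qz * qz;
          if (dd <= rad * rad) {
            int i = idx3(x, y, z, nx, ny);
            if (val > img[i]) img[i] = val;
          }
        }
      }
    }
  }
  return img;
}

// Additively render Gaussian blobs (puncta). centres: n x 3 physical um;
// sigma per axis in um; one amplitude per blob.
// [[Rcpp::export]]
NumericVector cpp_render_blobs(IntegerVector dim, NumericVector voxel_size,
                               NumericVector origin, NumericMatrix centres,
                               NumericVector sigma, NumericVector amplitude) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  NumericVector img(nx * ny * nz, 0.0);
  int dims[3] = {nx, ny, nz};
  for (int s = 0; s < centres.nrow(); ++s) {
    double c[3] = {centres(s, 0), centres(s, 1), centres(s, 2)};
    double amp = amplitude[s];
    int ilo[3], ihi[3];
    for (int a = 0; a < 3; ++a) {
      ilo[a] = (int) std::floor((c[a] - 3.5 * sigma[a] - origin[a]) /
                                voxel_size[a] - 0.5);
      ihi[a] = (int) std::ceil((c[a] + 3.5 * sigma[a] - origin[a]) /
                               voxel_size[a] - 0.5);
      if (ilo[a] < 0) ilo[a] = 0;
      if (ihi[a] > dims[a] - 1) ihi[a] = dims[a] - 1;
    }
    for (int z = ilo[2]; z <= ihi[2]; ++z) {
      double dz = origin[2] + (z + 0.5) * voxel_size[2] - c[2];
      for (int y = ilo[1]; y <= ihi[1]; ++y) {
        double dy = origin[1] + (y + 0.5) * voxel_size[1] - c[1];
        for (int x = ilo[0]; x <= ihi[0]; ++x) {
          double dx = origin[0] + (x + 0.5) * voxel_size[0] - c[0];
          double e = dx * dx / (2 * sigma[0] * sigma[0]) +
                     dy * dy / (2 * sigma[1] * sigma[1]) +
                     dz * dz / (2 * sigma[2] * sigma[2]);
          if (e < 12.0)
            img[idx3(x, y, z, nx, ny)] += amp * std::exp(-e);
        }
      }
    }
  }
  return img;
}

// Minimum Euclidean distance from arbitrary physical points to a
// polyline (treated as a chain of segments). points: n x 3; path: m x 3.
// [[Rcpp::export]]
NumericVector cpp_dist_points_to_polyline(NumericMatrix points,
                                          NumericMatrix path) {
  const int n = points.nrow(), m = path.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double px = points(i, 0), py = points(i, 1), pz = points(i, 2);
    double best = std::numeric_limits<double>::infinity();
    if (m == 1) {
      double dx = px - path(0, 0), dy = py - path(0, 1), dz = pz - path(0, 2);
      best = dx * dx + dy * dy + dz * dz;
    }
    for (int j = 0; j + 1 < m; ++j) {
      double ax = path(j, 0), ay = path(j, 1), az = path(j, 2);
      double dx = path(j + 1, 0) - ax, dy = path(j + 1, 1) - ay,
             dz = path(j + 1, 2) - az;
      double len2 = dx * dx + dy * dy + dz * dz;
      double t = 0.0;
      if (len2 > 0)
        t = clampd(((px - ax) * dx + (py - ay) * dy + (pz - az) * dz) / len2,
                   0.0, 1.0);
      double qx = ax + t * dx - px, qy = ay + t * dy - py,
             qz = az + t * dz - pz;
      double dd = qx * qx + qy * qy + qz * qz;
      if (dd < best) best = dd;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}

// Arc-length position on the polyline of the projection of each point
// (used to anchor spines on a parent path).
// [[Rcpp::export]]
NumericVector cpp_project_onto_polyline(NumericMatrix points,
                                        NumericMatrix path) {
  const int n = points.nrow(), m = path.nrow();
  std::vector<double> cum(m, 0.0);
  for (int j = 1; j < m; ++j) {
    double dx = path(j, 0) - path(j - 1, 0), dy = path(j, 1) - path(j - 1, 1),
           dz = path(j, 2) - path(j - 1, 2);
    cum[j] = cum[j - 1] + std::sqrt(dx * dx + dy * dy + dz * dz);
  }
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double px = points(i, 0), py = points(i, 1), pz = points(i, 2);
    double best = std::numeric_limits<double>::infinity(), bests = 0.0;
    for (int j = 0; j + 1 < m; ++j) {
      double ax = path(j, 0), ay = path(j, 1), az = path(j, 2);
      double dx = path(j + 1, 0) - ax, dy = path(j + 1, 1) - ay,
             dz = path(j + 1, 2) - az;
      double len2 = dx * dx + dy * dy + dz * dz;
      double t = 0.0;
      if (len2 > 0)
        t = clampd(((px - ax) * dx + (py - ay) * dy + (pz - az) * dz) / len2,
                   0.0, 1.0);
      double qx = ax + t * dx - px, qy = ay + t * dy - py,
             qz = az + t * dz - pz;
      double dd = qx * qx + qy * qy + qz * qz;
      if (dd < best) {
        best = dd;
        bests = cum[j] + t * std::sqrt(len2);
      }
    }
    out[i] = bests;
  }
  return out;
}

// Minimum distance from each point to any TRUE voxel centre of a mask.
// Returns +Inf where the mask is empty.
// [[Rcpp::export]]
NumericVector cpp_dist_points_to_mask(NumericMatrix points, LogicalVector mask,
                                      IntegerVector dim,
                                      NumericVector voxel_size,
                                      NumericVector origin) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  std::vector<double> mx, my, mz;
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x)
        if (mask[idx3(x, y, z, nx, ny)]) {
          mx.push_back(origin[0] + (x + 0.5) * voxel_size[0]);
          my.push_back(origin[1] + (y + 0.5) * voxel_size[1]);
          mz.push_back(origin[2] + (z + 0.5) * voxel_size[2]);
        }
  const int n = points.nrow(), m = (int) mx.size();
  NumericVector out(n, R_PosInf);
  for (int i = 0; i < n; ++i) {
    double px = points(i, 0), py = points(i, 1), pz = points(i, 2);
    double best = std::numeric_limits<double>::infinity();
    for (int j = 0; j < m; ++j) {
      double dx = px - mx[j], dy = py - my[j], dz = pz - mz[j];
      double dd = dx * dx + dy * dy + dz * dz;
      if (dd < best) best = dd;
    }
    if (m > 0) out[i] = std::sqrt(best);
  }
  return out;
}
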