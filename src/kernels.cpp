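// Low-level voxel kernels. All voxel indices are 0-based; linear index for
// (i,j,k) in a column-major array of dim (n1,n2,n3) is i + j*n1 + k*n1*n2,
// matching R's array layout.
#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
using namespace Rcpp;

static inline R_xlen_t lin(int i, int j, int k, int n1, int n2) {
  return (R_xlen_t)i + (R_xlen_t)j * n1 + (R_xlen_t)k * n1 * (R_xlen_t)n2;
}

// Trilinear (or nearest-neighbour) interpolation at continuous 0-based index
// coordinates. Points outside the grid return `fill`.
// [[Rcpp::export]]
NumericVector cpp_interp3(NumericVector vox, IntegerVector dim,
                          NumericMatrix idx, double fill, bool nearest) {
  const int n1 = dim[0], n2 = dim[1], n3 = dim[2];
  const R_xlen_t n = idx.nrow();
  NumericVector out(n);
  for (R_xlen_t p = 0; p < n; ++p) {
    double x = idx(p, 0), y = idx(p, 1), z = idx(p, 2);
    if (nearest) {
      int i = (int)std::lround(x), j = (int)std::lround(y), k = (int)std::lround(z);
      if (i < 0 || j < 0 || k < 0 || i >= n1 || j >= n2 || k >= n3) {
        out[p] = fill;
      } else {
        out[p] = vox[lin(i, j, k, n1, n2)];
      }
      continue;
    }
    if (x < 0 || y < 0 || z < 0 || x > n1 - 1 || y > n2 - 1 || z > n3 - 1) {
      out[p] = fill;
      continue;
    }
    int i0 = (int)std::floor(x), j0 = (int)std::floor(y), k0 = (int)std::floor(z);
    if (i0 == n1 - 1) i0--;
    if (j0 == n2 - 1) j0--;
    if (k0 == n3 - 1) k0--;
    if (n1 == 1) i0 = 0;
    if (n2 == 1) j0 = 0;
    if (n3 == 1) k0 = 0;
    double fx = x - i0, fy = y - j0, fz = z - k0;
    int i1 = std::min(i0 + 1, n1 - 1), j1 = std::min(j0 + 1, n2 - 1),
        k1 = std::min(k0 + 1, n3 - 1);
    double c000 = vox[lin(i0, j0, k0, n1, n2)], c100 = vox[lin(i1, j0, k0, n1, n2)];
    double c010 = vox[lin(i0, j1, k0, n1, n2)], c110 = vox[lin(i1, j1, k0, n1, n2)];
    double c001 = vox[lin(i0, j0, k1, n1, n2)], c101 = vox[lin(i1, j0, k1, n1, n2)];
    double c011 = vox[lin(i0, j1, k1, n1, n2)], c111 = vox[lin(i1, j1, k1, n1, n2)];
    double c00 = c000 * (1 - fx) + c100 * fx;
    double c10 = c010 * (1 - fx) + c110 * fx;
    double c01 = c001 * (1 - fx) + c101 * fx;
    double c11 = c011 * (1 - fx) + c111 * fx;
    double c0 = c00 * (1 - fy) + c10 * fy;
    double c1 = c01 * (1 - fy) + c11 * fy;
    out[p] = c0 * (1 - fz) + c1 * fz;
  }
  return out;
}

// 26-connected flood fill restricted to `allowed`, from 0-based linear seeds.
// [[Rcpp::export]]
LogicalVector cpp_region_grow(IntegerVector dim, LogicalVector allowed,
                              IntegerVector seeds) {
  const int n1 = dim[0], n2 = dim[1], n3 = dim[2];
  LogicalVector visited(allowed.size(), false);
  std::queue<R_xlen_t> q;
  for (int s = 0; s < seeds.size(); ++s) {
    R_xlen_t v = seeds[s];
    if (v >= 0 && v < allowed.size() && allowed[v] && !visited[v]) {
      visited[v] = true;
      q.push(v);
    }
  }
  while (!q.empty()) {
    R_xlen_t v = q.front();
    q.pop();
    int k = (int)(v / ((R_xlen_t)n1 * n2));
    int rem = (int)(v % ((R_xlen_t)n1 * n2));
    int j = rem / n1, i = rem % n1;
    for (int dk = -1; dk <= 1; ++dk)
      for (int dj = -1; dj <= 1; ++dj)
        for (int di = -1; di <= 1; ++di) {
          if (di == 0 && dj == 0 && dk == 0) continue;
          int ii = i + di, jj = j + dj, kk = k + dk;
          if (ii < 0 || jj < 0 || kk < 0 || ii >= n1 || jj >= n2 || kk >= n3)
            continue;
          R_xlen_t w = lin(ii, jj, kk, n1, n2);
          if (allowed[w] && !visited[w]) {
            visited[w] = true;
            q.push(w);
          }
        }
  }
  return visited;
}

// 26-connected component labelling; 0 = background.
// [[Rcpp::export]]
IntegerVector cpp_label_components(IntegerVector dim, LogicalVector mask) {
  const int n1 = dim[0], n2 = dim[1], n3 = dim[2];
  IntegerVector lab(mask.size(), 0);
  int next = 0;
  std::queue<R_xlen_t> q;
  for (R_xlen_t v0 = 0; v0 < mask.size(); ++v0) {
    if (!mask[v0] || lab[v0]) continue;
    lab[v0] = ++next;
    q.push(v0);
    while (!q.empty()) {
      R_xlen_t v = q.front();
      q.pop();
      int k = (int)(v / ((R_xlen_t)n1 * n2));
      int rem = (int)(v % ((R_xlen_t)n1 * n2));
      int j = rem / n1, i = rem % n1;
      for (int dk = -1; dk <= 1; ++dk)
        for (int dj = -1; dj <= 1; ++dj)
          for (int di = -1; di <= 1; ++di) {
            if (di == 0 && dj == 0 && dk == 0) continue;
            int ii = i + di, jj = j + dj, kk = k + dk;
            if (ii < 0 || jj < 0 || kk < 0 || ii >= n1 || jj >= n2 || kk >= n3)
              continue;
            R_xlen_t w = lin(ii, jj, kk, n1, n2);
            if (mask[w] && !lab[w]) {
              lab[w] = next;
              q.push(w);
            }
          }
    }
  }
  return lab;
}

// Morphological dilation with an ellipsoidal structuring element of physical
// radius `radius_mm` given the voxel spacing (mm).
// [[Rcpp::export]]
LogicalVector cpp_dilate(IntegerVector dim, LogicalVector mask,
                         NumericVector spacing, double radius_mm) {
  const int n1 = dim[0], n2 = dim[1], n3 = dim[2];
  if (radius_mm <= 0) return clone(mask);
  int r1 = (int)std::floor(radius_mm / spacing[0]);
  int r2 = (int)std::floor(radius_mm / spacing[1]);
  int r3 = (int)std::floor(radius_mm / spacing[2]);
  std::vector<std::array<int, 3>> offs;
  for (int dk = -r3; dk <= r3; ++dk)
    for (int dj = -r2; dj <= r2; ++dj)
      for (int di = -r1; di <= r1; ++di) {
        double d2 = di * spacing[0] * di * spacing[0] +
                    dj * spacing[1] * dj * spacing[1] +
                    dk * spacing[2] * dk * spacing[2];
        if (d2 <= radius_mm * radius_mm)
          offs.push_back({di, dj, dk});
      }
  LogicalVector out(mask.size(), false);
  for (R_xlen_t v = 0; v < mask.size(); ++v) {
    if (!mask[v]) continue;
    int k = (int)(v / ((R_xlen_t)n1 * n2));
    int rem = (int)(v % ((R_xlen_t)n1 * n2));
    int j = rem / n1, i = rem % n1;
    for (auto &o : offs) {
      int ii = i + o[0], jj = j + o[1], kk = k + o[2];
      if (ii < 0 || jj < 0 || kk < 0 || ii >= n1 || jj >= n2 || kk >= n3)
        continue;
      out[lin(ii, jj, kk, n1, n2)] = true;
    }
  }
  return out;
}

// Separable Gaussian blur, sigma per axis in voxel units; kernels truncated at
// 3 sigma and renormalised (reflecting nothing: edge handling by
// renormalisation over in-bounds taps).
static void blur_axis(std::vector<double> &a, int n1, int n2, int n3,
                      int axis, double sigma) {
  if (sigma <= 0) return;
  int r = std::max(1, (int)std::ceil(3.0 * sigma));
  std::vector<double> w(2 * r + 1);
  for (int t = -r; t <= r; ++t)
    w[t + r] = std::exp(-0.5 * t * t / (sigma * sigma));
  std::vector<double> b(a.size());
  int dims[3] = {n1, n2, n3};
  for (int k = 0; k < n3; ++k)
    for (int j = 0; j < n2; ++j)
      for (int i = 0; i < n1; ++i) {
        int c[3] = {i, j, k};
        double s = 0, ws = 0;
        for (int t = -r; t <= r; ++t) {
          int cc = c[axis] + t;
          if (cc < 0 || cc >= dims[axis]) continue;
          int p[3] = {i, j, k};
          p[axis] = cc;
          s += w[t + r] * a[lin(p[0], p[1], p[2], n1, n2)];
          ws += w[t + r];
        }
        b[lin(i, j, k, n1, n2)] = s / ws;
      }
  a.swap(b);
}

// [[Rcpp::export]]
NumericVector cpp_blur_sep(NumericVector vox, IntegerVector dim,
                           NumericVector sigma_vox) {
  std::vector<double> a(vox.begin(), vox.end());
  for (int ax = 0; ax < 3; ++ax)
    blur_axis(a, dim[0], dim[1], dim[2], ax, sigma_vox[ax]);
  return NumericVector(a.begin(), a.end());
}

// Joint histogram with linear (partial-volume) spreading across the two
// adjacent bins in each dimension; used by the mutual-information metric.
// [[Rcpp::export]]
NumericMatrix cpp_joint_hist(NumericVector a, NumericVector b, int nbins,
                             double amin, double amax, double bmin, double bmax) {
  NumericMatrix h(nbins, nbins);
  const double asc = (nbins - 1) / (amax - amin);
  const double bsc = (nbins - 1) / (bmax - bmin);
  for (R_xlen_t p = 0; p < a.size(); ++p) {
    double x = (a[p] - amin) * asc, y = (b[p] - bmin) * bsc;
    if (x < 0) x = 0;
    if (x > nbins - 1) x = nbins - 1;
    if (y < 0) y = 0;
    if (y > nbins - 1) y = nbins - 1;
    int i0 = (int)std::floor(x), j0 = (int)std::floor(y);
    if (i0 == nbins - 1) i0--;
    if (j0 == nbins - 1) j0--;
    double fx = x - i0, fy = y - j0;
    h(i0, j0) += (1 - fx) * (1 - fy);
    h(i0 + 1, j0) += fx * (1 - fy);
    h(i0, j0 + 1) += (1 - fx) * fy;
    h(i0 + 1, j0 + 1) += fx * fy;
  }
  return h;
}

// Distance from each point to a polyline (sequence of segments), plus the
// arc-length fraction [0,1] of the closest projection. Points and polyline in
// world mm. An optional coarse bounding check is left to the caller.
// [[Rcpp::export]]
List cpp_dist_polyline(NumericMatrix pts, NumericMatrix poly) {
  const R_xlen_t n = pts.nrow();
  const int m = poly.nrow();
  std::vector<double> cum(m, 0.0);
  for (int s = 1; s < m; ++s) {
    double dx = poly(s, 0) - poly(s - 1, 0), dy = poly(s, 1) - poly(s - 1, 1),
           dz = poly(s, 2) - poly(s - 1, 2);
    cum[s] = cum[s - 1] + std::sqrt(dx * dx + dy * dy + dz * dz);
  }
  double total = cum[m - 1] > 0 ? cum[m - 1] : 1.0;
  NumericVector dist(n), frac(n);
  for (R_xlen_t p = 0; p < n; ++p) {
    double px = pts(p, 0), py = pts(p, 1), pz = pts(p, 2);
    double best = R_PosInf, bestf = 0;
    for (int s = 0; s < m - 1; ++s) {
      double ax = poly(s, 0), ay = poly(s, 1), az = poly(s, 2);
      double ux = poly(s + 1, 0) - ax, uy = poly(s + 1, 1) - ay,
             uz = poly(s + 1, 2) - az;
      double L2 = ux * ux + uy * uy + uz * uz;
      double t = 0;
      if (L2 > 0)
        t = ((px - ax) * ux + (py - ay) * uy + (pz - az) * uz) / L2;
      if (t < 0) t = 0;
      if (t > 1) t = 1;
      double dx = px - (ax + t * ux), dy = py - (ay + t * uy),
             dz = pz - (az + t * uz);
      double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < best) {
        best = d2;
        bestf = (cum[s] + t * (cum[s + 1] - cum[s])) / total;
      }
    }
    dist[p] = std::sqrt(best);
    frac[p] = bestf;
  }
  return List::create(_["dist"] = dist, _["frac"] = frac);
}

// Dijkstra shortest path (edge weight = world distance) between two voxels
// within `allowed`, 26-connectivity. Returns 0-based linear indices of the
// path (src..dst), or empty if unreachable.
// [[Rcpp::export]]
IntegerVector cpp_shortest_path(IntegerVector dim, LogicalVector allowed,
                                int src, int dst, NumericVector spacing) {
  const int n1 = dim[0], n2 = dim[1], n3 = dim[2];
  const R_xlen_t N = allowed.size();
  std::vector<double> d(N, R_PosInf);
  std::vector<R_xlen_t> prev(N, -1);
  typedef std::pair<double, R_xlen_t> Node;
  std::priority_queue<Node, std::vector<Node>, std::greater<Node>> pq;
  if (!allowed[src] || !allowed[dst]) return IntegerVector(0);
  d[src] = 0;
  pq.push({0.0, (R_xlen_t)src});
  while (!pq.empty()) {
    Node t = pq.top();
    pq.pop();
    R_xlen_t v = t.second;
    if (t.first > d[v]) continue;
    if (v == dst) break;
    int k = (int)(v / ((R_xlen_t)n1 * n2));
    int rem = (int)(v % ((R_xlen_t)n1 * n2));
    int j = rem / n1, i = rem % n1;
    for (int dk = -1; dk <= 1; ++dk)
      for (int dj = -1; dj <= 1; ++dj)
        for (int di = -1; di <= 1; ++di) {
          if (di == 0 && dj == 0 && dk == 0) continue;
          int ii = i + di, jj = j + dj, kk = k + dk;
          if (ii < 0 || jj < 0 || kk < 0 || ii >= n1 || jj >= n2 || kk >= n3)
            continue;
          R_xlen_t w = lin(ii, jj, kk, n1, n2);
          if (!allowed[w]) continue;
          double step = std::sqrt(di * spacing[0] * di * spacing[0] +
                                  dj * spacing[1] * dj * spacing[1] +
                                  dk * spacing[2] * dk * spacing[2]);
          if (d[v] + step < d[w]) {
            d[w] = d[v] + step;
            prev[w] = v;
            pq.push({d[w], w});
          }
        }
  }
  if (!std::isfinite(d[dst])) return IntegerVector(0);
  std::vector<int> path;
  for (R_xlen_t v = dst; v != -1; v = prev[v]) path.push_back((int)v);
  std::reverse(path.begin(), path.end());
  return IntegerVector(path.begin(), path.end());
}

// Block-mean downsampling by integer factor per axis.
// [[Rcpp::export]]
List cpp_downsample(NumericVector vox, IntegerVector dim, IntegerVector f) {
  const int n1 = dim[0], n2 = dim[1], n3 = dim[2];
  const int m1 = n1 / f[0], m2 = n2 / f[1], m3 = n3 / f[2];
  NumericVector out((R_xlen_t)m1 * m2 * m3);
  for (int k = 0; k < m3; ++k)
    for (int j = 0; j < m2; ++j)
      for (int i = 0; i < m1; ++i) {
        double s = 0;
        int cnt = 0;
        for (int dk = 0; dk < f[2]; ++dk)
          for (int dj = 0; dj < f[1]; ++dj)
            for (int di = 0; di < f[0]; ++di) {
              s += vox[lin(i * f[0] + di, j * f[1] + dj, k * f[2] + dk, n1, n2)];
              cnt++;
            }
        out[(R_xlen_t)i + (R_xlen_t)j * m1 + (R_xlen_t)k * m1 * (R_xlen_t)m2] =
            s / cnt;
      }
  return List::create(_["vox"] = out,
                      _["dim"] = IntegerVector::create(m1, m2, m3));
}
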