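#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Distance from each query point to a 3D polyline.
// pts: n x 3 (x,y,z), poly: m x 3 vertex sequence.
// Returns per point: the minimum clamped distance, the arclength of the
// nearest projection, and the signed axial overshoot beyond the first and
// last end-planes (used for flat-capped tube membership tests).
// [[Rcpp::export]]
List cpp_polyline_distance(NumericMatrix pts, NumericMatrix poly) {
  const int n = pts.nrow(), m = poly.nrow();
  if (m < 2) stop("polyline needs >= 2 vertices");
  std::vector<double> seglen(m - 1), cum(m, 0.0);
  std::vector<double> dx(m - 1), dy(m - 1), dz(m - 1);
  for (int j = 0; j < m - 1; ++j) {
    dx[j] = poly(j + 1, 0) - poly(j, 0);
    dy[j] = poly(j + 1, 1) - poly(j, 1);
    dz[j] = poly(j + 1, 2) - poly(j, 2);
    seglen[j] = std::sqrt(dx[j] * dx[j] + dy[j] * dy[j] + dz[j] * dz[j]);
    cum[j + 1] = cum[j] + seglen[j];
  }
  // unit tangents at the two ends for the end-plane tests
  double t0x = dx[0] / seglen[0], t0y = dy[0] / seglen[0], t0z = dz[0] / seglen[0];
  int e = m - 2;
  double t1x = dx[e] / seglen[e], t1y = dy[e] / seglen[e], t1z = dz[e] / seglen[e];

  NumericVector dist(n), s(n), over0(n), over1(n);
  for (int i = 0; i < n; ++i) {
    double px = pts(i, 0), py = pts(i, 1), pz = pts(i, 2);
    double best = R_PosInf, bs = 0.0;
    for (int j = 0; j < m - 1; ++j) {
      if (seglen[j] <= 0) continue;
      double wx = px - poly(j, 0), wy = py - poly(j, 1), wz = pz - poly(j, 2);
      double t = (wx * dx[j] + wy * dy[j] + wz * dz[j]) / (seglen[j] * seglen[j]);
      if (t < 0) t = 0; else if (t > 1) t = 1;
      double qx = wx - t * dx[j], qy = wy - t * dy[j], qz = wz - t * dz[j];
      double d2 = qx * qx + qy * qy + qz * qz;
      if (d2 < best) { best = d2; bs = cum[j] + t * seglen[j]; }
    }
    dist[i] = std::sqrt(best);
    s[i] = bs;
    over0[i] = (px - poly(0, 0)) * t0x + (py - poly(0, 1)) * t0y + (pz - poly(0, 2)) * t0z;
    over1[i] = (px - poly(m - 1, 0)) * t1x + (py - poly(m - 1, 1)) * t1y + (pz - poly(m - 1, 2)) * t1z;
  }
  return List::create(_["dist"] = dist, _["s"] = s,
                      _["over0"] = over0, _["over1"] = over1,
                      _["length"] = cum[m - 1]);
}

static inline int sub2ind(int i, int j, int k, int n1, int n2) {
  return i + n1 * (j + n2 * k);
}

// Connected-component labeling of a 3D logical array (column-major, dims d).
// connectivity: 6 or 26. Labels are 1..K in discovery order, 0 = background.
// [[Rcpp::export]]
IntegerVector cpp_label_components(LogicalVector mask, IntegerVector d, int connectivity) {
  const int n1 = d[0], n2 = d[1], n3 = d[2];
  const int n = n1 * n2 * n3;
  if (mask.size() != n) stop("mask/dim mismatch");
  IntegerVector lab(n, 0);
  int next = 0;
  std::vector<int> stack;
  for (int idx = 0; idx < n; ++idx) {
    if (!mask[idx] || lab[idx]) continue;
    ++next;
    stack.push_back(idx);
    lab[idx] = next;
    while (!stack.empty()) {
      int cur = stack.back(); stack.pop_back();
      int k = cur / (n1 * n2), rem = cur % (n1 * n2);
      int j = rem / n1, i = rem % n1;
      for (int dk = -1; dk <= 1; ++dk)
        for (int dj = -1; dj <= 1; ++dj)
          for (int di = -1; di <= 1; ++di) {
            if (di == 0 && dj == 0 && dk == 0) continue;
            if (connectivity == 6 && std::abs(di) + std::abs(dj) + std::abs(dk) != 1) continue;
            int ii = i + di, jj = j + dj, kk = k + dk;
            if (ii < 0 || jj < 0 || kk < 0 || ii >= n1 || jj >= n2 || kk >= n3) continue;
            int nb = sub2ind(ii, jj, kk, n1, n2);
            if (mask[nb] && !lab[nb]) { lab[nb] = next; stack.push_back(nb); }
          }
    }
  }
  lab.attr("n_components") = next;
  return lab;
}

// Dijkstra over the 26-connected voxel graph restricted to mask voxels.
// vox: physical spacing per array dimension (d1,d2,d3). penalty: per-voxel
// multiplicative weight on incident edge halves (1 = plain Euclidean).
// start: 0-based linear index. Returns geodesic distance (Inf if unreached)
// and parent (-1 at start/unreached).
// [[Rcpp::export]]
List cpp_geodesic(LogicalVector mask, IntegerVector d, NumericVector vox,
                  int start, NumericVector penalty) {
  const int n1 = d[0], n2 = d[1], n3 = d[2];
  const int n = n1 * n2 * n3;
  if (!mask[start]) stop("start voxel not in mask");
  NumericVector dist(n, R_PosInf);
  IntegerVector parent(n, -1);
  typedef std::pair<double, int> Node;
  std::priority_queue<Node, std::vector<Node>, std::greater<Node> > pq;
  dist[start] = 0.0;
  pq.push(Node(0.0, start));
  while (!pq.empty()) {
    Node top = pq.top(); pq.pop();
    double dcur = top.first; int cur = top.second;
    if (dcur > dist[cur]) continue;
    int k = cur / (n1 * n2), rem = cur % (n1 * n2);
    int j = rem / n1, i = rem % n1;
    for (int dk = -1; dk <= 1; ++dk)
      for (int dj = -1; dj <= 1; ++dj)
        for (int di = -1; di <= 1; ++di) {
          if (di == 0 && dj == 0 && dk == 0) continue;
          int ii = i + di, jj = j + dj, kk = k + dk;
          if (ii < 0 || jj < 0 || kk < 0 || ii >= n1 || jj >= n2 || kk >= n3) continue;
          int nb = sub2ind(ii, jj, kk, n1, n2);
          if (!mask[nb]) continue;
          double step = std::sqrt(di * di * vox[0] * vox[0] +
                                  dj * dj * vox[1] * vox[1] +
                                  dk * dk * vox[2] * vox[2]);
          double w = step * 0.5 * (penalty[cur] + penalty[nb]);
          double alt = dcur + w;
          if (alt < dist[nb]) {
            dist[nb] = alt; parent[nb] = cur;
            pq.push(Node(alt, nb));
          }
        }
  }
  return List::create(_["dist"] = dist, _["parent"] = parent);
}

// Minimum Euclidean distance between two point sets (rows are x,y,z).
// [[Rcpp::export]]
double cpp_min_set_distance(NumericMatrix A, NumericMatrix B) {
  double best = R_PosInf;
  for (int i = 0; i < A.nrow(); ++i) {
    double ax = A(i, 0), ay = A(i, 1), az = A(i, 2);
    for (int j = 0; j < B.nrow(); ++j) {
      double dx = ax - B(j, 0), dy = ay - B(j, 1), dz = az - B(j, 2);
      double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < best) best = d2;
    }
  }
  return std::sqrt(best);
}

// For each query point the distance to its nearest reference point.
// [[Rcpp::export]]
NumericVector cpp_nn_distance(NumericMatrix Q, NumericMatrix R) {
  NumericVector out(Q.nrow());
  for (int i = 0; i < Q.nrow(); ++i) {
    double qx = Q(i, 0), qy = Q(i, 1), qz = Q(i, 2);
    double best = R_PosInf;
    for (int j = 0; j < R.nrow(); ++j) {
      double dx = qx - R(j, 0), dy = qy - R(j, 1), dz = qz - R(j, 2);
      double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < best) best = d2;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}

// 1D squared distance transform (Felzenszwalb & Huttenlocher) with uniform
// sample spacing h. f is overwritten with the transformed values.
static void dt1d(std::vector<double>& f, double h) {
  const int n = (int)f.size();
  std::vector<double> d(n);
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0; z[0] = -R_PosInf; z[1] = R_PosInf;
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      double xq = q * h, xv = v[k] * h;
      s = ((f[q] + xq * xq) - (f[v[k]] + xv * xv)) / (2 * xq - 2 * xv);
      if (s <= z[k]) { --k; } else break;
    }
    ++k;
    v[k] = q; z[k] = s; z[k + 1] = R_PosInf;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    double xq = q * h;
    while (z[k + 1] < xq) ++k;
    double xv = v[k] * h;
    d[q] = (xq - xv) * (xq - xv) + f[v[k]];
  }
  f = d;
}

// Euclidean distance transform of a 3D mask: for every voxel, the distance
// (in physical units, anisotropic spacing vox) to the nearest background
// voxel center. Background voxels get 0. Voxels of a mask that fills the
// whole array get a large finite value.
// [[Rcpp::export]]
NumericVector cpp_edt(LogicalVector mask, IntegerVector d, NumericVector vox) {
  const int n1 = d[0], n2 = d[1], n3 = d[2];
  const int n = n1 * n2 * n3;
  const double BIG = 1e12;
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = mask[i] ? BIG : 0.0;
  std::vector<double> buf;
  // axis 1
  buf.resize(n1);
  for (int k = 0; k < n3; ++k)
    for (int j = 0; j < n2; ++j) {
      for (int i = 0; i < n1; ++i) buf[i] = out[sub2ind(i, j, k, n1, n2)];
      dt1d(buf, vox[0]);
      for (int i = 0; i < n1; ++i) out[sub2ind(i, j, k, n1, n2)] = buf[i];
    }
  // axis 2
  buf.resize(n2);
  for (int k = 0; k < n3; ++k)
    for (int i = 0; i < n1; ++i) {
      for (int j = 0; j < n2; ++j) buf[j] = out[sub2ind(i, j, k, n1, n2)];
      dt1d(buf, vox[1]);
      for (int j = 0; j < n2; ++j) out[sub2ind(i, j, k, n1, n2)] = buf[j];
    }
  // axis 3
  buf.resize(n3);
  for (int j = 0; j < n2; ++j)
    for (int i = 0; i < n1; ++i) {
      for (int k = 0; k < n3; ++k) buf[k] = out[sub2ind(i, j, k, n1, n2)];
      dt1d(buf, vox[2]);
      for (int k = 0; k < n3; ++k) out[sub2ind(i, j, k, n1, n2)] = buf[k];
    }
  for (int i = 0; i < n; ++i) out[i] = std::sqrt(out[i]);
  out.attr("dim") = d;
  return out;
}

// 1D convolution of a 3D array along one axis (1, 2 or 3), zero padding.
// kernel must have odd length.
// [[Rcpp::export]]
NumericVector cpp_convolve_axis(NumericVector arr, IntegerVector d, int axis,
                                NumericVector kernel) {
  const int n1 = d[0], n2 = d[1], n3 = d[2];
  const int kl = kernel.size(), h = kl / 2;
  NumericVector out(arr.size());
  for (int k = 0; k < n3; ++k)
    for (int j = 0; j < n2; ++j)
      for (int i = 0; i < n1; ++i) {
        double acc = 0.0;
        for (int t = -h; t <= h; ++t) {
          int ii = i, jj = j, kk = k;
          if (axis == 1) ii += t; else if (axis == 2) jj += t; else kk += t;
          if (ii < 0 || jj < 0 || kk < 0 || ii >= n1 || jj >= n2 || kk >= n3) continue;
          acc += kernel[t + h] * arr[sub2ind(ii, jj, kk, n1, n2)];
        }
        out[sub2ind(i, j, k, n1, n2)] = acc;
      }
  out.attr("dim") = d;
  return out;
}
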