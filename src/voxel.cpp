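// Low-level 3D voxel operations shared by the renderer and the quantifiers.
// Arrays are R arrays with dim = c(nz, ny, nx) (column-major, z fastest),
// matching voxel_size = c(z, y, x) in micrometres.
#include <Rcpp.h>
#include <unordered_map>
#include <queue>
#include <vector>
#include <cmath>
using namespace Rcpp;

static inline int reflect(int i, int n) {
  if (n == 1) return 0;
  while (i < 0 || i >= n) {
    if (i < 0) i = -i - 1;
    if (i >= n) i = 2 * n - i - 1;
  }
  return i;
}

// Separable Gaussian blur with reflected boundaries; sigma in voxel units
// per axis (z, y, x). sigma <= 0 skips that axis.
// [[Rcpp::export(name = ".blur3d")]]
NumericVector blur3d(NumericVector arr, IntegerVector dim, NumericVector sigma) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  std::vector<double> buf(arr.begin(), arr.end());
  std::vector<double> out(buf.size());
  const int n[3] = {nz, ny, nx};
  const int stride[3] = {1, nz, nz * ny};

  for (int ax = 0; ax < 3; ++ax) {
    double s = sigma[ax];
    if (s <= 0) continue;
    int half = (int)std::ceil(4.0 * s);
    std::vector<double> k(2 * half + 1);
    double ksum = 0;
    for (int i = -half; i <= half; ++i) {
      k[i + half] = std::exp(-0.5 * (double)i * i / (s * s));
      ksum += k[i + half];
    }
    for (auto &v : k) v /= ksum;

    const int len = n[ax], st = stride[ax];
    // copy each line into a contiguous scratch buffer: the y/x passes are
    // otherwise dominated by strided cache misses
    std::vector<double> line(len + 2 * half);
    const int oa = (ax + 1) % 3, ob = (ax + 2) % 3;
    for (int b = 0; b < n[ob]; ++b) {
      for (int a = 0; a < n[oa]; ++a) {
        size_t base = (size_t)a * stride[oa] + (size_t)b * stride[ob];
        for (int i = 0; i < len; ++i)
          line[half + i] = buf[base + (size_t)i * st];
        for (int j = 0; j < half; ++j) {
          line[j] = line[half + reflect(j - half, len)];
          line[half + len + j] = line[half + reflect(len + j, len)];
        }
        for (int i = 0; i < len; ++i) {
          double acc = 0;
          const double *lp = &line[i];
          for (int j = 0; j <= 2 * half; ++j) acc += k[j] * lp[j];
          out[base + (size_t)i * st] = acc;
        }
      }
    }
    std::swap(buf, out);
  }
  NumericVector res(buf.begin(), buf.end());
  res.attr("dim") = dim;
  return res;
}

// 26-connected component labelling of a logical mask. Returns integer labels
// (0 = background) with the same dim attribute.
// [[Rcpp::export(name = ".label3d")]]
IntegerVector label3d(LogicalVector mask, IntegerVector dim) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  const size_t ntot = (size_t)nz * ny * nx;
  IntegerVector lab(ntot, 0);
  int next = 0;
  std::vector<size_t> stack;
  for (size_t s = 0; s < ntot; ++s) {
    if (!mask[s] || lab[s] != 0) continue;
    ++next;
    stack.push_back(s);
    lab[s] = next;
    while (!stack.empty()) {
      size_t cur = stack.back();
      stack.pop_back();
      int iz = cur % nz, iy = (cur / nz) % ny, ix = cur / ((size_t)nz * ny);
      for (int dz = -1; dz <= 1; ++dz)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dx = -1; dx <= 1; ++dx) {
            if (!dz && !dy && !dx) continue;
            int z = iz + dz, y = iy + dy, x = ix + dx;
            if (z < 0 || z >= nz || y < 0 || y >= ny || x < 0 || x >= nx) continue;
            size_t nb = (size_t)z + (size_t)nz * (y + (size_t)ny * x);
            if (mask[nb] && lab[nb] == 0) {
              lab[nb] = next;
              stack.push_back(nb);
            }
          }
    }
  }
  lab.attr("dim") = dim;
  return lab;
}

// Single-source shortest paths over the voxels of a logical mask, 26-neighbour
// edges weighted by physical step length. `start` is a 0-based linear index.
// Returns dist (Inf where unreachable or background) and parent (0-based linear
// index, -1 at the source / background).
// [[Rcpp::export(name = ".dijkstra_mask")]]
List dijkstra_mask(LogicalVector mask, IntegerVector dim, NumericVector vox,
                   int start) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  const size_t ntot = (size_t)nz * ny * nx;
  const double vz = vox[0], vy = vox[1], vx = vox[2];
  std::vector<double> dist(ntot, R_PosInf);
  std::vector<int> parent(ntot, -1);
  typedef std::pair<double, size_t> Node;
  std::priority_queue<Node, std::vector<Node>, std::greater<Node> > pq;
  if (start < 0 || (size_t)start >= ntot || !mask[start])
    stop("start voxel outside mask");
  dist[start] = 0.0;
  pq.push(Node(0.0, (size_t)start));
  // precompute the 26 step lengths
  double wlen[3][3][3];
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx)
        wlen[dz + 1][dy + 1][dx + 1] =
            std::sqrt(dz * dz * vz * vz + dy * dy * vy * vy + dx * dx * vx * vx);
  while (!pq.empty()) {
    Node top = pq.top();
    pq.pop();
    size_t cur = top.second;
    if (top.first > dist[cur]) continue;
    int iz = cur % nz, iy = (cur / nz) % ny, ix = cur / ((size_t)nz * ny);
    for (int dz = -1; dz <= 1; ++dz)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dx = -1; dx <= 1; ++dx) {
          if (!dz && !dy && !dx) continue;
          int z = iz + dz, y = iy + dy, x = ix + dx;
          if (z < 0 || z >= nz || y < 0 || y >= ny || x < 0 || x >= nx) continue;
          size_t nb = (size_t)z + (size_t)nz * (y + (size_t)ny * x);
          if (!mask[nb]) continue;
          double nd = dist[cur] + wlen[dz + 1][dy + 1][dx + 1];
          if (nd < dist[nb]) {
            dist[nb] = nd;
            parent[nb] = (int)cur;
            pq.push(Node(nd, nb));
          }
        }
  }
  return List::create(_["dist"] = NumericVector(dist.begin(), dist.end()),
                      _["parent"] = IntegerVector(parent.begin(), parent.end()));
}

// Gaussian blur of a sparse field by scatter-adding a truncated separable
// kernel patch around each nonzero voxel; equivalent to dense separable
// convolution when the signal occupies a small fraction of the volume
// (boundaries are clipped, not reflected — painted scenes keep an empty
// border). sigma in voxel units per axis (z, y, x).
// [[Rcpp::export(name = ".blur3d_sparse")]]
NumericVector blur3d_sparse(NumericVector arr, IntegerVector dim,
                            NumericVector sigma) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  const size_t ntot = (size_t)nz * ny * nx;
  int h[3];
  std::vector<double> k[3];
  for (int ax = 0; ax < 3; ++ax) {
    double s = sigma[ax];
    if (s <= 0) { h[ax] = 0; k[ax].assign(1, 1.0); continue; }
    h[ax] = (int)std::ceil(3.5 * s);
    k[ax].resize(2 * h[ax] + 1);
    double ksum = 0;
    for (int i = -h[ax]; i <= h[ax]; ++i) {
      k[ax][i + h[ax]] = std::exp(-0.5 * (double)i * i / (s * s));
      ksum += k[ax][i + h[ax]];
    }
    for (size_t i = 0; i < k[ax].size(); ++i) k[ax][i] /= ksum;
  }
  NumericVector out(ntot);
  out.attr("dim") = dim;
  for (size_t sidx = 0; sidx < ntot; ++sidx) {
    double v = arr[sidx];
    if (v == 0.0) continue;
    int iz = sidx % nz, iy = (sidx / nz) % ny, ix = sidx / ((size_t)nz * ny);
    int z0 = std::max(iz - h[0], 0), z1 = std::min(iz + h[0], nz - 1);
    int y0 = std::max(iy - h[1], 0), y1 = std::min(iy + h[1], ny - 1);
    int x0 = std::max(ix - h[2], 0), x1 = std::min(ix + h[2], nx - 1);
    for (int x = x0; x <= x1; ++x) {
      double kx = v * k[2][x - ix + h[2]];
      for (int y = y0; y <= y1; ++y) {
        double kxy = kx * k[1][y - iy + h[1]];
        double *col = REAL(out) + (size_t)nz * (y + (size_t)ny * x);
        const double *kz = &k[0][z0 - iz + h[0]];
        for (int z = z0; z <= z1; ++z)
          col[z] += kxy * kz[z - z0];
      }
    }
  }
  return out;
}

// Sparse single-source shortest paths over an explicit voxel set (0-based
// linear indices into a dim-shaped array), 26-neighbour edges weighted by
// physical step length. start is a position (0-based) within idx.
// Returns dist and parent positions (-1 at source), both length(idx).
// [[Rcpp::export(name = ".dijkstra_sparse")]]
List dijkstra_sparse(IntegerVector idx, IntegerVector dim, NumericVector vox,
                     int start) {
  const int nz = dim[0], ny = dim[1];
  const int n = idx.size();
  const double vz = vox[0], vy = vox[1], vx = vox[2];
  std::unordered_map<int, int> pos;
  pos.reserve(n * 2);
  for (int i = 0; i < n; ++i) pos[idx[i]] = i;
  std::vector<double> dist(n, R_PosInf);
  std::vector<int> parent(n, -1);
  typedef std::pair<double, int> Node;
  std::priority_queue<Node, std::vector<Node>, std::greater<Node> > pq;
  if (start < 0 || start >= n) stop("start outside voxel set");
  dist[start] = 0.0;
  pq.push(Node(0.0, start));
  double wlen[3][3][3];
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx)
        wlen[dz + 1][dy + 1][dx + 1] =
            std::sqrt(dz * dz * vz * vz + dy * dy * vy * vy + dx * dx * vx * vx);
  while (!pq.empty()) {
    Node top = pq.top();
    pq.pop();
    int cur = top.second;
    if (top.first > dist[cur]) continue;
    int lin = idx[cur];
    int iz = lin % nz, iy = (lin / nz) % ny, ix = lin / (nz * ny);
    for (int dz = -1; dz <= 1; ++dz)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dx = -1; dx <= 1; ++dx) {
          if (!dz && !dy && !dx) continue;
          int z = iz + dz, y = iy + dy, x = ix + dx;
          if (z < 0 || z >= dim[0] || y < 0 || y >= dim[1] || x < 0 ||
              x >= dim[2]) continue;
          std::unordered_map<int, int>::iterator it =
              pos.find(z + nz * (y + ny * x));
          if (it == pos.end()) continue;
          int nb = it->second;
          double nd = dist[cur] + wlen[dz + 1][dy + 1][dx + 1];
          if (nd < dist[nb]) {
            dist[nb] = nd;
            parent[nb] = cur;
            pq.push(Node(nd, nb));
          }
        }
  }
  return List::create(_["dist"] = NumericVector(dist.begin(), dist.end()),
                      _["parent"] = IntegerVector(parent.begin(), parent.end()));
}

// Binary dilation with an ellipsoidal (default) or box structuring element;
// radii in voxel units per axis (z, y, x).
// [[Rcpp::export(name = ".dilate3d")]]
LogicalVector dilate3d(LogicalVector mask, IntegerVector dim, NumericVector rad,
                       bool box = false) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  const double rz = std::max(rad[0], 0.0), ry = std::max(rad[1], 0.0),
               rx = std::max(rad[2], 0.0);
  const int hz = (int)std::floor(rz), hy = (int)std::floor(ry),
            hx = (int)std::floor(rx);
  // structuring element offsets
  std::vector<int> oz, oy, ox;
  for (int dz = -hz; dz <= hz; ++dz)
    for (int dy = -hy; dy <= hy; ++dy)
      for (int dx = -hx; dx <= hx; ++dx) {
        double q = 0;
        if (rz > 0) q += (double)dz * dz / (rz * rz);
        else if (dz) continue;
        if (ry > 0) q += (double)dy * dy / (ry * ry);
        else if (dy) continue;
        if (rx > 0) q += (double)dx * dx / (rx * rx);
        else if (dx) continue;
        if (box || q <= 1.0) { oz.push_back(dz); oy.push_back(dy); ox.push_back(dx); }
      }
  const size_t ntot = (size_t)nz * ny * nx;
  LogicalVector out(ntot, false);
  for (size_t s = 0; s < ntot; ++s) {
    if (!mask[s]) continue;
    int iz = s % nz, iy = (s / nz) % ny, ix = s / ((size_t)nz * ny);
    for (size_t k = 0; k < oz.size(); ++k) {
      int z = iz + oz[k], y = iy + oy[k], x = ix + ox[k];
      if (z < 0 || z >= nz || y < 0 || y >= ny || x < 0 || x >= nx) continue;
      out[(size_t)z + (size_t)nz * (y + (size_t)ny * x)] = true;
    }
  }
  out.attr("dim") = dim;
  return out;
}
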