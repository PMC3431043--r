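#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
#include <limits>

using namespace Rcpp;

// Felzenszwalb & Huttenlocher 1D squared distance transform with sample
// spacing h (parabolas at i*h). f is overwritten with the transform.
static void dt1d(std::vector<double>& f, double h, std::vector<double>& d,
                 std::vector<int>& v, std::vector<double>& z) {
  const int n = (int)f.size();
  const double INF = std::numeric_limits<double>::infinity();
  int k = 0;
  v[0] = 0;
  z[0] = -INF;
  z[1] = INF;
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      double qq = (double)q * h, vv = (double)v[k] * h;
      s = ((f[q] + qq * qq) - (f[v[k]] + vv * vv)) / (2.0 * qq - 2.0 * vv);
      if (s <= z[k]) { --k; } else break;
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = INF;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    double qq = (double)q * h;
    while (z[k + 1] < qq) ++k;
    double diff = qq - (double)v[k] * h;
    d[q] = diff * diff + f[v[k]];
  }
  for (int q = 0; q < n; ++q) f[q] = d[q];
}

// Anisotropic Euclidean distance transform of a 3D mask stored in R array
// order (dim = c(nz, ny, nx)); distance in physical units from each
// foreground voxel centre to the nearest background voxel centre.
// Background voxels get 0. Voxels on a face of the volume are treated as
// bordering background half a voxel away is NOT assumed: distances are to
// in-volume background only (standard convention).
// [[Rcpp::export]]
NumericVector cpp_edt3d(LogicalVector mask, IntegerVector dim,
                        NumericVector spacing) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  const double sz = spacing[0], sy = spacing[1], sx = spacing[2];
  const R_xlen_t n = (R_xlen_t)nz * ny * nx;
  // large finite sentinel: true infinity breaks the parabola-intersection
  // arithmetic (INF - INF) when a scan line starts on foreground
  const double BIG = 1e15;
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = mask[i] ? BIG : 0.0;

  int maxdim = std::max(nz, std::max(ny, nx));
  std::vector<double> f(maxdim), d(maxdim), z(maxdim + 1);
  std::vector<int> v(maxdim);

  // pass along z (stride 1)
  for (int i = 0; i < nx; ++i)
    for (int j = 0; j < ny; ++j) {
      R_xlen_t base = (R_xlen_t)j * nz + (R_xlen_t)i * nz * ny;
      f.assign(nz, 0.0);
      for (int k = 0; k < nz; ++k) f[k] = out[base + k];
      dt1d(f, sz, d, v, z);
      for (int k = 0; k < nz; ++k) out[base + k] = f[k];
    }
  // pass along y (stride nz)
  for (int i = 0; i < nx; ++i)
    for (int k = 0; k < nz; ++k) {
      R_xlen_t base = (R_xlen_t)k + (R_xlen_t)i * nz * ny;
      f.assign(ny, 0.0);
      for (int j = 0; j < ny; ++j) f[j] = out[base + (R_xlen_t)j * nz];
      dt1d(f, sy, d, v, z);
      for (int j = 0; j < ny; ++j) out[base + (R_xlen_t)j * nz] = f[j];
    }
  // pass along x (stride nz*ny)
  for (int j = 0; j < ny; ++j)
    for (int k = 0; k < nz; ++k) {
      R_xlen_t base = (R_xlen_t)k + (R_xlen_t)j * nz;
      f.assign(nx, 0.0);
      for (int i = 0; i < nx; ++i) f[i] = out[base + (R_xlen_t)i * nz * ny];
      dt1d(f, sx, d, v, z);
      for (int i = 0; i < nx; ++i) out[base + (R_xlen_t)i * nz * ny] = f[i];
    }
  for (R_xlen_t i = 0; i < n; ++i) out[i] = std::sqrt(out[i]);
  return out;
}

static void neighbour_offsets(int connectivity, const IntegerVector& dim,
                              const NumericVector& spacing,
                              std::vector<int>& dk, std::vector<int>& dj,
                              std::vector<int>& di, std::vector<double>& len) {
  dk.clear(); dj.clear(); di.clear(); len.clear();
  for (int a = -1; a <= 1; ++a)
    for (int b = -1; b <= 1; ++b)
      for (int c = -1; c <= 1; ++c) {
        if (a == 0 && b == 0 && c == 0) continue;
        int nn = std::abs(a) + std::abs(b) + std::abs(c);
        if (connectivity == 6 && nn > 1) continue;
        dk.push_back(a); dj.push_back(b); di.push_back(c);
        double dz = a * spacing[0], dy = b * spacing[1], dx = c * spacing[2];
        len.push_back(std::sqrt(dz * dz + dy * dy + dx * dx));
      }
}

// Connected-component labelling of a 3D mask (R array order, dim = nz,ny,nx).
// Labels assigned in scan order (deterministic); background = 0.
// [[Rcpp::export]]
IntegerVector cpp_label_components(LogicalVector mask, IntegerVector dim,
                                   int connectivity) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  const R_xlen_t n = (R_xlen_t)nz * ny * nx;
  IntegerVector lab(n, 0);
  std::vector<int> dk, dj, di;
  std::vector<double> len;
  NumericVector sp = NumericVector::create(1.0, 1.0, 1.0);
  neighbour_offsets(connectivity, dim, sp, dk, dj, di, len);
  const int noff = (int)dk.size();

  int next = 0;
  std::vector<R_xlen_t> stack;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (!mask[s] || lab[s] != 0) continue;
    ++next;
    lab[s] = next;
    stack.clear();
    stack.push_back(s);
    while (!stack.empty()) {
      R_xlen_t cur = stack.back();
      stack.pop_back();
      int k = (int)(cur % nz);
      int j = (int)((cur / nz) % ny);
      int i = (int)(cur / ((R_xlen_t)nz * ny));
      for (int o = 0; o < noff; ++o) {
        int k2 = k + dk[o], j2 = j + dj[o], i2 = i + di[o];
        if (k2 < 0 || k2 >= nz || j2 < 0 || j2 >= ny || i2 < 0 || i2 >= nx)
          continue;
        R_xlen_t q = (R_xlen_t)k2 + (R_xlen_t)j2 * nz + (R_xlen_t)i2 * nz * ny;
        if (mask[q] && lab[q] == 0) {
          lab[q] = next;
          stack.push_back(q);
        }
      }
    }
  }
  return lab;
}

// Dijkstra shortest-path tree over foreground voxels of a 3D grid.
// node_cost holds per-voxel traversal cost factors (NA / non-finite =
// not traversable). Edge weight between neighbouring voxels u,v is
// step_length(u,v) * (node_cost[u] + node_cost[v]) / 2.
// Ties broken on smaller linear voxel index for bit-reproducibility.
// Returns dist (physical geodesic cost), parent (1-based linear index,
// 0 at the seed, NA where unreached) and pathlen (accumulated Euclidean
// step length along the tree path, for geodesic arc length).
// [[Rcpp::export]]
List cpp_dijkstra_tree(NumericVector node_cost, IntegerVector dim,
                       NumericVector spacing, R_xlen_t seed1,
                       int connectivity) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  const R_xlen_t n = (R_xlen_t)nz * ny * nx;
  const double INF = std::numeric_limits<double>::infinity();
  std::vector<double> dist(n, INF), plen(n, INF);
  IntegerVector parent(n, NA_INTEGER);
  std::vector<int> dk, dj, di;
  std::vector<double> len;
  neighbour_offsets(connectivity, dim, spacing, dk, dj, di, len);
  const int noff = (int)dk.size();

  typedef std::pair<double, R_xlen_t> Q;
  std::priority_queue<Q, std::vector<Q>, std::greater<Q> > pq;
  R_xlen_t seed = seed1 - 1;
  if (seed < 0 || seed >= n) stop("seed index out of range");
  if (!R_finite(node_cost[seed])) stop("seed voxel is not traversable");
  dist[seed] = 0.0;
  plen[seed] = 0.0;
  parent[seed] = 0;
  pq.push(Q(0.0, seed));
  while (!pq.empty()) {
    Q top = pq.top();
    pq.pop();
    R_xlen_t u = top.second;
    if (top.first > dist[u]) continue;
    int k = (int)(u % nz);
    int j = (int)((u / nz) % ny);
    int i = (int)(u / ((R_xlen_t)nz * ny));
    double cu = node_cost[u];
    for (int o = 0; o < noff; ++o) {
      int k2 = k + dk[o], j2 = j + dj[o], i2 = i + di[o];
      if (k2 < 0 || k2 >= nz || j2 < 0 || j2 >= ny || i2 < 0 || i2 >= nx)
        continue;
      R_xlen_t v = (R_xlen_t)k2 + (R_xlen_t)j2 * nz + (R_xlen_t)i2 * nz * ny;
      double cv = node_cost[v];
      if (!R_finite(cv)) continue;
      double w = len[o] * 0.5 * (cu + cv);
      double nd = dist[u] + w;
      bool better = nd < dist[v] ||
        (nd == dist[v] && parent[v] != NA_INTEGER &&
         (R_xlen_t)(u + 1) < (R_xlen_t)parent[v]);
      if (better) {
        dist[v] = nd;
        plen[v] = plen[u] + len[o];
        parent[v] = (int)(u + 1);
        pq.push(Q(nd, v));
      }
    }
  }
  NumericVector dout(n), pout(n);
  for (R_xlen_t i2 = 0; i2 < n; ++i2) {
    dout[i2] = dist[i2];
    pout[i2] = plen[i2];
  }
  return List::create(_["dist"] = dout, _["parent"] = parent,
                      _["pathlen"] = pout);
}
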