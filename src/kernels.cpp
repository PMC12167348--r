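// Numeric kernels for correspondence search and depth rendering.
// Brute-force searches are deliberate: problem sizes in this package are a few
// thousand points against a few thousand primitives, where the O(N*M) scan in
// tight C++ beats tree construction overhead and stays trivially correct.

#include <Rcpp.h>
#include <cmath>
#include <limits>
#include <vector>

using namespace Rcpp;

// Nearest neighbour of each query row in ref (both N x 3).
// [[Rcpp::export(name = ".nn_search_cpp")]]
List nn_search_cpp(NumericMatrix query, NumericMatrix ref) {
  const int nq = query.nrow(), nr = ref.nrow();
  IntegerVector idx(nq);
  NumericVector dist(nq);
  for (int i = 0; i < nq; ++i) {
    const double qx = query(i, 0), qy = query(i, 1), qz = query(i, 2);
    double best = std::numeric_limits<double>::infinity();
    int bj = -1;
    for (int j = 0; j < nr; ++j) {
      const double dx = ref(j, 0) - qx, dy = ref(j, 1) - qy, dz = ref(j, 2) - qz;
      const double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < best) { best = d2; bj = j; }
    }
    idx[i] = bj + 1;  // 1-based for R
    dist[i] = std::sqrt(best);
  }
  return List::create(_["index"] = idx, _["distance"] = dist);
}

// k nearest neighbours of each point within the same cloud (self excluded
// when self_exclude is true). Returns an n x k index matrix (1-based).
// [[Rcpp::export(name = ".knn_cpp")]]
IntegerMatrix knn_cpp(NumericMatrix pts, int k, bool self_exclude) {
  const int n = pts.nrow();
  IntegerMatrix out(n, k);
  std::vector<double> d2(n);
  std::vector<int> ord(n);
  for (int i = 0; i < n; ++i) {
    const double px = pts(i, 0), py = pts(i, 1), pz = pts(i, 2);
    for (int j = 0; j < n; ++j) {
      const double dx = pts(j, 0) - px, dy = pts(j, 1) - py, dz = pts(j, 2) - pz;
      d2[j] = dx * dx + dy * dy + dz * dz;
      ord[j] = j;
    }
    if (self_exclude) d2[i] = std::numeric_limits<double>::infinity();
    std::partial_sort(ord.begin(), ord.begin() + k, ord.end(),
                      [&](int a, int b) { return d2[a] < d2[b]; });
    for (int m = 0; m < k; ++m) out(i, m) = ord[m] + 1;
  }
  return out;
}

// Moller-Trumbore ray/triangle intersection. Rays start at the origin of the
// camera frame; dirs are per-pixel direction vectors (n x 3, z component 1 for
// pinhole rays so the returned parameter equals z-depth). Vertices are already
// in the camera frame. Returns the smallest positive ray parameter per ray
// (Inf when the ray misses the mesh).
// [[Rcpp::export(name = ".raycast_cpp")]]
NumericVector raycast_cpp(NumericMatrix dirs, NumericMatrix V, IntegerMatrix F) {
  const int nray = dirs.nrow(), nf = F.nrow();
  const double eps = 1e-12;
  NumericVector out(nray, R_PosInf);
  // cache triangle vertices for locality
  std::vector<double> ax(nf), ay(nf), az(nf), e1x(nf), e1y(nf), e1z(nf),
      e2x(nf), e2y(nf), e2z(nf);
  for (int f = 0; f < nf; ++f) {
    const int i0 = F(f, 0) - 1, i1 = F(f, 1) - 1, i2 = F(f, 2) - 1;
    ax[f] = V(i0, 0); ay[f] = V(i0, 1); az[f] = V(i0, 2);
    e1x[f] = V(i1, 0) - ax[f]; e1y[f] = V(i1, 1) - ay[f]; e1z[f] = V(i1, 2) - az[f];
    e2x[f] = V(i2, 0) - ax[f]; e2y[f] = V(i2, 1) - ay[f]; e2z[f] = V(i2, 2) - az[f];
  }
  for (int r = 0; r < nray; ++r) {
    const double dx = dirs(r, 0), dy = dirs(r, 1), dz = dirs(r, 2);
    double best = R_PosInf;
    for (int f = 0; f < nf; ++f) {
      // h = d x e2
      const double hx = dy * e2z[f] - dz * e2y[f];
      const double hy = dz * e2x[f] - dx * e2z[f];
      const double hz = dx * e2y[f] - dy * e2x[f];
      const double a = e1x[f] * hx + e1y[f] * hy + e1z[f] * hz;
      if (std::fabs(a) < eps) continue;
      const double inv = 1.0 / a;
      // s = origin - v0 = -v0
      const double sx = -ax[f], sy = -ay[f], sz = -az[f];
      const double u = inv * (sx * hx + sy * hy + sz * hz);
      if (u < -1e-12 || u > 1.0 + 1e-12) continue;
      // q = s x e1
      const double qx = sy * e1z[f] - sz * e1y[f];
      const double qy = sz * e1x[f] - sx * e1z[f];
      const double qz = sx * e1y[f] - sy * e1x[f];
      const double v = inv * (dx * qx + dy * qy + dz * qz);
      if (v < -1e-12 || u + v > 1.0 + 1e-12) continue;
      const double t = inv * (e2x[f] * qx + e2y[f] * qy + e2z[f] * qz);
      if (t > eps && t < best) best = t;
    }
    out[r] = best;
  }
  return out;
}

static inline void closest_on_tri(const double *p, const double *a,
                                  const double *b, const double *c,
                                  double *cp) {
  // Ericson, Real-Time Collision Detection, 5.1.5
  double ab[3] = {b[0] - a[0], b[1] - a[1], b[2] - a[2]};
  double ac[3] = {c[0] - a[0], c[1] - a[1], c[2] - a[2]};
  double ap[3] = {p[0] - a[0], p[1] - a[1], p[2] - a[2]};
  double d1 = ab[0] * ap[0] + ab[1] * ap[1] + ab[2] * ap[2];
  double d2 = ac[0] * ap[0] + ac[1] * ap[1] + ac[2] * ap[2];
  if (d1 <= 0 && d2 <= 0) { cp[0] = a[0]; cp[1] = a[1]; cp[2] = a[2]; return; }
  double bp[3] = {p[0] - b[0], p[1] - b[1], p[2] - b[2]};
  double d3 = ab[0] * bp[0] + ab[1] * bp[1] + ab[2] * bp[2];
  double d4 = ac[0] * bp[0] + ac[1] * bp[1] + ac[2] * bp[2];
  if (d3 >= 0 && d4 <= d3) { cp[0] = b[0]; cp[1] = b[1]; cp[2] = b[2]; return; }
  double vc = d1 * d4 - d3 * d2;
  if (vc <= 0 && d1 >= 0 && d3 <= 0) {
    double v = d1 / (d1 - d3);
    for (int i = 0; i < 3; ++i) cp[i] = a[i] + v * ab[i];
    return;
  }
  double cpv[3] = {p[0] - c[0], p[1] - c[1], p[2] - c[2]};
  double d5 = ab[0] * cpv[0] + ab[1] * cpv[1] + ab[2] * cpv[2];
  double d6 = ac[0] * cpv[0] + ac[1] * cpv[1] + ac[2] * cpv[2];
  if (d6 >= 0 && d5 <= d6) { cp[0] = c[0]; cp[1] = c[1]; cp[2] = c[2]; return; }
  double vb = d5 * d2 - d1 * d6;
  if (vb <= 0 && d2 >= 0 && d6 <= 0) {
    double w = d2 / (d2 - d6);
    for (int i = 0; i < 3; ++i) cp[i] = a[i] + w * ac[i];
    return;
  }
  double va = d3 * d6 - d5 * d4;
  if (va <= 0 && (d4 - d3) >= 0 && (d5 - d6) >= 0) {
    double w = (d4 - d3) / ((d4 - d3) + (d5 - d6));
    for (int i = 0; i < 3; ++i) cp[i] = b[i] + w * (c[i] - b[i]);
    return;
  }
  double denom = 1.0 / (va + vb + vc);
  double v = vb * denom, w = vc * denom;
  for (int i = 0; i < 3; ++i) cp[i] = a[i] + ab[i] * v + ac[i] * w;
}

// Closest point on a triangle mesh for each query point. Candidate triangles
// are the two-ring of the nearest vertex, passed as a CSR structure
// (adj_start: nv+1 offsets into adj_tri, both 1-based from R). Exact for
// meshes where the true closest triangle touches the nearest vertex's
// two-ring neighbourhood, which holds for well-shaped surface meshes.
// [[Rcpp::export(name = ".closest_point_mesh_cpp")]]
List closest_point_mesh_cpp(NumericMatrix P, NumericMatrix V, IntegerMatrix F,
                            IntegerVector adj_start, IntegerVector adj_tri) {
  const int np = P.nrow(), nv = V.nrow();
  NumericMatrix cp(np, 3), nrm(np, 3);
  NumericVector dist(np);
  IntegerVector face(np);
  for (int i = 0; i < np; ++i) {
    const double p[3] = {P(i, 0), P(i, 1), P(i, 2)};
    // nearest vertex
    double best = std::numeric_limits<double>::infinity();
    int bv = 0;
    for (int j = 0; j < nv; ++j) {
      const double dx = V(j, 0) - p[0], dy = V(j, 1) - p[1], dz = V(j, 2) - p[2];
      const double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < best) { best = d2; bv = j; }
    }
    // candidate triangles
    double bestd2 = std::numeric_limits<double>::infinity();
    double bcp[3] = {V(bv, 0), V(bv, 1), V(bv, 2)};
    int bf = -1;
    const int s = adj_start[bv] - 1, e = adj_start[bv + 1] - 1;
    for (int m = s; m < e; ++m) {
      const int f = adj_tri[m] - 1;
      const int i0 = F(f, 0) - 1, i1 = F(f, 1) - 1, i2 = F(f, 2) - 1;
      const double a[3] = {V(i0, 0), V(i0, 1), V(i0, 2)};
      const double b[3] = {V(i1, 0), V(i1, 1), V(i1, 2)};
      const double c[3] = {V(i2, 0), V(i2, 1), V(i2, 2)};
      double q[3];
      closest_on_tri(p, a, b, c, q);
      const double dx = q[0] - p[0], dy = q[1] - p[1], dz = q[2] - p[2];
      const double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < bestd2) {
        bestd2 = d2; bf = f;
        bcp[0] = q[0]; bcp[1] = q[1]; bcp[2] = q[2];
      }
    }
    cp(i, 0) = bcp[0]; cp(i, 1) = bcp[1]; cp(i, 2) = bcp[2];
    dist[i] = std::sqrt(bestd2);
    face[i] = bf + 1;
    if (bf >= 0) {
      const int i0 = F(bf, 0) - 1, i1 = F(bf, 1) - 1, i2 = F(bf, 2) - 1;
      const double e1[3] = {V(i1, 0) - V(i0, 0), V(i1, 1) - V(i0, 1), V(i1, 2) - V(i0, 2)};
      const double e2[3] = {V(i2, 0) - V(i0, 0), V(i2, 1) - V(i0, 1), V(i2, 2) - V(i0, 2)};
      double nx = e1[1] * e2[2] - e1[2] * e2[1];
      double ny = e1[2] * e2[0] - e1[0] * e2[2];
      double nz = e1[0] * e2[1] - e1[1] * e2[0];
      const double nn = std::sqrt(nx * nx + ny * ny + nz * nz);
      if (nn > 0) { nx /= nn; ny /= nn; nz /= nn; }
      nrm(i, 0) = nx; nrm(i, 1) = ny; nrm(i, 2) = nz;
    }
  }
  return List::create(_["point"] = cp, _["normal"] = nrm,
                      _["distance"] = dist, _["face"] = face);
}
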