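#include <Rcpp.h>
#include <cmath>
#include <limits>
#include <vector>
using namespace Rcpp;

// Moller-Trumbore ray/triangle intersection. Returns t >= 0 or -1.
static inline double ray_tri(const double *o, const double *d,
                             const double *a, const double *b,
                             const double *c) {
  const double EPS = 1e-12;
  double e1[3], e2[3], p[3], tv[3], q[3];
  for (int i = 0; i < 3; ++i) { e1[i] = b[i] - a[i]; e2[i] = c[i] - a[i]; }
  p[0] = d[1] * e2[2] - d[2] * e2[1];
  p[1] = d[2] * e2[0] - d[0] * e2[2];
  p[2] = d[0] * e2[1] - d[1] * e2[0];
  double det = e1[0] * p[0] + e1[1] * p[1] + e1[2] * p[2];
  if (std::fabs(det) < EPS) return -1.0;
  double inv = 1.0 / det;
  for (int i = 0; i < 3; ++i) tv[i] = o[i] - a[i];
  double u = (tv[0] * p[0] + tv[1] * p[1] + tv[2] * p[2]) * inv;
  if (u < -1e-9 || u > 1.0 + 1e-9) return -1.0;
  q[0] = tv[1] * e1[2] - tv[2] * e1[1];
  q[1] = tv[2] * e1[0] - tv[0] * e1[2];
  q[2] = tv[0] * e1[1] - tv[1] * e1[0];
  double v = (d[0] * q[0] + d[1] * q[1] + d[2] * q[2]) * inv;
  if (v < -1e-9 || u + v > 1.0 + 1e-9) return -1.0;
  double t = (e2[0] * q[0] + e2[1] * q[1] + e2[2] * q[2]) * inv;
  return (t > 1e-9) ? t : -1.0;
}

// First-hit ray casting of N rays against a triangle mesh.
// origins, dirs: N x 3; V: vertex coords Vx3; F: 0-based face indices Fx3.
// Returns list(t = ray parameter (Inf if no hit), face = 1-based index or NA).
// [[Rcpp::export]]
List cpp_ray_cast(NumericMatrix origins, NumericMatrix dirs,
                  NumericMatrix V, IntegerMatrix F) {
  int n = origins.nrow(), nf = F.nrow();
  NumericVector tout(n, R_PosInf);
  IntegerVector fout(n, NA_INTEGER);
  std::vector<double> vx(V.nrow() * 3);
  for (int i = 0; i < V.nrow(); ++i)
    for (int j = 0; j < 3; ++j) vx[3 * i + j] = V(i, j);
  for (int i = 0; i < n; ++i) {
    double o[3] = { origins(i, 0), origins(i, 1), origins(i, 2) };
    double d[3] = { dirs(i, 0), dirs(i, 1), dirs(i, 2) };
    double best = R_PosInf; int bi = NA_INTEGER;
    for (int f = 0; f < nf; ++f) {
      const double *a = &vx[3 * F(f, 0)];
      const double *b = &vx[3 * F(f, 1)];
      const double *c = &vx[3 * F(f, 2)];
      double t = ray_tri(o, d, a, b, c);
      if (t > 0 && t < best) { best = t; bi = f + 1; }
    }
    tout[i] = best; fout[i] = bi;
  }
  return List::create(_["t"] = tout, _["face"] = fout);
}

// Closest point on triangle abc to p (Ericson, Real-Time Collision Detection).
static inline void closest_on_tri(const double *p, const double *a,
                                  const double *b, const double *c,
                                  double *out) {
  double ab[3], ac[3], ap[3];
  for (int i = 0; i < 3; ++i) { ab[i] = b[i] - a[i]; ac[i] = c[i] - a[i]; ap[i] = p[i] - a[i]; }
  double d1 = ab[0]*ap[0] + ab[1]*ap[1] + ab[2]*ap[2];
  double d2 = ac[0]*ap[0] + ac[1]*ap[1] + ac[2]*ap[2];
  if (d1 <= 0 && d2 <= 0) { for (int i = 0; i < 3; ++i) out[i] = a[i]; return; }
  double bp[3];
  for (int i = 0; i < 3; ++i) bp[i] = p[i] - b[i];
  double d3 = ab[0]*bp[0] + ab[1]*bp[1] + ab[2]*bp[2];
  double d4 = ac[0]*bp[0] + ac[1]*bp[1] + ac[2]*bp[2];
  if (d3 >= 0 && d4 <= d3) { for (int i = 0; i < 3; ++i) out[i] = b[i]; return; }
  double vc = d1 * d4 - d3 * d2;
  if (vc <= 0 && d1 >= 0 && d3 <= 0) {
    double v = d1 / (d1 - d3);
    for (int i = 0; i < 3; ++i) out[i] = a[i] + v * ab[i];
    return;
  }
  double cp[3];
  for (int i = 0; i < 3; ++i) cp[i] = p[i] - c[i];
  double d5 = ab[0]*cp[0] + ab[1]*cp[1] + ab[2]*cp[2];
  double d6 = ac[0]*cp[0] + ac[1]*cp[1] + ac[2]*cp[2];
  if (d6 >= 0 && d5 <= d6) { for (int i = 0; i < 3; ++i) out[i] = c[i]; return; }
  double vb = d5 * d2 - d1 * d6;
  if (vb <= 0 && d2 >= 0 && d6 <= 0) {
    double w = d2 / (d2 - d6);
    for (int i = 0; i < 3; ++i) out[i] = a[i] + w * ac[i];
    return;
  }
  double va = d3 * d6 - d5 * d4;
  if (va <= 0 && (d4 - d3) >= 0 && (d5 - d6) >= 0) {
    double w = (d4 - d3) / ((d4 - d3) + (d5 - d6));
    for (int i = 0; i < 3; ++i) out[i] = b[i] + w * (c[i] - b[i]);
    return;
  }
  double denom = 1.0 / (va + vb + vc);
  double v = vb * denom, w = vc * denom;
  for (int i = 0; i < 3; ++i) out[i] = a[i] + ab[i] * v + ac[i] * w;
}

// Closest surface point on a mesh for each query point.
// Returns list(points = Nx3, face = 1-based, dist = N).
// [[Rcpp::export]]
List cpp_closest_point(NumericMatrix P, NumericMatrix V, IntegerMatrix F) {
  int n = P.nrow(), nf = F.nrow();
  NumericMatrix out(n, 3);
  IntegerVector fout(n);
  NumericVector dout(n);
  std::vector<double> vx(V.nrow() * 3);
  for (int i = 0; i < V.nrow(); ++i)
    for (int j = 0; j < 3; ++j) vx[3 * i + j] = V(i, j);
  for (int i = 0; i < n; ++i) {
    double p[3] = { P(i, 0), P(i, 1), P(i, 2) };
    double best = std::numeric_limits<double>::infinity();
    double bp[3] = {0, 0, 0}; int bf = 1;
    for (int f = 0; f < nf; ++f) {
      double q[3];
      closest_on_tri(p, &vx[3 * F(f, 0)], &vx[3 * F(f, 1)], &vx[3 * F(f, 2)], q);
      double d2 = (q[0]-p[0])*(q[0]-p[0]) + (q[1]-p[1])*(q[1]-p[1]) +
                  (q[2]-p[2])*(q[2]-p[2]);
      if (d2 < best) { best = d2; bf = f + 1; bp[0] = q[0]; bp[1] = q[1]; bp[2] = q[2]; }
    }
    out(i, 0) = bp[0]; out(i, 1) = bp[1]; out(i, 2) = bp[2];
    fout[i] = bf; dout[i] = std::sqrt(best);
  }
  return List::create(_["points"] = out, _["face"] = fout, _["dist"] = dout);
}

// 8-connected component labeling of a logical mask (two-pass BFS flood fill).
// Returns an integer matrix of labels, 0 for background.
// [[Rcpp::export]]
IntegerMatrix cpp_label_components(LogicalMatrix mask) {
  int h = mask.nrow(), w = mask.ncol();
  IntegerMatrix lab(h, w);
  std::fill(lab.begin(), lab.end(), 0);
  int next = 0;
  std::vector<int> stack;
  for (int j = 0; j < w; ++j) {
    for (int i = 0; i < h; ++i) {
      if (!mask(i, j) || lab(i, j)) continue;
      ++next;
      stack.clear();
      stack.push_back(i + j * h);
      lab(i, j) = next;
      while (!stack.empty()) {
        int idx = stack.back(); stack.pop_back();
        int ci = idx % h, cj = idx / h;
        for (int dj = -1; dj <= 1; ++dj) {
          for (int di = -1; di <= 1; ++di) {
            if (di == 0 && dj == 0) continue;
            int ni = ci + di, nj = cj + dj;
            if (ni < 0 || nj < 0 || ni >= h || nj >= w) continue;
            if (mask(ni, nj) && !lab(ni, nj)) {
              lab(ni, nj) = next;
              stack.push_back(ni + nj * h);
            }
          }
        }
      }
    }
  }
  return lab;
}

// Hungarian algorithm (shortest augmenting path with potentials, O(n^3)).
// cost: n x m with n <= m. Returns 1-based column assigned to each row.
// [[Rcpp::export]]
IntegerVector cpp_hungarian(NumericMatrix cost) {
  int n = cost.nrow(), m = cost.ncol();
  if (n > m) stop("cost matrix must have nrow <= ncol");
  const double INF = std::numeric_limits<double>::infinity();
  std::vector<double> u(n + 1, 0.0), v(m + 1, 0.0);
  std::vector<int> p(m + 1, 0), way(m + 1, 0);
  for (int i = 1; i <= n; ++i) {
    p[0] = i;
    int j0 = 0;
    std::vector<double> minv(m + 1, INF);
    std::vector<char> used(m + 1, 0);
    do {
      used[j0] = 1;
      int i0 = p[j0], j1 = -1;
      double delta = INF;
      for (int j = 1; j <= m; ++j) {
        if (used[j]) continue;
        double cur = cost(i0 - 1, j - 1) - u[i0] - v[j];
        if (cur < minv[j]) { minv[j] = cur; way[j] = j0; }
        if (minv[j] < delta) { delta = minv[j]; j1 = j; }
      }
      for (int j = 0; j <= m; ++j) {
        if (used[j]) { u[p[j]] += delta; v[j] -= delta; }
        else minv[j] -= delta;
      }
      j0 = j1;
    } while (p[j0] != 0);
    do { int j1 = way[j0]; p[j0] = p[j1]; j0 = j1; } while (j0);
  }
  IntegerVector ans(n);
  for (int j = 1; j <= m; ++j)
    if (p[j] > 0) ans[p[j] - 1] = j;
  return ans;
}
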