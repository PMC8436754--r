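#include <Rcpp.h>
#include <vector>
#include <queue>
#include <limits>
#include <cmath>

using namespace Rcpp;

// Exact squared Euclidean distance transform, separable lower-envelope
// algorithm (Felzenszwalb & Huttenlocher), generalised to anisotropic
// sample spacing: samples along one axis sit at positions 0, w, 2w, ...

static const double INF = std::numeric_limits<double>::infinity();

static void dt1d(const double *f, double *d, int n, double w,
                 std::vector<int> &v, std::vector<double> &z) {
  if (n == 1) { d[0] = f[0]; return; }
  int k = 0;
  v[0] = 0;
  z[0] = -INF;
  z[1] = INF;
  for (int q = 1; q < n; q++) {
    if (f[q] == INF) continue;
    double qp = q * w;
    double s;
    for (;;) {
      if (f[v[k]] == INF) {
        // previous parabola is at +infinity: drop it
        if (k == 0) { v[0] = q; z[0] = -INF; z[1] = INF; s = -INF; break; }
        k--;
        continue;
      }
      double vp = v[k] * w;
      s = ((f[q] + qp * qp) - (f[v[k]] + vp * vp)) / (2.0 * qp - 2.0 * vp);
      if (s <= z[k]) {
        if (k == 0) { v[0] = q; z[0] = -INF; z[1] = INF; break; }
        k--;
      } else {
        k++;
        v[k] = q;
        z[k] = s;
        z[k + 1] = INF;
        break;
      }
    }
  }
  // all-infinite row: nothing to envelope
  if (f[v[0]] == INF) {
    for (int q = 0; q < n; q++) d[q] = INF;
    return;
  }
  k = 0;
  for (int q = 0; q < n; q++) {
    double qp = q * w;
    while (z[k + 1] < qp) k++;
    double diff = qp - v[k] * w;
    d[q] = diff * diff + f[v[k]];
  }
}

// [[Rcpp::export]]
NumericVector edt_mm_cpp(LogicalVector mask, IntegerVector dim,
                         NumericVector spacing) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  if (mask.size() != n)
    stop("mask length does not match dim");
  std::vector<double> f(n);
  for (R_xlen_t i = 0; i < n; i++)
    f[i] = (mask[i] == TRUE) ? 0.0 : INF;

  int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> row(nmax), drow(nmax), z(nmax + 1);
  std::vector<int> v(nmax);

  // x axis
  for (int k = 0; k < nz; k++)
    for (int j = 0; j < ny; j++) {
      R_xlen_t base = (R_xlen_t)k * nx * ny + (R_xlen_t)j * nx;
      dt1d(&f[base], &drow[0], nx, spacing[0], v, z);
      for (int i = 0; i < nx; i++) f[base + i] = drow[i];
    }
  // y axis
  for (int k = 0; k < nz; k++)
    for (int i = 0; i < nx; i++) {
      R_xlen_t base = (R_xlen_t)k * nx * ny + i;
      for (int j = 0; j < ny; j++) row[j] = f[base + (R_xlen_t)j * nx];
      dt1d(&row[0], &drow[0], ny, spacing[1], v, z);
      for (int j = 0; j < ny; j++) f[base + (R_xlen_t)j * nx] = drow[j];
    }
  // z axis
  const R_xlen_t nxy = (R_xlen_t)nx * ny;
  for (int j = 0; j < ny; j++)
    for (int i = 0; i < nx; i++) {
      R_xlen_t base = (R_xlen_t)j * nx + i;
      for (int k = 0; k < nz; k++) row[k] = f[base + k * nxy];
      dt1d(&row[0], &drow[0], nz, spacing[2], v, z);
      for (int k = 0; k < nz; k++) f[base + k * nxy] = drow[k];
    }

  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; i++)
    out[i] = std::isinf(f[i]) ? R_PosInf : std::sqrt(f[i]);
  return out;
}

// 6-connected (face-adjacent) component labelling of a binary 3-D lattice.
// [[Rcpp::export]]
IntegerVector label_components_cpp(LogicalVector mask, IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  if (mask.size() != n)
    stop("mask length does not match dim");
  IntegerVector lab(n, 0);
  int next = 0;
  std::vector<R_xlen_t> stack;
  const R_xlen_t nxy = (R_xlen_t)nx * ny;
  for (R_xlen_t s = 0; s < n; s++) {
    if (mask[s] != TRUE || lab[s] != 0) continue;
    next++;
    stack.push_back(s);
    lab[s] = next;
    while (!stack.empty()) {
      R_xlen_t p = stack.back();
      stack.pop_back();
      int i = (int)(p % nx);
      int j = (int)((p / nx) % ny);
      int k = (int)(p / nxy);
      const int di[6] = {-1, 1, 0, 0, 0, 0};
      const int dj[6] = {0, 0, -1, 1, 0, 0};
      const int dk[6] = {0, 0, 0, 0, -1, 1};
      for (int q = 0; q < 6; q++) {
        int ii = i + di[q], jj = j + dj[q], kk = k + dk[q];
        if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 || kk >= nz)
          continue;
        R_xlen_t np = (R_xlen_t)kk * nxy + (R_xlen_t)jj * nx + ii;
        if (mask[np] == TRUE && lab[np] == 0) {
          lab[np] = next;
          stack.push_back(np);
        }
      }
    }
  }
  lab.attr("n_components") = next;
  return lab;
}
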