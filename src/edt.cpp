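#include <Rcpp.h>
#include <vector>
#include <limits>

// Exact Euclidean distance transform (Felzenszwalb & Huttenlocher 2012),
// separable lower-envelope-of-parabolas scheme, generalized to anisotropic
// voxel spacing. Input: a logical 3D source mask; output: squared world-mm
// distance from every voxel center to the nearest source voxel center.

static const double INF = std::numeric_limits<double>::infinity();

// 1-D squared distance transform along one axis with squared step w2.
// f: input costs at n parabola sites; d: output minima.
static void dt1d(const std::vector<double>& f, std::vector<double>& d,
                 std::vector<int>& v, std::vector<double>& z,
                 int n, double w2) {
  int k = -1; // index of rightmost parabola in the lower envelope
  for (int q = 0; q < n; ++q) {
    if (f[q] == INF) continue; // infinite sites never contribute
    double s = 0.0;
    while (k >= 0) {
      s = ((f[q] + w2 * q * q) - (f[v[k]] + w2 * v[k] * v[k])) /
          (2.0 * w2 * (q - v[k]));
      if (s <= z[k]) --k; else break;
    }
    if (k < 0) { k = 0; v[0] = q; z[0] = -INF; }
    else       { ++k; v[k] = q; z[k] = s; }
    z[k + 1] = INF;
  }
  if (k < 0) { // whole line infinite; later passes may still resolve it
    for (int q = 0; q < n; ++q) d[q] = INF;
    return;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    double dq = (double)q - (double)v[k];
    d[q] = w2 * dq * dq + f[v[k]];
  }
}

// [[Rcpp::export(name = ".edt_squared")]]
Rcpp::NumericVector edt_squared(Rcpp::LogicalVector mask,
                                Rcpp::IntegerVector dims,
                                Rcpp::NumericVector spacing) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  Rcpp::NumericVector out(n);
  double* g = REAL(out);
  bool any_src = false;
  for (R_xlen_t i = 0; i < n; ++i) {
    g[i] = mask[i] ? 0.0 : INF;
    if (mask[i]) any_src = true;
  }
  if (!any_src) Rcpp::stop("distance transform source mask is empty");

  int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);

  // x-axis passes (fastest-varying index)
  double w2 = spacing[0] * spacing[0];
  for (int kz = 0; kz < nz; ++kz)
    for (int ky = 0; ky < ny; ++ky) {
      R_xlen_t base = (R_xlen_t)kz * nx * ny + (R_xlen_t)ky * nx;
      for (int i = 0; i < nx; ++i) f[i] = g[base + i];
      dt1d(f, d, v, z, nx, w2);
      for (int i = 0; i < nx; ++i) g[base + i] = d[i];
    }
  // y-axis passes
  w2 = spacing[1] * spacing[1];
  for (int kz = 0; kz < nz; ++kz)
    for (int kx = 0; kx < nx; ++kx) {
      R_xlen_t base = (R_xlen_t)kz * nx * ny + kx;
      for (int j = 0; j < ny; ++j) f[j] = g[base + (R_xlen_t)j * nx];
      dt1d(f, d, v, z, ny, w2);
      for (int j = 0; j < ny; ++j) g[base + (R_xlen_t)j * nx] = d[j];
    }
  // z-axis passes
  w2 = spacing[2] * spacing[2];
  R_xlen_t nxy = (R_xlen_t)nx * ny;
  for (int ky = 0; ky < ny; ++ky)
    for (int kx = 0; kx < nx; ++kx) {
      R_xlen_t base = (R_xlen_t)ky * nx + kx;
      for (int kk = 0; kk < nz; ++kk) f[kk] = g[base + (R_xlen_t)kk * nxy];
      dt1d(f, d, v, z, nz, w2);
      for (int kk = 0; kk < nz; ++kk) g[base + (R_xlen_t)kk * nxy] = d[kk];
    }

  out.attr("dim") = dims;
  return out;
}
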