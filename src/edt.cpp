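#include <Rcpp.h>
#include <vector>
#include <limits>

using namespace Rcpp;

// 1-D squared distance transform (Felzenszwalb & Huttenlocher) with grid step.
// f holds squared distances on input; overwritten with the lower envelope.
static void dt1d(std::vector<double> &f, double step) {
  const int n = (int)f.size();
  if (n == 1) return;
  std::vector<double> d(n), z(n + 1);
  std::vector<int> v(n);
  const double INF = std::numeric_limits<double>::infinity();
  int k = 0;
  v[0] = 0;
  z[0] = -INF;
  z[1] = INF;
  for (int q = 1; q < n; ++q) {
    double qs = q * step;
    double s;
    while (true) {
      double vs = v[k] * step;
      s = ((f[q] + qs * qs) - (f[v[k]] + vs * vs)) / (2.0 * (qs - vs));
      if (s <= z[k]) {
        --k;
      } else {
        break;
      }
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = INF;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    double qs = q * step;
    while (z[k + 1] < qs) ++k;
    double vs = v[k] * step;
    d[q] = (qs - vs) * (qs - vs) + f[v[k]];
  }
  f = d;
}

// [[Rcpp::export(name = ".edt_squared_cpp")]]
NumericVector edt_squared_cpp(LogicalVector sources, IntegerVector dims,
                              NumericVector spacing) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const double BIG = 1e20;  // finite sentinel: Inf breaks the envelope arithmetic
  NumericVector out(nx * ny * nz);
  for (int i = 0; i < out.size(); ++i)
    out[i] = sources[i] ? 0.0 : BIG;

  std::vector<double> line;

  // pass along x
  line.resize(nx);
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y) {
      const int off = y * nx + z * nx * ny;
      for (int x = 0; x < nx; ++x) line[x] = out[off + x];
      dt1d(line, spacing[0]);
      for (int x = 0; x < nx; ++x) out[off + x] = line[x];
    }

  // pass along y
  line.resize(ny);
  for (int z = 0; z < nz; ++z)
    for (int x = 0; x < nx; ++x) {
      const int off = x + z * nx * ny;
      for (int y = 0; y < ny; ++y) line[y] = out[off + y * nx];
      dt1d(line, spacing[1]);
      for (int y = 0; y < ny; ++y) out[off + y * nx] = line[y];
    }

  // pass along z
  line.resize(nz);
  for (int y = 0; y < ny; ++y)
    for (int x = 0; x < nx; ++x) {
      const int off = x + y * nx;
      for (int z = 0; z < nz; ++z) line[z] = out[off + z * nx * ny];
      dt1d(line, spacing[2]);
      for (int z = 0; z < nz; ++z) out[off + z * nx * ny] = line[z];
    }

  return out;
}
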