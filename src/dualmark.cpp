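#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// neighbour offsets for 6/18/26-connectivity on a 3-D grid
static std::vector<int> neighbour_offsets(const IntegerVector& dims,
                                          int connectivity,
                                          std::vector<int>& dx,
                                          std::vector<int>& dy,
                                          std::vector<int>& dz) {
  dx.clear(); dy.clear(); dz.clear();
  for (int a = -1; a <= 1; ++a)
    for (int b = -1; b <= 1; ++b)
      for (int c = -1; c <= 1; ++c) {
        if (a == 0 && b == 0 && c == 0) continue;
        int m = std::abs(a) + std::abs(b) + std::abs(c);
        if (connectivity == 6 && m > 1) continue;
        if (connectivity == 18 && m > 2) continue;
        dx.push_back(a); dy.push_back(b); dz.push_back(c);
      }
  return dx;
}

// [[Rcpp::export]]
List cpp_label_components(LogicalVector mask, IntegerVector dims,
                          int connectivity) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int n = nx * ny * nz;
  if (mask.size() != n) stop("mask length does not match dims");
  std::vector<int> dx, dy, dz;
  neighbour_offsets(dims, connectivity, dx, dy, dz);
  const int nb = (int) dx.size();

  IntegerVector labels(n, 0);
  std::vector<int> sizes;
  std::vector<int> stack;
  int next = 0;
  for (int i = 0; i < n; ++i) {
    if (!mask[i] || labels[i] != 0) continue;
    ++next;
    int sz = 0;
    stack.clear();
    stack.push_back(i);
    labels[i] = next;
    while (!stack.empty()) {
      int v = stack.back(); stack.pop_back();
      ++sz;
      int x = v % nx, y = (v / nx) % ny, z = v / (nx * ny);
      for (int k = 0; k < nb; ++k) {
        int xx = x + dx[k], yy = y + dy[k], zz = z + dz[k];
        if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
          continue;
        int w = xx + nx * (yy + ny * zz);
        if (mask[w] && labels[w] == 0) {
          labels[w] = next;
          stack.push_back(w);
        }
      }
    }
    sizes.push_back(sz);
  }
  return List::create(_["labels"] = labels,
                      _["sizes"] = IntegerVector(sizes.begin(), sizes.end()));
}

// TFCE: sum over thresholds h = dh, 2dh, ..., max of e(h,v)^E * h^H * dh,
// where e(h,v) is the voxel count of the component containing v among
// voxels with stat >= h. Voxels with stat <= 0 get 0.
//
// Implementation processes thresholds from the top down with an
// incremental union-find: a voxel enters at the highest step s with
// stat[v] >= s*dh (the comparison uses the same double arithmetic as a
// direct per-threshold scan, so results match a brute-force
// threshold-label-sum implementation bit-for-bit).
// [[Rcpp::export]]
NumericVector cpp_tfce(NumericVector stat, IntegerVector dims,
                       double E, double H, int n_steps, int connectivity) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int n = nx * ny * nz;
  if (stat.size() != n) stop("stat length does not match dims");
  NumericVector out(n, 0.0);
  double mx = 0.0;
  for (int i = 0; i < n; ++i) if (stat[i] > mx) mx = stat[i];
  if (mx <= 0.0) return out;
  const double dh = mx / n_steps;

  std::vector<int> dx, dy, dz;
  neighbour_offsets(dims, connectivity, dx, dy, dz);
  const int nb = (int) dx.size();

  // entry step: largest s in [1, n_steps] with stat[v] >= s*dh (binary
  // search over the monotone sequence s*dh)
  std::vector<int> entry(n, 0);
  std::vector<int> bucketCount(n_steps + 1, 0);
  for (int i = 0; i < n; ++i) {
    double v = stat[i];
    if (v < dh) continue;
    int lo = 1, hi = n_steps;
    while (lo < hi) {
      int mid = (lo + hi + 1) / 2;
      if (v >= mid * dh) lo = mid; else hi = mid - 1;
    }
    entry[i] = lo;
    ++bucketCount[lo];
  }
  // order voxels by entry step, highest first (counting sort)
  std::vector<int> bucketStart(n_steps + 2, 0);
  for (int s = n_steps - 1; s >= 1; --s)
    bucketStart[s] = bucketStart[s + 1] + bucketCount[s + 1];
  std::vector<int> offs(n_steps + 1, 0);
  std::vector<int> ordered(bucketStart[1] + bucketCount[1]);
  for (int i = 0; i < n; ++i) {
    int s = entry[i];
    if (s == 0) continue;
    ordered[bucketStart[s] + offs[s]++] = i;
  }

  std::vector<int> parent(n, -1), csize(n, 0);
  std::vector<int> stamp(n, -1);
  std::vector<double> cachedPow(n, 0.0);
  // iterative find with path halving
  auto find = [&](int v) {
    while (parent[v] != v) {
      parent[v] = parent[parent[v]];
      v = parent[v];
    }
    return v;
  };

  std::vector<double> hTerm(n_steps + 1);
  for (int s = 1; s <= n_steps; ++s)
    hTerm[s] = std::pow(s * dh, H) * dh;

  int added = 0;
  for (int s = n_steps; s >= 1; --s) {
    // activate voxels entering at this step and union with live neighbours
    int upto = bucketStart[s] + bucketCount[s];
    for (int q = added; q < upto; ++q) {
      int v = ordered[q];
      parent[v] = v;
      csize[v] = 1;
      int x = v % nx, y = (v / nx) % ny, z = v / (nx * ny);
      for (int k = 0; k < nb; ++k) {
        int xx = x + dx[k], yy = y + dy[k], zz = z + dz[k];
        if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
          continue;
        int w = xx + nx * (yy + ny * zz);
        if (parent[w] < 0) continue;
        int rv = find(v), rw = find(w);
        if (rv == rw) continue;
        if (csize[rv] < csize[rw]) std::swap(rv, rw);
        parent[rw] = rv;
        csize[rv] += csize[rw];
      }
    }
    added = upto;
    // accumulate this threshold's contribution for every live voxel
    double ht = hTerm[s];
    for (int q = 0; q < added; ++q) {
      int v = ordered[q];
      int r = find(v);
      if (stamp[r] != s) {
        cachedPow[r] = std::pow((double) csize[r], E);
        stamp[r] = s;
      }
      out[v] += cachedPow[r] * ht;
    }
  }
  return out;
}

// direct-form-II-transposed IIR filter of one column, state initialised
// with zi * x0 (scipy lfilter_zi convention)
static void df2t_filter(const std::vector<double>& b,
                        const std::vector<double>& a,
                        const std::vector<double>& zi,
                        const double* x, double* y, int n) {
  const int m = (int) zi.size();   // filter order
  std::vector<double> z(m);
  for (int j = 0; j < m; ++j) z[j] = zi[j] * x[0];
  for (int i = 0; i < n; ++i) {
    double xi = x[i];
    double yi = b[0] * xi + z[0];
    for (int j = 0; j < m - 1; ++j)
      z[j] = b[j + 1] * xi + z[j + 1] - a[j + 1] * yi;
    z[m - 1] = b[m] * xi - a[m] * yi;
    y[i] = yi;
  }
}

// zero-phase forward-backward filtering along columns with odd-reflection
// padding; b, a already normalised (a[0] == 1), zi per scipy lfilter_zi
// [[Rcpp::export]]
NumericMatrix cpp_filtfilt(NumericVector b, NumericVector a,
                           NumericVector zi, NumericMatrix X, int padlen) {
  const int n = X.nrow(), nc = X.ncol();
  if (padlen >= n) padlen = n - 1;
  if (padlen < 0) padlen = 0;
  const int ne = n + 2 * padlen;
  std::vector<double> bb(b.begin(), b.end()), aa(a.begin(), a.end()),
      zz(zi.begin(), zi.end());
  NumericMatrix out(n, nc);
  std::vector<double> ext(ne), tmp(ne);
  for (int c = 0; c < nc; ++c) {
    const double* x = &X(0, c);
    for (int i = 0; i < padlen; ++i)
      ext[i] = 2.0 * x[0] - x[padlen - i];
    for (int i = 0; i < n; ++i) ext[padlen + i] = x[i];
    for (int i = 0; i < padlen; ++i)
      ext[padlen + n + i] = 2.0 * x[n - 1] - x[n - 2 - i];
    df2t_filter(bb, aa, zz, ext.data(), tmp.data(), ne);
    std::reverse(tmp.begin(), tmp.end());
    df2t_filter(bb, aa, zz, tmp.data(), ext.data(), ne);
    std::reverse(ext.begin(), ext.end());
    for (int i = 0; i < n; ++i) out(i, c) = ext[padlen + i];
  }
  return out;
}
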