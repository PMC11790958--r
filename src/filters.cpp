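#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Disc structuring element: Euclidean ball of the given radius, boundary
// ties (dx^2 + dy^2 == r^2) included.  Shared by the median filter and the
// grayscale morphology so the whole pipeline uses one disc definition.
static void disc_offsets(const int radius, std::vector<int> &dr,
                         std::vector<int> &dc) {
  const double r2 = static_cast<double>(radius) * radius;
  for (int i = -radius; i <= radius; ++i)
    for (int j = -radius; j <= radius; ++j)
      if (static_cast<double>(i) * i + static_cast<double>(j) * j <= r2) {
        dr.push_back(i);
        dc.push_back(j);
      }
}

// reflect index into [0, n-1] (mirror without repeating the edge sample,
// scipy-style "reflect" i.e. (d c b a | a b c d | d c b a))
static inline int reflect(int i, const int n) {
  if (n == 1) return 0;
  const int period = 2 * n;
  i %= period;
  if (i < 0) i += period;
  return (i < n) ? i : period - 1 - i;
}

// [[Rcpp::export(name = ".disc_median_cpp")]]
NumericMatrix disc_median_cpp(const NumericMatrix x, const int radius) {
  const int nr = x.nrow(), nc = x.ncol();
  if (radius <= 0) return clone(x);
  std::vector<int> dr, dc;
  disc_offsets(radius, dr, dc);
  const int k = static_cast<int>(dr.size());
  NumericMatrix out(nr, nc);
  std::vector<double> buf(k);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      for (int m = 0; m < k; ++m)
        buf[m] = x(reflect(i + dr[m], nr), reflect(j + dc[m], nc));
      const int mid = k / 2;
      std::nth_element(buf.begin(), buf.begin() + mid, buf.end());
      double med = buf[mid];
      if (k % 2 == 0) {
        std::nth_element(buf.begin(), buf.begin() + mid - 1,
                         buf.begin() + mid);
        med = 0.5 * (med + buf[mid - 1]);
      }
      out(i, j) = med;
    }
  }
  return out;
}

// Grayscale erosion/dilation over the disc, neighbourhood clipped to the
// image domain (no padding value is ever introduced).
static NumericMatrix morph(const NumericMatrix x, const int radius,
                           const bool erode) {
  const int nr = x.nrow(), nc = x.ncol();
  std::vector<int> dr, dc;
  disc_offsets(radius, dr, dc);
  const int k = static_cast<int>(dr.size());
  NumericMatrix out(nr, nc);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      double v = erode ? R_PosInf : R_NegInf;
      for (int m = 0; m < k; ++m) {
        const int ii = i + dr[m], jj = j + dc[m];
        if (ii < 0 || ii >= nr || jj < 0 || jj >= nc) continue;
        const double z = x(ii, jj);
        v = erode ? std::min(v, z) : std::max(v, z);
      }
      out(i, j) = v;
    }
  }
  return out;
}

// [[Rcpp::export(name = ".disc_erode_cpp")]]
NumericMatrix disc_erode_cpp(const NumericMatrix x, const int radius) {
  return morph(x, radius, true);
}

// [[Rcpp::export(name = ".disc_dilate_cpp")]]
NumericMatrix disc_dilate_cpp(const NumericMatrix x, const int radius) {
  return morph(x, radius, false);
}
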