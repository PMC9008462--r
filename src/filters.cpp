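#include <Rcpp.h>
using namespace Rcpp;

// mirror (reflect) index: d c b a | a b c d
static inline int reflect(int i, int n) {
  if (n == 1) return 0;
  while (i < 0 || i >= n) {
    if (i < 0) i = -i - 1;
    if (i >= n) i = 2 * n - i - 1;
  }
  return i;
}

static std::vector<double> gauss_kernel(double sigma) {
  int r = (int)std::ceil(3.0 * sigma);
  if (r < 1) r = 1;
  std::vector<double> k(2 * r + 1);
  double s = 0.0;
  for (int i = -r; i <= r; ++i) {
    k[i + r] = std::exp(-0.5 * (double)i * i / (sigma * sigma));
    s += k[i + r];
  }
  for (double& w : k) w /= s;
  return k;
}

// separable Gaussian blur with mirror boundary handling; boundary pixels
// use reflected indices, interior pixels run on a branch-free fast path
// [[Rcpp::export(name = ".gauss_blur_cpp")]]
NumericMatrix gauss_blur_cpp(NumericMatrix img, double sigma) {
  int nr = img.nrow(), nc = img.ncol();
  std::vector<double> k = gauss_kernel(sigma);
  int r = ((int)k.size() - 1) / 2;
  NumericMatrix tmp(nr, nc), out(nr, nc);
  const double* kp = k.data();
  // along rows (vertical, contiguous in memory)
  for (int j = 0; j < nc; ++j) {
    const double* col = &img(0, j);
    double* dst = &tmp(0, j);
    int lo = std::min(r, nr), hi = std::max(nr - r, lo);
    for (int i = 0; i < lo; ++i) {
      double s = 0.0;
      for (int d = -r; d <= r; ++d) s += kp[d + r] * col[reflect(i + d, nr)];
      dst[i] = s;
    }
    for (int i = lo; i < hi; ++i) {
      double s = 0.0;
      const double* p = col + i - r;
      for (int d = 0; d <= 2 * r; ++d) s += kp[d] * p[d];
      dst[i] = s;
    }
    for (int i = hi; i < nr; ++i) {
      double s = 0.0;
      for (int d = -r; d <= r; ++d) s += kp[d + r] * col[reflect(i + d, nr)];
      dst[i] = s;
    }
  }
  // along columns (horizontal, stride nr)
  for (int j = 0; j < nc; ++j) {
    bool interior = (j >= r) && (j < nc - r);
    double* dst = &out(0, j);
    if (interior) {
      const double* base = &tmp(0, j - r);
      for (int i = 0; i < nr; ++i) {
        double s = 0.0;
        const double* p = base + i;
        for (int d = 0; d <= 2 * r; ++d) s += kp[d] * p[(R_xlen_t)d * nr];
        dst[i] = s;
      }
    } else {
      for (int i = 0; i < nr; ++i) {
        double s = 0.0;
        for (int d = -r; d <= r; ++d) s += kp[d + r] * tmp(i, reflect(j + d, nc));
        dst[i] = s;
      }
    }
  }
  return out;
}

// strict 8-neighbour local maxima above threshold; on a tied plateau the
// smallest (row, col) pixel wins: require strictly greater than neighbours
// that precede the pixel in column-major (row, col) order, >= for the rest.
// [[Rcpp::export(name = ".local_maxima_cpp")]]
DataFrame local_maxima_cpp(NumericMatrix img, double threshold) {
  int nr = img.nrow(), nc = img.ncol();
  std::vector<int> rows, cols;
  std::vector<double> vals;
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      double v = img(i, j);
      if (!(v > threshold)) continue;
      bool ok = true;
      for (int dj = -1; dj <= 1 && ok; ++dj)
        for (int di = -1; di <= 1 && ok; ++di) {
          if (di == 0 && dj == 0) continue;
          int ii = i + di, jj = j + dj;
          if (ii < 0 || ii >= nr || jj < 0 || jj >= nc) continue;
          double w = img(ii, jj);
          bool precedes = (jj < j) || (jj == j && ii < i);
          if (precedes ? (w >= v) : (w > v)) ok = false;
        }
      if (ok) { rows.push_back(i + 1); cols.push_back(j + 1); vals.push_back(v); }
    }
  return DataFrame::create(_["row"] = rows, _["col"] = cols, _["response"] = vals);
}
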