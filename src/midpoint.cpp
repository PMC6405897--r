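#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Diamond-square midpoint displacement without random additions. The grid
// has side 2^levels + 1; corners start from standard normals; at level l
// both the diamond and square steps perturb with sd (1/2)^(l*H). Edge
// midpoints average their 3 in-grid axial neighbours. Uses R's RNG so the
// surface is reproducible from set.seed().

// [[Rcpp::export]]
NumericMatrix midpoint_displacement_cpp(double hurst, int levels) {
  const int n = (1 << levels) + 1;
  NumericMatrix v(n, n);
  RNGScope scope;
  v(0, 0) = norm_rand();
  v(n - 1, 0) = norm_rand();
  v(0, n - 1) = norm_rand();
  v(n - 1, n - 1) = norm_rand();

  for (int l = 1; l <= levels; ++l) {
    const int half = 1 << (levels - l);
    const int step = 2 * half;
    const double sd = std::pow(0.5, l * hurst);

    // diamond step: cell centres from the four diagonal corners
    for (int j = half; j < n; j += step)
      for (int i = half; i < n; i += step)
        v(i, j) = 0.25 * (v(i - half, j - half) + v(i - half, j + half) +
                          v(i + half, j - half) + v(i + half, j + half)) +
                  norm_rand() * sd;

    // square step: edge midpoints from 3-4 axial neighbours
    // pattern A: corner columns, centre rows; pattern B: centre columns,
    // corner rows
    for (int pass = 0; pass < 2; ++pass) {
      const int i0 = (pass == 0) ? half : 0;
      const int j0 = (pass == 0) ? 0 : half;
      for (int j = j0; j < n; j += step) {
        for (int i = i0; i < n; i += step) {
          double s = 0.0;
          int k = 0;
          if (i - half >= 0) { s += v(i - half, j); ++k; }
          if (i + half < n)  { s += v(i + half, j); ++k; }
          if (j - half >= 0) { s += v(i, j - half); ++k; }
          if (j + half < n)  { s += v(i, j + half); ++k; }
          v(i, j) = s / k + norm_rand() * sd;
        }
      }
    }
  }
  return v;
}
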