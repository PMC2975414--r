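#include <Rcpp.h>
using namespace Rcpp;

// Symmetric (half-sample) reflection: -1 -> 0, n -> n-1.
// Valid while the overshoot is < n, which parameter validation guarantees
// (half_width < min(H, W)).
static inline int reflect(int i, int n) {
  if (i < 0) i = -i - 1;
  if (i >= n) i = 2 * n - 1 - i;
  return i;
}

//' @title Single bilateral-filter pass (compiled kernel)
//' @description Internal workhorse: one pass of the Gaussian bilateral filter
//'   over a matrix, with either the conventional absolute-intensity range
//'   distance or the speckle-reducing centre-normalized range distance.
//'   Boundaries are handled by symmetric reflection.
//' @noRd
// [[Rcpp::export]]
NumericMatrix bilateral_pass_cpp(const NumericMatrix& img,
                                 double sigma_d, double sigma_r,
                                 int half_width, bool normalized,
                                 double epsilon) {
  const int H = img.nrow(), W = img.ncol(), h = half_width;
  const int w = 2 * h + 1;
  NumericMatrix out(H, W);

  // spatial kernel, precomputed once
  std::vector<double> spatial(w * w);
  const double inv2sd2 = 1.0 / (2.0 * sigma_d * sigma_d);
  for (int dy = -h; dy <= h; ++dy)
    for (int dx = -h; dx <= h; ++dx)
      spatial[(dy + h) * w + (dx + h)] =
        std::exp(-(double)(dy * dy + dx * dx) * inv2sd2);

  const double inv2sr2 = 1.0 / (2.0 * sigma_r * sigma_r); // 0 when sigma_r = Inf

  for (int c = 0; c < W; ++c) {
    for (int r = 0; r < H; ++r) {
      const double centre = img(r, c);
      const double scale = normalized ?
        1.0 / std::max(std::abs(centre), epsilon) : 1.0;
      double num = 0.0, den = 0.0;
      for (int dx = -h; dx <= h; ++dx) {
        const int cc = reflect(c + dx, W);
        for (int dy = -h; dy <= h; ++dy) {
          const int rr = reflect(r + dy, H);
          const double val = img(rr, cc);
          double d = (val - centre) * scale;
          double wgt = spatial[(dy + h) * w + (dx + h)] *
            std::exp(-d * d * inv2sr2);
          num += wgt * val;
          den += wgt;
        }
      }
      out(r, c) = num / den;
    }
  }
  return out;
}
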