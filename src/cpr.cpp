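#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Images are height x width matrices; pixel (x, y) is img(y, x), 0-based.
// Out-of-bounds samples are clamped to the nearest pixel.

static inline double sampleClamped(const double *img, int h, int w,
                                   double x, double y) {
  int xi = (int)std::floor(x + 0.5);
  int yi = (int)std::floor(y + 0.5);
  if (xi < 0) xi = 0;
  if (yi < 0) yi = 0;
  if (xi >= w) xi = w - 1;
  if (yi >= h) yi = h - 1;
  return img[yi + (size_t)h * xi];
}

// Pose-indexed feature pool for a set of (image, pose) samples.
// imgIdx: 0-based index into images; poses: N x 2 (x, y);
// pool: P x 4 offsets (ax, ay, bx, by). Returns N x P intensity differences.
// [[Rcpp::export(name = ".cprPoolFeatures")]]
NumericMatrix cprPoolFeatures(List images, IntegerVector imgIdx,
                              NumericMatrix poses, NumericMatrix pool) {
  int n = poses.nrow(), p = pool.nrow();
  NumericMatrix out(n, p);
  for (int i = 0; i < n; ++i) {
    NumericMatrix img = images[imgIdx[i]];
    const double *ptr = img.begin();
    int h = img.nrow(), w = img.ncol();
    double x = poses(i, 0), y = poses(i, 1);
    for (int j = 0; j < p; ++j) {
      out(i, j) = sampleClamped(ptr, h, w, x + pool(j, 0), y + pool(j, 1)) -
                  sampleClamped(ptr, h, w, x + pool(j, 2), y + pool(j, 3));
    }
  }
  return out;
}

// Run the full fern cascade on one image from a set of initial poses.
// offsets:    [4, depth, nFerns, nStages] (ax, ay, bx, by)
// thresholds: [depth, nFerns, nStages]
// outputs:    [2, 2^depth, nFerns, nStages] (dx, dy)
// The initialization loop is innermost so each fern's parameters are read
// once per frame. Poses are clamped to the image bounds after every stage.
// [[Rcpp::export(name = ".cprApplyCascade")]]
NumericMatrix cprApplyCascade(NumericMatrix image, NumericMatrix inits,
                              NumericVector offsets, NumericVector thresholds,
                              NumericVector outputs, int nStages, int nFerns,
                              int depth) {
  int k = inits.nrow();
  int nbins = 1 << depth;
  int h = image.nrow(), w = image.ncol();
  const double *img = image.begin();
  double wmax = w - 1.0, hmax = h - 1.0;
  std::vector<double> x(k), y(k);
  for (int i = 0; i < k; ++i) { x[i] = inits(i, 0); y[i] = inits(i, 1); }
  const double *off = offsets.begin();
  const double *thr = thresholds.begin();
  const double *out = outputs.begin();
  for (int s = 0; s < nStages; ++s) {
    for (int f = 0; f < nFerns; ++f) {
      const double *offF = off + 4 * (size_t)depth * (f + (size_t)nFerns * s);
      const double *thrF = thr + (size_t)depth * (f + (size_t)nFerns * s);
      const double *outF = out + 2 * (size_t)nbins * (f + (size_t)nFerns * s);
      for (int i = 0; i < k; ++i) {
        int bin = 0;
        double xi = x[i], yi = y[i];
        for (int d = 0; d < depth; ++d) {
          double v = sampleClamped(img, h, w, xi + offF[4 * d], yi + offF[4 * d + 1]) -
                     sampleClamped(img, h, w, xi + offF[4 * d + 2], yi + offF[4 * d + 3]);
          if (v > thrF[d]) bin |= (1 << d);
        }
        x[i] += outF[2 * bin];
        y[i] += outF[2 * bin + 1];
      }
    }
    for (int i = 0; i < k; ++i) {
      if (x[i] < 0) x[i] = 0;
      if (y[i] < 0) y[i] = 0;
      if (x[i] > wmax) x[i] = wmax;
      if (y[i] > hmax) y[i] = hmax;
    }
  }
  NumericMatrix pose(k, 2);
  for (int i = 0; i < k; ++i) { pose(i, 0) = x[i]; pose(i, 1) = y[i]; }
  return pose;
}
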