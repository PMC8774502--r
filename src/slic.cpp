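#include <Rcpp.h>
#include <cmath>
#include <limits>
using namespace Rcpp;

// SLIC superpixels on an H x W x 3 RGB image (intensities in [0,1]).
// Deterministic: cluster centres are initialised on a regular grid and
// updated with plain Lloyd iterations restricted to a 2S window, following
// the original algorithm. Colour distances are computed on a 0-255 scale so
// the conventional compactness values (~10) balance colour and space.
//
// Returns an H x W integer matrix of 1-based superpixel labels.
// [[Rcpp::export]]
IntegerMatrix slic_cpp(NumericVector image, int h, int w,
                       int n_superpixels, double compactness,
                       int iterations) {
  const int n = h * w;
  const double *r = image.begin();
  const double *g = image.begin() + n;
  const double *b = image.begin() + 2 * n;

  double S = std::sqrt((double)n / (double)n_superpixels);
  int per_row = std::max(1, (int)std::round((double)w / S));
  int per_col = std::max(1, (int)std::round((double)h / S));
  int k = per_row * per_col;

  std::vector<double> cx(k), cy(k), cr(k), cg(k), cb(k);
  int idx = 0;
  for (int j = 0; j < per_col; ++j) {
    for (int i = 0; i < per_row; ++i, ++idx) {
      double x = (i + 0.5) * w / per_row;
      double y = (j + 0.5) * h / per_col;
      int xi = std::min(w - 1, std::max(0, (int)x));
      int yi = std::min(h - 1, std::max(0, (int)y));
      cx[idx] = x; cy[idx] = y;
      int p = xi * h + yi; // column-major
      cr[idx] = r[p] * 255.0; cg[idx] = g[p] * 255.0; cb[idx] = b[p] * 255.0;
    }
  }

  std::vector<int> label(n, -1);
  std::vector<double> dist(n);
  double invS2 = (compactness * compactness) / (S * S);
  int win = (int)std::ceil(2.0 * S);

  for (int it = 0; it < iterations; ++it) {
    std::fill(dist.begin(), dist.end(), std::numeric_limits<double>::max());
    for (int c = 0; c < k; ++c) {
      int x0 = std::max(0, (int)cx[c] - win), x1 = std::min(w - 1, (int)cx[c] + win);
      int y0 = std::max(0, (int)cy[c] - win), y1 = std::min(h - 1, (int)cy[c] + win);
      for (int x = x0; x <= x1; ++x) {
        for (int y = y0; y <= y1; ++y) {
          int p = x * h + y;
          double dr = r[p] * 255.0 - cr[c];
          double dg = g[p] * 255.0 - cg[c];
          double db = b[p] * 255.0 - cb[c];
          double dx = x + 0.5 - cx[c];
          double dy = y + 0.5 - cy[c];
          double d = dr * dr + dg * dg + db * db + (dx * dx + dy * dy) * invS2;
          if (d < dist[p]) { dist[p] = d; label[p] = c; }
        }
      }
    }
    std::vector<double> sx(k, 0), sy(k, 0), sr(k, 0), sg(k, 0), sb(k, 0);
    std::vector<int> cnt(k, 0);
    for (int x = 0; x < w; ++x) {
      for (int y = 0; y < h; ++y) {
        int p = x * h + y;
        int c = label[p];
        if (c < 0) continue;
        sx[c] += x + 0.5; sy[c] += y + 0.5;
        sr[c] += r[p] * 255.0; sg[c] += g[p] * 255.0; sb[c] += b[p] * 255.0;
        cnt[c]++;
      }
    }
    for (int c = 0; c < k; ++c) {
      if (cnt[c] == 0) continue;
      cx[c] = sx[c] / cnt[c]; cy[c] = sy[c] / cnt[c];
      cr[c] = sr[c] / cnt[c]; cg[c] = sg[c] / cnt[c]; cb[c] = sb[c] / cnt[c];
    }
  }

  // orphan pixels (possible if a centre drifted away): nearest centre globally
  for (int p = 0; p < n; ++p) {
    if (label[p] >= 0) continue;
    int x = p / h, y = p % h;
    double best = std::numeric_limits<double>::max();
    for (int c = 0; c < k; ++c) {
      double dx = x + 0.5 - cx[c], dy = y + 0.5 - cy[c];
      double d = dx * dx + dy * dy;
      if (d < best) { best = d; label[p] = c; }
    }
  }

  IntegerMatrix out(h, w);
  for (int x = 0; x < w; ++x)
    for (int y = 0; y < h; ++y)
      out(y, x) = label[x * h + y] + 1;
  return out;
}
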