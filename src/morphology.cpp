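#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Grayscale erosion/dilation with a non-flat spherical ("rolling ball")
// structuring element. Height profile b(d) = scale * sqrt(r^2 - d^2) for
// d <= r. Out-of-bounds neighbours are ignored (treated as +Inf for
// erosion, -Inf for dilation), which keeps opening(I) <= I everywhere
// including at image borders. The image is embedded in a padded buffer so
// the inner loop needs no bounds checks.
static NumericMatrix ball_filter(const NumericMatrix& img, double radius,
                                 double height_scale, bool erode) {
  const int nr = img.nrow(), nc = img.ncol();
  const int r = (int)std::floor(radius);
  const int pr = nr + 2 * r;

  std::vector<int> off;
  std::vector<double> h;
  for (int j = -r; j <= r; ++j) {
    for (int i = -r; i <= r; ++i) {
      double d2 = (double)i * i + (double)j * j;
      if (d2 <= radius * radius) {
        off.push_back(j * pr + i);
        h.push_back(height_scale * std::sqrt(radius * radius - d2));
      }
    }
  }
  const int nk = (int)h.size();

  const double fill = erode ? R_PosInf : R_NegInf;
  std::vector<double> pad((size_t)pr * (nc + 2 * r), fill);
  for (int x = 0; x < nc; ++x)
    for (int y = 0; y < nr; ++y)
      pad[(size_t)(x + r) * pr + (y + r)] = img(y, x);

  NumericMatrix out(nr, nc);
  const int* poff = off.data();
  const double* ph = h.data();
  for (int x = 0; x < nc; ++x) {
    const double* centre = pad.data() + (size_t)(x + r) * pr + r;
    for (int y = 0; y < nr; ++y) {
      const double* c = centre + y;
      double acc = fill;
      if (erode) {
        for (int k = 0; k < nk; ++k) {
          double v = c[poff[k]] - ph[k];
          if (v < acc) acc = v;
        }
      } else {
        for (int k = 0; k < nk; ++k) {
          double v = c[poff[k]] + ph[k];
          if (v > acc) acc = v;
        }
      }
      out(y, x) = acc;
    }
  }
  return out;
}

// [[Rcpp::export(name = ".ball_opening")]]
NumericMatrix ball_opening(NumericMatrix img, double radius,
                           double height_scale) {
  NumericMatrix ero = ball_filter(img, radius, height_scale, true);
  return ball_filter(ero, radius, height_scale, false);
}

// Sizes of 8-connected components of a logical mask. Returns an integer
// vector of component pixel counts.
// [[Rcpp::export(name = ".component_sizes")]]
IntegerVector component_sizes(LogicalMatrix mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  std::vector<int> label(nr * nc, 0);
  std::vector<int> sizes;
  std::vector<int> stack;
  int next = 0;
  for (int x = 0; x < nc; ++x) {
    for (int y = 0; y < nr; ++y) {
      int idx = x * nr + y;
      if (!mask(y, x) || label[idx]) continue;
      ++next;
      int count = 0;
      stack.push_back(idx);
      label[idx] = next;
      while (!stack.empty()) {
        int cur = stack.back();
        stack.pop_back();
        ++count;
        int cy = cur % nr, cx = cur / nr;
        for (int jj = -1; jj <= 1; ++jj) {
          for (int ii = -1; ii <= 1; ++ii) {
            if (ii == 0 && jj == 0) continue;
            int yy = cy + ii, xx = cx + jj;
            if (yy < 0 || yy >= nr || xx < 0 || xx >= nc) continue;
            int nidx = xx * nr + yy;
            if (mask(yy, xx) && !label[nidx]) {
              label[nidx] = next;
              stack.push_back(nidx);
            }
          }
        }
      }
      sizes.push_back(count);
    }
  }
  return wrap(sizes);
}
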