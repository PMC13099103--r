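#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Per-pixel disc coverage counts via row-wise run-length accumulation:
// every (point, disc row) contributes one contiguous pixel span, recorded
// in a difference array and resolved by a per-row prefix sum. Points are
// pre-snapped integer pixel centers; a pixel belongs to the disc when
// dx^2 + dy^2 <= r^2 (centers on the circle included). Discs are
// truncated at the field border. Pixel (px, py) maps to index
// px + (py - 1) * width (1-based).
// [[Rcpp::export(name = ".disc_coverage_cpp")]]
IntegerVector disc_coverage(IntegerVector ix, IntegerVector iy, double r,
                            int width, int height) {
  const R_xlen_t npt = ix.size();
  const R_xlen_t total = (R_xlen_t) width * height;
  IntegerVector counts(total);
  int* d = INTEGER(counts);
  const int ri = (int) std::floor(r);
  const double r2 = r * r;
  // half-width of the disc at each row offset, consistent with the
  // integer stencil dx^2 + dy^2 <= r^2
  std::vector<int> hw(2 * ri + 1);
  for (int dy = -ri; dy <= ri; ++dy) {
    int w = (int) std::floor(std::sqrt(std::max(0.0, r2 - (double) dy * dy)));
    while ((double)(w + 1) * (w + 1) + (double) dy * dy <= r2) ++w;
    while (w > 0 && (double) w * w + (double) dy * dy > r2) --w;
    hw[dy + ri] = w;
  }
  for (R_xlen_t p = 0; p < npt; ++p) {
    const int cx = ix[p], cy = iy[p];
    const int y0 = std::max(1, cy - ri), y1 = std::min(height, cy + ri);
    for (int py = y0; py <= y1; ++py) {
      const int w = hw[py - cy + ri];
      const int xs = std::max(1, cx - w), xe = std::min(width, cx + w);
      if (xs > xe) continue;
      const R_xlen_t row = (R_xlen_t)(py - 1) * width;
      d[row + xs - 1] += 1;
      if (xe < width) d[row + xe] -= 1;
    }
  }
  for (int py = 0; py < height; ++py) {
    const R_xlen_t row = (R_xlen_t) py * width;
    int acc = 0;
    for (int px = 0; px < width; ++px) {
      acc += d[row + px];
      d[row + px] = acc;
    }
  }
  return counts;
}

// intersection and union pixel counts of two coverage fields
// [[Rcpp::export(name = ".jaccard_counts_cpp")]]
IntegerVector jaccard_counts(IntegerVector ci, IntegerVector cj) {
  const R_xlen_t n = ci.size();
  const int* a = INTEGER(ci);
  const int* b = INTEGER(cj);
  R_xlen_t inter = 0, uni = 0;
  for (R_xlen_t k = 0; k < n; ++k) {
    const bool ba = a[k] > 0, bb = b[k] > 0;
    inter += (ba && bb);
    uni += (ba || bb);
  }
  return IntegerVector::create((int) inter, (int) uni);
}

// pixels covered at least once and at least twice
// [[Rcpp::export(name = ".coverage_tally_cpp")]]
IntegerVector coverage_tally(IntegerVector counts) {
  const R_xlen_t n = counts.size();
  const int* a = INTEGER(counts);
  R_xlen_t hit = 0, multi = 0;
  for (R_xlen_t k = 0; k < n; ++k) {
    hit += (a[k] > 0);
    multi += (a[k] > 1);
  }
  return IntegerVector::create((int) hit, (int) multi);
}
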