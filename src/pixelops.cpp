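#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// 8-connected component labeling of a logical mask by iterative flood fill.
// Returns an integer matrix: 0 = background, 1..k = component ids
// (ids assigned in raster scan order of each component's first pixel).
// [[Rcpp::export(name = ".cpp_label_components")]]
IntegerMatrix cpp_label_components(LogicalMatrix mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  int next_id = 0;
  std::vector<int> stack;
  stack.reserve(1024);
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (!mask(r, c) || lab(r, c) != 0) continue;
      ++next_id;
      lab(r, c) = next_id;
      stack.push_back(r + c * nr);
      while (!stack.empty()) {
        int idx = stack.back();
        stack.pop_back();
        int rr = idx % nr, cc = idx / nr;
        for (int dc = -1; dc <= 1; ++dc) {
          int c2 = cc + dc;
          if (c2 < 0 || c2 >= nc) continue;
          for (int dr = -1; dr <= 1; ++dr) {
            int r2 = rr + dr;
            if (r2 < 0 || r2 >= nr || (dr == 0 && dc == 0)) continue;
            if (mask(r2, c2) && lab(r2, c2) == 0) {
              lab(r2, c2) = next_id;
              stack.push_back(r2 + c2 * nr);
            }
          }
        }
      }
    }
  }
  return lab;
}

// Geodesic binary reconstruction of `seed` inside `mask` by alternating
// forward/backward raster sweeps with 8-connectivity. One "sweep" is a
// forward plus a backward pass; sweeps stop early at convergence, so
// `max_sweeps` is a safety cap (monotone curves converge in 2-3 sweeps).
// [[Rcpp::export(name = ".cpp_grow_selection")]]
LogicalMatrix cpp_grow_selection(LogicalMatrix mask, LogicalMatrix seed,
                                 int max_sweeps) {
  const int nr = mask.nrow(), nc = mask.ncol();
  LogicalMatrix sel(nr, nc);
  for (int i = 0; i < nr * nc; ++i) sel[i] = seed[i] && mask[i];
  auto scan_nbr = [&](int r, int c, bool forward) -> bool {
    // neighbors already visited in this pass direction
    for (int dc = -1; dc <= 1; ++dc) {
      for (int dr = -1; dr <= 1; ++dr) {
        if (dr == 0 && dc == 0) continue;
        bool before = forward ? (dc < 0 || (dc == 0 && dr < 0))
                              : (dc > 0 || (dc == 0 && dr > 0));
        if (!before) continue;
        int r2 = r + dr, c2 = c + dc;
        if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
        if (sel(r2, c2)) return true;
      }
    }
    return false;
  };
  for (int sweep = 0; sweep < max_sweeps; ++sweep) {
    bool changed = false;
    for (int c = 0; c < nc; ++c)
      for (int r = 0; r < nr; ++r)
        if (mask(r, c) && !sel(r, c) && scan_nbr(r, c, true)) {
          sel(r, c) = true; changed = true;
        }
    for (int c = nc - 1; c >= 0; --c)
      for (int r = nr - 1; r >= 0; --r)
        if (mask(r, c) && !sel(r, c) && scan_nbr(r, c, false)) {
          sel(r, c) = true; changed = true;
        }
    if (!changed) break;
  }
  return sel;
}

// 3x3 median filter with edge replication (each out-of-range neighbor is
// replaced by the nearest in-range pixel, so corner/edge windows still hold
// 9 values).
// [[Rcpp::export(name = ".cpp_median3x3")]]
NumericMatrix cpp_median3x3(NumericMatrix x) {
  const int nr = x.nrow(), nc = x.ncol();
  NumericMatrix out(nr, nc);
  double w[9];
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      int k = 0;
      for (int dc = -1; dc <= 1; ++dc) {
        int c2 = c + dc;
        if (c2 < 0) c2 = 0; else if (c2 >= nc) c2 = nc - 1;
        for (int dr = -1; dr <= 1; ++dr) {
          int r2 = r + dr;
          if (r2 < 0) r2 = 0; else if (r2 >= nr) r2 = nr - 1;
          w[k++] = x(r2, c2);
        }
      }
      // median of 9 by partial selection
      std::nth_element(w, w + 4, w + 9);
      out(r, c) = w[4];
    }
  }
  return out;
}
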