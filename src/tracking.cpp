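#include <Rcpp.h>
using namespace Rcpp;

// 4-connected component labelling; keeps the largest component among
// those touching the seed columns (1-based); if no component touches
// them (or seed_cols is empty), the globally largest is kept.
// [[Rcpp::export]]
LogicalMatrix keep_largest_component(LogicalMatrix mask,
                                     IntegerVector seed_cols) {
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerVector lab(nr * nc, 0);
  std::vector<int> area(1, 0);
  std::vector<int> stack;
  int next = 0;
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      int p0 = i + j * nr;
      if (!mask[p0] || lab[p0] != 0) continue;
      ++next;
      int a = 0;
      lab[p0] = next;
      stack.push_back(p0);
      while (!stack.empty()) {
        int p = stack.back();
        stack.pop_back();
        ++a;
        int pi = p % nr, pj = p / nr;
        if (pi > 0 && mask[p - 1] && lab[p - 1] == 0) {
          lab[p - 1] = next; stack.push_back(p - 1);
        }
        if (pi < nr - 1 && mask[p + 1] && lab[p + 1] == 0) {
          lab[p + 1] = next; stack.push_back(p + 1);
        }
        if (pj > 0 && mask[p - nr] && lab[p - nr] == 0) {
          lab[p - nr] = next; stack.push_back(p - nr);
        }
        if (pj < nc - 1 && mask[p + nr] && lab[p + nr] == 0) {
          lab[p + nr] = next; stack.push_back(p + nr);
        }
      }
      area.push_back(a);
    }
  }
  std::vector<bool> seeded(next + 1, false);
  bool any_seed = false;
  for (int k = 0; k < seed_cols.size(); ++k) {
    int j = seed_cols[k] - 1;
    if (j < 0 || j >= nc) continue;
    for (int i = 0; i < nr; ++i) {
      int l = lab[i + j * nr];
      if (l > 0) { seeded[l] = true; any_seed = true; }
    }
  }
  int best = 0, best_area = 0;
  for (int l = 1; l <= next; ++l) {
    if (any_seed && !seeded[l]) continue;
    if (area[l] > best_area) { best_area = area[l]; best = l; }
  }
  LogicalMatrix out(nr, nc);
  for (int p = 0; p < nr * nc; ++p) out[p] = (lab[p] == best);
  return out;
}

// Per-column beam extent and subpixel midline. Returns an nc x 4 matrix:
// top edge, bottom edge, midline (1-based, subpixel rows) and an ok flag
// (0 = empty or non-contiguous column). Edges are refined by linear
// interpolation of the grayscale threshold crossing when `gray` has the
// same shape as `mask`.
// [[Rcpp::export]]
NumericMatrix column_edges(LogicalMatrix mask, NumericMatrix gray,
                           double thresh) {
  int nr = mask.nrow(), nc = mask.ncol();
  bool use_gray = (gray.nrow() == nr && gray.ncol() == nc);
  NumericMatrix out(nc, 4);
  for (int j = 0; j < nc; ++j) {
    int i0 = -1, i1 = -1;
    for (int i = 0; i < nr; ++i) {
      if (mask(i, j)) { if (i0 < 0) i0 = i; i1 = i; }
    }
    if (i0 < 0) { out(j, 3) = 0; continue; }
    bool contiguous = true;
    for (int i = i0; i <= i1; ++i)
      if (!mask(i, j)) { contiguous = false; break; }
    if (!contiguous) { out(j, 3) = 0; continue; }
    double top = i0 + 1.0, bot = i1 + 1.0;   // 1-based centres
    double mid = 0.5 * (top + bot);
    if (use_gray) {
      // subpixel edges: linear interpolation of the threshold crossing
      if (i0 > 0) {
        double g1 = gray(i0, j), g0 = gray(i0 - 1, j);
        if (g1 > g0) {
          double f = (g1 - thresh) / (g1 - g0);
          if (f < 0) f = 0; if (f > 1) f = 1;
          top = i0 + 1.0 - f;
        }
      }
      if (i1 < nr - 1) {
        double g1 = gray(i1, j), g0 = gray(i1 + 1, j);
        if (g1 > g0) {
          double f = (g1 - thresh) / (g1 - g0);
          if (f < 0) f = 0; if (f > 1) f = 1;
          bot = i1 + 1.0 + f;
        }
      }
      // midline: intensity-weighted centroid over the band plus a 2-px
      // apron; exact for the symmetric anti-aliased silhouette profile
      int lo = i0 - 2; if (lo < 0) lo = 0;
      int hi = i1 + 2; if (hi > nr - 1) hi = nr - 1;
      double s = 0.0, sy = 0.0;
      for (int i = lo; i <= hi; ++i) {
        double g = gray(i, j);
        s += g;
        sy += g * (i + 1.0);
      }
      if (s > 0) mid = sy / s;
    }
    out(j, 0) = top;
    out(j, 1) = bot;
    out(j, 2) = mid;
    out(j, 3) = 1;
  }
  return out;
}
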