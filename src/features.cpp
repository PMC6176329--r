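#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Summed-area table with a zero-padded first row/column:
// out(i, j) = sum of x[0..i-1, 0..j-1] (0-based), so out is (nr+1) x (nc+1).
// [[Rcpp::export(name = ".cpp_integral_image")]]
NumericMatrix cpp_integral_image(NumericMatrix x) {
  int nr = x.nrow(), nc = x.ncol();
  NumericMatrix out(nr + 1, nc + 1);
  for (int j = 0; j < nc; ++j) {
    double colsum = 0.0;
    for (int i = 0; i < nr; ++i) {
      colsum += x(i, j);
      out(i + 1, j + 1) = out(i + 1, j) + colsum;
    }
  }
  return out;
}

static inline double rect_sum(const NumericMatrix& ii,
                              int top, int left, int h, int w) {
  // top/left are 1-based pixel coordinates of the rectangle's corner,
  // rectangle covers rows top..top+h-1, cols left..left+w-1.
  return ii(top + h - 1, left + w - 1) - ii(top - 1, left + w - 1)
       - ii(top + h - 1, left - 1)     + ii(top - 1, left - 1);
}

// Evaluate a pool of Haar-like features. `rects` has one row per signed
// sub-rectangle: (featureId [1-based], top, left, height, width, sign).
// [[Rcpp::export(name = ".cpp_haar_eval")]]
NumericVector cpp_haar_eval(NumericMatrix ii, IntegerMatrix rects, int nFeatures) {
  NumericVector out(nFeatures);
  int n = rects.nrow();
  for (int k = 0; k < n; ++k) {
    int f = rects(k, 0) - 1;
    out[f] += rects(k, 5) *
      rect_sum(ii, rects(k, 1), rects(k, 2), rects(k, 3), rects(k, 4));
  }
  return out;
}

// 8-neighbour LBP codes for interior pixels; neighbour order p = 0..7 is
// clockwise from the top-left: (-1,-1),(-1,0),(-1,1),(0,1),(1,1),(1,0),(1,-1),(0,-1).
// Ties (neighbour == centre) count as 1, matching the >= comparison.
// [[Rcpp::export(name = ".cpp_lbp_codes")]]
IntegerMatrix cpp_lbp_codes(NumericMatrix x) {
  int nr = x.nrow(), nc = x.ncol();
  if (nr < 3 || nc < 3) stop("patch must be at least 3x3 for LBP coding");
  static const int dr[8] = {-1, -1, -1, 0, 1, 1, 1, 0};
  static const int dc[8] = {-1, 0, 1, 1, 1, 0, -1, -1};
  IntegerMatrix out(nr - 2, nc - 2);
  for (int i = 1; i < nr - 1; ++i) {
    for (int j = 1; j < nc - 1; ++j) {
      double fc = x(i, j);
      int code = 0;
      for (int p = 0; p < 8; ++p)
        if (x(i + dr[p], j + dc[p]) >= fc) code |= (1 << p);
      out(i - 1, j - 1) = code;
    }
  }
  return out;
}

// Per-cell unsigned gradient-orientation histograms. Gradients are central
// differences with clamped (replicated) borders; orientation in [0, pi) is
// hard-binned; votes are gradient magnitudes. Returns an array
// (cellsR x cellsC x bins) flattened column-major with a dim attribute.
// [[Rcpp::export(name = ".cpp_hog_cells")]]
NumericVector cpp_hog_cells(NumericMatrix x, int cell, int bins) {
  int nr = x.nrow(), nc = x.ncol();
  int cr = nr / cell, cc = nc / cell;
  if (cr < 1 || cc < 1) stop("patch smaller than one HOG cell");
  NumericVector out(cr * cc * bins);
  double binw = M_PI / bins;
  for (int i = 0; i < cr * cell; ++i) {
    int ci = i / cell;
    for (int j = 0; j < cc * cell; ++j) {
      int cj = j / cell;
      int jm = j > 0 ? j - 1 : 0, jp = j < nc - 1 ? j + 1 : nc - 1;
      int im = i > 0 ? i - 1 : 0, ip = i < nr - 1 ? i + 1 : nr - 1;
      double fx = (x(i, jp) - x(i, jm)) / 2.0;
      double fy = (x(ip, j) - x(im, j)) / 2.0;
      double mag = std::sqrt(fx * fx + fy * fy);
      if (mag == 0.0) continue;
      double theta = std::atan2(fy, fx);
      if (theta < 0) theta += M_PI;
      if (theta >= M_PI) theta -= M_PI;
      int b = (int)(theta / binw);
      if (b >= bins) b = bins - 1;
      out[ci + cr * (cj + cc * b)] += mag;
    }
  }
  out.attr("dim") = IntegerVector::create(cr, cc, bins);
  return out;
}

// Exhaustive weighted decision-stump search. For every feature, every split
// between distinct sorted values (plus the all-0 / all-1 boundary splits) and
// both polarities are scanned; returns the stump minimising the weighted
// 0/1 error sum_i w_i |h(x_i) - y_i|. Among error ties the stump with the
// widest value gap at its threshold wins (features are assumed z-scored, so
// gaps are comparable across features); remaining ties keep the earliest
// candidate (lowest feature index, then lowest threshold). Features listed
// in `exclude` (1-based) are skipped.
// Polarity +1 predicts 1 when x >= threshold; -1 predicts 1 when x <= threshold.
// [[Rcpp::export(name = ".cpp_best_stump")]]
List cpp_best_stump(NumericMatrix X, IntegerVector y, NumericVector w,
                    IntegerVector exclude) {
  int n = X.nrow(), F = X.ncol();
  double W1 = 0.0, W0 = 0.0;
  for (int i = 0; i < n; ++i) (y[i] == 1 ? W1 : W0) += w[i];
  std::vector<bool> skip(F, false);
  for (int k = 0; k < exclude.size(); ++k)
    if (exclude[k] >= 1 && exclude[k] <= F) skip[exclude[k] - 1] = true;

  const double tol = 1e-12;
  double bestErr = R_PosInf, bestThr = 0.0, bestGap = -1.0;
  int bestFeat = -1, bestPol = 1;
  std::vector<int> ord(n);
  std::vector<double> v(n);

  for (int f = 0; f < F; ++f) {
    if (skip[f]) continue;
    for (int i = 0; i < n; ++i) { ord[i] = i; v[i] = X(i, f); }
    std::sort(ord.begin(), ord.end(),
              [&](int a, int b) { return v[a] < v[b]; });
    double cum1 = 0.0, cum0 = 0.0;
    // split index k: items with sorted rank < k fall on the "low" side
    for (int k = 0; k <= n; ++k) {
      if (k > 0 && k < n && v[ord[k - 1]] == v[ord[k]]) {
        int idx = ord[k - 1];
        (y[idx] == 1 ? cum1 : cum0) += w[idx];
        continue;
      }
      if (k > 0) {
        int idx = ord[k - 1];
        (y[idx] == 1 ? cum1 : cum0) += w[idx];
      }
      double thr, gap;
      if (k == 0)      { thr = v[ord[0]] - 1.0;     gap = 0.0; }
      else if (k == n) { thr = v[ord[n - 1]] + 1.0; gap = 0.0; }
      else {
        thr = (v[ord[k - 1]] + v[ord[k]]) / 2.0;
        gap = v[ord[k]] - v[ord[k - 1]];
      }
      // polarity +1: high side predicted 1 -> err = pos below + neg above
      double errPlus  = cum1 + (W0 - cum0);
      // polarity -1: low side predicted 1 -> err = neg below + pos above
      double errMinus = cum0 + (W1 - cum1);
      if (errPlus < bestErr - tol ||
          (errPlus < bestErr + tol && gap > bestGap + tol)) {
        bestErr = errPlus; bestFeat = f; bestThr = thr; bestPol = 1;
        bestGap = gap;
      }
      if (errMinus < bestErr - tol ||
          (errMinus < bestErr + tol && gap > bestGap + tol)) {
        bestErr = errMinus; bestFeat = f; bestThr = thr; bestPol = -1;
        bestGap = gap;
      }
    }
  }
  return List::create(_["feature"] = bestFeat + 1,
                      _["threshold"] = bestThr,
                      _["polarity"] = bestPol,
                      _["error"] = bestErr,
                      _["gap"] = bestGap);
}
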