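// Binary morphology and connected-component labelling for spectrogram masks.
// Masks are n_freq x n_time logical matrices; structuring elements are
// axis-aligned rectangles given by half-widths (rows = frequency, cols = time).
#include <Rcpp.h>
#include <vector>
#include <climits>
using namespace Rcpp;

// Sliding-window count along one dimension using prefix sums.
// mode 0: dilation (true if any true in window, out-of-range counts false)
// mode 1: erosion  (true if all in-range cells true; out-of-range counts true)
static void window_pass(const std::vector<char>& in, std::vector<char>& out,
                        int nr, int nc, int h, bool along_rows, int mode) {
  if (h <= 0) { out = in; return; }
  if (along_rows) {
    std::vector<int> S(nr + 1);
    for (int j = 0; j < nc; ++j) {
      const char* col = &in[(size_t)j * nr];
      S[0] = 0;
      for (int i = 0; i < nr; ++i) S[i + 1] = S[i] + (col[i] ? 1 : 0);
      char* oc = &out[(size_t)j * nr];
      for (int i = 0; i < nr; ++i) {
        int lo = std::max(0, i - h), hi = std::min(nr, i + h + 1);
        int cnt = S[hi] - S[lo];
        oc[i] = (mode == 0) ? (cnt > 0) : (cnt == hi - lo);
      }
    }
  } else {
    std::vector<int> S(nc + 1);
    for (int i = 0; i < nr; ++i) {
      S[0] = 0;
      for (int j = 0; j < nc; ++j) S[j + 1] = S[j] + (in[(size_t)j * nr + i] ? 1 : 0);
      for (int j = 0; j < nc; ++j) {
        int lo = std::max(0, j - h), hi = std::min(nc, j + h + 1);
        int cnt = S[hi] - S[lo];
        out[(size_t)j * nr + i] = (mode == 0) ? (cnt > 0) : (cnt == hi - lo);
      }
    }
  }
}

// Morphological closing (dilation then erosion) with a (2*hf+1) x (2*ht+1)
// rectangular structuring element. Erosion treats out-of-bounds as true so the
// result always contains the input mask.
// [[Rcpp::export]]
LogicalMatrix close_mask_cpp(LogicalMatrix mask, int hf, int ht) {
  int nr = mask.nrow(), nc = mask.ncol();
  std::vector<char> a((size_t)nr * nc), b((size_t)nr * nc);
  for (size_t k = 0; k < a.size(); ++k) a[k] = mask[k] ? 1 : 0;
  window_pass(a, b, nr, nc, hf, true, 0);
  window_pass(b, a, nr, nc, ht, false, 0);
  window_pass(a, b, nr, nc, hf, true, 1);
  window_pass(b, a, nr, nc, ht, false, 1);
  LogicalMatrix out(nr, nc);
  for (size_t k = 0; k < a.size(); ++k) out[k] = a[k] != 0;
  return out;
}

// Label connected components (4- or 8-connectivity) by flood fill.
// Returns an integer matrix of labels (0 = background) with attribute "n".
// [[Rcpp::export]]
IntegerMatrix label_components_cpp(LogicalMatrix mask, int connectivity) {
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix labels(nr, nc);
  std::vector<std::pair<int, int> > stack;
  int lab = 0;
  const int dr8[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int dc8[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  const int dr4[4] = {-1, 1, 0, 0};
  const int dc4[4] = {0, 0, -1, 1};
  int nnb = (connectivity == 4) ? 4 : 8;
  const int* dr = (connectivity == 4) ? dr4 : dr8;
  const int* dc = (connectivity == 4) ? dc4 : dc8;
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (!mask(i, j) || labels(i, j)) continue;
      ++lab;
      stack.clear();
      stack.push_back(std::make_pair(i, j));
      labels(i, j) = lab;
      while (!stack.empty()) {
        std::pair<int, int> p = stack.back();
        stack.pop_back();
        for (int k = 0; k < nnb; ++k) {
          int r = p.first + dr[k], c = p.second + dc[k];
          if (r < 0 || r >= nr || c < 0 || c >= nc) continue;
          if (mask(r, c) && !labels(r, c)) {
            labels(r, c) = lab;
            stack.push_back(std::make_pair(r, c));
          }
        }
      }
    }
  }
  labels.attr("n") = lab;
  return labels;
}

// Per-component bounding boxes and power statistics (1-based indices).
// pixel_count counts pixels of the pre-closing mask inside each component.
// [[Rcpp::export]]
DataFrame component_stats_cpp(IntegerMatrix labels, LogicalMatrix orig_mask,
                              NumericMatrix power, int n) {
  int nr = labels.nrow(), nc = labels.ncol();
  std::vector<int> rmin(n, INT_MAX), rmax(n, -1), cmin(n, INT_MAX), cmax(n, -1);
  std::vector<int> npix(n, 0), norig(n, 0);
  std::vector<double> peak(n, R_NegInf);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      int l = labels(i, j);
      if (!l) continue;
      int k = l - 1;
      if (i < rmin[k]) rmin[k] = i;
      if (i > rmax[k]) rmax[k] = i;
      if (j < cmin[k]) cmin[k] = j;
      if (j > cmax[k]) cmax[k] = j;
      ++npix[k];
      if (orig_mask(i, j)) ++norig[k];
      double p = power(i, j);
      if (p > peak[k]) peak[k] = p;
    }
  }
  IntegerVector R1(n), R2(n), C1(n), C2(n), NP(n), NO(n);
  NumericVector PK(n);
  for (int k = 0; k < n; ++k) {
    R1[k] = rmin[k] + 1; R2[k] = rmax[k] + 1;
    C1[k] = cmin[k] + 1; C2[k] = cmax[k] + 1;
    NP[k] = npix[k]; NO[k] = norig[k]; PK[k] = peak[k];
  }
  return DataFrame::create(_["row_min"] = R1, _["row_max"] = R2,
                           _["col_min"] = C1, _["col_max"] = C2,
                           _["n_closed"] = NP, _["pixel_count"] = NO,
                           _["peak_db"] = PK);
}
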