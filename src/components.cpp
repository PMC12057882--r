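#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Connected-component labeling of a class-coded grid. Two cells join the
// same patch when they carry the same class code and are adjacent under the
// requested connectivity (4 = edge, 8 = edge or corner). NA cells get
// label 0. Labels are positive integers, assigned in scan order.
// [[Rcpp::export(name = ".cpp_label_components")]]
IntegerMatrix cpp_label_components(IntegerMatrix values, int connectivity) {
  if (connectivity != 4 && connectivity != 8)
    stop("connectivity must be 4 or 8");
  const int nr = values.nrow(), nc = values.ncol();
  IntegerMatrix labels(nr, nc);
  std::fill(labels.begin(), labels.end(), 0);

  static const int dr8[8] = {-1, 1, 0, 0, -1, -1, 1, 1};
  static const int dc8[8] = {0, 0, -1, 1, -1, 1, -1, 1};
  const int ndir = (connectivity == 4) ? 4 : 8;

  int next_label = 0;
  std::vector<int> stack;
  stack.reserve(256);

  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (values(r, c) == NA_INTEGER || labels(r, c) != 0) continue;
      const int cls = values(r, c);
      ++next_label;
      labels(r, c) = next_label;
      stack.push_back(r + c * nr);
      while (!stack.empty()) {
        const int idx = stack.back();
        stack.pop_back();
        const int cr = idx % nr, cc = idx / nr;
        for (int d = 0; d < ndir; ++d) {
          const int rr = cr + dr8[d], ccn = cc + dc8[d];
          if (rr < 0 || rr >= nr || ccn < 0 || ccn >= nc) continue;
          if (labels(rr, ccn) != 0) continue;
          if (values(rr, ccn) == NA_INTEGER || values(rr, ccn) != cls)
            continue;
          labels(rr, ccn) = next_label;
          stack.push_back(rr + ccn * nr);
        }
      }
    }
  }
  return labels;
}

// 3x3 majority (modal) filter for class-coded grids. The centre cell keeps
// its class on ties (including the common case where no class strictly
// dominates the window); NA cells stay NA and do not vote.
// [[Rcpp::export(name = ".cpp_majority_filter")]]
IntegerMatrix cpp_majority_filter(IntegerMatrix values, int n_classes) {
  const int nr = values.nrow(), nc = values.ncol();
  IntegerMatrix out(nr, nc);
  std::vector<int> count(n_classes + 1, 0);

  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      const int centre = values(r, c);
      if (centre == NA_INTEGER) { out(r, c) = NA_INTEGER; continue; }
      std::fill(count.begin(), count.end(), 0);
      for (int dc = -1; dc <= 1; ++dc) {
        for (int dr = -1; dr <= 1; ++dr) {
          const int rr = r + dr, cc = c + dc;
          if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
          const int v = values(rr, cc);
          if (v == NA_INTEGER) continue;
          if (v >= 1 && v <= n_classes) ++count[v];
        }
      }
      int best = centre;
      // strict majority over the centre's own count is required to flip
      for (int k = 1; k <= n_classes; ++k)
        if (count[k] > count[best]) best = k;
      out(r, c) = best;
    }
  }
  return out;
}

// Per-cell Markov class update: cell with class i draws its next class from
// row i of the cumulative transition matrix, using uniforms supplied from R
// so that all randomness stays under R's seeded RNG.
// [[Rcpp::export(name = ".cpp_markov_step")]]
IntegerMatrix cpp_markov_step(IntegerMatrix values, NumericMatrix cumP,
                              NumericVector u) {
  const int nr = values.nrow(), nc = values.ncol();
  const int K = cumP.ncol();
  if ((int)u.size() != nr * nc) stop("need one uniform per cell");
  IntegerMatrix out(nr, nc);
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      const int idx = r + c * nr;
      const int cls = values(r, c);
      if (cls == NA_INTEGER) { out(r, c) = NA_INTEGER; continue; }
      const double x = u[idx];
      int nxt = K;
      for (int k = 0; k < K; ++k) {
        if (x <= cumP(cls - 1, k)) { nxt = k + 1; break; }
      }
      out(r, c) = nxt;
    }
  }
  return out;
}
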