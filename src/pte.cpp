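#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Joint-histogram entropy machinery for phase transfer entropy.
//
// Phases are pre-binned in R into integer codes 1..B. All entropies use the
// natural logarithm; empty cells contribute nothing (0 log 0 = 0). The
// estimator is
//   PTE(x -> y) = H(y_t, x_t) + H(y_td, y_t) - H(y_t) - H(y_td, y_t, x_t)
// with y_td the target phase delay samples ahead of y_t.

static double entropy_from_counts(const std::vector<int> &counts,
                                  const std::vector<int> &touched,
                                  double n) {
  double h = 0.0;
  for (size_t k = 0; k < touched.size(); ++k) {
    int c = counts[touched[k]];
    if (c > 0) {
      double p = c / n;
      h -= p * std::log(p);
    }
  }
  return h;
}

// Entropy of a single pre-binned sequence (codes 1..B).
static double entropy1(const int *b, int len, int B) {
  std::vector<int> counts(B, 0);
  for (int t = 0; t < len; ++t) counts[b[t] - 1]++;
  double h = 0.0, n = (double)len;
  for (int k = 0; k < B; ++k)
    if (counts[k] > 0) {
      double p = counts[k] / n;
      h -= p * std::log(p);
    }
  return h;
}

// Entropy of the joint (a, b) histogram.
static double entropy2(const int *a, const int *b, int len, int B,
                       std::vector<int> &counts, std::vector<int> &touched) {
  touched.clear();
  for (int t = 0; t < len; ++t) {
    int idx = (a[t] - 1) + B * (b[t] - 1);
    if (counts[idx]++ == 0) touched.push_back(idx);
  }
  double h = entropy_from_counts(counts, touched, (double)len);
  for (size_t k = 0; k < touched.size(); ++k) counts[touched[k]] = 0;
  return h;
}

// Entropy of the joint (a, b, c) histogram.
static double entropy3(const int *a, const int *b, const int *c, int len,
                       int B, std::vector<int> &counts,
                       std::vector<int> &touched) {
  touched.clear();
  for (int t = 0; t < len; ++t) {
    int idx = (a[t] - 1) + B * ((b[t] - 1) + B * (c[t] - 1));
    if (counts[idx]++ == 0) touched.push_back(idx);
  }
  double h = entropy_from_counts(counts, touched, (double)len);
  for (size_t k = 0; k < touched.size(); ++k) counts[touched[k]] = 0;
  return h;
}

// [[Rcpp::export]]
double pte_pair_cpp(IntegerVector bx, IntegerVector by, int delay, int B) {
  int n = bx.size();
  int len = n - delay;
  if (len < 2) stop("delay leaves fewer than 2 usable samples");
  const int *x = INTEGER(bx);
  const int *y = INTEGER(by);
  const int *ytd = y + delay;
  std::vector<int> counts((size_t)B * B * B, 0);
  std::vector<int> touched;
  touched.reserve(len);
  double h_y = entropy1(y, len, B);
  double h_yx = entropy2(y, x, len, B, counts, touched);
  double h_ydy = entropy2(ytd, y, len, B, counts, touched);
  double h_ydyx = entropy3(ytd, y, x, len, B, counts, touched);
  return h_yx + h_ydy - h_y - h_ydyx;
}

// All-pairs PTE from a nodes x samples matrix of bin codes. Entry (i, j) is
// the flow node i -> node j; the diagonal is zero.
// [[Rcpp::export]]
NumericMatrix pte_matrix_cpp(IntegerMatrix bins, int delay, int B) {
  int n_nodes = bins.nrow();
  int n = bins.ncol();
  int len = n - delay;
  if (len < 2) stop("delay leaves fewer than 2 usable samples");

  // column-major access: copy rows into contiguous buffers once
  std::vector<std::vector<int>> node(n_nodes, std::vector<int>(n));
  for (int i = 0; i < n_nodes; ++i)
    for (int t = 0; t < n; ++t) node[i][t] = bins(i, t);

  std::vector<int> counts((size_t)B * B * B, 0);
  std::vector<int> touched;
  touched.reserve(len);

  // per-target terms reused across all sources
  std::vector<double> h_y(n_nodes), h_ydy(n_nodes);
  for (int j = 0; j < n_nodes; ++j) {
    const int *y = node[j].data();
    h_y[j] = entropy1(y, len, B);
    h_ydy[j] = entropy2(y + delay, y, len, B, counts, touched);
  }

  NumericMatrix out(n_nodes, n_nodes);
  for (int i = 0; i < n_nodes; ++i) {
    const int *x = node[i].data();
    for (int j = 0; j < n_nodes; ++j) {
      if (i == j) continue;
      const int *y = node[j].data();
      double h_yx = entropy2(y, x, len, B, counts, touched);
      double h_ydyx = entropy3(y + delay, y, x, len, B, counts, touched);
      out(i, j) = h_yx + h_ydy[j] - h_y[j] - h_ydyx;
    }
  }
  return out;
}
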