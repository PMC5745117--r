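#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Union-find with path compression
static int uf_find(std::vector<int> &parent, int i) {
  while (parent[i] != i) {
    parent[i] = parent[parent[i]];
    i = parent[i];
  }
  return i;
}

static void uf_union(std::vector<int> &parent, int a, int b) {
  int ra = uf_find(parent, a), rb = uf_find(parent, b);
  if (ra < rb) parent[rb] = ra; else if (rb < ra) parent[ra] = rb;
}

// Connected-component labelling of a logical matrix.
// connectivity: 4 or 8. Labels are 1..k in order of first occurrence
// (column-major, matching R's matrix layout); background stays 0.
// [[Rcpp::export(name = ".ccLabelCpp")]]
IntegerMatrix ccLabelCpp(LogicalMatrix fg, int connectivity) {
  int nr = fg.nrow(), nc = fg.ncol(), n = nr * nc;
  std::vector<int> parent(n);
  for (int i = 0; i < n; ++i) parent[i] = i;

  // two-pass: link each foreground pixel to already-visited neighbours
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      int i = c * nr + r;
      if (!fg(r, c)) continue;
      if (r > 0 && fg(r - 1, c)) uf_union(parent, i, i - 1);
      if (c > 0 && fg(r, c - 1)) uf_union(parent, i, i - nr);
      if (connectivity == 8) {
        if (r > 0 && c > 0 && fg(r - 1, c - 1)) uf_union(parent, i, i - nr - 1);
        if (r < nr - 1 && c > 0 && fg(r + 1, c - 1)) uf_union(parent, i, i - nr + 1);
      }
    }
  }

  IntegerMatrix lab(nr, nc);
  std::vector<int> remap(n, 0);
  int k = 0;
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (!fg(r, c)) continue;
      int root = uf_find(parent, c * nr + r);
      if (remap[root] == 0) remap[root] = ++k;
      lab(r, c) = remap[root];
    }
  }
  return lab;
}

// Weighted (masked) separable Gaussian blur: conv(x*w) / conv(w).
// Pixels where the accumulated weight is zero are returned as 0.
// [[Rcpp::export(name = ".gaussBlurMaskedCpp")]]
NumericMatrix gaussBlurMaskedCpp(NumericMatrix x, NumericMatrix w, double sigma) {
  int nr = x.nrow(), nc = x.ncol();
  int half = (int) std::ceil(3.0 * sigma);
  std::vector<double> kern(2 * half + 1);
  double s = 0.0;
  for (int i = -half; i <= half; ++i) {
    kern[i + half] = std::exp(-0.5 * (double) i * i / (sigma * sigma));
    s += kern[i + half];
  }
  for (size_t i = 0; i < kern.size(); ++i) kern[i] /= s;

  NumericMatrix xw(nr, nc), ww(nr, nc);
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r) {
      xw(r, c) = x(r, c) * w(r, c);
      ww(r, c) = w(r, c);
    }

  // columns pass
  NumericMatrix tx(nr, nc), tw(nr, nc);
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      double ax = 0.0, aw = 0.0;
      int lo = std::max(0, r - half), hi = std::min(nr - 1, r + half);
      for (int j = lo; j <= hi; ++j) {
        double kv = kern[j - r + half];
        ax += kv * xw(j, c);
        aw += kv * ww(j, c);
      }
      tx(r, c) = ax; tw(r, c) = aw;
    }
  }
  // rows pass
  NumericMatrix out(nr, nc);
  for (int r = 0; r < nr; ++r) {
    for (int c = 0; c < nc; ++c) {
      double ax = 0.0, aw = 0.0;
      int lo = std::max(0, c - half), hi = std::min(nc - 1, c + half);
      for (int j = lo; j <= hi; ++j) {
        double kv = kern[j - c + half];
        ax += kv * tx(r, j);
        aw += kv * tw(r, j);
      }
      out(r, c) = (aw > 0.0) ? ax / aw : 0.0;
    }
  }
  return out;
}

// Nearest labelled point for each query pixel (Euclidean distance on pixel
// centres); ties broken toward the lowest point index.
// [[Rcpp::export(name = ".nearestPointCpp")]]
IntegerVector nearestPointCpp(NumericVector qr, NumericVector qc,
                              NumericVector pr, NumericVector pc) {
  int nq = qr.size(), np = pr.size();
  IntegerVector idx(nq);
  for (int i = 0; i < nq; ++i) {
    double best = R_PosInf;
    int bestj = 0;
    for (int j = 0; j < np; ++j) {
      double dr = qr[i] - pr[j], dc = qc[i] - pc[j];
      double d = dr * dr + dc * dc;
      if (d < best) { best = d; bestj = j; }
    }
    idx[i] = bestj + 1;
  }
  return idx;
}
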