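#include <Rcpp.h>
#include <queue>
using namespace Rcpp;

// Zhang-Suen thinning of a 0/1 integer matrix. The caller must guarantee an
// empty 1-pixel border (pad before calling); the result is an 8-connected,
// topology-preserving, 1-px-wide medial skeleton.
// [[Rcpp::export]]
IntegerMatrix zs_thin_cpp(IntegerMatrix img) {
  int nr = img.nrow(), nc = img.ncol();
  IntegerMatrix m = clone(img);
  // active foreground list: pixels are only ever deleted, never added
  std::vector<std::pair<int, int> > fg;
  for (int j = 1; j < nc - 1; ++j)
    for (int i = 1; i < nr - 1; ++i)
      if (m(i, j)) fg.push_back(std::make_pair(i, j));
  std::vector<std::pair<int, int> > del;
  bool changed = true;
  while (changed) {
    changed = false;
    for (int step = 0; step < 2; ++step) {
      del.clear();
      for (size_t k = 0; k < fg.size(); ++k) {
        {
          int i = fg[k].first, j = fg[k].second;
          if (!m(i, j)) continue;
          int p2 = m(i - 1, j),     p3 = m(i - 1, j + 1), p4 = m(i, j + 1),
              p5 = m(i + 1, j + 1), p6 = m(i + 1, j),     p7 = m(i + 1, j - 1),
              p8 = m(i, j - 1),     p9 = m(i - 1, j - 1);
          int B = p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9;
          if (B < 2 || B > 6) continue;
          int A = (p2 == 0 && p3 == 1) + (p3 == 0 && p4 == 1) +
                  (p4 == 0 && p5 == 1) + (p5 == 0 && p6 == 1) +
                  (p6 == 0 && p7 == 1) + (p7 == 0 && p8 == 1) +
                  (p8 == 0 && p9 == 1) + (p9 == 0 && p2 == 1);
          if (A != 1) continue;
          if (step == 0) {
            if (p2 * p4 * p6 != 0 || p4 * p6 * p8 != 0) continue;
          } else {
            if (p2 * p4 * p8 != 0 || p2 * p6 * p8 != 0) continue;
          }
          del.push_back(std::make_pair(i, j));
        }
      }
      if (!del.empty()) changed = true;
      for (size_t k = 0; k < del.size(); ++k) m(del[k].first, del[k].second) = 0;
    }
    // compact the active list every sweep pair
    size_t w = 0;
    for (size_t k = 0; k < fg.size(); ++k)
      if (m(fg[k].first, fg[k].second)) fg[w++] = fg[k];
    fg.resize(w);
  }
  return m;
}

// Connected-component labelling (BFS), connectivity 4 or 8.
// [[Rcpp::export]]
IntegerMatrix label_components_cpp(IntegerMatrix img, int connectivity) {
  int nr = img.nrow(), nc = img.ncol();
  IntegerMatrix lab(nr, nc);
  int next = 0;
  const int dx8[] = {-1, 1, 0, 0, -1, -1, 1, 1};
  const int dy8[] = {0, 0, -1, 1, -1, 1, -1, 1};
  int ndir = (connectivity == 8) ? 8 : 4;
  std::queue<std::pair<int, int> > q;
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (!img(i, j) || lab(i, j)) continue;
      lab(i, j) = ++next;
      q.push(std::make_pair(i, j));
      while (!q.empty()) {
        std::pair<int, int> p = q.front(); q.pop();
        for (int d = 0; d < ndir; ++d) {
          int ii = p.first + dx8[d], jj = p.second + dy8[d];
          if (ii < 0 || ii >= nr || jj < 0 || jj >= nc) continue;
          if (img(ii, jj) && !lab(ii, jj)) {
            lab(ii, jj) = next;
            q.push(std::make_pair(ii, jj));
          }
        }
      }
    }
  }
  return lab;
}

// Stamp filled discs of radius r[k] centred at (row[k], col[k]) (1-based,
// fractional allowed) onto a canvas; used by the synthetic stroke renderer.
// [[Rcpp::export]]
IntegerMatrix stamp_discs_cpp(IntegerMatrix canvas, NumericVector row,
                              NumericVector col, NumericVector r) {
  int nr = canvas.nrow(), nc = canvas.ncol();
  IntegerMatrix m = clone(canvas);
  for (int k = 0; k < row.size(); ++k) {
    double cy = row[k] - 1.0, cx = col[k] - 1.0, rad = r[k];
    if (rad < 0.5) rad = 0.5;
    int i0 = std::max(0, (int)std::floor(cy - rad)),
        i1 = std::min(nr - 1, (int)std::ceil(cy + rad)),
        j0 = std::max(0, (int)std::floor(cx - rad)),
        j1 = std::min(nc - 1, (int)std::ceil(cx + rad));
    double r2 = rad * rad;
    for (int j = j0; j <= j1; ++j) {
      double dx = j - cx;
      for (int i = i0; i <= i1; ++i) {
        double dy = i - cy;
        if (dx * dx + dy * dy <= r2) m(i, j) = 1;
      }
    }
  }
  return m;
}

// Nearest-neighbour inverse-mapped rotation (degrees, about the input centre)
// plus isotropic scaling, onto an output canvas large enough to hold the
// transformed input; background fills with 0 so binary masks stay binary.
// [[Rcpp::export]]
IntegerMatrix affine_nn_cpp(IntegerMatrix img, double angle_deg, double scale,
                            int out_nr, int out_nc) {
  int nr = img.nrow(), nc = img.ncol();
  IntegerMatrix out(out_nr, out_nc);
  double th = angle_deg * M_PI / 180.0;
  double ct = std::cos(th), st = std::sin(th);
  double icy = (nr - 1) / 2.0, icx = (nc - 1) / 2.0;
  double ocy = (out_nr - 1) / 2.0, ocx = (out_nc - 1) / 2.0;
  for (int j = 0; j < out_nc; ++j) {
    double x = j - ocx;
    for (int i = 0; i < out_nr; ++i) {
      double y = i - ocy;
      // inverse transform: rotate by -angle, scale by 1/scale
      double xs = (ct * x + st * y) / scale;
      double ys = (-st * x + ct * y) / scale;
      int ii = (int)std::floor(ys + icy + 0.5);
      int jj = (int)std::floor(xs + icx + 0.5);
      if (ii >= 0 && ii < nr && jj >= 0 && jj < nc) out(i, j) = img(ii, jj);
    }
  }
  return out;
}
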