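#include <Rcpp.h>
using namespace Rcpp;

// Two-pass connected-component labeling with union-find.
// Input: logical/integer matrix (nonzero = foreground), connectivity 4 or 8.
// Output: integer matrix with labels 1..n assigned in raster-scan order of
// each component's first pixel, so labeling is deterministic.

static int find_root(std::vector<int> &parent, int i) {
  while (parent[i] != i) {
    parent[i] = parent[parent[i]];
    i = parent[i];
  }
  return i;
}

static void unite(std::vector<int> &parent, int a, int b) {
  int ra = find_root(parent, a), rb = find_root(parent, b);
  if (ra < rb) parent[rb] = ra; else parent[ra] = rb;
}

// [[Rcpp::export(name = ".label_components")]]
IntegerMatrix label_components(const LogicalMatrix &mask, int connectivity) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  std::vector<int> parent(1, 0); // parent[0] unused
  int next = 1;

  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (!mask(i, j)) continue;
      int up   = (i > 0 && mask(i - 1, j)) ? lab(i - 1, j) : 0;
      int left = (j > 0 && mask(i, j - 1)) ? lab(i, j - 1) : 0;
      int ul = 0, dl = 0;
      if (connectivity == 8) {
        ul = (i > 0 && j > 0 && mask(i - 1, j - 1)) ? lab(i - 1, j - 1) : 0;
        dl = (i < nr - 1 && j > 0 && mask(i + 1, j - 1)) ? lab(i + 1, j - 1) : 0;
      }
      int nb[4] = {up, left, ul, dl};
      int assigned = 0;
      for (int k = 0; k < 4; ++k)
        if (nb[k] > 0) assigned = assigned ? std::min(assigned, nb[k]) : nb[k];
      if (assigned == 0) {
        parent.push_back(next);
        assigned = next++;
      } else {
        for (int k = 0; k < 4; ++k)
          if (nb[k] > 0 && nb[k] != assigned) unite(parent, nb[k], assigned);
      }
      lab(i, j) = assigned;
    }
  }

  // Resolve equivalences and relabel consecutively in first-appearance order.
  std::vector<int> remap(next, 0);
  int count = 0;
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      int l = lab(i, j);
      if (!l) continue;
      int r = find_root(parent, l);
      if (!remap[r]) remap[r] = ++count;
      lab(i, j) = remap[r];
    }
  lab.attr("n") = count;
  return lab;
}

// Fill capsule (stadium) shape into an intensity matrix: pixels whose center
// lies within distance `radius` of the segment (x1,y1)-(x2,y2) are set to
// `value`. Coordinates in pixel units, pixel centers at (col-0.5, row-0.5).
// [[Rcpp::export(name = ".fill_capsule")]]
void fill_capsule(NumericMatrix img, double x1, double y1, double x2, double y2,
                  double radius, double value) {
  const int nr = img.nrow(), nc = img.ncol();
  double xmin = std::min(x1, x2) - radius, xmax = std::max(x1, x2) + radius;
  double ymin = std::min(y1, y2) - radius, ymax = std::max(y1, y2) + radius;
  int c0 = std::max(0, (int)std::floor(xmin)), c1 = std::min(nc - 1, (int)std::ceil(xmax));
  int r0 = std::max(0, (int)std::floor(ymin)), r1 = std::min(nr - 1, (int)std::ceil(ymax));
  double dx = x2 - x1, dy = y2 - y1;
  double len2 = dx * dx + dy * dy;
  double r2 = radius * radius;
  for (int c = c0; c <= c1; ++c) {
    double px = c + 0.5;
    for (int r = r0; r <= r1; ++r) {
      double py = r + 0.5;
      double t = len2 > 0 ? ((px - x1) * dx + (py - y1) * dy) / len2 : 0.0;
      if (t < 0) t = 0; else if (t > 1) t = 1;
      double ex = px - (x1 + t * dx), ey = py - (y1 + t * dy);
      if (ex * ex + ey * ey <= r2) img(r, c) = value;
    }
  }
}
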