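#include <Rcpp.h>
using namespace Rcpp;

// 3D connected-component labelling of a logical mask stored as an R array
// with dim = (nz, ny, nx), i.e. plane index varies fastest. Connectivity is
// 6 (faces), 18 (faces+edges) or 26 (full). Labels are assigned in
// raster-scan order of the first voxel of each component, so the labelling
// is deterministic for a given mask.
// [[Rcpp::export]]
IntegerVector cc_label3d(LogicalVector mask, IntegerVector dim, int connectivity = 26) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  const R_xlen_t n = (R_xlen_t)nz * ny * nx;
  if (mask.size() != n) stop("mask length does not match dim");
  if (connectivity != 6 && connectivity != 18 && connectivity != 26)
    stop("connectivity must be 6, 18 or 26");

  std::vector<int> dzs, dys, dxs;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        int m = std::abs(dz) + std::abs(dy) + std::abs(dx);
        if (m == 0) continue;
        if (connectivity == 6 && m > 1) continue;
        if (connectivity == 18 && m > 2) continue;
        dzs.push_back(dz); dys.push_back(dy); dxs.push_back(dx);
      }

  IntegerVector lab(n);
  std::vector<R_xlen_t> todo;
  int next = 0;
  for (R_xlen_t i = 0; i < n; ++i) {
    if (mask[i] == TRUE && lab[i] == 0) {
      ++next;
      lab[i] = next;
      todo.push_back(i);
      while (!todo.empty()) {
        R_xlen_t v = todo.back(); todo.pop_back();
        int z = (int)(v % nz);
        R_xlen_t r = v / nz;
        int y = (int)(r % ny);
        int x = (int)(r / ny);
        for (size_t k = 0; k < dzs.size(); ++k) {
          int z2 = z + dzs[k], y2 = y + dys[k], x2 = x + dxs[k];
          if (z2 < 0 || z2 >= nz || y2 < 0 || y2 >= ny || x2 < 0 || x2 >= nx) continue;
          R_xlen_t j = (R_xlen_t)z2 + (R_xlen_t)nz * ((R_xlen_t)y2 + (R_xlen_t)ny * x2);
          if (mask[j] == TRUE && lab[j] == 0) { lab[j] = next; todo.push_back(j); }
        }
      }
    }
  }
  lab.attr("dim") = dim;
  return lab;
}

// Minimum Euclidean distance between two point sets (rows are physical
// coordinates in um). Used for the voxel-centre gap in the
// colocalized/adjacent/distant classifier.
// [[Rcpp::export]]
double min_pair_dist(NumericMatrix a, NumericMatrix b) {
  if (a.ncol() != 3 || b.ncol() != 3) stop("expected n x 3 coordinate matrices");
  double best = R_PosInf;
  for (int i = 0; i < a.nrow(); ++i) {
    const double ax = a(i, 0), ay = a(i, 1), az = a(i, 2);
    for (int j = 0; j < b.nrow(); ++j) {
      const double dx = ax - b(j, 0), dy = ay - b(j, 1), dz = az - b(j, 2);
      const double d = dx * dx + dy * dy + dz * dz;
      if (d < best) {
        best = d;
        if (best == 0.0) return 0.0;
      }
    }
  }
  return std::sqrt(best);
}
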