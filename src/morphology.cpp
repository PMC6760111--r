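#include <Rcpp.h>
#include <queue>
using namespace Rcpp;

// Flat morphological transform of a binary voxel grid by an explicit offset
// set. Out-of-grid neighbours count as background (0), so erosion shrinks
// at the volume border and dilation never wraps.
// [[Rcpp::export]]
IntegerVector cpp_morph(IntegerVector mask, IntegerVector dims,
                        IntegerMatrix offsets, bool dilate) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int no = offsets.nrow();
  IntegerVector out(mask.size());
  for (int z = 0; z < nz; ++z) {
    for (int y = 0; y < ny; ++y) {
      for (int x = 0; x < nx; ++x) {
        int acc = dilate ? 0 : 1;
        for (int k = 0; k < no; ++k) {
          int xi = x + offsets(k, 0);
          int yi = y + offsets(k, 1);
          int zi = z + offsets(k, 2);
          int v = 0;
          if (xi >= 0 && xi < nx && yi >= 0 && yi < ny && zi >= 0 && zi < nz)
            v = mask[xi + (size_t)nx * (yi + (size_t)ny * zi)];
          if (dilate) { if (v) { acc = 1; break; } }
          else        { if (!v) { acc = 0; break; } }
        }
        out[x + (size_t)nx * (y + (size_t)ny * z)] = acc;
      }
    }
  }
  out.attr("dim") = dims;
  return out;
}

// Connected-component labelling of a 3D binary grid (6- or 26-connectivity).
// [[Rcpp::export]]
IntegerVector cpp_label3d(IntegerVector mask, IntegerVector dims,
                          int connectivity) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const size_t n = (size_t)nx * ny * nz;
  IntegerVector lab(mask.size());
  std::vector<std::array<int,3> > offs;
  if (connectivity == 6) {
    int six[6][3] = {{1,0,0},{-1,0,0},{0,1,0},{0,-1,0},{0,0,1},{0,0,-1}};
    for (int i = 0; i < 6; ++i) offs.push_back({six[i][0], six[i][1], six[i][2]});
  } else {
    for (int dz = -1; dz <= 1; ++dz)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dx = -1; dx <= 1; ++dx)
          if (dx || dy || dz) offs.push_back({dx, dy, dz});
  }
  int next = 0;
  std::queue<size_t> q;
  for (size_t s = 0; s < n; ++s) {
    if (!mask[s] || lab[s]) continue;
    lab[s] = ++next;
    q.push(s);
    while (!q.empty()) {
      size_t c = q.front(); q.pop();
      int x = c % nx, y = (c / nx) % ny, z = c / ((size_t)nx * ny);
      for (size_t k = 0; k < offs.size(); ++k) {
        int xi = x + offs[k][0], yi = y + offs[k][1], zi = z + offs[k][2];
        if (xi < 0 || xi >= nx || yi < 0 || yi >= ny || zi < 0 || zi >= nz)
          continue;
        size_t idx = xi + (size_t)nx * (yi + (size_t)ny * zi);
        if (mask[idx] && !lab[idx]) { lab[idx] = next; q.push(idx); }
      }
    }
  }
  lab.attr("dim") = dims;
  return lab;
}

// Directed Hausdorff distance max_{a in A} min_{b in B} |a - b| over
// physical point coordinates (rows are points, columns x/y/z in mm).
// [[Rcpp::export]]
double cpp_directed_hausdorff(NumericMatrix A, NumericMatrix B) {
  const int na = A.nrow(), nb = B.nrow();
  double hmax = 0.0;
  for (int i = 0; i < na; ++i) {
    double dmin = R_PosInf;
    const double ax = A(i,0), ay = A(i,1), az = A(i,2);
    for (int j = 0; j < nb; ++j) {
      double dx = ax - B(j,0), dy = ay - B(j,1), dz = az - B(j,2);
      double d2 = dx*dx + dy*dy + dz*dz;
      if (d2 < dmin) dmin = d2;
      if (dmin == 0.0) break;
    }
    if (dmin > hmax) hmax = dmin;
  }
  return std::sqrt(hmax);
}

// Composite smoothing primitives over the four discrete line segments of
// length k (horizontal, vertical, two diagonals, in-plane):
// op = 0: sup of erosions  (a voxel survives if SOME full line fits inside)
// op = 1: inf of dilations (a voxel joins if EVERY line touches the mask)
// [[Rcpp::export]]
IntegerVector cpp_line_morph(IntegerVector mask, IntegerVector dims,
                             int k, int op) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int h = (k - 1) / 2;
  const int dirs[4][2] = {{1,0},{0,1},{1,1},{1,-1}};
  IntegerVector out(mask.size());
  for (int z = 0; z < nz; ++z) {
    const size_t zoff = (size_t)nx * ny * z;
    for (int y = 0; y < ny; ++y) {
      for (int x = 0; x < nx; ++x) {
        int res = (op == 0) ? 0 : 1;
        for (int d = 0; d < 4; ++d) {
          int line;
          if (op == 0) {          // erosion by this line: all voxels set
            line = 1;
            for (int s = -h; s <= h && line; ++s) {
              int xi = x + s * dirs[d][0], yi = y + s * dirs[d][1];
              if (xi < 0 || xi >= nx || yi < 0 || yi >= ny ||
                  !mask[zoff + xi + (size_t)nx * yi]) line = 0;
            }
            if (line) { res = 1; break; }
          } else {                // dilation by this line: any voxel set
            line = 0;
            for (int s = -h; s <= h && !line; ++s) {
              int xi = x + s * dirs[d][0], yi = y + s * dirs[d][1];
              if (xi >= 0 && xi < nx && yi >= 0 && yi < ny &&
                  mask[zoff + xi + (size_t)nx * yi]) line = 1;
            }
            if (!line) { res = 0; break; }
          }
        }
        out[zoff + x + (size_t)nx * y] = res;
      }
    }
  }
  out.attr("dim") = dims;
  return out;
}
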