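// 3D binary morphology: 6-connected component labelling, 6-neighbourhood
// erosion, and dilation by an arbitrary offset set (e.g. a Euclidean ball).

#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Labels 6-connected foreground components 1..K in the order of the first
// voxel encountered in a linear (x-fastest) scan.
// [[Rcpp::export]]
IntegerVector cc_label6_cpp(IntegerVector mask, IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  if (mask.size() != n) stop("mask length does not match dims");
  IntegerVector lab(n, 0);
  std::vector<R_xlen_t> stack_;
  int next = 0;
  const R_xlen_t sx = 1, sy = nx, sz = (R_xlen_t)nx * ny;
  for (R_xlen_t i = 0; i < n; ++i) {
    if (mask[i] == 0 || lab[i] != 0) continue;
    ++next;
    lab[i] = next;
    stack_.push_back(i);
    while (!stack_.empty()) {
      const R_xlen_t v = stack_.back();
      stack_.pop_back();
      const int x = v % nx, y = (v / nx) % ny, z = v / sz;
      const R_xlen_t nb[6] = {v - sx, v + sx, v - sy, v + sy, v - sz, v + sz};
      const bool ok[6] = {x > 0, x < nx - 1, y > 0, y < ny - 1, z > 0, z < nz - 1};
      for (int k = 0; k < 6; ++k) {
        if (!ok[k]) continue;
        const R_xlen_t w = nb[k];
        if (mask[w] != 0 && lab[w] == 0) {
          lab[w] = next;
          stack_.push_back(w);
        }
      }
    }
  }
  lab.attr("n_components") = next;
  return lab;
}

// [[Rcpp::export]]
LogicalVector erode6_cpp(LogicalVector mask, IntegerVector dim, int iters) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  if (mask.size() != n) stop("mask length does not match dims");
  std::vector<char> cur(mask.begin(), mask.end()), nxt(n);
  const R_xlen_t sz = (R_xlen_t)nx * ny;
  for (int it = 0; it < iters; ++it) {
    for (R_xlen_t i = 0; i < n; ++i) {
      if (!cur[i]) { nxt[i] = 0; continue; }
      const int x = i % nx, y = (i / nx) % ny, z = i / sz;
      bool keep = x > 0 && x < nx - 1 && y > 0 && y < ny - 1 && z > 0 && z < nz - 1;
      if (keep)
        keep = cur[i - 1] && cur[i + 1] && cur[i - nx] && cur[i + nx] &&
               cur[i - sz] && cur[i + sz];
      nxt[i] = keep ? 1 : 0;
    }
    cur.swap(nxt);
  }
  LogicalVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = cur[i] != 0;
  return out;
}

// Dilation: out = union over offsets of the shifted mask. offsets is an
// n_off x 3 matrix of integer voxel displacements.
// [[Rcpp::export]]
LogicalVector dilate_offsets_cpp(LogicalVector mask, IntegerVector dim,
                                 IntegerMatrix offsets) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  if (mask.size() != n) stop("mask length does not match dims");
  LogicalVector out(n, false);
  std::vector<R_xlen_t> fg;
  for (R_xlen_t i = 0; i < n; ++i)
    if (mask[i]) fg.push_back(i);
  const int noff = offsets.nrow();
  for (int k = 0; k < noff; ++k) {
    const int dx = offsets(k, 0), dy = offsets(k, 1), dz = offsets(k, 2);
    for (const R_xlen_t v : fg) {
      const int x = v % nx + dx;
      if (x < 0 || x >= nx) continue;
      const int y = (v / nx) % ny + dy;
      if (y < 0 || y >= ny) continue;
      const int z = v / ((R_xlen_t)nx * ny) + dz;
      if (z < 0 || z >= nz) continue;
      out[x + (R_xlen_t)nx * (y + (R_xlen_t)ny * z)] = true;
    }
  }
  return out;
}
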